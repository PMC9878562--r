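# Tracklet decomposition and instantaneous motility measures.
#
# A tracklet is a fixed-length window of W consecutive frames of one track.
# Per tracklet we compute displacement D (straight-line start to end, um),
# path length L (sum of step lengths, um), velocity v = L / elapsed time
# (um/min), the continuous arrest coefficient A (fraction of steps whose
# instantaneous speed is below v_arrest -- the proportion of time the cell
# does not move), and directionality Gamma (straightness D/L; for
# near-stationary tracklets with L below eps_path, the coherence of the
# polarity vectors when available, else 0).

#' Tracklet decomposition and metric parameters
#'
#' @param W Tracklet window length in frames (>= 2). Default 10 frames,
#'   i.e. 3.3 min at 20 s sampling -- a timescale on which lymphocyte
#'   turning and pausing are visible.
#' @param stride Frames between consecutive tracklet starts (1..W). The
#'   default, `W`, gives disjoint windows so that sampled tracklets are not
#'   autocorrelated duplicates.
#' @param v_arrest Arrest threshold in um/min: a step slower than this
#'   counts as "not moving". Default 2 um/min, below typical motile
#'   lymphocyte speeds but above positional jitter.
#' @param eps_path Path-length floor in um below which D/L is considered
#'   numerically meaningless and the polarity fallback (or 0) is used for
#'   directionality. Default 1 um.
#' @param polarity_fallback Use polarity-vector coherence as the
#'   directionality of near-stationary tracklets when polarity data are
#'   present (captures visibly polarized but arrested cells).
#' @return A `tracklet_config` list.
#' @export
tracklet_config <- function(W = 10L, stride = NULL, v_arrest = 2,
                            eps_path = 1, polarity_fallback = TRUE) {
  W <- as.integer(W)
  stride <- as.integer(stride %||% W)
  if (is.na(W) || W < 2L) stop_config("W must be an integer >= 2")
  if (is.na(stride) || stride < 1L || stride > W) {
    stop_config("stride must be an integer in 1..W")
  }
  if (!is_number(v_arrest) || v_arrest <= 0) stop_config("v_arrest must be > 0")
  if (!is_number(eps_path) || eps_path <= 0) stop_config("eps_path must be > 0")
  if (!is_flag(polarity_fallback)) stop_config("polarity_fallback must be TRUE/FALSE")
  structure(list(W = W, stride = stride, v_arrest = v_arrest,
                 eps_path = eps_path, polarity_fallback = polarity_fallback),
            class = "tracklet_config")
}

#' Decompose tracks into fixed-length tracklets
#'
#' Per cell, windows of `W` frames starting at frames 0, stride, 2*stride,
#' ... are cut while a full window fits. Cells shorter than `W` frames
#' yield no tracklets (a message reports how many were skipped). The input
#' must be on a uniform time grid (see [regularize()]).
#'
#' @param table A regularized `track_table`.
#' @param cfg A [tracklet_config()].
#' @return A long tibble with one row per (tracklet, frame): `tracklet_id`,
#'   `cell_id`, `group`, `start_frame`, `step` (0..W-1), `frame`, `t`,
#'   positions and any polarity columns. The config is attached as
#'   attribute `"tracklet_config"`.
#' @export
decompose_tracklets <- function(table, cfg = tracklet_config()) {
  stopifnot(inherits(cfg, "tracklet_config"))
  validate_tracks(table, require_uniform_dt = TRUE)
  tab <- as_tibble(table)
  keep <- intersect(c("cell_id", "group", "frame", "t", "x", "y", "z",
                      POLARITY_COLS), names(tab))
  tab <- tab[, keep, drop = FALSE]
  W <- cfg$W
  s <- cfg$stride
  n_short <- 0L
  pieces <- lapply(split(tab, tab$cell_id), function(cc) {
    n <- nrow(cc)
    if (n < W) {
      n_short <<- n_short + 1L
      return(NULL)
    }
    starts <- seq.int(1L, n - W + 1L, by = s)
    rows <- rep(starts, each = W) + rep(0:(W - 1L), times = length(starts))
    out <- cc[rows, , drop = FALSE]
    out$start_frame <- rep(cc$frame[starts], each = W)
    out$step <- rep(0:(W - 1L), times = length(starts))
    out$tracklet_id <- sprintf("%s.f%05d", out$cell_id, out$start_frame)
    out
  })
  if (n_short > 0) {
    message("decompose_tracklets: ", n_short, " cell(s) shorter than W = ",
            W, " frames yielded no tracklets")
  }
  out <- bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble(tracklet_id = character(), cell_id = character(),
                  group = character(), start_frame = integer(),
                  step = integer(), frame = integer(), t = numeric(),
                  x = numeric(), y = numeric())
  } else {
    front <- c("tracklet_id", "cell_id", "group", "start_frame", "step")
    out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  }
  attr(out, "tracklet_config") <- cfg
  out
}

# Extract a (W x n_tracklets) matrix for one column of a tracklet table
# whose rows are ordered tracklet-blockwise with step ascending.
tracklet_matrix <- function(tracklets, col, W) {
  matrix(tracklets[[col]], nrow = W)
}

#' Motility metrics for every tracklet
#'
#' Computes displacement `D`, path length `L`, velocity `v`, arrest
#' coefficient `A` and directionality `Gamma` for each tracklet in one
#' vectorized pass.
#'
#' @param tracklets Output of [decompose_tracklets()].
#' @param cfg A [tracklet_config()]; defaults to the one attached to
#'   `tracklets`.
#' @return A tibble with one row per tracklet: `tracklet_id`, `cell_id`,
#'   `group`, `start_frame`, `dt`, `D`, `L`, `v`, `A`, `Gamma`. The config
#'   is carried along as attribute `"tracklet_config"`.
#' @export
tracklet_metrics <- function(tracklets,
                             cfg = attr(tracklets, "tracklet_config")) {
  if (is.null(cfg)) cfg <- tracklet_config()
  stopifnot(inherits(cfg, "tracklet_config"))
  W <- cfg$W
  if (nrow(tracklets) == 0) {
    return(structure(
      tibble(tracklet_id = character(), cell_id = character(),
             group = character(), start_frame = integer(), dt = numeric(),
             D = numeric(), L = numeric(), v = numeric(), A = numeric(),
             Gamma = numeric()),
      tracklet_config = cfg))
  }
  if (nrow(tracklets) %% W != 0) {
    stop_validation("tracklet table length is not a multiple of W")
  }
  # ensure blockwise layout (decompose_tracklets already guarantees it)
  ord <- order(match(tracklets$tracklet_id, unique(tracklets$tracklet_id)),
               tracklets$step)
  tracklets <- tracklets[ord, , drop = FALSE]
  X <- tracklet_matrix(tracklets, "x", W)
  Y <- tracklet_matrix(tracklets, "y", W)
  Z <- if ("z" %in% names(tracklets)) tracklet_matrix(tracklets, "z", W) else
    matrix(0, nrow = W, ncol = ncol(X))
  Tm <- tracklet_matrix(tracklets, "t", W)
  dt <- Tm[2, ] - Tm[1, ]
  step_len <- sqrt(diff(X)^2 + diff(Y)^2 + diff(Z)^2)
  if (W == 2) step_len <- matrix(step_len, nrow = 1)
  L <- colSums(step_len)
  D <- sqrt((X[W, ] - X[1, ])^2 + (Y[W, ] - Y[1, ])^2 + (Z[W, ] - Z[1, ])^2)
  v <- L / ((W - 1) * dt / 60)
  speeds <- sweep(step_len, 2, dt / 60, "/")
  A <- colMeans(speeds < cfg$v_arrest)
  fallback <- rep(0, ncol(X))
  if (cfg$polarity_fallback && all(POLARITY_COLS %in% names(tracklets))) {
    PX <- tracklet_matrix(tracklets, "px", W)
    PY <- tracklet_matrix(tracklets, "py", W)
    PZ <- tracklet_matrix(tracklets, "pz", W)
    mx <- colMeans(PX)
    my <- colMeans(PY)
    mz <- colMeans(PZ)
    fb <- sqrt(mx^2 + my^2 + mz^2)
    fallback <- ifelse(is.na(fb), 0, pmin(fb, 1))
  }
  Gamma <- ifelse(L >= cfg$eps_path, pmin(D / L, 1), fallback)
  idx <- seq(1, nrow(tracklets), by = W)
  structure(
    tibble(tracklet_id = tracklets$tracklet_id[idx],
           cell_id = tracklets$cell_id[idx],
           group = tracklets$group[idx],
           start_frame = tracklets$start_frame[idx],
           dt = dt, D = D, L = L, v = v, A = A, Gamma = Gamma),
    tracklet_config = cfg)
}

# Coerce positions to an n x 3 matrix (2D input gets z = 0).
as_positions <- function(positions) {
  m <- as.matrix(positions)
  if (!is.numeric(m) || !(ncol(m) %in% c(2L, 3L))) {
    stop_validation("positions must be an n x 2 or n x 3 numeric matrix")
  }
  if (ncol(m) == 2L) m <- cbind(m, 0)
  if (any(!is.finite(m))) stop_validation("positions must be finite")
  m
}

#' Summary metrics of a single track
#'
#' Displacement (straight line from first to last position), path length
#' (sum of step lengths) and velocity (path length per elapsed minute) of
#' one full track sampled at interval `dt`.
#'
#' @param positions An n x 2 or n x 3 numeric matrix of positions in um,
#'   n >= 2.
#' @param dt Inter-frame interval in seconds.
#' @return A one-row tibble with `D` (um), `L` (um) and `v` (um/min).
#' @export
summarize_track <- function(positions, dt) {
  m <- as_positions(positions)
  if (nrow(m) < 2) stop_validation("a track needs at least 2 frames")
  steps <- sqrt(rowSums(diff(m)^2))
  L <- sum(steps)
  D <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  tibble(D = D, L = L, v = L / ((nrow(m) - 1) * dt / 60))
}

#' Continuous arrest coefficient of one tracklet
#'
#' The fraction of steps whose instantaneous speed is below the arrest
#' threshold: the proportion of time during which the cell does not move.
#'
#' @inheritParams summarize_track
#' @param cfg A [tracklet_config()] supplying `v_arrest`.
#' @return A number in \[0, 1\].
#' @export
arrest_coefficient <- function(positions, dt, cfg = tracklet_config()) {
  m <- as_positions(positions)
  if (nrow(m) < 2) stop_validation("a tracklet needs at least 2 frames")
  speeds <- sqrt(rowSums(diff(m)^2)) / (dt / 60)
  mean(speeds < cfg$v_arrest)
}

#' Instantaneous directionality (straightness) of one tracklet
#'
#' `D / L` when the path length is at least `eps_path`; otherwise the
#' norm of the mean polarity unit vector (if polarity is supplied and the
#' fallback is enabled) or 0. High values mark polarized cells migrating
#' along straight trajectories.
#'
#' @inheritParams arrest_coefficient
#' @param polarity Optional n x 3 matrix of unit polarity vectors.
#' @return A number in \[0, 1\].
#' @export
directionality <- function(positions, dt, cfg = tracklet_config(),
                           polarity = NULL) {
  m <- as_positions(positions)
  if (nrow(m) < 2) stop_validation("a tracklet needs at least 2 frames")
  steps <- sqrt(rowSums(diff(m)^2))
  L <- sum(steps)
  if (L >= cfg$eps_path) {
    D <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
    return(min(D / L, 1))
  }
  if (cfg$polarity_fallback && !is.null(polarity)) {
    pm <- as.matrix(polarity)
    mv <- colMeans(pm)
    return(min(sqrt(sum(mv^2)), 1))
  }
  0
}
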