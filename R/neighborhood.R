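# Contact-independent neighborhood influence.
#
# Two questions, both at a fixed radius around each focal cell (50 um by
# default): (1) does a cell's instantaneous velocity increase with the
# number of motile leader cells nearby, and (2) are a follower's
# directionality changes preceded by a nearby leader's directionality
# changes? "Motile" is defined through the behavioral gates (the covering
# tracklet is in the chemokinesis or directional gate), keeping a single
# definition of motility across the package.

#' Neighborhood-analysis parameters
#'
#' @param radius Neighborhood radius in um (boundary inclusive).
#'   Default 50.
#' @param motile_gates Gate labels whose tracklets count as motile.
#' @param max_neighbor_bin Neighbor counts at or above this value are
#'   pooled into one bin (default 2: bins 0, 1, >=2).
#' @param lag_window Lead-lag window in seconds: a follower event at time
#'   t is "preceded" if a leader event falls in \[t - lag_window, t).
#'   Default 60 s (3 frames at 20 s sampling).
#' @param turn_angle Heading change in degrees that defines a
#'   direction-change event. Default 60.
#' @param eps_speed Minimum instantaneous speed (um/min) for a step to
#'   define a heading. Default 2, matching the arrest threshold.
#' @param n_perm Circular-shift permutations for the lead-lag null
#'   (default 999).
#' @return A `neighborhood_config` list.
#' @export
neighborhood_config <- function(radius = 50,
                                motile_gates = c("chemokinesis", "directional"),
                                max_neighbor_bin = 2L,
                                lag_window = 60,
                                turn_angle = 60,
                                eps_speed = 2,
                                n_perm = 999L) {
  if (!is_number(radius) || radius <= 0) stop_config("radius must be > 0")
  if (!all(motile_gates %in% GATE_LEVELS)) {
    stop_config("motile_gates must be a subset of the four gate labels")
  }
  max_neighbor_bin <- as.integer(max_neighbor_bin)
  if (is.na(max_neighbor_bin) || max_neighbor_bin < 1L) {
    stop_config("max_neighbor_bin must be >= 1")
  }
  if (!is_number(lag_window) || lag_window <= 0) {
    stop_config("lag_window must be > 0 seconds")
  }
  if (!is_number(turn_angle) || turn_angle <= 0 || turn_angle >= 180) {
    stop_config("turn_angle must be in (0, 180) degrees")
  }
  if (!is_number(eps_speed) || eps_speed <= 0) stop_config("eps_speed must be > 0")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop_config("n_perm must be >= 1")
  structure(list(radius = radius, motile_gates = motile_gates,
                 max_neighbor_bin = max_neighbor_bin,
                 lag_window = lag_window, turn_angle = turn_angle,
                 eps_speed = eps_speed, n_perm = n_perm),
            class = "neighborhood_config")
}

# Per-cell, per-frame motility flags from gated tracklet metrics.
# A frame is covered by the latest-starting tracklet window containing it;
# frames with no covering tracklet are not motile. Returns a logical
# matrix cells x frames (0-based frames in columns 1..n_frames).
motile_frame_matrix <- function(gated, W, n_frames, cells, motile_gates) {
  m <- matrix(FALSE, nrow = length(cells), ncol = n_frames,
              dimnames = list(cells, NULL))
  gated <- gated[gated$cell_id %in% cells, , drop = FALSE]
  if (nrow(gated) == 0) {
    return(m)
  }
  gated <- gated[order(gated$start_frame), , drop = FALSE]
  for (i in seq_len(nrow(gated))) {
    fr <- gated$start_frame[i]:(gated$start_frame[i] + W - 1L)
    fr <- fr[fr < n_frames]
    m[gated$cell_id[i], fr + 1L] <-
      as.character(gated$gate[i]) %in% motile_gates
  }
  m
}

#' Count motile leader cells around one focal cell at one time
#'
#' Counts leader-group cells whose position at acquisition time `t` lies
#' within the configured radius of the focal cell (boundary inclusive) and
#' whose covering tracklet is in a motile gate. The focal cell never
#' counts itself.
#'
#' @param table A regularized `track_table`.
#' @param gated Gated tracklet metrics from [classify_tracklets()].
#' @param focal_cell Cell id of the focal cell.
#' @param t Acquisition time in seconds; must be a frame of the focal
#'   cell's track.
#' @param cfg A [neighborhood_config()].
#' @param leader_group Group label of the leader population.
#' @return An integer count.
#' @export
motile_neighbor_count <- function(table, gated, focal_cell, t,
                                  cfg = neighborhood_config(),
                                  leader_group = "wt") {
  focal <- table[table$cell_id == focal_cell, , drop = FALSE]
  if (nrow(focal) == 0) stop_validation(paste0("unknown cell '", focal_cell, "'"))
  hit <- which(abs(focal$t - t) <= 1e-6 * max(1, abs(t)))
  if (length(hit) == 0) {
    stop_validation(paste0("t = ", t, " s is not an observed frame of cell '",
                           focal_cell, "'"))
  }
  frame <- focal$frame[hit[1]]
  fx <- unlist(focal[hit[1], intersect(c("x", "y", "z"), names(focal))])
  cand <- table[table$group == leader_group & table$frame == frame &
                  table$cell_id != focal_cell, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(0L)
  }
  W <- attr(gated, "tracklet_config")$W %||% tracklet_config()$W
  n_frames <- max(table$frame) + 1L
  mm <- motile_frame_matrix(gated, W, n_frames, unique(cand$cell_id),
                            cfg$motile_gates)
  motile <- mm[cand$cell_id, frame + 1L]
  pos <- as.matrix(cand[, intersect(c("x", "y", "z"), names(cand))])
  d <- sqrt(colSums((t(pos) - fx)^2))
  sum(motile & d <= cfg$radius)
}

#' Instantaneous velocity stratified by motile-neighbor count
#'
#' For every (cell, frame) with a defined forward step, records the
#' instantaneous velocity and the number of motile leader-group cells
#' within the radius, bins the counts (0, 1, ..., >=`max_neighbor_bin`),
#' summarizes each (focal group, bin) and runs rank-based two-sample
#' comparisons: bin 0 vs bins >= 1, and bin 1 vs bins >= 2 (with
#' Benjamini-Hochberg adjustment across the emitted comparisons).
#'
#' @inheritParams motile_neighbor_count
#' @return A list with `records` (one row per cell-frame), `summary`
#'   (per group and bin: n, mean, median velocity), `tests` (rank-test
#'   table) and `config`.
#' @export
conditional_velocity <- function(table, gated, cfg = neighborhood_config(),
                                 leader_group = "wt") {
  validate_tracks(table, require_uniform_dt = TRUE)
  df <- as_tibble(table)
  pos_cols <- intersect(c("x", "y", "z"), names(df))
  df <- df[order(df$cell_id, df$frame, method = "radix"), , drop = FALSE]
  # forward-step instantaneous velocity, um/min
  v_inst <- rep(NA_real_, nrow(df))
  idx_by_cell <- split(seq_len(nrow(df)), df$cell_id)
  for (idx in idx_by_cell) {
    if (length(idx) < 2) next
    p <- as.matrix(df[idx, pos_cols])
    stepd <- sqrt(rowSums(diff(p)^2))
    v_inst[idx[-length(idx)]] <- stepd / diff(df$t[idx]) * 60
  }
  n_frames <- max(df$frame) + 1L
  leader_cells <- unique(df$cell_id[df$group == leader_group])
  W <- attr(gated, "tracklet_config")$W %||% tracklet_config()$W
  mm <- motile_frame_matrix(gated, W, n_frames, leader_cells,
                            cfg$motile_gates)
  n_motile <- rep(NA_integer_, nrow(df))
  rows_by_frame <- split(seq_len(nrow(df)), df$frame)
  for (rows in rows_by_frame) {
    f <- df$frame[rows[1]]
    is_leader <- df$cell_id[rows] %in% leader_cells
    lead_rows <- rows[is_leader]
    lead_motile <- logical(length(lead_rows))
    if (length(lead_rows) > 0) {
      lead_motile <- mm[df$cell_id[lead_rows], f + 1L]
    }
    ml_rows <- lead_rows[lead_motile]
    if (length(ml_rows) == 0) {
      n_motile[rows] <- 0L
      next
    }
    dmat <- cross_dist(as.matrix(df[rows, pos_cols]),
                       as.matrix(df[ml_rows, pos_cols]))
    cnt <- rowSums(dmat <= cfg$radius)
    # a focal cell that is itself a motile leader is at distance 0 of itself
    self <- match(ml_rows, rows)
    cnt[self] <- cnt[self] - 1L
    n_motile[rows] <- as.integer(cnt)
  }
  ok <- !is.na(v_inst)
  records <- tibble(cell_id = df$cell_id[ok], group = df$group[ok],
                    frame = df$frame[ok], t = df$t[ok],
                    velocity = v_inst[ok], n_motile = n_motile[ok])
  records$bin <- pmin(records$n_motile, cfg$max_neighbor_bin)
  records$bin <- factor(records$bin, levels = 0:cfg$max_neighbor_bin,
                        labels = c(as.character(0:(cfg$max_neighbor_bin - 1)),
                                   paste0(">=", cfg$max_neighbor_bin)))
  summary <- records |>
    group_by(.data$group, .data$bin, .drop = FALSE) |>
    summarise(n = n(), mean_velocity = mean(.data$velocity),
              median_velocity = median(.data$velocity), .groups = "drop")
  tests <- list()
  for (g in sort(unique(records$group), method = "radix")) {
    rg <- records[records$group == g, , drop = FALSE]
    v0 <- rg$velocity[rg$n_motile == 0]
    v1p <- rg$velocity[rg$n_motile >= 1]
    v1 <- rg$velocity[rg$n_motile == 1]
    v2p <- rg$velocity[rg$n_motile >= 2]
    if (length(v0) > 0 && length(v1p) > 0) {
      p <- suppressWarnings(wilcox.test(v1p, v0)$p.value)
      tests[[length(tests) + 1L]] <-
        tibble(group = g, comparison = "0_vs_ge1", n_low = length(v0),
               n_high = length(v1p), p_value = p)
    }
    if (length(v1) > 0 && length(v2p) > 0) {
      p <- suppressWarnings(wilcox.test(v2p, v1)$p.value)
      tests[[length(tests) + 1L]] <-
        tibble(group = g, comparison = "1_vs_ge2", n_low = length(v1),
               n_high = length(v2p), p_value = p)
    }
  }
  tests <- bind_rows(tests)
  if (nrow(tests) > 1) tests$p_adj <- p.adjust(tests$p_value, method = "BH")
  list(records = records, summary = summary, tests = tests, config = cfg)
}

#' Sliding-window directionality series and direction-change events
#'
#' Computes, per frame, the directionality (straightness) of the window of
#' `window` frames centered on that frame (truncated at the track edges),
#' plus direction-change events: frames at which the heading -- the unit
#' step vector, defined only when the instantaneous speed reaches
#' `eps_speed` -- turns by more than `turn_angle` degrees relative to the
#' previous defined heading.
#'
#' @param track A `track_table` containing a single cell.
#' @param window Sliding-window width in frames.
#' @param cfg A [neighborhood_config()].
#' @param eps_path Path-length floor below which the window directionality
#'   is reported as 0.
#' @return A `directionality_series` list with `cell_id`, `series`
#'   (tibble frame, t, gamma) and `events` (tibble frame, t).
#' @export
directionality_series <- function(track, window = 10L,
                                  cfg = neighborhood_config(),
                                  eps_path = 1) {
  if (length(unique(track$cell_id)) != 1) {
    stop_validation("directionality_series expects a single-cell track")
  }
  track <- track[order(track$frame), , drop = FALSE]
  pos_cols <- intersect(c("x", "y", "z"), names(track))
  p <- as.matrix(track[, pos_cols])
  n <- nrow(p)
  if (n < window) stop_validation("track shorter than the sliding window")
  steps <- diff(p)
  stepd <- sqrt(rowSums(steps^2))
  cumL <- c(0, cumsum(stepd))
  h <- floor(window / 2)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  L <- cumL[hi] - cumL[lo]
  D <- sqrt(rowSums((p[hi, , drop = FALSE] - p[lo, , drop = FALSE])^2))
  gamma <- ifelse(L >= eps_path, pmin(D / L, 1), 0)
  # direction-change events
  dtv <- diff(track$t)
  speeds <- stepd / dtv * 60
  defined <- speeds >= cfg$eps_speed & stepd > 0
  events <- integer(0)
  prev <- NULL
  cos_thr <- cos(cfg$turn_angle * pi / 180)
  for (i in which(defined)) {
    hcur <- steps[i, ] / stepd[i]
    if (!is.null(prev) && sum(hcur * prev) < cos_thr) {
      events <- c(events, i)
    }
    prev <- hcur
  }
  structure(list(
    cell_id = track$cell_id[1],
    series = tibble(frame = track$frame, t = track$t, gamma = gamma),
    events = tibble(frame = track$frame[events], t = track$t[events])
  ), class = "directionality_series")
}

#' Lead-lag precedence score with a circular-shift null
#'
#' Fraction of follower direction-change events preceded, within the lag
#' window, by at least one leader event; significance by circularly
#' shifting the leader event train around the recording period.
#'
#' @param follower_times Times (s) of the follower's direction-change
#'   events.
#' @param leader_times Times (s) of leader direction-change events already
#'   restricted to leaders within the radius of the follower at event
#'   time.
#' @param cfg A [neighborhood_config()] supplying `lag_window` and
#'   `n_perm`.
#' @param period Length-2 numeric, the recording interval (s) over which
#'   event times wrap.
#' @param seed Optional seed for the permutation offsets; `NULL` uses the
#'   current RNG state.
#' @param return_null Also return the permuted fractions.
#' @return A list with `fraction`, `p_value`, `n_follower_events`,
#'   `n_leader_events`, `null_mean`, `null_sd` (and `null` when
#'   requested). With zero follower events the score is undefined:
#'   `fraction` and `p_value` are `NA` and `status` is
#'   `"no_follower_events"`.
#' @export
lead_lag_score <- function(follower_times, leader_times,
                           cfg = neighborhood_config(), period,
                           seed = NULL, return_null = FALSE) {
  if (length(follower_times) == 0) {
    return(list(fraction = NA_real_, p_value = NA_real_,
                n_follower_events = 0L,
                n_leader_events = length(leader_times),
                status = "no_follower_events"))
  }
  t0 <- period[1]
  T_len <- period[2] - period[1]
  if (!is_number(T_len) || T_len <= 0) stop_config("invalid period")
  run <- function() {
    if (length(leader_times) == 0) {
      null <- rep(0, cfg$n_perm)
      obs <- 0
    } else {
      # circular gaps follower - leader; precedence <=> gap in (0, lag]
      gaps <- outer(follower_times, leader_times, "-") %% T_len
      hit <- gaps > 0 & gaps <= cfg$lag_window
      obs <- mean(apply(hit, 1, any))
      offs <- runif(cfg$n_perm, 0, T_len)
      null <- vapply(offs, function(o) {
        g <- (gaps - o) %% T_len
        mean(apply(g > 0 & g <= cfg$lag_window, 1, any))
      }, numeric(1))
    }
    p <- (1 + sum(null >= obs)) / (cfg$n_perm + 1)
    out <- list(fraction = obs, p_value = p,
                n_follower_events = length(follower_times),
                n_leader_events = length(leader_times),
                null_mean = mean(null), null_sd = stats::sd(null),
                status = "ok")
    if (return_null) out$null <- null
    out
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

#' Lead-lag analysis between leader and follower populations
#'
#' For every follower cell with at least one direction-change event,
#' collects the direction-change events of leader cells that were within
#' the radius of the follower at the leader's event time, scores the
#' precedence fraction with [lead_lag_score()], and pools the scores into
#' an overall fraction with a joint permutation p-value (the same circular
#' shifts drive the pooled null).
#'
#' @inheritParams conditional_velocity
#' @param follower_group Group label of the follower population.
#' @param window Sliding window (frames) for [directionality_series()].
#' @param seed Seed for the permutation offsets.
#' @param max_followers Cap on the number of followers scored (those with
#'   the most events are kept; ties broken by cell id). Keeps the
#'   permutation cost bounded on large simulations.
#' @return A list with `per_follower` (tibble), `overall` (fraction and
#'   p-value) and `config`.
#' @export
lead_lag_analysis <- function(table, cfg = neighborhood_config(),
                              leader_group = "wt", follower_group = "ko",
                              window = 10L, seed = 1L,
                              max_followers = 20L) {
  validate_tracks(table, require_uniform_dt = TRUE)
  df <- as_tibble(table)
  pos_cols <- intersect(c("x", "y", "z"), names(df))
  period <- range(df$t)
  cells <- split(df, df$cell_id)
  ev <- lapply(cells, function(cc) {
    if (nrow(cc) < window) {
      return(NULL)
    }
    s <- directionality_series(cc, window = window, cfg = cfg)
    if (nrow(s$events) == 0) {
      return(NULL)
    }
    tibble(cell_id = cc$cell_id[1], group = cc$group[1],
           frame = s$events$frame, t = s$events$t)
  })
  ev <- bind_rows(ev)
  lead_ev <- ev[!is.na(ev$group) & ev$group == leader_group, , drop = FALSE]
  foll_ev <- ev[!is.na(ev$group) & ev$group == follower_group, , drop = FALSE]
  empty <- tibble(cell_id = character(), n_events = integer(),
                  n_leader_events = integer(), fraction = numeric(),
                  p_value = numeric())
  if (nrow(foll_ev) == 0) {
    return(list(per_follower = empty,
                overall = list(fraction = NA_real_, p_value = NA_real_,
                               status = "no_follower_events"),
                config = cfg))
  }
  f_cells <- foll_ev |>
    group_by(.data$cell_id) |>
    summarise(n_events = n(), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_events), .data$cell_id)
  f_cells <- head(f_cells$cell_id, max_followers)
  res <- with_preserved_seed(seed, {
    lapply(f_cells, function(fc) {
      fe <- foll_ev$t[foll_ev$cell_id == fc]
      ftrack <- cells[[fc]]
      # leader events with the leader within radius of this follower at
      # the leader's event time
      lt <- numeric(0)
      if (nrow(lead_ev) > 0) {
        fpos <- ftrack[match(lead_ev$frame, ftrack$frame), pos_cols]
        lrow <- df[match(paste(lead_ev$cell_id, lead_ev$frame),
                         paste(df$cell_id, df$frame)), pos_cols]
        d <- sqrt(rowSums((as.matrix(fpos) - as.matrix(lrow))^2))
        lt <- lead_ev$t[!is.na(d) & d <= cfg$radius]
      }
      sc <- lead_lag_score(fe, lt, cfg = cfg, period = period,
                           return_null = TRUE)
      sc$cell_id <- fc
      sc
    })
  })
  per_follower <- bind_rows(lapply(res, function(s) {
    tibble(cell_id = s$cell_id, n_events = s$n_follower_events,
           n_leader_events = s$n_leader_events, fraction = s$fraction,
           p_value = s$p_value)
  }))
  if (nrow(per_follower) > 1) {
    per_follower$p_adj <- p.adjust(per_follower$p_value, method = "BH")
  }
  w <- per_follower$n_events
  overall_frac <- sum(w * per_follower$fraction) / sum(w)
  null_mat <- vapply(res, function(s) s$null %||% rep(0, cfg$n_perm),
                     numeric(cfg$n_perm))
  pooled_null <- as.numeric(null_mat %*% w) / sum(w)
  overall_p <- (1 + sum(pooled_null >= overall_frac)) / (cfg$n_perm + 1)
  list(per_follower = per_follower,
       overall = list(fraction = overall_frac, p_value = overall_p,
                      status = "ok"),
       config = cfg)
}

#' Mean neighborhood directionality around a focal cell
#'
#' Per frame of the focal cell, the mean sliding-window directionality of
#' all other cells (any group) within the radius; frames with no neighbor
#' yield `NA` (a gap).
#'
#' @inheritParams conditional_velocity
#' @param focal_cell Cell id of the focal cell.
#' @param window Sliding window (frames) for [directionality_series()].
#' @return A tibble with `frame`, `t`, `n_neighbors`, `mean_gamma`.
#' @export
neighborhood_mean_directionality <- function(table, focal_cell,
                                             cfg = neighborhood_config(),
                                             window = 10L) {
  validate_tracks(table, require_uniform_dt = TRUE)
  df <- as_tibble(table)
  pos_cols <- intersect(c("x", "y", "z"), names(df))
  cells <- split(df, df$cell_id)
  if (!focal_cell %in% names(cells)) {
    stop_validation(paste0("unknown cell '", focal_cell, "'"))
  }
  gam <- lapply(cells, function(cc) {
    if (nrow(cc) < window) {
      return(NULL)
    }
    s <- directionality_series(cc, window = window, cfg = cfg)
    setNames(s$series$gamma, s$series$frame)
  })
  focal <- cells[[focal_cell]]
  out <- tibble(frame = focal$frame, t = focal$t,
                n_neighbors = 0L, mean_gamma = NA_real_)
  for (i in seq_len(nrow(focal))) {
    f <- focal$frame[i]
    fpos <- unlist(focal[i, pos_cols])
    vals <- numeric(0)
    for (cid in names(cells)) {
      if (cid == focal_cell || is.null(gam[[cid]])) next
      g <- gam[[cid]][as.character(f)]
      if (is.na(g)) next
      other <- cells[[cid]]
      j <- match(f, other$frame)
      d <- sqrt(sum((unlist(other[j, pos_cols]) - fpos)^2))
      if (d <= cfg$radius) vals <- c(vals, g)
    }
    out$n_neighbors[i] <- length(vals)
    if (length(vals) > 0) out$mean_gamma[i] <- mean(vals)
  }
  out
}

#' Translate tracks to a common origin
#'
#' Each track is translated so that its first observed position is the
#' origin; a `disp` column records the running distance from the start
#' (the last frame's value equals the track displacement `D`).
#'
#' @param table A `track_table`.
#' @return A `track_table` with translated positions and a `disp` column.
#' @export
common_origin <- function(table) {
  validate_tracks(table)
  df <- as_tibble(table)
  pos_cols <- intersect(c("x", "y", "z"), names(df))
  pieces <- lapply(split(df, df$cell_id), function(cc) {
    for (pc in pos_cols) cc[[pc]] <- cc[[pc]] - cc[[pc]][1]
    cc$disp <- sqrt(rowSums(as.matrix(cc[, pos_cols])^2))
    cc
  })
  as_track_table(bind_rows(pieces))
}
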