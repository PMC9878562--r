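# Agent-based leader-follower chemotaxis simulator.
#
# Mechanism: "leader" cells (wt; ACKR3+, CXCR4+) perform a persistent
# biased random walk up a CXCL12 gradient. While exposed to CXCL12 above a
# low secretion threshold, each leader emits a short-range LTB4 cue,
# modeled as a quasi-steady-state exponential kernel q*exp(-d/lambda)
# re-evaluated every frame. "Follower" cells (ko; ACKR3-deficient) are
# essentially immobile on their own; a follower whose local LTB4 reaches
# the activation threshold *and* that sits in CXCL12 (a hard synergy gate:
# LTB4 alone does not move the cells) switches to a faster, weakly biased
# walk. Perturbations: PTX on leaders removes their chemotactic bias and
# their LTB4 secretion; a C-terminally truncated scavenger receptor
# (deltaC) does the same while leaving chemokinesis; PTX on followers or
# loss of the LTB4 receptor BLT1 (blt1r_ko) removes the follower response
# without touching leader secretion.

#' Simulation parameters
#'
#' Defaults emulate a 3D chemotaxis-chamber experiment: a 1000 x 500 x
#' 100 um arena with a linear CXCL12 gradient along x (nominal source
#' concentration 400 nM), 6 h of recording at 20 s frame intervals, and a
#' 1:1 mixture of 100 leaders and 100 followers.
#'
#' @param arena Box dimensions in um (length 3).
#' @param gradient_axis Axis of the attractant gradient (1 = x).
#' @param gradient_profile `"linear"` (c0 * x / x_max) or `"erf"`
#'   (sigmoidal diffusion-like front).
#' @param c0 Nominal source concentration (arbitrary units; 400 after the
#'   nM of the loaded chemokine).
#' @param c_min Minimum local CXCL12 for a leader to secrete LTB4
#'   (secretion starts just above background; default 0.5% of `c0`).
#' @param n_leaders,n_followers Agent counts.
#' @param dt Frame interval, s.
#' @param duration Recording length, s; must be a multiple of `dt`.
#' @param leader_speed Leader step-length scale sigma_v, um/min.
#' @param persistence Heading persistence p in \[0, 1): weight of the
#'   previous heading in the heading update.
#' @param leader_bias Chemotactic bias chi of leaders in \[0, 1\]: weight
#'   of the gradient direction against a uniform random direction.
#' @param pause_enter,pause_exit Per-frame probabilities for a leader to
#'   enter/leave a paused (jitter-only) state; pausing leaders keep
#'   secreting, reproducing cells that arrest where a leader briefly
#'   stopped.
#' @param follower_speed0 Baseline follower step scale (positional jitter),
#'   um/min.
#' @param follower_speed1 Activated follower step scale, um/min.
#' @param follower_bias Chemotactic bias of activated followers.
#' @param ltb4_lambda LTB4 kernel length scale, um.
#' @param ltb4_q Per-leader LTB4 source strength (arbitrary units).
#' @param ltb4_threshold Follower activation threshold; the default
#'   `ltb4_q * exp(-50 / ltb4_lambda)` makes a single secreting leader
#'   effective out to the 50 um neighborhood radius and no further.
#' @param ltb4_mode `"field"` (quasi-steady state around current leader
#'   positions) or `"deposit"` (decaying point cues dropped where a leader
#'   pauses).
#' @param deposit_decay Exponential decay time (s) of deposited cues.
#' @param scavenging Strength of an optional CXCL12 sink around leaders
#'   (0 disables; exploratory, off by default).
#' @param ptx_leaders,ptx_followers,ackr3_deltaC,blt1r_ko Perturbation
#'   flags.
#' @param seed Integer seed; (config, seed) fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(arena = c(1000, 500, 100),
                       gradient_axis = 1L,
                       gradient_profile = c("linear", "erf"),
                       c0 = 400, c_min = 2,
                       n_leaders = 100L, n_followers = 100L,
                       dt = 20, duration = 21600,
                       leader_speed = 4, persistence = 0.3,
                       leader_bias = 0.5,
                       pause_enter = 0.02, pause_exit = 0.02,
                       follower_speed0 = 0.2, follower_speed1 = 2.5,
                       follower_bias = 0.05,
                       ltb4_lambda = 15, ltb4_q = 1,
                       ltb4_threshold = NULL,
                       ltb4_mode = c("field", "deposit"),
                       deposit_decay = 600,
                       scavenging = 0,
                       ptx_leaders = FALSE, ptx_followers = FALSE,
                       ackr3_deltaC = FALSE, blt1r_ko = FALSE,
                       seed = 1L) {
  gradient_profile <- match.arg(gradient_profile)
  ltb4_mode <- match.arg(ltb4_mode)
  if (length(arena) != 3 || any(!is.finite(arena)) || any(arena <= 0)) {
    stop_config("arena must be three positive extents (um)")
  }
  gradient_axis <- as.integer(gradient_axis)
  if (!gradient_axis %in% 1:3) stop_config("gradient_axis must be 1, 2 or 3")
  for (nm in c("c0", "dt", "duration", "leader_speed", "follower_speed1",
               "ltb4_lambda", "ltb4_q", "deposit_decay")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0) stop_config(paste0(nm, " must be > 0"))
  }
  for (nm in c("c_min", "follower_speed0", "scavenging")) {
    v <- get(nm)
    if (!is_number(v) || v < 0) stop_config(paste0(nm, " must be >= 0"))
  }
  if (!is_number(persistence) || persistence < 0 || persistence >= 1) {
    stop_config("persistence must be in [0, 1)")
  }
  for (nm in c("leader_bias", "follower_bias", "pause_enter", "pause_exit")) {
    v <- get(nm)
    if (!is_number(v) || v < 0 || v > 1) {
      stop_config(paste0(nm, " must be in [0, 1]"))
    }
  }
  n_leaders <- as.integer(n_leaders)
  n_followers <- as.integer(n_followers)
  if (is.na(n_leaders) || n_leaders < 0L) stop_config("n_leaders must be >= 0")
  if (is.na(n_followers) || n_followers < 0L) stop_config("n_followers must be >= 0")
  if (n_leaders + n_followers < 1L) stop_config("need at least one agent")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop_config("dt must divide duration")
  }
  for (nm in c("ptx_leaders", "ptx_followers", "ackr3_deltaC", "blt1r_ko")) {
    if (!is_flag(get(nm))) stop_config(paste0(nm, " must be TRUE/FALSE"))
  }
  if (is.null(ltb4_threshold)) {
    ltb4_threshold <- ltb4_q * exp(-50 / ltb4_lambda)
  }
  if (!is_number(ltb4_threshold) || ltb4_threshold <= 0) {
    stop_config("ltb4_threshold must be > 0")
  }
  if (!is_number(seed)) stop_config("seed must be a single integer")
  structure(list(
    arena = as.numeric(arena), gradient_axis = gradient_axis,
    gradient_profile = gradient_profile, c0 = c0, c_min = c_min,
    n_leaders = n_leaders, n_followers = n_followers,
    dt = dt, duration = duration, n_steps = as.integer(round(n_steps)),
    leader_speed = leader_speed, persistence = persistence,
    leader_bias = leader_bias,
    pause_enter = pause_enter, pause_exit = pause_exit,
    follower_speed0 = follower_speed0, follower_speed1 = follower_speed1,
    follower_bias = follower_bias,
    ltb4_lambda = ltb4_lambda, ltb4_q = ltb4_q,
    ltb4_threshold = ltb4_threshold, ltb4_mode = ltb4_mode,
    deposit_decay = deposit_decay, scavenging = scavenging,
    ptx_leaders = ptx_leaders, ptx_followers = ptx_followers,
    ackr3_deltaC = ackr3_deltaC, blt1r_ko = blt1r_ko,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Named simulation presets for the experimental arms
#'
#' `ko_alone` (followers only), `wt_alone` (leaders only), `mixed_1to1`
#' (1:1 leader/follower mixture) and the perturbed mixtures
#' `mixed_ptx_wt`, `mixed_ptx_ko`, `mixed_deltaC`, `mixed_blt1rko`, which
#' differ from `mixed_1to1` only in the corresponding perturbation flag.
#'
#' @param name Preset name.
#' @param seed Simulation seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("ko_alone", "wt_alone", "mixed_1to1",
                                "mixed_ptx_wt", "mixed_ptx_ko",
                                "mixed_deltaC", "mixed_blt1rko"),
                       seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    ko_alone = list(n_leaders = 0L, n_followers = 100L),
    wt_alone = list(n_leaders = 100L, n_followers = 0L),
    mixed_1to1 = list(),
    mixed_ptx_wt = list(ptx_leaders = TRUE),
    mixed_ptx_ko = list(ptx_followers = TRUE),
    mixed_deltaC = list(ackr3_deltaC = TRUE),
    mixed_blt1rko = list(blt1r_ko = TRUE)
  )
  cfg <- do.call(sim_config, modifyList(args, list(seed = seed, ...)))
  cfg$preset <- name
  cfg
}

#' Attractant concentration at given positions
#'
#' Monotone non-decreasing along the gradient axis: linear
#' `c0 * x / x_max` by default, or a diffusion-like error-function front.
#' An optional exponential sink around leader positions (scavenging by the
#' decoy receptor) can locally deplete the field; it is off by default.
#'
#' @param position Numeric vector (length 3) or n x 3 matrix of positions
#'   in um; must lie inside the arena.
#' @param cfg A [sim_config()].
#' @param leader_positions Optional m x 3 matrix used by the scavenging
#'   sink.
#' @return Concentrations, same length as rows of `position`.
#' @export
cxcl12_field <- function(position, cfg, leader_positions = NULL) {
  m <- if (is.null(dim(position))) matrix(position, ncol = 3) else
    as.matrix(position)
  tol <- 1e-9
  for (ax in 1:3) {
    if (any(m[, ax] < -tol | m[, ax] > cfg$arena[ax] + tol)) {
      stop_validation("position outside the arena")
    }
  }
  xr <- pmin(pmax(m[, cfg$gradient_axis], 0), cfg$arena[cfg$gradient_axis])
  xmax <- cfg$arena[cfg$gradient_axis]
  conc <- switch(cfg$gradient_profile,
    linear = cfg$c0 * xr / xmax,
    erf = {
      # error-function front centered mid-arena, width 20% of the axis
      z <- (xr - xmax / 2) / (0.2 * xmax)
      cfg$c0 * pnorm(z * sqrt(2))
    })
  if (cfg$scavenging > 0 && !is.null(leader_positions) &&
      nrow(leader_positions) > 0) {
    d <- cross_dist(m, leader_positions)
    sink <- rowSums(exp(-d / cfg$ltb4_lambda))
    conc <- conc * exp(-cfg$scavenging * sink)
  }
  conc
}

#' LTB4 level at given positions
#'
#' Sum over currently secreting leaders of `q * exp(-d / lambda)`. A
#' leader secretes iff it is a non-PTX, non-deltaC leader whose local
#' CXCL12 is at least `c_min`; secretion is independent of BLT1 (in
#' `blt1r_ko` the cue is still produced, only the follower response is
#' lost).
#'
#' @param position Length-3 vector or n x 3 matrix of query positions.
#' @param leader_positions m x 3 matrix of leader positions.
#' @param cfg A [sim_config()].
#' @param secreting Optional logical vector overriding the secretion
#'   eligibility computed from `cfg` and the local CXCL12.
#' @return LTB4 levels (arbitrary units), 0 everywhere when no leader
#'   secretes.
#' @export
ltb4_field <- function(position, leader_positions, cfg, secreting = NULL) {
  m <- if (is.null(dim(position))) matrix(position, ncol = 3) else
    as.matrix(position)
  if (is.null(leader_positions) || nrow(leader_positions) == 0) {
    return(rep(0, nrow(m)))
  }
  if (is.null(secreting)) {
    eligible <- !cfg$ptx_leaders && !cfg$ackr3_deltaC
    secreting <- if (eligible) {
      cxcl12_field(leader_positions, cfg) >= cfg$c_min
    } else {
      rep(FALSE, nrow(leader_positions))
    }
  }
  lp <- leader_positions[secreting, , drop = FALSE]
  if (nrow(lp) == 0) {
    return(rep(0, nrow(m)))
  }
  d <- cross_dist(m, lp)
  rowSums(cfg$ltb4_q * exp(-d / cfg$ltb4_lambda))
}

# Reflect positions into the arena box.
reflect_into_arena <- function(pos, arena) {
  for (ax in 1:3) {
    repeat {
      below <- pos[, ax] < 0
      above <- pos[, ax] > arena[ax]
      if (!any(below) && !any(above)) break
      pos[below, ax] <- -pos[below, ax]
      pos[above, ax] <- 2 * arena[ax] - pos[above, ax]
    }
  }
  pos
}

#' Advance all agents by one frame
#'
#' One step of the persistent biased random walk. The new heading is
#' `normalize(p * heading + (1 - p) * (chi * gradient + (1 - chi) * u))`
#' with `u` a uniform random unit vector; the step length is half-normal
#' with scale `sigma * dt`. Speed scale and bias depend on type, pause
#' state, activation and perturbation flags (see [sim_config()]). Uses the
#' current RNG state; positions reflect at the arena boundary.
#'
#' @param state List with `pos` (n x 3), `heading` (n x 3 unit rows),
#'   `type` (`"leader"`/`"follower"`), `paused`, `activated` (logicals).
#' @param cfg A [sim_config()].
#' @param cues Optional deposited-cue state (deposit mode), a list with
#'   `pos`, `t0`; maintained by [simulate_tracks()].
#' @param t_now Current time (s), used by deposit-mode cue decay.
#' @return The updated state (same shape, plus refreshed `activated` and
#'   `paused`).
#' @export
step_agents <- function(state, cfg, cues = NULL, t_now = 0) {
  n <- nrow(state$pos)
  leaders <- state$type == "leader"
  followers <- !leaders
  cx <- cxcl12_field(state$pos, cfg,
                     leader_positions = state$pos[leaders, , drop = FALSE])
  # secretion eligibility of leaders
  secreting <- leaders & !cfg$ptx_leaders & !cfg$ackr3_deltaC & cx >= cfg$c_min
  # LTB4 at follower positions
  lvl <- rep(0, n)
  if (any(followers)) {
    if (cfg$ltb4_mode == "field") {
      lvl[followers] <- ltb4_field(state$pos[followers, , drop = FALSE],
                                   state$pos[leaders, , drop = FALSE], cfg,
                                   secreting = secreting[leaders])
    } else {
      if (!is.null(cues) && length(cues$t0) > 0) {
        d <- cross_dist(state$pos[followers, , drop = FALSE], cues$pos)
        decay <- exp(-(t_now - cues$t0) / cfg$deposit_decay)
        lvl[followers] <- as.numeric(exp(-d / cfg$ltb4_lambda) %*%
                                       (cfg$ltb4_q * decay))
      }
    }
  }
  activated <- followers & lvl >= cfg$ltb4_threshold & cx > 0 &
    !cfg$blt1r_ko & !cfg$ptx_followers
  # leader pause-state update
  paused <- state$paused
  u_pause <- runif(n)
  enter <- leaders & !paused & u_pause < cfg$pause_enter
  leave <- leaders & paused & u_pause < cfg$pause_exit
  paused <- (paused | enter) & !leave
  # per-agent speed scale (um/min) and bias
  sigma <- numeric(n)
  chi <- numeric(n)
  sigma[leaders] <- ifelse(paused[leaders], cfg$follower_speed0,
                           cfg$leader_speed)
  chi[leaders] <- if (cfg$ptx_leaders || cfg$ackr3_deltaC) 0 else
    cfg$leader_bias
  sigma[followers] <- ifelse(activated[followers], cfg$follower_speed1,
                             cfg$follower_speed0)
  chi[followers] <- ifelse(activated[followers], cfg$follower_bias, 0)
  # heading update
  g <- rep(0, 3)
  g[cfg$gradient_axis] <- 1
  u <- normalize_rows(matrix(rnorm(3 * n), ncol = 3))
  target <- chi * matrix(g, n, 3, byrow = TRUE) + (1 - chi) * u
  heading <- normalize_rows(cfg$persistence * state$heading +
                              (1 - cfg$persistence) * target)
  # degenerate cancellation: keep the old heading
  zero <- row_norms(heading) == 0
  heading[zero, ] <- state$heading[zero, , drop = FALSE]
  step_len <- abs(rnorm(n, 0, sigma * cfg$dt / 60))
  pos <- reflect_into_arena(state$pos + heading * step_len, cfg$arena)
  list(pos = pos, heading = heading, type = state$type, paused = paused,
       activated = activated, secreting = secreting, ltb4 = lvl)
}

#' Simulate a leader-follower migration experiment
#'
#' Places agents uniformly in the arena, advances them with
#' [step_agents()] for `duration / dt` frames, and returns the canonical
#' track table (groups `"wt"` for leaders, `"ko"` for followers) together
#' with per-frame ground truth. Identical (config, seed) pairs give
#' bit-identical output.
#'
#' @param cfg A [sim_config()] or [sim_preset()].
#' @return A `migr_sim` list with `tracks` (a `track_table`), `truth`
#'   (list: `agents` tibble with types and applied perturbation flags,
#'   `activation` long tibble of per-frame follower activation states) and
#'   `config`.
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_leaders + cfg$n_followers
  n_frames <- cfg$n_steps + 1L
  type <- rep(c("leader", "follower"), c(cfg$n_leaders, cfg$n_followers))
  ids <- c(sprintf("wt_%03d", seq_len(cfg$n_leaders)),
           sprintf("ko_%03d", seq_len(cfg$n_followers)))
  out <- with_preserved_seed(cfg$seed, {
    pos <- cbind(runif(n, 0, cfg$arena[1]), runif(n, 0, cfg$arena[2]),
                 runif(n, 0, cfg$arena[3]))
    state <- list(pos = pos,
                  heading = normalize_rows(matrix(rnorm(3 * n), ncol = 3)),
                  type = type,
                  paused = rep(FALSE, n),
                  activated = rep(FALSE, n))
    P <- array(NA_real_, dim = c(n, 3, n_frames))
    P[, , 1] <- pos
    act <- matrix(FALSE, nrow = n, ncol = n_frames)
    cues <- list(pos = matrix(numeric(0), ncol = 3), t0 = numeric(0))
    prev_paused <- state$paused
    for (k in seq_len(cfg$n_steps)) {
      state <- step_agents(state, cfg, cues = cues, t_now = (k - 1) * cfg$dt)
      if (cfg$ltb4_mode == "deposit") {
        # a cue is dropped when a secreting leader enters a pause
        newly <- which(state$paused & !prev_paused & state$secreting)
        if (length(newly) > 0) {
          cues$pos <- rbind(cues$pos, state$pos[newly, , drop = FALSE])
          cues$t0 <- c(cues$t0, rep((k - 1) * cfg$dt, length(newly)))
        }
        keep <- ((k - 1) * cfg$dt - cues$t0) < 5 * cfg$deposit_decay
        cues$pos <- cues$pos[keep, , drop = FALSE]
        cues$t0 <- cues$t0[keep]
        prev_paused <- state$paused
      }
      P[, , k + 1L] <- state$pos
      act[, k + 1L] <- state$activated
    }
    list(P = P, act = act)
  })
  frames <- 0:(n_frames - 1L)
  tracks <- tibble(
    cell_id = rep(ids, each = n_frames),
    group = rep(ifelse(type == "leader", "wt", "ko"), each = n_frames),
    frame = rep(frames, times = n),
    t = rep(frames * cfg$dt, times = n),
    x = as.vector(t(out$P[, 1, , drop = TRUE])),
    y = as.vector(t(out$P[, 2, , drop = TRUE])),
    z = as.vector(t(out$P[, 3, , drop = TRUE]))
  )
  tracks <- as_track_table(tracks)
  agents <- tibble(cell_id = ids, type = type,
                   ptx = ifelse(type == "leader", cfg$ptx_leaders,
                                cfg$ptx_followers),
                   ackr3_deltaC = type == "leader" & cfg$ackr3_deltaC,
                   blt1r_ko = type == "follower" & cfg$blt1r_ko)
  f_idx <- which(type == "follower")
  activation <- tibble(
    cell_id = rep(ids[f_idx], each = n_frames),
    frame = rep(frames, times = length(f_idx)),
    activated = as.vector(t(out$act[f_idx, , drop = FALSE]))
  )
  structure(list(tracks = tracks,
                 truth = list(agents = agents, activation = activation),
                 config = cfg),
            class = "migr_sim")
}

#' @export
print.migr_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated migration experiment",
      if (!is.null(cfg$preset)) paste0("(preset '", cfg$preset, "')"), "\n")
  cat(" ", cfg$n_leaders, "leaders +", cfg$n_followers, "followers,",
      cfg$n_steps + 1, "frames at dt =", cfg$dt, "s, seed =", cfg$seed, "\n")
  invisible(x)
}

#' Transwell-surrogate readout: percent of input past a plane
#'
#' Percentage of each group's agents that crossed a plane orthogonal to
#' the gradient axis during the recording -- started at or before the
#' plane and finished beyond it -- a plane-crossing surrogate for the
#' "% of input migrated" readout of a transwell assay. A group whose
#' agents all start beyond the plane is already fully past the input
#' plane and reports 100.
#'
#' @param table A `track_table`.
#' @param plane Plane position (um) along the axis.
#' @param axis Axis orthogonal to the plane (default 1 = x, the gradient
#'   axis).
#' @return A tibble with `group`, `n` (agents at or before the plane at
#'   start) and `pct_crossed`.
#' @export
transwell_surrogate <- function(table, plane, axis = 1L) {
  validate_tracks(table)
  ax_col <- c("x", "y", "z")[axis]
  df <- as_tibble(table)
  ends <- df |>
    group_by(.data$cell_id) |>
    summarise(group = first(.data$group),
              start = .data[[ax_col]][which.min(.data$frame)],
              final = .data[[ax_col]][which.max(.data$frame)],
              .groups = "drop")
  ends |>
    group_by(.data$group) |>
    summarise(n = sum(.data$start <= plane),
              pct_crossed = if (sum(.data$start <= plane) == 0) 100 else
                100 * sum(.data$start <= plane & .data$final > plane) /
                  sum(.data$start <= plane),
              .groups = "drop")
}
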