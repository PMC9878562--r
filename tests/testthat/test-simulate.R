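# Small-scale simulator tests; population-level structure is covered by
# the acceptance suite at full preset scale.

small <- function(...) {
  sim_config(n_leaders = 10, n_followers = 10, duration = 1200, ...)
}

test_that("the attractant field is linear along the gradient axis", {
  cfg <- sim_config()
  expect_equal(cxcl12_field(c(0, 100, 50), cfg), 0)
  expect_equal(cxcl12_field(c(1000, 100, 50), cfg), 400)
  expect_equal(cxcl12_field(c(500, 100, 50), cfg), 200)
  expect_error(cxcl12_field(c(-5, 100, 50), cfg), "outside",
               class = "migratrack_validation_error")
  # erf profile is monotone with the same endpoints ordering
  cfg_e <- sim_config(gradient_profile = "erf")
  xs <- seq(0, 1000, by = 50)
  vals <- cxcl12_field(cbind(xs, 100, 50), cfg_e)
  expect_true(all(diff(vals) >= 0))
})

test_that("the LTB4 kernel sums exponential contributions of secreting
           leaders", {
  cfg <- sim_config()
  p <- c(500, 250, 50)
  expect_equal(ltb4_field(p, matrix(numeric(0), ncol = 3), cfg), 0)
  one <- matrix(p, ncol = 3)
  expect_equal(ltb4_field(p, one, cfg, secreting = TRUE), cfg$ltb4_q)
  at_lambda <- matrix(p + c(cfg$ltb4_lambda, 0, 0), ncol = 3)
  expect_equal(ltb4_field(p, at_lambda, cfg, secreting = TRUE),
               cfg$ltb4_q * exp(-1))
  # random configuration vs direct summation oracle
  set.seed(91)
  leaders <- cbind(runif(30, 0, 1000), runif(30, 0, 500), runif(30, 0, 100))
  sec <- runif(30) < 0.6
  got <- ltb4_field(p, leaders, cfg, secreting = sec)
  want <- 0
  for (j in which(sec)) {
    want <- want + cfg$ltb4_q * exp(-sqrt(sum((leaders[j, ] - p)^2)) /
                                      cfg$ltb4_lambda)
  }
  expect_equal(got, want, tolerance = 1e-12)
  # no secretion from PTX or deltaC leaders
  cfg_ptx <- sim_config(ptx_leaders = TRUE)
  expect_equal(ltb4_field(p, one, cfg_ptx), 0)
})

test_that("simulation is deterministic and respects frame arithmetic", {
  cfg <- small(seed = 4)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)

  short <- sim_config(n_leaders = 2, n_followers = 2, duration = 40, dt = 20)
  s <- simulate_tracks(short)
  expect_equal(nrow(s$tracks), 4 * 3)  # duration = 2 dt -> 3 frames each

  # agent count conserved, positions inside the arena
  expect_equal(length(unique(a$tracks$cell_id)), 20)
  expect_true(all(a$tracks$x >= 0 & a$tracks$x <= cfg$arena[1]))
  expect_true(all(a$tracks$y >= 0 & a$tracks$y <= cfg$arena[2]))
  expect_true(all(a$tracks$z >= 0 & a$tracks$z <= cfg$arena[3]))
  # activation is false at t = 0
  act0 <- a$truth$activation[a$truth$activation$frame == 0, ]
  expect_false(any(act0$activated))
})

test_that("followers without leaders are effectively stationary", {
  cfg <- sim_config(n_leaders = 0, n_followers = 30, duration = 3600,
                    seed = 5)
  sim <- simulate_tracks(cfg)
  disp <- sim$tracks |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(D = sqrt((dplyr::last(x) - dplyr::first(x))^2 +
                              (dplyr::last(y) - dplyr::first(y))^2 +
                              (dplyr::last(z) - dplyr::first(z))^2))
  # sub-arrest jitter cannot carry a cell far in an hour
  expect_lt(max(disp$D), 2 * cfg$follower_speed0 * cfg$duration / 60)
  expect_false(any(sim$truth$activation$activated))
})

test_that("a fully biased, non-persistent leader runs straight up the
           gradient with directionality 1", {
  cfg <- sim_config(n_leaders = 1, n_followers = 0, duration = 1200,
                    persistence = 0, leader_bias = 1,
                    pause_enter = 0, seed = 6)
  sim <- simulate_tracks(cfg)
  expect_true(all(diff(sim$tracks$x) >= 0))
  expect_equal(sd(sim$tracks$y), 0, tolerance = 1e-12)
  met <- tracklet_metrics(decompose_tracklets(sim$tracks,
                                              tracklet_config(W = 10)))
  expect_true(all(met$Gamma == 1))
})

test_that("unbiased walks have no net drift along the gradient", {
  cfg <- sim_config(n_leaders = 150, n_followers = 0, duration = 1200,
                    leader_bias = 0, pause_enter = 0, seed = 7,
                    arena = c(4000, 4000, 4000))
  sim <- simulate_tracks(cfg)
  dx <- sim$tracks |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(dx = dplyr::last(x) - dplyr::first(x))
  se <- sd(dx$dx) / sqrt(nrow(dx))
  expect_lte(abs(mean(dx$dx)), 3 * se)
})

test_that("presets encode the experimental arms", {
  expect_equal(sim_preset("ko_alone")$n_leaders, 0L)
  expect_equal(sim_preset("wt_alone")$n_followers, 0L)
  m <- sim_preset("mixed_1to1")
  expect_equal(m$n_leaders, m$n_followers)
  b <- sim_preset("mixed_blt1rko")
  expect_true(b$blt1r_ko)
  for (f in c("n_leaders", "n_followers", "leader_speed", "persistence",
              "ltb4_threshold")) {
    expect_equal(b[[f]], m[[f]])
  }
  expect_true(sim_preset("mixed_ptx_wt")$ptx_leaders)
  expect_true(sim_preset("mixed_ptx_ko")$ptx_followers)
  expect_true(sim_preset("mixed_deltaC")$ackr3_deltaC)
  expect_error(sim_preset("nope"))
})

test_that("config validation rejects impossible parameterizations", {
  expect_error(sim_config(dt = 30, duration = 100), "divide",
               class = "migratrack_config_error")
  expect_error(sim_config(persistence = 1), class = "migratrack_config_error")
  expect_error(sim_config(n_leaders = 0, n_followers = 0),
               class = "migratrack_config_error")
  expect_error(sim_config(arena = c(-1, 10, 10)),
               class = "migratrack_config_error")
})

test_that("the transwell surrogate counts plane crossings of the input", {
  # all agents start beyond the plane -> trivially 100% past the input
  still <- as_track_table(dplyr::bind_rows(
    make_track(matrix(900, 3, 3), cell_id = "a", group = "wt"),
    make_track(matrix(950, 3, 3), cell_id = "b", group = "wt")))
  tw <- transwell_surrogate(still, plane = 500)
  expect_equal(tw$pct_crossed, 100)

  crosser <- as_track_table(dplyr::bind_rows(
    make_track(straight_positions(5, step = c(100, 0, 0)),
               cell_id = "go", group = "wt"),     # 0 -> 400, plane 200
    make_track(matrix(10, 5, 3), cell_id = "stay", group = "wt")))
  tw2 <- transwell_surrogate(crosser, plane = 200)
  expect_equal(tw2$pct_crossed, 50)
})

test_that("deposit-mode cues rescue followers near a paused leader", {
  # force frequent pausing so cues are actually dropped
  cfg <- sim_config(n_leaders = 20, n_followers = 20, duration = 3600,
                    ltb4_mode = "deposit", pause_enter = 0.2,
                    pause_exit = 0.05, seed = 9)
  sim <- simulate_tracks(cfg)
  expect_true(any(sim$truth$activation$activated))
})

test_that("with no bias anywhere, motile agents are chemokinetic rather
           than directional", {
  cfg <- sim_config(n_leaders = 100, n_followers = 0, duration = 7200,
                    leader_bias = 0, seed = 10)
  sim <- simulate_tracks(cfg)
  met <- tracklet_metrics(decompose_tracklets(sim$tracks))
  g <- gate_count_matrix(gate_counts(met, gate_config(
    seed = 1, sample_N = 1000, allow_short_groups = TRUE)))
  expect_lte(g["wt", "directional"], g["wt", "chemokinesis"])
})
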