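test_that("decomposition yields the expected window count and starts", {
  cases <- list(
    list(n = 30, W = 10, s = 10, n_tr = 3, starts = c(0, 10, 20)),
    list(n = 9, W = 10, s = 10, n_tr = 0, starts = integer(0)),
    list(n = 25, W = 10, s = 5, n_tr = 4, starts = c(0, 5, 10, 15))
  )
  for (cs in cases) {
    tab <- make_track(straight_positions(cs$n, step = c(1, 0, 0)))
    cfg <- tracklet_config(W = cs$W, stride = cs$s)
    tr <- suppressMessages(decompose_tracklets(tab, cfg))
    expect_equal(nrow(tr), cs$n_tr * cs$W)
    expect_equal(unique(tr$start_frame), cs$starts)
  }
})

test_that("track summary metrics match hand calculations", {
  s <- summarize_track(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)), dt = 60)
  expect_equal(s$D, 20)
  expect_equal(s$L, 20)
  expect_equal(s$v, 10)

  # out-and-back: displacement cancels, path does not
  s2 <- summarize_track(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 0, 0)), dt = 60)
  expect_equal(s2$D, 0)
  expect_equal(s2$L, 20)
  expect_equal(s2$v, 10)

  expect_error(summarize_track(matrix(0, 1, 3), dt = 60), "2 frames")
})

test_that("path length of a long random walk matches per-step summation", {
  set.seed(11)
  pos <- random_walk_positions(101, sd = 3)
  s <- summarize_track(pos, dt = 20)
  # independent oracle: explicit per-step loop
  L <- 0
  for (k in 1:100) L <- L + sqrt(sum((pos[k + 1, ] - pos[k, ])^2))
  expect_equal(s$L, L, tolerance = 1e-12)
})

test_that("arrest coefficient counts sub-threshold steps", {
  cfg <- tracklet_config(v_arrest = 2)
  still <- matrix(5, nrow = 6, ncol = 3)
  expect_equal(arrest_coefficient(still, dt = 20, cfg), 1)

  fast <- straight_positions(6, step = c(10, 0, 0))  # 10 um per min at dt=60
  expect_equal(arrest_coefficient(fast, dt = 60, cfg), 0)

  # 10 steps, exactly 4 below threshold: speeds alternate 0.6 and 6 um/min
  steps <- c(rep(0.2, 4), rep(2, 6))  # um per 20 s -> 0.6 / 6 um/min
  pos <- cbind(cumsum(c(0, steps)), 0, 0)
  expect_equal(arrest_coefficient(pos, dt = 20, cfg), 0.4)
})

test_that("directionality is straightness with a polarity fallback", {
  cfg <- tracklet_config()
  expect_equal(directionality(straight_positions(10), dt = 20, cfg), 1)

  # two perpendicular 10 um legs
  legs <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0))
  expect_equal(directionality(legs, dt = 20, cfg), sqrt(2) / 2,
               tolerance = 1e-12)

  # stationary but polarized: fallback to polarity coherence
  still <- matrix(1, nrow = 5, ncol = 3)
  pol <- matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE)
  expect_equal(directionality(still, dt = 20, cfg, polarity = pol), 1)
  # without polarity the near-stationary tracklet scores 0
  expect_equal(directionality(still, dt = 20, cfg), 0)
})

test_that("vectorized metrics equal an independent brute-force pass", {
  set.seed(21)
  tabs <- lapply(1:100, function(i) {
    make_track(random_walk_positions(10, sd = runif(1, 0.1, 10)),
               cell_id = sprintf("c%03d", i),
               group = sample(c("wt", "ko"), 1))
  })
  tab <- as_track_table(dplyr::bind_rows(tabs))
  cfg <- tracklet_config(W = 10)
  met <- tracklet_metrics(decompose_tracklets(tab, cfg), cfg)
  expect_equal(nrow(met), 100)
  for (i in seq_len(nrow(met))) {
    cc <- tab[tab$cell_id == met$cell_id[i], ]
    o <- oracle_metrics(as.matrix(cc[, c("x", "y", "z")]), dt = 20)
    expect_equal(met$D[i], o$D, tolerance = 1e-12)
    expect_equal(met$L[i], o$L, tolerance = 1e-12)
    expect_equal(met$v[i], o$v, tolerance = 1e-12)
    expect_equal(met$A[i], o$A, tolerance = 1e-12)
    expect_equal(met$Gamma[i], o$Gamma, tolerance = 1e-12)
  }
})

test_that("tracklet metrics equal stand-alone track metrics on the same positions", {
  set.seed(31)
  pos <- random_walk_positions(10, sd = 4)
  tab <- make_track(pos)
  cfg <- tracklet_config(W = 10)
  met <- tracklet_metrics(decompose_tracklets(tab, cfg), cfg)
  s <- summarize_track(pos, dt = 20)
  expect_equal(met$D, s$D)
  expect_equal(met$L, s$L)
  expect_equal(met$v, s$v)
  expect_equal(met$A, arrest_coefficient(pos, 20, cfg))
  expect_equal(met$Gamma, directionality(pos, 20, cfg))
})

test_that("metrics are invariant under rigid motion and D <= L always", {
  set.seed(41)
  cfg <- tracklet_config(W = 10)
  for (i in 1:50) {
    pos <- random_walk_positions(10, sd = runif(1, 0.05, 8))
    moved <- rigid_transform(pos)
    m1 <- summarize_track(pos, 20)
    m2 <- summarize_track(moved, 20)
    expect_equal(m1$D, m2$D, tolerance = 1e-9)
    expect_equal(m1$L, m2$L, tolerance = 1e-9)
    expect_lte(m1$D, m1$L + 1e-12)
    expect_equal(arrest_coefficient(pos, 20, cfg),
                 arrest_coefficient(moved, 20, cfg))
    expect_equal(directionality(pos, 20, cfg),
                 directionality(moved, 20, cfg), tolerance = 1e-9)
  }
})

test_that("a ballistic tracklet has directionality 1 at any speed and a
           step-function arrest around the true speed", {
  cfg_lo <- tracklet_config(v_arrest = 0.5)
  cfg_hi <- tracklet_config(v_arrest = 50)
  for (speed in c(0.5, 1, 10)) {  # um/min at dt = 60 s (path >= eps_path)
    pos <- straight_positions(10, step = c(speed, 0, 0))
    expect_equal(directionality(pos, 60, tracklet_config()), 1)
  }
  pos <- straight_positions(10, step = c(5, 0, 0))  # 5 um/min
  expect_equal(arrest_coefficient(pos, 60, cfg_lo), 0)
  expect_equal(arrest_coefficient(pos, 60, cfg_hi), 1)
})

test_that("metrics_table behaviors: empty input, archetypes, row counts", {
  cfg <- tracklet_config(W = 5)
  empty <- suppressMessages(
    decompose_tracklets(make_track(straight_positions(3)), cfg))
  expect_equal(nrow(tracklet_metrics(empty, cfg)), 0)

  still <- make_track(matrix(2, 5, 3), cell_id = "still")
  ball <- make_track(straight_positions(5, step = c(5, 0, 0)),
                     cell_id = "ball")
  tab <- as_track_table(dplyr::bind_rows(still, ball))
  met <- tracklet_metrics(decompose_tracklets(tab, cfg), cfg)
  expect_equal(nrow(met), 2)
  ms <- met[met$cell_id == "still", ]
  mb <- met[met$cell_id == "ball", ]
  expect_equal(ms$A, 1)
  expect_equal(ms$Gamma, 0)
  expect_equal(mb$A, 0)
  expect_equal(mb$Gamma, 1)
})
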