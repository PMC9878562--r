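# Fixtures: hand-built constellations of leaders and followers on a
# uniform 20 s grid, with gates assigned through the normal machinery.

# A leader that marches and a gate table that marks it motile everywhere.
fixture_two_cells <- function(dist_um, n = 10) {
  leader <- make_track(straight_positions(n, step = c(2, 0, 0)),
                       cell_id = "L1", group = "wt")
  follower <- make_track(matrix(rep(c(0, dist_um, 0), n), ncol = 3,
                                byrow = TRUE),
                         cell_id = "F1", group = "ko")
  tab <- as_track_table(dplyr::bind_rows(leader, follower))
  cfg <- tracklet_config(W = n)
  gated <- classify_tracklets(tracklet_metrics(decompose_tracklets(tab, cfg),
                                               cfg),
                              gate_config())
  list(tab = tab, gated = gated)
}

test_that("the 50 um neighbor boundary is inclusive", {
  near <- fixture_two_cells(49.9)
  far <- fixture_two_cells(50.1)
  expect_equal(motile_neighbor_count(near$tab, near$gated, "F1", t = 0), 1L)
  expect_equal(motile_neighbor_count(far$tab, far$gated, "F1", t = 0), 0L)
  # exact boundary counts (<= r)
  at <- fixture_two_cells(50)
  expect_equal(motile_neighbor_count(at$tab, at$gated, "F1", t = 0), 1L)
})

test_that("an isolated focal cell has zero motile neighbors and
           out-of-range times error", {
  solo <- make_track(straight_positions(10), cell_id = "F1", group = "ko")
  cfg <- tracklet_config(W = 10)
  gated <- classify_tracklets(tracklet_metrics(decompose_tracklets(solo, cfg),
                                               cfg), gate_config())
  expect_equal(motile_neighbor_count(solo, gated, "F1", t = 0), 0L)
  expect_error(motile_neighbor_count(solo, gated, "F1", t = 1e6),
               "not an observed frame",
               class = "migratrack_validation_error")
})

test_that("neighbor counts match an all-pairs brute-force scan on 200 cells", {
  set.seed(61)
  n_cells <- 200
  n_frames <- 50
  tabs <- lapply(seq_len(n_cells), function(i) {
    make_track(random_walk_positions(n_frames, sd = 8,
                                     origin = runif(3, 0, 300)),
               cell_id = sprintf("c%03d", i),
               group = if (i <= 100) "wt" else "ko")
  })
  tab <- as_track_table(dplyr::bind_rows(tabs))
  cfg_t <- tracklet_config(W = 10)
  gated <- classify_tracklets(
    tracklet_metrics(decompose_tracklets(tab, cfg_t), cfg_t), gate_config())
  cfg_n <- neighborhood_config(radius = 50)
  cv <- conditional_velocity(tab, gated, cfg_n)

  # independent oracle: plain loops over cells and frames
  W <- 10
  motile_lookup <- function(cell, frame) {
    rows <- gated[gated$cell_id == cell, ]
    rows <- rows[rows$start_frame <= frame &
                   frame < rows$start_frame + W, ]
    if (nrow(rows) == 0) return(FALSE)
    rows <- rows[which.max(rows$start_frame), ]
    as.character(rows$gate) %in% c("chemokinesis", "directional")
  }
  df <- as.data.frame(tab)
  check <- cv$records[sample(nrow(cv$records), 50), ]
  for (i in seq_len(nrow(check))) {
    rec <- check[i, ]
    here <- df[df$frame == rec$frame, ]
    fpos <- unlist(here[here$cell_id == rec$cell_id, c("x", "y", "z")])
    cnt <- 0
    for (j in seq_len(nrow(here))) {
      if (here$cell_id[j] == rec$cell_id || here$group[j] != "wt") next
      d <- sqrt(sum((unlist(here[j, c("x", "y", "z")]) - fpos)^2))
      if (d <= 50 && motile_lookup(here$cell_id[j], rec$frame)) cnt <- cnt + 1
    }
    expect_equal(rec$n_motile, cnt)
  }
})

test_that("conditional velocity separates constructed bins exactly", {
  # follower near a motile leader moves at 5 um/min; isolated follower at 1
  n <- 10
  leader <- make_track(straight_positions(n, step = c(4, 0, 0),
                                          origin = c(0, 0, 0)),
                       cell_id = "L1", group = "wt")
  near_f <- make_track(straight_positions(n, step = c(5 / 3, 0, 0),
                                          origin = c(0, 10, 0)),
                       cell_id = "F1", group = "ko")
  far_f <- make_track(straight_positions(n, step = c(1 / 3, 0, 0),
                                         origin = c(5000, 5000, 0)),
                      cell_id = "F2", group = "ko")
  tab <- as_track_table(dplyr::bind_rows(leader, near_f, far_f))
  cfg_t <- tracklet_config(W = n)
  gated <- classify_tracklets(
    tracklet_metrics(decompose_tracklets(tab, cfg_t), cfg_t), gate_config())
  cv <- conditional_velocity(tab, gated, neighborhood_config())
  s <- cv$summary[cv$summary$group == "ko", ]
  expect_equal(s$mean_velocity[s$bin == "1"], 5, tolerance = 1e-9)
  expect_equal(s$mean_velocity[s$bin == "0"], 1, tolerance = 1e-9)
})

test_that("immobile-gated leaders never count as motile neighbors", {
  n <- 10
  leader <- make_track(matrix(rep(c(0, 10, 0), n), ncol = 3, byrow = TRUE),
                       cell_id = "L1", group = "wt")
  follower <- make_track(straight_positions(n, step = c(2, 0, 0)),
                         cell_id = "F1", group = "ko")
  tab <- as_track_table(dplyr::bind_rows(leader, follower))
  cfg_t <- tracklet_config(W = n)
  gated <- classify_tracklets(
    tracklet_metrics(decompose_tracklets(tab, cfg_t), cfg_t), gate_config())
  cv <- conditional_velocity(tab, gated, neighborhood_config())
  expect_true(all(cv$records$n_motile == 0))
})

test_that("directionality series and events behave on canonical shapes", {
  cfg <- neighborhood_config(turn_angle = 45)
  ballistic <- make_track(straight_positions(20, step = c(2, 0, 0)))
  s <- directionality_series(ballistic, window = 10, cfg = cfg)
  expect_true(all(s$series$gamma == 1))
  expect_equal(nrow(s$events), 0)

  # single 90 degree turn -> one event at the turn frame
  pos <- rbind(straight_positions(10, step = c(2, 0, 0)),
               t(c(18, 0, 0) + outer(c(0, 2, 0), 1:9)))
  turn <- make_track(pos)
  s2 <- directionality_series(turn, window = 10, cfg = cfg)
  expect_equal(nrow(s2$events), 1)
  expect_equal(s2$events$frame, 9)

  still <- make_track(matrix(3, 15, 3))
  s3 <- directionality_series(still, window = 10, cfg = cfg)
  expect_equal(nrow(s3$events), 0)
})

test_that("lead-lag scoring handles perfect precedence, absence and nulls", {
  cfg <- neighborhood_config(lag_window = 60, n_perm = 999)
  period <- c(0, 3600)
  # every follower event exactly one frame (20 s) after a leader event
  lead <- seq(100, 3000, by = 200)
  foll <- lead + 20
  sc <- lead_lag_score(foll, lead, cfg, period, seed = 1)
  expect_equal(sc$fraction, 1)
  expect_lt(sc$p_value, 0.05)

  # no leader events -> fraction 0 (not undefined)
  sc0 <- lead_lag_score(foll, numeric(0), cfg, period, seed = 1)
  expect_equal(sc0$fraction, 0)

  # zero follower events -> undefined, distinctly signaled
  scna <- lead_lag_score(numeric(0), lead, cfg, period, seed = 1)
  expect_true(is.na(scna$fraction))
  expect_equal(scna$status, "no_follower_events")
})

test_that("independent event trains score near the circular-shift null", {
  set.seed(71)
  period <- c(0, 7200)
  cfg <- neighborhood_config(lag_window = 60, n_perm = 999)
  lead <- sort(runif(40, 0, 7200))
  foll <- sort(runif(30, 0, 7200))
  sc <- lead_lag_score(foll, lead, cfg, period, seed = 2)
  expect_lte(abs(sc$fraction - sc$null_mean), 3 * sc$null_sd + 1e-12)
  expect_gt(sc$p_value, 0.01)
})

test_that("time reversal of symmetric event trains preserves the score", {
  cfg <- neighborhood_config(lag_window = 60, n_perm = 99)
  period <- c(0, 1000)
  lead <- c(100, 300, 500, 700, 900)
  foll <- lead + 20
  fwd <- lead_lag_score(foll, lead, cfg, period, seed = 3)
  # reversed: follower events precede leader events by the same margins
  rev_lead <- sort(1000 - foll)
  rev_foll <- sort(1000 - lead)
  bwd <- lead_lag_score(rev_foll, rev_lead, cfg, period, seed = 3)
  expect_equal(fwd$fraction, bwd$fraction)
})

test_that("neighborhood mean directionality averages in-radius neighbors", {
  n <- 12
  focal <- make_track(matrix(1, n, 3), cell_id = "F", group = "ko")
  mk <- function(id, gamma_target, offset) {
    # constant-velocity tracks have gamma 1; a stationary one has gamma 0;
    # here use straight (gamma 1) and still (gamma 0) neighbors
    if (gamma_target == 1) {
      make_track(straight_positions(n, step = c(2, 0, 0), origin = offset),
                 cell_id = id, group = "wt")
    } else {
      make_track(matrix(rep(offset, n), ncol = 3, byrow = TRUE),
                 cell_id = id, group = "wt")
    }
  }
  tab <- as_track_table(dplyr::bind_rows(
    focal, mk("N1", 1, c(0, 10, 0)), mk("N2", 0, c(0, 20, 0))))
  out <- neighborhood_mean_directionality(tab, "F",
                                          neighborhood_config(radius = 100),
                                          window = 6)
  mid <- out$mean_gamma[out$frame == 6]
  expect_equal(out$n_neighbors[out$frame == 6], 2)
  expect_equal(mid, 0.5)

  # no neighbors ever -> all gaps
  lonely <- neighborhood_mean_directionality(
    as_track_table(focal), "F", neighborhood_config(), window = 6)
  expect_true(all(is.na(lonely$mean_gamma)))
})

test_that("common origin translates starts to zero and matches D", {
  set.seed(81)
  pos <- random_walk_positions(15, sd = 5, origin = c(100, 200, 300))
  tab <- make_track(pos)
  out <- common_origin(tab)
  expect_equal(unlist(out[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  s <- summarize_track(pos, dt = 20)
  expect_equal(out$disp[nrow(out)], s$D, tolerance = 1e-12)

  shifted <- make_track(pos + matrix(rep(c(7, -3, 11), 15), ncol = 3,
                                     byrow = TRUE),
                        cell_id = "c2")
  out2 <- common_origin(as_track_table(shifted))
  expect_equal(out$x, out2$x, tolerance = 1e-9)
  expect_equal(out$disp, out2$disp, tolerance = 1e-9)
})
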