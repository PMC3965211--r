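test_that("a noiseless constant-velocity ramp yields one processive segment", {
  t <- seq(0, 30, by = 0.5)
  s <- segment_track(data.frame(t_s = t, arc_pos_um = 0.14 * t))
  expect_equal(nrow(s$segments), 1)
  expect_equal(s$segments$state, "PROCESSIVE_PLUS")
  expect_equal(s$segments$velocity_nm_s, 140, tolerance = 1 / 140)

  sm <- segment_track(data.frame(t_s = t, arc_pos_um = 5 - 0.14 * t))
  expect_equal(sm$segments$state, "PROCESSIVE_MINUS")
  expect_equal(sm$segments$velocity_nm_s, -140, tolerance = 1 / 140)
})

test_that("a mid-track plateau is one pause of the constructed duration", {
  t <- seq(0, 40, by = 0.5)
  pos <- cumsum(c(0, ifelse(t[-1] > 15 & t[-1] <= 21, 0, 0.14 * 0.5)))
  s <- segment_track(data.frame(t_s = t, arc_pos_um = pos))
  paused <- s$segments[s$segments$state == "PAUSED", ]
  expect_equal(nrow(paused), 1)
  expect_equal(paused$duration_s, 6, tolerance = 1 / 6)
  # segments tile the track without overlap
  expect_equal(s$segments$start_idx[1], 1)
  expect_equal(s$segments$end_idx[nrow(s$segments)], length(t))
  expect_true(all(s$segments$start_idx[-1] ==
                    head(s$segments$end_idx, -1) + 1))
})

test_that("tracks shorter than the window are rejected", {
  expect_error(segment_track(data.frame(t_s = c(0, 0.5), arc_pos_um = c(0, 0))),
               "too short")
})

test_that("segment labels agree with generator truth on >= 90% of attached time", {
  agree <- unlist(lapply(seq_along(shared_analysis$kept), function(k) {
    tr <- shared_ensemble[[shared_analysis$kept[k]]]
    frame_labels(shared_analysis$segmented[[k]]) == tr$points$state
  }))
  expect_gt(length(agree), 10000)
  expect_gte(mean(agree), 0.90)
})

test_that("run metrics: single clean run, and the pause-bridging rule", {
  t <- seq(0, 14, by = 0.5)
  s <- segment_track(data.frame(t_s = t, arc_pos_um = (2 / 14) * t))
  m <- compute_run_metrics(s)
  expect_equal(m$run_lengths, 2.0, tolerance = 1e-6)
  expect_equal(m$pause_count, 0)

  # 1.0 um run + 6 s pause + 0.9 um run, same direction -> one bridged run
  v <- 0.14
  t2 <- seq(0, 1 / v + 6 + 0.9 / v, by = 0.5)
  pos2 <- vapply(t2, function(x) {
    if (x <= 1 / v) v * x
    else if (x <= 1 / v + 6) 1.0
    else 1.0 + v * (x - 1 / v - 6)
  }, numeric(1))
  m2 <- compute_run_metrics(segment_track(data.frame(t_s = t2, arc_pos_um = pos2)))
  expect_equal(length(m2$run_lengths), 1)
  expect_equal(m2$run_lengths, 1.9, tolerance = 0.02)
  expect_equal(m2$pause_count, 1)
  expect_equal(m2$pause_durations, 6, tolerance = 1 / 6)
})

test_that("pause frequency is total pauses over total processive path", {
  mk <- function(n_pauses, path) {
    structure(list(pause_count = n_pauses, pause_durations = rep(1, n_pauses),
                   processive_path_um = path), class = "run_metrics")
  }
  expect_equal(pause_frequency(lapply(1:10, function(i) mk(0, 1)))$frequency_per_um, 0)
  expect_equal(pause_frequency(list(mk(3, 10)))$frequency_per_um, 0.30)
  expect_error(pause_frequency(list(mk(0, 0))), "zero processive path")
  grp <- pause_frequency(list(mk(3, 10), mk(2, 10), mk(4, 10)),
                         experiment = c(1, 2, 3))
  expect_equal(grp$mean, 0.3, tolerance = 1e-9)
  expect_equal(grp$sd, 0.1, tolerance = 1e-9)
})

test_that("pipeline recovers the configured motility statistics at n=250", {
  sm <- motility_summary(shared_analysis, seed = 5)
  expect_equal(sm$velocity$median, 137.8, tolerance = 0.10)
  expect_equal(sm$run_length$median, 1.9, tolerance = 0.10)
  expect_equal(sm$residency$median, 26.3, tolerance = 0.10)
  expect_equal(sm$pause_duration$median, 5.0, tolerance = 0.15)
  expect_equal(sm$pause_frequency$frequency_per_um, 0.30, tolerance = 0.04 / 0.30)
})

test_that("motile fraction normalization against a control", {
  mk <- function(motile) structure(list(motile = motile), class = "run_metrics")
  ctrl <- c(lapply(1:90, function(i) mk(TRUE)), lapply(1:10, function(i) mk(FALSE)))
  expect_equal(motile_fraction(ctrl, 100, ctrl, 100)$motile_fraction, 1.0)
  cond <- c(lapply(1:27, function(i) mk(TRUE)), lapply(1:10, function(i) mk(FALSE)))
  expect_equal(motile_fraction(cond, 100, ctrl, 100)$motile_fraction, 0.30)
  allstatic <- lapply(1:50, function(i) mk(FALSE))
  expect_equal(motile_fraction(allstatic, 100, ctrl, 100)$motile_fraction, 0)
  expect_error(motile_fraction(ctrl, 100, allstatic, 100), "normalization")
})

test_that("residency censored at 180 s still recovers the median within 10%", {
  # right-censoring: drop tracks attached at the end of the window (the
  # analysis path) rather than truncating their values
  ens <- simulate_ensemble(default_params, long_mt, 600, seed = 88, t_max = 180)
  an <- analyze_tracks(ens, long_mt)
  sm <- motility_summary(an, seed = 1)
  expect_gt(sm$n_censored_residency, 0)
  expect_equal(sm$residency$median, 26.3, tolerance = 0.10)
  expect_gt(sm$residency$observed_max, 100)
})
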