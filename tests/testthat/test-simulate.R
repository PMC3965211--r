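test_that("simulation is a pure function of (params, network, seed)", {
  a <- simulate_trajectory(default_params, long_mt, seed = 42)
  b <- simulate_trajectory(default_params, long_mt, seed = 42)
  expect_identical(a$points, b$points)
  expect_identical(a$truth, b$truth)
  c <- simulate_trajectory(default_params, long_mt, seed = 43)
  expect_false(identical(a$points, c$points))
  # an ensemble member equals a direct call with the derived seed
  ens <- simulate_ensemble(default_params, long_mt, 3, seed = 9)
  expect_identical(ens[[2]]$points,
                   simulate_trajectory(default_params, long_mt,
                                       seed = derive_seed(9, 2))$points)
})

test_that("argument errors are raised", {
  expect_error(simulate_trajectory(default_params, long_mt, dt = 0), "dt")
  expect_error(simulate_trajectory(default_params, long_mt,
                                   t_max = 0.1, dt = 0.5), "t_max")
})

test_that("zero pause rate produces no paused points", {
  p0 <- motility_params(pause_rate = 0)
  for (i in 1:60) {
    tr <- simulate_trajectory(p0, long_mt, seed = 100 + i)
    expect_false(any(tr$points$state == "PAUSED"))
  }
})

test_that("generator-truth run lengths have the configured exponential median", {
  ens <- simulate_ensemble(default_params, long_mt, 1000, seed = 5, t_max = 120)
  runs <- do.call(rbind, lapply(ens, function(x) x$truth$runs))
  done <- runs$length_um[runs$v_nm_s > 0 & runs$end_type == "run_end"]
  expect_gt(length(done), 700)
  expect_gt(median(done), 1.8)
  expect_lt(median(done), 2.0)
  # exponential parameterisation: median m implies mean m / ln 2
  expect_equal(mean(runs$L_drawn_um[runs$v_nm_s > 0]), 1.9 / log(2),
               tolerance = 0.06)
})

test_that("dwell-time ingredients pass KS tests against their configured laws", {
  ens <- simulate_ensemble(default_params, short_mt, 900, seed = 8, t_max = 250)
  p <- default_params
  dwell <- unlist(lapply(ens, function(x) x$truth$dwells$dur_drawn))
  expect_gt(length(dwell), 250)
  expect_true(all(dwell >= p$end_dwell_min))
  expect_gt(stats::ks.test(dwell - p$end_dwell_min, stats::pexp,
                           rate = log(2) / (p$end_dwell_med - p$end_dwell_min))$p.value,
            0.01)
  expect_equal(median(dwell), p$end_dwell_med, tolerance = 0.08)

  ens2 <- simulate_ensemble(default_params, long_mt, 700, seed = 9, t_max = 180)
  pause <- unlist(lapply(ens2, function(x) x$truth$pauses$dur_drawn))
  expect_gt(length(pause), 400)
  cdf <- function(q) kinetrax:::ptrunc_exp(q, p$pause_rexp_rate,
                                           p$pause_dur_min, p$pause_dur_max)
  expect_gt(stats::ks.test(pause, cdf)$p.value, 0.01)
  # observable pause median equals the configured one by construction
  expect_equal(median(pause), p$pause_dur_med, tolerance = 0.08)

  runs <- do.call(rbind, lapply(ens2, function(x) x$truth$runs))
  done <- runs$L_drawn_um[runs$v_nm_s > 0]
  expect_gt(stats::ks.test(done, stats::pexp,
                           rate = log(2) / p$run_len_med_plus)$p.value, 0.01)
})

test_that("realized residency median matches the configured value", {
  ens <- simulate_ensemble(default_params, long_mt, 1200, seed = 13)
  plus <- sapply(ens, function(x) identical(x$truth$direction, "plus"))
  res <- sapply(ens, function(x) x$truth$residency_s)
  med <- median(res[plus], na.rm = TRUE)
  expect_equal(med, default_params$residency_med, tolerance = 0.08)
})

test_that("trajectory points are on-lattice and time is uniform", {
  for (i in 1:30) {
    tr <- simulate_trajectory(default_params, grid_network, seed = 300 + i)
    pts <- tr$points
    if (nrow(pts) < 2) next
    expect_equal(diff(pts$t_s), rep(tr$dt, nrow(pts) - 1))
    xy <- arc_to_xy(grid_network, pts$mt_id, pts$arc_pos_um)
    expect_equal(pts$x_um, unname(xy[, 1]))
    expect_equal(pts$y_um, unname(xy[, 2]))
    expect_true(all(pts$arc_pos_um >= 0))
    expect_true(all(pts$arc_pos_um <= mt_length(grid_network, pts$mt_id) + 1e-9))
  }
})

test_that("switch events keep the xy path continuous through the crossing", {
  found <- 0
  for (i in 1:300) {
    tr <- simulate_trajectory(default_params, grid_network, seed = 7000 + i)
    enc <- tr$truth$encounters
    if (is.null(enc) || !any(enc$outcome == "SWITCH")) next
    found <- found + 1
    pts <- tr$points
    if (nrow(pts) < 2) next
    step_xy <- sqrt(diff(pts$x_um)^2 + diff(pts$y_um)^2)
    # largest conceivable per-frame motion: velocity, diffusion, or the jump
    # onto the crossing microtubule within the capture radius
    vmax_um <- default_params$v_max / 1000 * tr$dt
    diff_99 <- 4 * sqrt(2 * default_params$D_diff * tr$dt)
    expect_lt(max(step_xy), max(vmax_um, diff_99) +
                2 * default_params$capture_radius_nm / 1000)
  }
  expect_gt(found, 10)
})

test_that("directional mixture and static fraction follow their probabilities", {
  ens <- simulate_ensemble(default_params, long_mt, 504, seed = 3)
  plus <- mean(sapply(ens, function(x) x$truth$direction) == "plus")
  ci <- qbinom(c(0.025, 0.975), 504, 0.875) / 504
  expect_gte(plus, ci[1])
  expect_lte(plus, ci[2])

  ps <- motility_params(p_static = 0.7)
  ens2 <- simulate_ensemble(ps, long_mt, 1000, seed = 4, t_max = 30)
  st <- mean(sapply(ens2, function(x) isTRUE(x$truth$static)))
  ci2 <- qbinom(c(0.005, 0.995), 1000, 0.7) / 1000
  expect_gte(st, ci2[1])
  expect_lte(st, ci2[2])
})

test_that("mode interconversion produces diffusive episodes that end runs", {
  pm <- motility_params(p_mode_switch = 0.1)
  ens <- simulate_ensemble(pm, long_mt, 120, seed = 6)
  runs <- do.call(rbind, lapply(ens, function(x) x$truth$runs))
  expect_true(any(runs$end_type == "mode_switch"))
  has_diff <- any(sapply(ens, function(x) any(x$points$state == "DIFFUSIVE") &&
                           any(x$truth$runs$end_type == "mode_switch")))
  expect_true(has_diff)
})
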