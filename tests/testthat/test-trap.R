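test_that("a motor that never steps leaves the bead at the trap centre", {
  tp <- trap_params(stepping_rate = 0, noise_sd = 0)
  tr <- simulate_trap_trace(tp, 1, seed = 1)
  expect_true(all(tr$bead_pos_nm == 0))
  expect_equal(nrow(tr$truth), 0)
})

test_that("load arithmetic: detachment at threshold / stiffness", {
  # single engagement, no rebind, stiffness 0.05 pN/nm: a 2.5 pN threshold
  # releases at a 50 nm excursion
  tp <- trap_params(stiffness = 0.05, detach_load_low = 2.5,
                    detach_load_high = 2.5, noise_sd = 0, rebind = FALSE)
  tr <- simulate_trap_trace(tp, 5, seed = 2)
  expect_equal(nrow(tr$truth), 1)
  expect_equal(tr$truth$excursion_nm, 50)
  expect_equal(tr$truth$load_pN, 2.5)
  expect_equal(tr$truth$load_pN, tp$stiffness * tr$truth$excursion_nm)
  expect_equal(max(tr$bead_pos_nm), 50)
})

test_that("true detachment loads are uniform on [1.5, 3.5] pN", {
  tp <- trap_params(noise_sd = 0)
  loads <- c()
  i <- 0
  while (length(loads) < 1000) {
    i <- i + 1
    tr <- simulate_trap_trace(tp, 100, seed = 100 + i)
    loads <- c(loads, tr$truth$load_pN[tr$truth$type == "processive"])
  }
  loads <- loads[1:1000]
  expect_true(all(loads >= 1.5 & loads <= 3.5))
  expect_gt(stats::ks.test(loads, stats::punif, 1.5, 3.5)$p.value, 0.01)
})

test_that("boxcar filter: constant, impulse response and noise variance", {
  x <- rep(3, 1000)
  expect_equal(boxcar_filter(x, width = 10, sample_rate = 1), x)

  imp <- c(rep(0, 100), 1, rep(0, 100))
  w <- 11
  f <- boxcar_filter(imp, width = w, sample_rate = 1)
  expect_equal(sum(f > 1e-12), w)
  expect_equal(max(f), 1 / w)
  expect_equal(sum(f[90:110] == 1 / w), w)

  set.seed(5)
  noise <- rnorm(1e6)
  fw <- boxcar_filter(noise, width = 22, sample_rate = 1)
  core <- fw[100:(1e6 - 100)]
  expect_equal(sd(core), 1 / sqrt(22), tolerance = 0.1)

  expect_error(boxcar_filter(1:10, width = 1, sample_rate = 1), "width")
})

test_that("detachment detector finds events with loads exact versus truth", {
  tp <- trap_params(noise_sd = 0)
  tr <- simulate_trap_trace(tp, 30, seed = 6)
  ev <- detect_detachments(boxcar_filter(tr), tp)
  tru <- tr$truth[tr$truth$type == "processive", ]
  expect_equal(nrow(ev), nrow(tru))
  err <- vapply(seq_len(nrow(ev)), function(i) {
    ev$load_pN[i] - tru$load_pN[which.min(abs(tru$t_detach - ev$t_s[i]))]
  }, numeric(1))
  expect_lt(max(abs(err)), 0.2)
})

test_that("detector stays quiet on motor-free noise traces", {
  tp <- trap_params(stepping_rate = 0, noise_sd = 2)
  n_ev <- vapply(1:40, function(i) {
    tr <- simulate_trap_trace(tp, 1, seed = 500 + i)
    nrow(detect_detachments(boxcar_filter(tr), tp))
  }, numeric(1))
  expect_gte(mean(n_ev == 0), 0.95)
})

test_that("zero-load velocity: ramp, stepping statistics, stationary trace", {
  v <- zero_load_velocity(140 * seq(0, 10, 0.1), dt = 0.1)
  expect_equal(v$v_nm_s, 140, tolerance = 1e-9) # 140 nm/s ramp

  # 8 nm stepper at 17.2 steps/s -> 137.6 nm/s
  vs <- mean(vapply(1:40, function(i) {
    pos <- simulate_stepping_trace(17.2, 8, t_max = 20, dt = 0.1,
                                   seed = 700 + i)
    zero_load_velocity(pos, 0.1)$v_nm_s
  }, numeric(1)))
  expect_equal(vs, 137.6, tolerance = 0.05)

  set.seed(9)
  still <- rnorm(100, 0, 2)
  vz <- zero_load_velocity(still, 0.01)
  expect_lt(abs(vz$v_nm_s), 3 * vz$v_se_nm_s)
  expect_error(zero_load_velocity(1:3, 0.1), "at least 5")
})

test_that("lattice-inhibited motors hold super-threshold loads without snap-back", {
  tp <- trap_params(tpx2_static = TRUE, noise_sd = 0)
  tr <- simulate_trap_trace(tp, 10, seed = 11)
  # sustained holding above detach_load_high
  tail_pos <- tr$bead_pos_nm[(length(tr$bead_pos_nm) - 1000):length(tr$bead_pos_nm)]
  expect_true(all(tail_pos * tp$stiffness > tp$detach_load_high))
  expect_equal(nrow(detect_detachments(boxcar_filter(tr), tp)), 0)
})
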