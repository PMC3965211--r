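test_that("noiseless staircases are recovered exactly", {
  y <- rep(c(4, 3, 2, 1) * 90, each = 25)
  f <- detect_steps(y)
  expect_equal(f$n_steps, 3)
  expect_equal(f$n_down_steps, 3)
  expect_equal(f$levels, c(360, 270, 180, 90))
  expect_equal(f$step_idx, c(25, 50, 75))
  expect_equal(f$residual_rms, 0)

  # constant trace: zero steps, not an error
  expect_equal(detect_steps(rep(5, 30))$n_steps, 0)
  expect_error(detect_steps(rep(1, 5)), "too short")

  # steps of either sign are detected; only downward ones count as bleaching
  y2 <- c(rep(100, 20), rep(200, 20), rep(50, 20))
  f2 <- detect_steps(y2)
  expect_equal(f2$n_steps, 2)
  expect_equal(f2$n_down_steps, 1)
})

test_that("binary segmentation matches the exhaustive DP oracle on noiseless stairs", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    levels <- sort(runif(k + 1, 0, 10), decreasing = TRUE)
    lens <- sample(5:20, k + 1, replace = TRUE)
    y <- rep(levels, lens)
    f <- detect_steps(y, max_steps = 8)
    expect_equal(f$n_steps, k)
    expect_lt(f$residual_rms, 1e-6)
    # oracle: optimal RSS with k change points is also (numerically) zero,
    # and with k-1 it is not
    rss <- dp_best_rss(y, k)
    expect_lt(rss[k + 1], 1e-9)
    expect_gt(rss[k], 1e-4)
  }
})

test_that("greedy split RSS is near-optimal versus the DP oracle under noise", {
  set.seed(32)
  for (rep in 1:10) {
    y <- rep(c(300, 200, 100), each = 20) + rnorm(60, 0, 25)
    f <- detect_steps(y, max_steps = 4)
    if (f$n_steps == 0) next
    rss_dp <- dp_best_rss(y, f$n_steps)[f$n_steps + 1]
    expect_lte(length(y) * f$residual_rms^2, rss_dp * 1.3 + 1e-9)
  }
})

test_that("false-positive rate on step-free noise is at most 5%", {
  set.seed(33)
  fp <- mean(replicate(200, detect_steps(rnorm(60, 100, 10))$n_steps > 0))
  expect_lte(fp, 0.05)
})

test_that("detection power grows with the step-height to noise ratio", {
  set.seed(34)
  power_at <- function(ratio) {
    mean(replicate(100, {
      y <- rep(c(2, 1) * 30 * ratio, each = 25) + rnorm(50, 0, 30)
      detect_steps(y)$n_down_steps >= 1
    }))
  }
  p <- vapply(c(1, 2, 3, 5), power_at, numeric(1))
  expect_true(all(diff(p) >= -0.02)) # monotone up to binomial noise
  expect_gte(p[3], 0.95)
})

test_that("simulated tetramer traces at SNR 3 have modal bleaching count 4", {
  fits <- lapply(1:220, function(i) {
    tt <- seq(0, 75, by = 0.25)
    pts <- simulate_intensity_trace(
      data.frame(t_s = tt),
      fluor_model(noise_sd = 30, unit_intensity = 90),
      seed = derive_seed(5, i))
    detect_steps(pts$intensity_au, t = pts$t_s)
  })
  sc <- summarize_step_counts(fits)
  expect_true(sc$modal_count %in% c(3, 4))
  expect_equal(sc$modal_count, 4)
  expect_equal(sc$inferred_copy_number, max(sc$counts))
  expect_error(summarize_step_counts(list()), "at least one")
})

test_that("step-count histogram with pre-bleaching matches Binomial(4, 0.8)", {
  # noiseless, well-separated bleaches: detected count = number of initially
  # active fluorophores (minus rare frame-coincident pairs)
  fits <- lapply(1:400, function(i) {
    tt <- seq(0, 120, by = 0.25)
    pts <- simulate_intensity_trace(
      data.frame(t_s = tt),
      fluor_model(bleach_rate = 0.05, noise_sd = 0, p_prebleached = 0.2),
      seed = derive_seed(77, i))
    detect_steps(pts$intensity_au, t = pts$t_s)
  })
  counts <- summarize_step_counts(fits)$counts
  obs <- tabulate(counts + 1, 5) # counts of 0..4
  expected <- 400 * dbinom(0:4, 4, 0.8)
  chi <- suppressWarnings(chisq.test(obs, p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.01)
})

test_that("inferred copy number is the maximum observed count", {
  mk <- function(n) structure(list(n_down_steps = n), class = "step_fit")
  s <- summarize_step_counts(lapply(c(3, 4, 4, 2), mk))
  expect_equal(s$inferred_copy_number, 4)
  expect_equal(summarize_step_counts(list(mk(1)))$inferred_copy_number, 1)
})
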