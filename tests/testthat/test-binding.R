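test_that("Poisson binding probabilities: closed forms and orderings", {
  expect_equal(poisson_binding_prob(0, "ge1"), 0)
  expect_equal(poisson_binding_prob(0, "ge2"), 0)
  # at m = ln 1.5 exactly one third of beads carry any motor
  expect_equal(poisson_binding_prob(log(1.5), "ge1"), 1 / 3, tolerance = 1e-12)
  # P(>=2 | >=1) at the same occupancy
  m <- log(1.5)
  cond <- poisson_binding_prob(m, "ge2") / poisson_binding_prob(m, "ge1")
  expect_equal(cond, (1 - (2 / 3) * (1 + log(1.5))) / (1 / 3), tolerance = 1e-12)
  expect_equal(cond, 0.189, tolerance = 0.003)
  expect_error(poisson_binding_prob(-1), "must be >= 0")

  mm <- seq(0, 10, 0.01)
  p1 <- poisson_binding_prob(mm, "ge1")
  p2 <- poisson_binding_prob(mm, "ge2")
  expect_true(all(p2 <= p1 + 1e-15))
  expect_gt(min(tail(p1, 10)), 0.9999)
  # slope identity dP(>=1)/dm = exp(-m), checked numerically
  num <- diff(p1) / 0.01
  expect_equal(num, exp(-(mm[-1] - 0.005)), tolerance = 1e-4)
})

test_that("order selection recovers the generating model", {
  concs <- c(0.25, 0.5, 1, 2, 4, 8)
  s1 <- simulate_bead_binding(0.4, concs, n_beads = 100, seed = 21)
  f1 <- fit_poisson_binding(s1)
  expect_equal(f1$preferred_order, "ge1")
  expect_equal(unname(f1$lam_per_conc["ge1"]), 0.4, tolerance = 0.15)

  # data generated from the >= 2 curve
  s2 <- with_seed(22, {
    p <- poisson_binding_prob(0.4 * concs, "ge2")
    data.frame(rel_conc = concs,
               frac_bound = rbinom(length(concs), 100, p) / 100,
               n_beads = 100)
  })
  expect_equal(fit_poisson_binding(s2)$preferred_order, "ge2")

  # saturation: both orders fit; flagged unresolved
  s3 <- data.frame(rel_conc = c(50, 100, 200, 400),
                   frac_bound = rep(0.999, 4), n_beads = 100)
  f3 <- fit_poisson_binding(s3)
  expect_false(f3$resolved)
  expect_error(fit_poisson_binding(data.frame(rel_conc = 1:3,
                                              frac_bound = rep(0, 3))),
               "degenerate")
})

test_that("model selection is consistent in >= 95% of seeded trials", {
  concs <- c(0.25, 0.5, 1, 2, 4, 8)
  hits <- vapply(1:200, function(i) {
    s <- simulate_bead_binding(0.4, concs, n_beads = 200, seed = 3000 + i)
    fit_poisson_binding(s)$preferred_order == "ge1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("bead-binding simulation matches the analytic fraction", {
  s0 <- simulate_bead_binding(0, c(1, 2, 4), n_beads = 50, seed = 1)
  expect_true(all(s0$frac_bound == 0))
  s <- simulate_bead_binding(log(1.5), 1, n_beads = 1e5, seed = 2)
  expect_equal(s$frac_bound, 1 / 3, tolerance = 0.005 / (1 / 3))
  expect_equal(attr(s, "attach_criterion_s"), 2)
  # round trip: simulate then fit recovers lambda within 10%
  rt <- simulate_bead_binding(0.4, c(0.25, 0.5, 1, 2, 4, 8), 200, seed = 3)
  f <- fit_poisson_binding(rt)
  expect_equal(unname(f$lam_per_conc["ge1"]), 0.4, tolerance = 0.10)
})

test_that("Kd fit: noiseless exactness, half-saturation identity", {
  s <- simulate_cosed(490, bmax = 1, noise_sd = 0, seed = 1)
  f <- fit_kd(s)
  expect_equal(f$kd_nM, 490, tolerance = 1e-6)
  expect_equal(f$bmax, 1, tolerance = 1e-6)
  # frac at [MT] = Kd is bmax / 2
  expect_equal(0.8 * 0.49 / (0.49 + 0.49), 0.8 / 2)
  expect_error(fit_kd(data.frame(mt_conc_um = 1:3, frac_bound = 1:3 / 10)),
               "at least 4")
  expect_warning(fit_kd(data.frame(mt_conc_um = c(0.001, 0.002, 0.003, 0.004),
                                   frac_bound = c(0.001, 0.003, 0.004, 0.009))),
                 "ill-conditioned")
})

test_that("Kd recovery is calibrated over seeded replicates", {
  fits <- lapply(1:200, function(i) fit_kd(simulate_cosed(490, 1, seed = 2000 + i)))
  kds <- vapply(fits, function(f) f$kd_nM, numeric(1))
  expect_equal(median(kds), 490, tolerance = 0.10)
  expect_lt(abs(mean(kds) - 490) / 490, 0.05) # estimator bias < 5%
  cover <- mean(vapply(fits, function(f) abs(f$kd_nM - 490) < f$kd_se_nM,
                       logical(1)))
  expect_gte(cover, 0.58)
  expect_lte(cover, 0.78)
})
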