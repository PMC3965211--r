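test_that("approach detection: far tracks, single pass-through, reference errors", {
  far <- data.frame(t_s = seq(0, 10, 0.5), mt_id = 1,
                    arc_pos_um = seq(0, 1, length.out = 21))
  expect_equal(nrow(detect_approaches(far, grid_network)), 0)

  # constant-velocity track through the first crossing (arc 2 um on mt 1)
  t <- seq(0, 20, 0.5)
  thr <- data.frame(t_s = t, mt_id = 1, arc_pos_um = 1.5 + 0.1 * t)
  cand <- detect_approaches(thr, grid_network)
  cand1 <- cand[cand$int_id == grid_network$intersections$int_id[
    grid_network$intersections$arc_a_um == 2][1], ]
  expect_equal(nrow(cand1), 1)
  t_cross <- (2 - 1.5) / 0.1
  expect_lte(abs((cand1$t_enter + cand1$t_exit) / 2 - t_cross), 1.5)

  bad <- data.frame(t_s = c(0, 0.5), mt_id = 99, arc_pos_um = c(0, 0))
  expect_error(detect_approaches(bad, grid_network), "absent")
})

test_that("constructed events classify as pass, pause and dissociate", {
  # crossing of the grid network at arc 2 on mt 1
  ii <- grid_network$intersections[grid_network$intersections$arc_a_um == 2, ][1, ]
  # pass: drives straight through
  t <- seq(0, 30, 0.5)
  pass <- data.frame(t_s = t, mt_id = 1, arc_pos_um = 1 + 0.14 * t)
  ev <- classify_events(pass, grid_network, t_max = 60)
  ev <- ev[ev$int_id == ii$int_id, ]
  expect_equal(ev$outcome, "PASS")
  # stationary 8 s at the crossing then trace ends (bleach-free detach)
  t2 <- seq(0, 14, 0.5)
  pos2 <- pmin(1 + 0.14 * t2, 2)
  pause <- data.frame(t_s = t2, mt_id = 1, arc_pos_um = pos2)
  ev2 <- classify_events(pause, grid_network, t_max = 60)
  ev2 <- ev2[ev2$int_id == ii$int_id, ]
  expect_equal(ev2$outcome, "PAUSE")
  expect_equal(ev2$pause_s, 14 - (2 - 1) / 0.14, tolerance = 0.3)
  # immediate detachment at the crossing
  t3 <- seq(0, 7, 0.5)
  dis <- data.frame(t_s = t3, mt_id = 1, arc_pos_um = 1 + 0.145 * t3)
  ev3 <- classify_events(dis, grid_network, t_max = 60)
  ev3 <- ev3[ev3$int_id == ii$int_id, ]
  expect_equal(ev3$outcome, "DISSOCIATE")
  # same trace ending at the window end is indeterminate instead
  ev4 <- classify_events(dis, grid_network, t_max = 7.4)
  ev4 <- ev4[ev4$int_id == ii$int_id, ]
  expect_true(ev4$indeterminate)
})

test_that("simulated switch events classify as SWITCH onto the crossing microtubule", {
  found <- 0
  for (i in 1:200) {
    tr <- simulate_trajectory(default_params, grid_network, seed = 7000 + i)
    enc <- tr$truth$encounters
    if (is.null(enc) || !any(enc$outcome == "SWITCH")) next
    if (nrow(tr$points) < 5) next
    s <- segment_track(tr, network = grid_network)
    ev <- classify_events(s, grid_network, t_max = tr$t_max)
    sw <- ev[!is.na(ev$outcome) & ev$outcome == "SWITCH", ]
    if (nrow(sw) == 0) next
    found <- found + 1
    tsw <- enc[enc$outcome == "SWITCH", ][1, ]
    j <- which.min(abs(sw$t_approach_s - tsw$t_s))
    expect_equal(sw$mt_after[j], tsw$mt_to)
    expect_false(sw$mt_after[j] == sw$mt_before[j])
  }
  expect_gt(found, 10)
})

test_that("classified outcome fractions and per-class recall on a simulated ensemble", {
  ens <- simulate_ensemble(default_params, grid_network, 900, seed = 31)
  te <- do.call(rbind, lapply(seq_along(ens), function(i) {
    e <- ens[[i]]$truth$encounters
    if (!is.null(e)) cbind(traj = i, e)
  }))
  ev <- do.call(rbind, lapply(seq_along(ens), function(i) {
    tr <- ens[[i]]
    if (nrow(tr$points) < 5) return(NULL)
    s <- segment_track(tr, network = grid_network)
    classify_events(s, grid_network, t_max = tr$t_max, traj_id = i)
  }))
  sf <- summarize_event_fractions(ev)
  expect_gte(sf$n_classified, 300)
  expect_equal(sum(sf$fractions), 1, tolerance = 1e-12)
  expect_equal(sum(sf$counts), sf$n_classified)
  # each fraction within the 99% binomial CI of 0.25
  ci <- qbinom(c(0.005, 0.995), sf$n_classified, 0.25) / sf$n_classified
  for (fr in sf$fractions) {
    expect_gte(fr, ci[1])
    expect_lte(fr, ci[2])
  }
  # per-class recall vs generator truth >= 0.9
  evc <- ev[!ev$indeterminate, ]
  key <- paste(te$traj, te$int_id)
  near <- vapply(seq_len(nrow(evc)), function(i) {
    j <- which(key == paste(evc$traj_id[i], evc$int_id[i]))
    if (!length(j)) return(NA_integer_)
    j[which.min(abs(te$t_s[j] - evc$t_approach_s[i]))]
  }, integer(1))
  ok <- !is.na(near) & abs(te$t_s[near] - evc$t_approach_s) < 30
  conf <- table(factor(te$outcome[near[ok]],
                       levels = c("PASS", "SWITCH", "PAUSE", "DISSOCIATE")),
                factor(evc$outcome[ok],
                       levels = c("PASS", "SWITCH", "PAUSE", "DISSOCIATE")))
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  expect_true(all(rowSums(conf) > 30))
  expect_true(all(recall >= 0.9))
})

test_that("event fraction arithmetic on constructed sets", {
  mk <- function(outcomes) {
    data.frame(traj_id = seq_along(outcomes), int_id = 1,
               t_approach_s = seq_along(outcomes), outcome = outcomes,
               pause_s = 0, mt_before = 1, mt_after = 1,
               indeterminate = FALSE)
  }
  f1 <- summarize_event_fractions(mk(c("PASS", "SWITCH", "PAUSE", "DISSOCIATE")))
  expect_equal(f1$fractions, rep(0.25, 4))
  f2 <- summarize_event_fractions(mk(c("PASS", "PASS", "PASS", "PASS", "SWITCH")))
  expect_equal(f2$fractions[2], 0.20) # every fifth motor switches
  f3 <- summarize_event_fractions(mk(rep("PASS", 7)))
  expect_equal(f3$fractions, c(1, 0, 0, 0))
  expect_error(summarize_event_fractions(mk("PASS")[0, ]), "no events")
})

test_that("effective path length and predicted reach follow the printed identities", {
  expect_equal(effective_path_length(c(1.6, 3.7, 2.1)), 7.4)
  expect_equal(predicted_reach(2.0, 0), 2.0)
  expect_equal(predicted_reach(1.9, 2), 5.7)
  expect_error(effective_path_length(c(-1, 2)), "non-negative")
  expect_error(predicted_reach(-1, 0), "non-negative")
})
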