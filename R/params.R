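#' @keywords internal
"_PACKAGE"

# ---- seeded evaluation ------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr` and
#' restores the previous state, so that seeded simulation functions are pure
#' functions of their arguments and never perturb the session RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# ---- distribution helpers ---------------------------------------------------

# exponential rate from a configured median
rate_from_median <- function(med) log(2) / med

# truncated normal on (lo, hi] by inverse-CDF sampling
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# exponential truncated to [lo, hi], inverse-CDF sampling
rtrunc_exp <- function(n, rate, lo = 0, hi = Inf) {
  plo <- stats::pexp(lo, rate)
  phi <- stats::pexp(hi, rate)
  stats::qexp(plo + stats::runif(n) * (phi - plo), rate)
}

ptrunc_exp <- function(q, rate, lo = 0, hi = Inf) {
  plo <- stats::pexp(lo, rate)
  phi <- stats::pexp(hi, rate)
  pmin(pmax((stats::pexp(q, rate) - plo) / (phi - plo), 0), 1)
}

#' Rate of a truncated exponential with a prescribed median
#'
#' Solves for the rate `r` such that an exponential with rate `r`, truncated
#' to `[lower, upper]`, has median `med`. Used to draw pause durations whose
#' observable (truncated) median equals the configured one.
#'
#' @param med target median of the truncated distribution.
#' @param lower,upper truncation bounds; `lower < med < (lower + upper) / 2`.
#' @return The exponential rate (1 / units of `med`).
#' @export
truncated_exp_rate_for_median <- function(med, lower, upper) {
  if (!(lower < med && med < (lower + upper) / 2)) {
    stop("median must lie in (lower, (lower + upper) / 2) for a truncated ",
         "exponential; got ", med, " with bounds [", lower, ", ", upper, "]")
  }
  f <- function(r) {
    sl <- exp(-r * lower)
    su <- exp(-r * upper)
    -log((sl + su) / 2) / r - med
  }
  stats::uniroot(f, c(1e-8, 100), tol = 1e-12)$root
}

# ---- residency linger calibration -------------------------------------------

# Detachment rate of the post-run weakly bound (diffusive linger) state, solved
# so that the median of total realized residency (run time + pauses + linger)
# equals residency_med. Uses a fixed internal seed: deterministic in the
# parameters, independent of the caller's RNG stream.
calibrate_linger_rate <- function(run_len_med, v_med, v_sd, v_min, v_max,
                                  pause_rate, pause_rexp_rate,
                                  pause_dur_min, pause_dur_max,
                                  residency_med, n = 40000L) {
  with_seed(204823L, {
    L <- stats::rexp(n, rate_from_median(run_len_med))
    v <- rtrunc_norm(n, v_med, v_sd, v_min, v_max) / 1000 # um/s
    npause <- stats::rpois(n, pause_rate * L)
    ptot <- numeric(n)
    tot <- sum(npause)
    if (tot > 0) {
      durs <- rtrunc_exp(tot, pause_rexp_rate, pause_dur_min, pause_dur_max)
      idx <- rep.int(seq_len(n), npause)
      agg <- rowsum(durs, idx)
      ptot[as.integer(rownames(agg))] <- agg[, 1]
    }
    D <- L / v + ptot
    if (stats::median(D) >= residency_med) {
      warning("configured residency median is not reachable: processive run ",
              "time alone exceeds it; linger state disabled")
      return(Inf)
    }
    E1 <- stats::rexp(n)
    f <- function(log_mu) stats::median(D + E1 / exp(log_mu)) - residency_med
    exp(stats::uniroot(f, c(log(1e-6), log(1e6)), tol = 1e-10)$root)
  })
}

# ---- parameter containers ---------------------------------------------------

#' Generative motility parameters for a single tetrameric motor
#'
#' The full parameter set of the stochastic state machine used by
#' [simulate_trajectory()]. Exponential dwell and run ingredients are
#' parameterised by their MEDIAN (rate = ln 2 / median) because single-molecule
#' studies report medians. Two internal rates are derived at construction:
#' the base rate of the truncated pause-duration law (so the truncated median
#' equals `pause_dur_med`) and the detachment rate of the post-run diffusive
#' linger state (so the median of total residency equals `residency_med`).
#'
#' @param v_plus_med median plus-end velocity, nm/s.
#' @param v_sd per-run velocity standard deviation, nm/s (truncated Gaussian).
#' @param v_max maximum velocity, nm/s.
#' @param v_min minimum velocity, nm/s; per-run draws are truncated to
#'   `[v_min, v_max]`. Motors slower than the pause-scoring threshold are not
#'   observable as processive, so the generative velocity law has a floor.
#' @param v_minus_med median minus-end velocity, nm/s.
#' @param run_len_med_plus,run_len_med_minus median processive run length, um.
#' @param residency_med median total lattice residency, s (plus-directed);
#'   minus-directed residency is scaled by the run-length ratio.
#' @param pause_rate pause frequency per um of processive path.
#' @param pause_dur_med median pause duration, s (of the truncated law).
#' @param pause_dur_max maximum pause duration, s; longer draws are resampled.
#' @param pause_dur_min minimum generated pause duration, s. Pauses below
#'   ~2 frames are not resolvable on kymographs, and the printed pause
#'   statistics count visible pauses only, so the generator emulates those.
#' @param end_dwell_med median plus-end dwell, s (of the observable, shifted
#'   law; see `end_dwell_min`).
#' @param end_dwell_min minimum end-dwell duration, s. Dwells are drawn as
#'   `end_dwell_min + Exp(median end_dwell_med - end_dwell_min)`: a dwell
#'   shorter than ~2 frames cannot be scored on a kymograph, and the reported
#'   dwell median describes scorable dwells, so the generated law has the
#'   configured median without an unobservable sub-frame tail.
#' @param p_detach_at_end probability of immediate detachment on reaching the
#'   plus end (otherwise the motor dwells).
#' @param p_plus probability a directional track is plus-end-directed.
#' @param D_diff 1-D diffusion coefficient, um^2/s.
#' @param p_mode_switch per-second rate of processive <-> diffusive
#'   interconversion (0 disables episodic interconversion).
#' @param intersection_probs length-4 probability vector of outcomes at a
#'   microtubule intersection: pass, switch, pause, dissociate. Must sum to 1.
#' @param p_static probability a motor is immobile for the whole observation
#'   (used for the lattice-bound inhibitor scenario).
#' @param v_mixture optional list `(weight, slow_med, fast_med, slow_sd,
#'   fast_sd)` replacing the single velocity law with a two-component mixture
#'   (`weight` = slow-component fraction), for the inhibitor scenario.
#' @param capture_radius_nm capture radius around an intersection, nm.
#' @return An object of class `motility_params`.
#' @export
motility_params <- function(v_plus_med = 137.8,
                            v_sd = 60,
                            v_max = 550,
                            v_min = 30,
                            v_minus_med = 137.8,
                            run_len_med_plus = 1.9,
                            run_len_med_minus = 0.6,
                            residency_med = 26.3,
                            pause_rate = 0.30,
                            pause_dur_med = 5.0,
                            pause_dur_max = 20.5,
                            pause_dur_min = 2.0,
                            end_dwell_med = 18.8,
                            end_dwell_min = 2.0,
                            p_detach_at_end = 0.1,
                            p_plus = 0.875,
                            D_diff = 0.04,
                            p_mode_switch = 0,
                            intersection_probs = c(0.25, 0.25, 0.25, 0.25),
                            p_static = 0,
                            v_mixture = NULL,
                            capture_radius_nm = 200) {
  probs <- c(p_detach_at_end, p_plus, p_static, p_mode_switch >= 0)
  if (any(c(p_detach_at_end, p_plus, p_static) < 0 |
          c(p_detach_at_end, p_plus, p_static) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (length(intersection_probs) != 4 || any(intersection_probs < 0) ||
      abs(sum(intersection_probs) - 1) > 1e-12) {
    stop("intersection_probs must be a 4-vector of non-negative values ",
         "summing to 1")
  }
  meds <- c(v_plus_med, v_minus_med, run_len_med_plus, run_len_med_minus,
            residency_med, pause_dur_med, end_dwell_med)
  if (any(meds <= 0)) stop("all medians must be > 0")
  if (pause_rate < 0 || p_mode_switch < 0 || D_diff < 0) {
    stop("rates must be >= 0")
  }
  if (v_max < v_plus_med) stop("v_max must be >= v_plus_med")
  if (v_min < 0 || v_min >= v_plus_med) stop("v_min must be in [0, v_plus_med)")
  if (end_dwell_min < 0 || end_dwell_min >= end_dwell_med) {
    stop("end_dwell_min must be in [0, end_dwell_med)")
  }
  if (!is.null(v_mixture)) {
    v_mixture <- as.list(v_mixture)
    if (is.null(v_mixture$slow_sd)) v_mixture$slow_sd <- 12
    if (is.null(v_mixture$fast_sd)) v_mixture$fast_sd <- 25
    stopifnot(v_mixture$weight >= 0, v_mixture$weight <= 1,
              v_mixture$slow_med > 0, v_mixture$fast_med > 0)
  }

  pause_rexp_rate <- truncated_exp_rate_for_median(pause_dur_med,
                                                   pause_dur_min,
                                                   pause_dur_max)
  residency_med_minus <- residency_med * run_len_med_minus / run_len_med_plus
  linger_rate_plus <- calibrate_linger_rate(
    run_len_med_plus, v_plus_med, v_sd, v_min, v_max, pause_rate,
    pause_rexp_rate, pause_dur_min, pause_dur_max, residency_med)
  linger_rate_minus <- calibrate_linger_rate(
    run_len_med_minus, v_minus_med, v_sd, v_min, v_max, pause_rate,
    pause_rexp_rate, pause_dur_min, pause_dur_max, residency_med_minus)

  structure(list(
    v_plus_med = v_plus_med, v_sd = v_sd, v_max = v_max, v_min = v_min,
    v_minus_med = v_minus_med,
    run_len_med_plus = run_len_med_plus,
    run_len_med_minus = run_len_med_minus,
    residency_med = residency_med,
    residency_med_minus = residency_med_minus,
    pause_rate = pause_rate, pause_dur_med = pause_dur_med,
    pause_dur_max = pause_dur_max, pause_dur_min = pause_dur_min,
    end_dwell_med = end_dwell_med, end_dwell_min = end_dwell_min,
    p_detach_at_end = p_detach_at_end,
    p_plus = p_plus, D_diff = D_diff, p_mode_switch = p_mode_switch,
    intersection_probs = intersection_probs, p_static = p_static,
    v_mixture = v_mixture, capture_radius_nm = capture_radius_nm,
    pause_rexp_rate = pause_rexp_rate,
    linger_rate_plus = linger_rate_plus,
    linger_rate_minus = linger_rate_minus),
    class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat("Motility parameters (medians; exponential rate = ln2/median)\n")
  cat(sprintf("  v+ %.1f nm/s (sd %.0f, max %.0f); v- %.1f nm/s\n",
              x$v_plus_med, x$v_sd, x$v_max, x$v_minus_med))
  cat(sprintf("  run length +%.2f / -%.2f um; residency %.1f s\n",
              x$run_len_med_plus, x$run_len_med_minus, x$residency_med))
  cat(sprintf("  pauses %.2f /um, %.1f s median on [%.1f, %.1f] s\n",
              x$pause_rate, x$pause_dur_med, x$pause_dur_min, x$pause_dur_max))
  cat(sprintf("  end dwell %.1f s; P(detach at end) %.2f; P(plus) %.3f\n",
              x$end_dwell_med, x$p_detach_at_end, x$p_plus))
  cat(sprintf("  intersection outcomes (pass/switch/pause/dissociate): %s\n",
              paste(format(x$intersection_probs), collapse = " ")))
  invisible(x)
}

#' Fluorophore/photobleaching model
#'
#' @param n_fluor number of fluorophores per motor (4 for an eGFP tetramer).
#' @param bleach_rate per-fluorophore bleaching rate, 1/s. The default keeps
#'   successive bleaches resolvable at the 4 fps bleaching frame rate, as
#'   they are in the reference recordings.
#' @param unit_intensity intensity contributed by one active fluorophore, a.u.
#' @param noise_sd Gaussian intensity noise sd, a.u.
#' @param p_prebleached probability each fluorophore is dark from the start.
#' @return An object of class `fluor_model`.
#' @export
fluor_model <- function(n_fluor = 4, bleach_rate = 0.08, unit_intensity = 100,
                        noise_sd = 0, p_prebleached = 0) {
  stopifnot(n_fluor >= 1, bleach_rate >= 0, noise_sd >= 0,
            p_prebleached >= 0, p_prebleached <= 1, unit_intensity >= 0)
  structure(list(n_fluor = as.integer(n_fluor), bleach_rate = bleach_rate,
                 unit_intensity = unit_intensity, noise_sd = noise_sd,
                 p_prebleached = p_prebleached),
            class = "fluor_model")
}

#' Track segmentation configuration
#'
#' Thresholds of the state classifier in [segment_track()]. The classification
#' the original assays did by eye on kymographs is operationalised here by a
#' sliding-window velocity with explicit thresholds.
#'
#' @param window sliding window for local velocity, frames (odd recommended).
#' @param v_pause_thresh speed below which a point counts as stationary, nm/s.
#' @param min_pause_dur minimum duration of a pause, s.
#' @param min_proc_dur minimum duration of a processive segment, s.
#' @param msd_alpha_proc minimum MSD scaling exponent for processive motion.
#' @param max_resid_nm maximum RMS residual around the least-squares line for
#'   a moving stretch to count as processive; diffusive excursions are
#'   locally sign-consistent but not straight, so this separates the two.
#' @param end_radius distance from the plus end within which a stationary
#'   motor is classified as end-dwelling, nm.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(window = 5, v_pause_thresh = 20, min_pause_dur = 1.5,
                       min_proc_dur = 2.0, msd_alpha_proc = 1.5,
                       max_resid_nm = 60, end_radius = 150) {
  stopifnot(window >= 3, v_pause_thresh > 0, min_pause_dur > 0,
            min_proc_dur > 0, msd_alpha_proc > 0, max_resid_nm > 0,
            end_radius > 0)
  structure(list(window = as.integer(window), v_pause_thresh = v_pause_thresh,
                 min_pause_dur = min_pause_dur, min_proc_dur = min_proc_dur,
                 msd_alpha_proc = msd_alpha_proc, max_resid_nm = max_resid_nm,
                 end_radius = end_radius),
            class = "seg_config")
}

#' Optical trap simulation parameters
#'
#' @param stiffness trap stiffness, pN/nm.
#' @param step_size motor step size, nm.
#' @param stepping_rate stepping rate, steps/s (137.6 nm/s at 8 nm steps).
#' @param detach_load_low,detach_load_high bounds of the uniform
#'   detachment-load threshold, pN.
#' @param sample_rate trace sampling rate, Hz.
#' @param noise_sd Gaussian bead positional noise sd, nm.
#' @param rebind whether the motor re-engages after detachment.
#' @param rebind_wait_mean mean exponential wait before re-engagement, s.
#' @param p_diffusive fraction of engagements that are bidirectional-diffusive
#'   (zero mean drift) rather than processive.
#' @param tpx2_static if `TRUE`, emulate lattice-inhibited motors: the motor
#'   walks to a load above `detach_load_high` and then holds indefinitely
#'   without detaching.
#' @return An object of class `trap_params`.
#' @export
trap_params <- function(stiffness = 0.05, step_size = 8, stepping_rate = 17.2,
                        detach_load_low = 1.5, detach_load_high = 3.5,
                        sample_rate = 22000, noise_sd = 2, rebind = TRUE,
                        rebind_wait_mean = 0.2, p_diffusive = 0,
                        tpx2_static = FALSE) {
  stopifnot(stiffness > 0, step_size > 0, stepping_rate >= 0,
            detach_load_low > 0, detach_load_low <= detach_load_high,
            sample_rate > 0, noise_sd >= 0, rebind_wait_mean > 0,
            p_diffusive >= 0, p_diffusive <= 1)
  structure(list(stiffness = stiffness, step_size = step_size,
                 stepping_rate = stepping_rate,
                 detach_load_low = detach_load_low,
                 detach_load_high = detach_load_high,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 rebind = rebind, rebind_wait_mean = rebind_wait_mean,
                 p_diffusive = p_diffusive, tpx2_static = tpx2_static),
            class = "trap_params")
}
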