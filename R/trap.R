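# Optical trap: bead-motor-trap trace simulation and detachment analysis.
#
# A motor on a trapped bead steps away from the trap centre in discrete
# increments until the load (stiffness x excursion) reaches a detachment
# threshold drawn uniformly per engagement; it then releases at exactly the
# threshold load (partial final step), holds briefly, and the bead snaps back
# to the trap centre before the next engagement. The brief hold - a
# detachment latency of 2 ms plus an exponential step-waiting time - ensures
# a 1 ms boxcar-filtered trace resolves the terminal load.

#' Simulate a bead position trace in a harmonic trap
#'
#' @param tp a [trap_params()].
#' @param t_max trace duration, s.
#' @param seed integer seed.
#' @return An object of class `trap_trace`: list with `bead_pos_nm` (sampled
#'   at `tp$sample_rate`), `sample_rate`, `params` and `truth`, a data frame
#'   of generator-truth engagements (`t_start, t_detach, load_pN,
#'   excursion_nm, type`). With `tp$tpx2_static`, the motor walks to a load
#'   above `detach_load_high` and then holds for the rest of the trace
#'   without detaching (lattice-inhibited scenario).
#' @export
simulate_trap_trace <- function(tp, t_max, seed = 1L) {
  stopifnot(inherits(tp, "trap_params"), t_max > 0)
  with_seed(seed, {
    events <- list() # step-level changes: (t, pos)
    truth <- list()
    t <- 0
    pos_t <- numeric(); pos_x <- numeric()
    push <- function(tt, x) {
      pos_t[length(pos_t) + 1] <<- tt
      pos_x[length(pos_x) + 1] <<- x
    }
    push(0, 0)
    while (t < t_max && tp$stepping_rate > 0) {
      t_start <- t
      if (tp$tpx2_static) {
        # inhibited motor: steps up to a super-threshold load, then holds
        target <- 1.2 * tp$detach_load_high / tp$stiffness
        x <- 0
        while (x < target && t < t_max) {
          t <- t + stats::rexp(1, tp$stepping_rate)
          x <- x + tp$step_size
          push(t, x)
        }
        break # holds to the end of the trace; no detachment
      }
      diffusive <- tp$p_diffusive > 0 && stats::runif(1) < tp$p_diffusive
      if (diffusive) {
        dur <- stats::rexp(1, 0.5) # ~2 s bidirectional episode
        t_end <- min(t + dur, t_max)
        x <- 0
        while (t < t_end) {
          t <- t + stats::rexp(1, tp$stepping_rate)
          if (t >= t_end) break
          x <- x + sample(c(-1, 1), 1) * tp$step_size
          push(t, x)
        }
        push(t_end, 0) # releases near the centre
        t <- t_end
        truth[[length(truth) + 1]] <- data.frame(
          t_start = t_start, t_detach = t_end, load_pN = NA_real_,
          excursion_nm = NA_real_, type = "diffusive")
      } else {
        thresh <- stats::runif(1, tp$detach_load_low, tp$detach_load_high)
        x_star <- thresh / tp$stiffness
        x <- 0
        while (t < t_max) {
          t <- t + stats::rexp(1, tp$stepping_rate)
          x <- min(x + tp$step_size, x_star)
          push(t, x)
          if (x >= x_star) break
        }
        if (t >= t_max) break
        # detachment latency, then snap to the trap centre
        t_det <- t + 0.002 + stats::rexp(1, tp$stepping_rate)
        if (t_det >= t_max) t_det <- t_max
        push(t_det, 0)
        truth[[length(truth) + 1]] <- data.frame(
          t_start = t_start, t_detach = t_det, load_pN = thresh,
          excursion_nm = x_star, type = "processive")
        t <- t_det
        if (!tp$rebind) break
        t <- t + stats::rexp(1, 1 / tp$rebind_wait_mean)
      }
    }
    n <- floor(t_max * tp$sample_rate)
    tt <- (seq_len(n) - 1) / tp$sample_rate
    pos <- pos_x[findInterval(tt, pos_t)]
    if (tp$noise_sd > 0) pos <- pos + stats::rnorm(n, 0, tp$noise_sd)
    structure(list(bead_pos_nm = pos, sample_rate = tp$sample_rate,
                   params = tp,
                   truth = if (length(truth)) do.call(rbind, truth) else
                     data.frame(t_start = numeric(), t_detach = numeric(),
                                load_pN = numeric(), excursion_nm = numeric(),
                                type = character())),
              class = "trap_trace")
  })
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("Trap trace: %.3g s at %g kHz, %d engagements\n",
              length(x$bead_pos_nm) / x$sample_rate, x$sample_rate / 1000,
              nrow(x$truth)))
  invisible(x)
}

#' Boxcar (moving-average) filter of a trap trace
#'
#' Centred moving average of the stated width; edges use truncated windows,
#' so the length is preserved.
#'
#' @param trace a `trap_trace` or numeric vector.
#' @param width filter width, s (or samples when `trace` is a bare vector
#'   and `sample_rate` is NULL).
#' @param sample_rate sampling rate, Hz; taken from the trace if present.
#' @return Same type as the input, with the filtered position.
#' @export
boxcar_filter <- function(trace, width = 0.001, sample_rate = NULL) {
  is_trace <- inherits(trace, "trap_trace")
  x <- if (is_trace) trace$bead_pos_nm else as.numeric(trace)
  if (is.null(sample_rate)) {
    sample_rate <- if (is_trace) trace$sample_rate else 1
  }
  w <- max(2L, round(width * sample_rate))
  if (width < 2 / sample_rate) stop("filter width below two samples")
  n <- length(x)
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  if (is_trace) { trace$bead_pos_nm <- out; trace } else out
}

#' Detect motor detachment events in a (filtered) trap trace
#'
#' An event is a rapid return towards the trap centre - a position drop whose
#' rate exceeds `rate_threshold` - from an excursion whose load is at least
#' `min_load`. The load is read from the filtered position just before the
#' snap-back.
#'
#' @param trace a `trap_trace` (ideally [boxcar_filter()]ed).
#' @param tp the [trap_params()] used (for stiffness and the default
#'   thresholds).
#' @param rate_threshold snap-back speed threshold, nm/s; default 10x the
#'   maximum stepping speed.
#' @param min_load minimum pre-snap load for a genuine event, pN; default
#'   `detach_load_low / 2`.
#' @return data frame of events: `t_s, load_pN, excursion_nm`.
#' @export
detect_detachments <- function(trace, tp, rate_threshold = NULL,
                               min_load = NULL) {
  stopifnot(inherits(trace, "trap_trace"))
  if (is.null(rate_threshold)) {
    rate_threshold <- 10 * tp$step_size * max(tp$stepping_rate, 1)
  }
  if (is.null(min_load)) min_load <- tp$detach_load_low / 2
  x <- trace$bead_pos_nm
  sr <- trace$sample_rate
  n <- length(x)
  gap <- max(1L, round(0.0015 * sr)) # look 1.5 ms ahead
  if (n <= gap + 1) return(data.frame(t_s = numeric(), load_pN = numeric(),
                                      excursion_nm = numeric()))
  drop <- x[seq_len(n - gap)] - x[(gap + 1):n]
  min_drop <- max(rate_threshold * gap / sr, min_load / tp$stiffness)
  idx <- which(drop >= min_drop)
  if (!length(idx)) return(data.frame(t_s = numeric(), load_pN = numeric(),
                                      excursion_nm = numeric()))
  # cluster candidate indices closer than one window
  cl_starts <- idx[c(TRUE, diff(idx) > gap)]
  out <- lapply(cl_starts, function(i) {
    pre <- x[max(1, i - round(0.002 * sr)):i]
    exc <- max(pre)
    data.frame(t_s = (i - 1) / sr, load_pN = exc * tp$stiffness,
               excursion_nm = exc)
  })
  out <- do.call(rbind, out)
  out[out$load_pN >= min_load, , drop = FALSE]
}

#' Least-squares velocity of a zero-load bead position series
#'
#' @param pos positions, nm.
#' @param dt sample interval, s.
#' @return list with `v_nm_s` and `v_se_nm_s`.
#' @export
zero_load_velocity <- function(pos, dt) {
  pos <- as.numeric(pos)
  if (length(pos) < 5) stop("need at least 5 points")
  sl <- ls_slope((seq_along(pos) - 1) * dt, pos)
  list(v_nm_s = sl[1], v_se_nm_s = sl[2])
}

#' Simulate a zero-load stepping position series
#'
#' Poisson stepping at `rate` with `step_size` increments, sampled at `dt`
#' (video-rate tracking of a bead outside the trap).
#'
#' @param rate stepping rate, steps/s.
#' @param step_size nm.
#' @param t_max duration, s.
#' @param dt sample interval, s.
#' @param seed integer seed.
#' @return numeric vector of positions, nm.
#' @export
simulate_stepping_trace <- function(rate, step_size = 8, t_max = 10,
                                    dt = 0.1, seed = 1L) {
  with_seed(seed, {
    n <- floor(t_max / dt)
    cumsum(stats::rpois(n, rate * dt)) * step_size
  })
}
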