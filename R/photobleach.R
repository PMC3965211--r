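# Photobleaching step counting by penalized change-point detection.
#
# A fluorescence trace of a motor carrying several fluorophores is a
# piecewise-constant signal plus noise; each downward step is one bleaching
# event, and the maximum number of steps across an ensemble reports the
# fluorophore stoichiometry (four for an eGFP-tagged tetramer). Steps are
# found by top-down binary segmentation of the residual sum of squares, and
# the number of change points is selected with a Schwarz-type criterion
#   n * ln(RSS_k / n) + penalty * k * ln(n),
# ties broken toward fewer steps.

#' Detect intensity steps in a photobleaching trace
#'
#' @param intensity intensity values, a.u. (>= 10 samples).
#' @param t sample times, s; defaults to a unit-spaced index.
#' @param penalty multiplier of the `k * ln(n)` model-size term. The default
#'   of 3 holds the false-positive rate on step-free noise traces below a few
#'   percent while keeping full power at step-height/noise ratios >= 3 (a
#'   plain BIC penalty of 2 over-segments because the greedy search maximises
#'   the gain over all split positions).
#' @param max_steps maximum number of change points considered.
#' @param min_size minimum samples per level.
#' @return An object of class `step_fit`: list with `step_times` (time of the
#'   first sample after each change), `step_idx`, `levels` (length
#'   `n_steps + 1`), `n_steps`, `n_down_steps` (bleaching steps),
#'   `residual_rms`, `criterion_value`, `fitted`.
#' @export
detect_steps <- function(intensity, t = NULL, penalty = 3, max_steps = 10,
                         min_size = 2) {
  y <- as.numeric(intensity)
  n <- length(y)
  if (n < 10) stop("trace too short: need at least 10 samples")
  if (is.null(t)) t <- seq_len(n) - 1
  stopifnot(length(t) == n, min_size >= 1)

  # cumulative sums for O(1) segment costs
  cy <- c(0, cumsum(y))
  cy2 <- c(0, cumsum(y^2))
  seg_cost <- function(a, b) { # RSS of constant fit on a..b
    m <- b - a + 1
    s <- cy[b + 1] - cy[a]
    max((cy2[b + 1] - cy2[a]) - s^2 / m, 0)
  }
  best_split <- function(a, b) {
    # best single change point within a..b honouring min_size
    cand <- seq(a + min_size - 1, b - min_size)
    if (length(cand) < 1 || cand[1] > cand[length(cand)]) return(NULL)
    costs <- vapply(cand, function(j) seg_cost(a, j) + seg_cost(j + 1, b),
                    numeric(1))
    j <- cand[which.min(costs)]
    list(at = j, gain = seg_cost(a, b) - min(costs))
  }

  # greedy binary segmentation, recording the order in which splits are added
  segs <- list(c(1, n))
  splits <- integer(); gains <- numeric()
  cand <- list(best_split(1, n))
  gain_floor <- 1e-12 * max(cy2[n + 1], 1)
  while (length(splits) < max_steps) {
    gs <- vapply(cand, function(z) if (is.null(z)) -Inf else z$gain, numeric(1))
    if (!length(gs)) break
    k <- which.max(gs)
    if (!is.finite(gs[k]) || gs[k] <= gain_floor) break
    z <- cand[[k]]
    sp <- z$at
    # which segment contains it
    si <- which(vapply(segs, function(s) sp >= s[1] && sp < s[2], logical(1)))[1]
    a <- segs[[si]][1]; b <- segs[[si]][2]
    splits <- c(splits, sp); gains <- c(gains, z$gain)
    segs[[si]] <- c(a, sp)
    segs[[length(segs) + 1]] <- c(sp + 1, b)
    cand[[k]] <- best_split(a, sp)
    cand[[length(cand) + 1]] <- best_split(sp + 1, b)
  }

  # model selection over k = 0..length(splits)
  rss_floor <- 1e-12 * max(cy2[n + 1], 1)
  rss0 <- seg_cost(1, n)
  crit <- numeric(length(splits) + 1)
  rss_k <- numeric(length(splits) + 1)
  for (k in 0:length(splits)) {
    bps <- sort(splits[seq_len(k)])
    bounds <- c(0, bps, n)
    rss <- sum(vapply(seq_len(length(bounds) - 1), function(i) {
      seg_cost(bounds[i] + 1, bounds[i + 1])
    }, numeric(1)))
    rss_k[k + 1] <- rss
    crit[k + 1] <- n * log(max(rss, rss_floor) / n) + penalty * k * log(n)
  }
  k_best <- which.min(crit) - 1L # ties resolved toward fewer by which.min

  bps <- sort(splits[seq_len(k_best)])
  bounds <- c(0, bps, n)
  levels <- vapply(seq_len(length(bounds) - 1), function(i) {
    mean(y[(bounds[i] + 1):bounds[i + 1]])
  }, numeric(1))
  fitted <- rep(levels, diff(bounds))
  structure(list(
    step_idx = bps,
    step_times = t[pmin(bps + 1, n)],
    levels = levels,
    n_steps = k_best,
    n_down_steps = if (k_best > 0) sum(diff(levels) < 0) else 0L,
    residual_rms = sqrt(rss_k[k_best + 1] / n),
    criterion_value = crit[k_best + 1],
    fitted = fitted), class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d change points (%d bleaching steps), RMS %.3g\n",
              x$n_steps, x$n_down_steps, x$residual_rms))
  invisible(x)
}

#' Summarise bleaching step counts over an ensemble of traces
#'
#' The inferred fluorophore copy number is the maximum observed downward step
#' count; note that an n-step trace implies at least n fluorophores (n + 1 if
#' the final level sits above background), and pre-bleached fluorophores make
#' traces undercount, so the maximum over many motors is the robust
#' stoichiometry readout.
#'
#' @param fits list of [detect_steps()] results.
#' @return list with `counts` (per-trace downward step counts), `histogram`,
#'   `modal_count`, `inferred_copy_number` and a `caveat` string.
#' @export
summarize_step_counts <- function(fits) {
  if (length(fits) < 1) stop("need at least one step fit")
  counts <- vapply(fits, function(f) as.integer(f$n_down_steps), integer(1))
  hist <- table(factor(counts, levels = 0:max(counts)))
  modal <- as.integer(names(hist)[which.max(hist)])
  list(counts = counts, histogram = hist,
       modal_count = modal,
       inferred_copy_number = max(counts),
       caveat = paste("an n-step trace indicates >= n fluorophores (n + 1",
                      "with a residual level); pre-bleached or co-bleaching",
                      "fluorophores reduce the observed count"))
}
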