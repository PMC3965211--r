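# Ensemble-level analysis: segment every track, compute per-track metrics and
# pool the motility statistics the assays report.

#' Segment and measure every track of an ensemble
#'
#' Tracks with fewer frames than the segmentation window are skipped (too
#' short to classify, as they would be on a kymograph) and counted.
#'
#' @param trajs list of trajectories ([simulate_ensemble()] output or data
#'   frames as accepted by [segment_track()]).
#' @param network the [build_network()] the tracks live on.
#' @param cfg a [seg_config()].
#' @param t_max observation window, s, for right-censoring flags; taken from
#'   trajectory objects when present.
#' @return list with `segmented` (list of `segmented_track`), `metrics`
#'   (list of `run_metrics`), `kept` (indices of analysed tracks) and
#'   `n_skipped`.
#' @export
analyze_tracks <- function(trajs, network, cfg = seg_config(), t_max = NULL) {
  segs <- list(); mets <- list(); kept <- integer()
  short_res <- numeric()
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    pts <- if (inherits(tr, "trajectory")) tr$points else as.data.frame(tr)
    npts <- nrow(pts)
    tm <- if (!is.null(t_max)) t_max else
      if (inherits(tr, "trajectory")) tr$t_max else NULL
    if (npts < cfg$window) {
      # too short to classify, but its lattice residency is still observable
      if (npts >= 2) {
        span <- pts$t_s[npts] - pts$t_s[1]
        cens <- !is.null(tm) && pts$t_s[npts] >= tm - 1.5 * stats::median(diff(pts$t_s))
        if (!cens) short_res <- c(short_res, span)
      }
      next
    }
    s <- segment_track(tr, cfg = cfg, network = network)
    m <- compute_run_metrics(s, network = network, t_max = tm)
    kept <- c(kept, i)
    segs[[length(segs) + 1]] <- s
    mets[[length(mets) + 1]] <- m
  }
  list(segmented = segs, metrics = mets, kept = kept,
       short_residency_s = short_res,
       n_skipped = length(trajs) - length(kept))
}

#' Pooled motility statistics of an analysed ensemble
#'
#' Reproduces the headline single-molecule statistics: the plus-end velocity
#' (Gaussian fit of per-segment velocities), run length and residency
#' (exponential-decay fits, medians with bootstrap SEM), pause and end-dwell
#' durations, the pause frequency per micrometre of processive path, and the
#' plus-end-directed fraction. Run lengths exclude runs that arrived at the
#' plus end (end-censored); residencies exclude tracks still attached at the
#' end of the observation window (right-censored), with counts reported.
#'
#' @param analysis an [analyze_tracks()] result.
#' @param n_boot,seed bootstrap controls for the SEM of the median.
#' @param n_experiments split for the pause-frequency mean +/- SD across
#'   pseudo-experiments.
#' @return list of `distribution_fit` objects and scalar statistics.
#' @export
motility_summary <- function(analysis, n_boot = 1000, seed = 1L,
                             n_experiments = 3) {
  mets <- analysis$metrics
  segs <- analysis$segmented

  vels <- unlist(lapply(segs, function(s) {
    s$segments$velocity_nm_s[s$segments$state == "PROCESSIVE_PLUS"]
  }))
  run_plus <- unlist(lapply(mets, function(m) {
    m$runs$length_um[m$runs$direction == "plus" & !m$runs$reached_end]
  }))
  dirs <- vapply(mets, function(m) {
    if (is.null(m$direction) || is.na(m$direction)) NA_character_ else m$direction
  }, character(1))
  # Residency over tracks that are not minus-directed (the reference
  # statistic is for plus-end motors) and not right-censored; tracks too
  # short to classify still contribute their observable attachment span, so
  # the sample is not truncated from below.
  res <- vapply(seq_along(mets), function(i) {
    m <- mets[[i]]
    if (!identical(dirs[i], "minus") && !isTRUE(m$censored))
      m$residency_time_s else NA_real_
  }, numeric(1))
  res <- c(res, analysis$short_residency_s)
  pauses <- unlist(lapply(mets, function(m) m$pause_durations))
  dwells <- unlist(lapply(mets, function(m) m$end_dwell_times_s))

  fit_or_null <- function(x, model) {
    x <- x[is.finite(x) & (model != "exponential_decay" | x > 0)]
    if (length(x) >= 3) fit_distribution(x, model, n_boot = n_boot,
                                         seed = seed) else NULL
  }
  exper <- rep(seq_len(n_experiments), length.out = length(mets))
  pf <- tryCatch(pause_frequency(mets, experiment = exper),
                 error = function(e) NULL)
  n_dir <- sum(!is.na(dirs))

  list(
    velocity = fit_or_null(vels, "gaussian"),
    run_length = fit_or_null(run_plus, "exponential_decay"),
    residency = fit_or_null(res, "exponential_decay"),
    pause_duration = fit_or_null(pauses, "exponential_decay"),
    end_dwell = fit_or_null(dwells, "exponential_decay"),
    pause_frequency = pf,
    plus_fraction = if (n_dir > 0) sum(dirs == "plus", na.rm = TRUE) / n_dir
                    else NA_real_,
    n_directional = n_dir,
    n_runs = length(run_plus),
    n_residency = sum(is.finite(res)),
    n_censored_residency = sum(vapply(mets, function(m) isTRUE(m$censored),
                                      logical(1))),
    n_pauses = length(pauses),
    n_dwells = length(dwells),
    n_skipped = analysis$n_skipped)
}
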