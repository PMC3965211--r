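# Per-track motility metrics from a segmented track.

#' Compute run metrics for one segmented track
#'
#' A processive run is a maximal stretch of same-direction processive
#' segments on one microtubule, bridging internal pauses (a pause flanked by
#' same-direction processive motion does not end the run, because the motor
#' has not dissociated). Runs terminate at conversions to diffusive motion,
#' microtubule switches, end arrival, or dissociation. Run length is the net
#' arc displacement of the run.
#'
#' @param seg a [segment_track()] result.
#' @param network optional [build_network()] for end-arrival detection.
#' @param t_max observation window used to flag right-censored tracks;
#'   defaults to the last time point (no censoring flag possible).
#' @return An object of class `run_metrics`: list with `runs` (data frame
#'   `length_um, direction, n_pauses, reached_end, t0, t1`), `run_lengths`,
#'   `pause_durations`, `pause_count`, `processive_path_um`,
#'   `residency_time_s`, `end_dwell_times_s`, `direction`, `reached_end`,
#'   `motile`, `censored`.
#' @export
compute_run_metrics <- function(seg, network = NULL, t_max = NULL) {
  stopifnot(inherits(seg, "segmented_track"))
  if (is.null(network)) network <- seg$network
  segs <- seg$segments
  pts <- seg$points
  proc <- c("PROCESSIVE_PLUS", "PROCESSIVE_MINUS")

  runs <- list()
  pause_durs <- numeric()
  i <- 1
  nseg <- nrow(segs)
  while (i <= nseg) {
    if (segs$state[i] %in% proc) {
      dir_state <- segs$state[i]
      mt <- segs$mt_id[i]
      j <- i
      # extend across internal pauses flanked by same-direction motion
      while (j + 1 <= nseg) {
        nxt <- segs$state[j + 1]
        if (nxt == dir_state && segs$mt_id[j + 1] == mt) {
          j <- j + 1
        } else if (nxt == "PAUSED" && j + 2 <= nseg &&
                   segs$state[j + 2] == dir_state &&
                   segs$mt_id[j + 2] == mt) {
          pause_durs <- c(pause_durs, segs$duration_s[j + 1])
          j <- j + 2
        } else {
          break
        }
      }
      a0 <- pts$arc_pos_um[segs$start_idx[i]]
      a1 <- pts$arc_pos_um[segs$end_idx[j]]
      reached <- FALSE
      if (j + 1 <= nseg && segs$state[j + 1] == "END_DWELL") reached <- TRUE
      if (!is.null(network) && dir_state == "PROCESSIVE_PLUS") {
        len <- mt_length(network, mt)
        if (a1 >= len - seg$cfg$end_radius / 1000) reached <- TRUE
      }
      runs[[length(runs) + 1]] <- data.frame(
        length_um = abs(a1 - a0),
        direction = if (dir_state == "PROCESSIVE_PLUS") "plus" else "minus",
        n_pauses = sum(segs$state[i:j] == "PAUSED"),
        reached_end = reached,
        t0 = pts$t_s[segs$start_idx[i]], t1 = pts$t_s[segs$end_idx[j]])
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(length_um = numeric(), direction = character(),
               n_pauses = integer(), reached_end = logical(),
               t0 = numeric(), t1 = numeric())

  # Pauses during processive movement: every PAUSED segment flanked on at
  # least one side by a processive segment. Pauses strictly interior to a run
  # already bridged above; boundary pauses (a run's last act before a mode
  # change or dissociation) still count towards the pause statistics, as
  # they would on a kymograph.
  pause_durs <- numeric()
  for (k in seq_len(nseg)) {
    if (segs$state[k] != "PAUSED") next
    prev_proc <- k > 1 && segs$state[k - 1] %in% proc
    next_proc <- k < nseg && segs$state[k + 1] %in% proc
    if (prev_proc || next_proc) pause_durs <- c(pause_durs, segs$duration_s[k])
  }

  proc_path <- sum(abs(segs$net_disp_um[segs$state %in% proc]))
  net_proc <- sum(segs$net_disp_um[segs$state %in% proc])
  dwells <- segs$duration_s[segs$state == "END_DWELL"]
  residency <- pts$t_s[nrow(pts)] - pts$t_s[1]
  censored <- if (is.null(t_max)) NA else
    pts$t_s[nrow(pts)] >= t_max - 1.5 * seg$dt
  motile <- any(segs$state %in% c(proc, "DIFFUSIVE"))

  structure(list(
    runs = runs,
    run_lengths = runs$length_um,
    pause_durations = pause_durs,
    pause_count = length(pause_durs),
    processive_path_um = proc_path,
    residency_time_s = residency,
    end_dwell_times_s = dwells,
    direction = if (nrow(runs) > 0) {
      if (net_proc >= 0) "plus" else "minus"
    } else {
      # no classifiable run: fall back on the net track displacement, the way
      # a short directional trace would still be scored on a kymograph
      net <- pts$arc_pos_um[nrow(pts)] - pts$arc_pos_um[1]
      if (abs(net) >= 0.15) { if (net > 0) "plus" else "minus" } else
        NA_character_
    },
    reached_end = any(runs$reached_end),
    motile = motile,
    censored = censored), class = "run_metrics")
}

#' Pause frequency per micrometre of processive path
#'
#' @param metrics list of [compute_run_metrics()] results.
#' @param experiment optional grouping vector (one id per track); when given,
#'   the per-experiment frequencies are returned with their mean and SD.
#' @return list with `frequency_per_um` (pooled), and when grouped,
#'   `per_experiment`, `mean`, `sd`.
#' @export
pause_frequency <- function(metrics, experiment = NULL) {
  npauses <- vapply(metrics, function(m) m$pause_count, numeric(1))
  path <- vapply(metrics, function(m) m$processive_path_um, numeric(1))
  if (sum(path) <= 0) stop("undefined pause frequency: zero processive path")
  out <- list(frequency_per_um = sum(npauses) / sum(path))
  if (!is.null(experiment)) {
    per <- tapply(seq_along(metrics), experiment, function(ii) {
      if (sum(path[ii]) <= 0) return(NA_real_)
      sum(npauses[ii]) / sum(path[ii])
    })
    out$per_experiment <- per
    out$mean <- mean(per, na.rm = TRUE)
    out$sd <- stats::sd(per, na.rm = TRUE)
  }
  out
}

#' Normalized motile fraction relative to a control condition
#'
#' Track counts are normalised to the total microtubule length imaged in each
#' condition; the control's static density is subtracted and the condition's
#' motile density is expressed relative to the control's (control = 1 by
#' construction).
#'
#' @param tracks list of [compute_run_metrics()] (or logical vector of
#'   per-track motility) for the condition.
#' @param total_mt_length total microtubule length in the condition, um.
#' @param control_tracks,control_length same for the control condition.
#' @return list with `motile_fraction` (condition motile density / control
#'   motile density), `static_excess_density` and the raw densities.
#' @export
motile_fraction <- function(tracks, total_mt_length,
                            control_tracks, control_length) {
  stopifnot(total_mt_length > 0, control_length > 0)
  as_motile <- function(x) {
    if (is.logical(x)) x else vapply(x, function(m) isTRUE(m$motile), logical(1))
  }
  mo <- as_motile(tracks); mo_c <- as_motile(control_tracks)
  d_mot <- sum(mo) / total_mt_length
  d_stat <- sum(!mo) / total_mt_length
  d_mot_c <- sum(mo_c) / control_length
  d_stat_c <- sum(!mo_c) / control_length
  if (d_mot_c <= 0) stop("undefined normalization: control has no motile tracks")
  list(motile_fraction = d_mot / d_mot_c,
       static_excess_density = (d_stat - d_stat_c) / d_mot_c,
       condition_density = c(motile = d_mot, static = d_stat),
       control_density = c(motile = d_mot_c, static = d_stat_c))
}
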