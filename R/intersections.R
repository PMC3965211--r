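# Motor behaviour at microtubule intersections: approach detection, four-way
# outcome classification (pass / switch / pause / dissociate), and switching
# statistics.
#
# Outcome definitions follow the standard single-molecule scheme:
#   PASS       - continues moving on the same microtubule beyond the crossing
#                (possibly after a pause at the intersection);
#   SWITCH     - continues moving on the crossing microtubule (possibly after
#                a pause); the motor never leaves the lattice;
#   PAUSE      - pauses for more than 5 s at the intersection and does not
#                continue (eventually dissociates or bleaches);
#   DISSOCIATE - detaches essentially immediately at the intersection.

#' Detect approaches of a motor to microtubule intersections
#'
#' One candidate event per contiguous interval during which the motor is
#' within `radius` of an intersection involving its current microtubule;
#' re-approaches after leaving the radius count separately. An interval that
#' spans a microtubule switch (the motor is within the radius first on one
#' partner, then on the other) is a single candidate.
#'
#' @param track a `trajectory`, `segmented_track`, or points data frame with
#'   `t_s, mt_id, arc_pos_um`.
#' @param network the [build_network()].
#' @param radius capture radius, nm.
#' @return data frame of candidates: `int_id, idx_enter, idx_exit, t_enter,
#'   t_exit` (indices into the track's points).
#' @export
detect_approaches <- function(track, network, radius = 200) {
  pts <- track_points(track)
  if (!all(pts$mt_id %in% network$mts$mt_id)) {
    stop("track references microtubule ids absent from the network")
  }
  # with a segmented track, only processively moving motors approach: a
  # diffusive excursion that wanders into the radius is not an approach
  labels <- NULL
  if (inherits(track, "segmented_track")) {
    labels <- point_labels(track)
  }
  r_um <- radius / 1000
  out <- list()
  for (k in seq_len(nrow(network$intersections))) {
    ii <- network$intersections[k, ]
    within <- (pts$mt_id == ii$mt_a & abs(pts$arc_pos_um - ii$arc_a_um) <= r_um) |
      (pts$mt_id == ii$mt_b & abs(pts$arc_pos_um - ii$arc_b_um) <= r_um)
    if (!any(within)) next
    r <- rle(within)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1
    for (m in which(r$values)) {
      if (!is.null(labels)) {
        ent <- labels[max(lo[m] - 1, 1):lo[m]]
        if (!any(ent %in% c("PROCESSIVE_PLUS", "PROCESSIVE_MINUS"))) next
      }
      out[[length(out) + 1]] <- data.frame(
        int_id = ii$int_id, idx_enter = lo[m], idx_exit = hi[m],
        t_enter = pts$t_s[lo[m]], t_exit = pts$t_s[hi[m]])
    }
  }
  if (!length(out)) {
    return(data.frame(int_id = integer(), idx_enter = integer(),
                      idx_exit = integer(), t_enter = numeric(),
                      t_exit = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$t_enter), , drop = FALSE]
}

track_points <- function(track) {
  if (inherits(track, "trajectory")) track$points
  else if (inherits(track, "segmented_track")) track$points
  else as.data.frame(track)
}

# expand segment labels back onto points
point_labels <- function(seg) {
  lab <- character(nrow(seg$points))
  for (i in seq_len(nrow(seg$segments))) {
    lab[seg$segments$start_idx[i]:seg$segments$end_idx[i]] <-
      seg$segments$state[i]
  }
  lab
}

#' Classify one intersection approach
#'
#' Decision rules, in order: detachment within one frame of arrival gives
#' DISSOCIATE; movement continuing for at least `min_frames_beyond` frames
#' beyond the radius on the same microtubule gives PASS, on the crossing
#' microtubule SWITCH (the time spent inside the radius is recorded as
#' `pause_s` either way); a dwell of more than `pause_thresh_s` (frame
#' tolerance of half a frame) with no continuation gives PAUSE; a shorter
#' dwell ending in detachment gives DISSOCIATE. A trace that ends inside the
#' radius without detaching (observation window end, bleaching) is
#' indeterminate and excluded from fractions.
#'
#' @param candidate one row of [detect_approaches()].
#' @param track the same track.
#' @param network the network.
#' @param radius capture radius, nm.
#' @param t_max observation window end, s (to distinguish dissociation from a
#'   censored trace); taken from a `trajectory` object when available.
#' @param pause_thresh_s pause threshold at an intersection, s.
#' @param min_frames_beyond frames of continued movement beyond the radius
#'   required to call a pass/switch.
#' @return data frame row: `int_id, t_approach_s, outcome, pause_s,
#'   mt_before, mt_after, indeterminate`.
#' @export
classify_event <- function(candidate, track, network, radius = 200,
                           t_max = NULL, pause_thresh_s = 5,
                           min_frames_beyond = 3, labels = NULL) {
  pts <- track_points(track)
  if (is.null(t_max) && inherits(track, "trajectory")) t_max <- track$t_max
  if (is.null(labels) && inherits(track, "segmented_track")) {
    labels <- point_labels(track)
  }
  dt <- stats::median(diff(pts$t_s))
  n <- nrow(pts)
  i0 <- candidate$idx_enter
  i1 <- candidate$idx_exit
  mt_before <- pts$mt_id[i0]
  dwell <- pts$t_s[i1] - pts$t_s[i0]
  censored_end <- !is.null(t_max) && pts$t_s[n] >= t_max - 1.5 * dt

  mk <- function(outcome, pause_s, mt_after, indet = FALSE) {
    data.frame(int_id = candidate$int_id, t_approach_s = pts$t_s[i0],
               outcome = outcome, pause_s = pause_s, mt_before = mt_before,
               mt_after = mt_after, indeterminate = indet)
  }

  if (i1 >= n) { # trace ends inside the radius
    if (censored_end) {
      return(mk(NA_character_, dwell, NA_integer_, indet = TRUE))
    }
    if (dwell <= dt + 1e-9) return(mk("DISSOCIATE", 0, NA_integer_))
    if (dwell > pause_thresh_s - dt / 2) return(mk("PAUSE", dwell, NA_integer_))
    return(mk("DISSOCIATE", dwell, NA_integer_))
  }
  after <- (i1 + 1):min(i1 + min_frames_beyond, n)
  mt_after <- pts$mt_id[after[length(after)]]
  if (length(after) < min_frames_beyond && censored_end) {
    return(mk(NA_character_, dwell, mt_after, indet = TRUE))
  }
  if (mt_after != mt_before) return(mk("SWITCH", dwell, mt_after))

  # Same microtubule: a pass must actually traverse the crossing. A motor
  # whose run happens to end inside the radius drifts back out diffusively
  # without crossing; that is not an intersection behaviour.
  ii <- network$intersections[network$intersections$int_id == candidate$int_id, ]
  arc_int <- if (ii$mt_a == mt_before) ii$arc_a_um else ii$arc_b_um
  side_enter <- sign(pts$arc_pos_um[i0] - arc_int)
  side_after <- sign(pts$arc_pos_um[after[length(after)]] - arc_int)
  traversed <- side_enter != 0 && side_after != 0 && side_enter != side_after
  moving_after <- is.null(labels) ||
    any(labels[after] %in% c("PROCESSIVE_PLUS", "PROCESSIVE_MINUS", "PAUSED"))
  if (traversed && moving_after) return(mk("PASS", dwell, mt_after))
  if (dwell > pause_thresh_s - dt / 2) return(mk("PAUSE", dwell, mt_after))
  mk(NA_character_, dwell, mt_after, indet = TRUE)
}

#' Detect and classify all intersection events of a track
#'
#' @inheritParams classify_event
#' @param traj_id identifier copied into the result.
#' @return data frame of [classify_event()] rows.
#' @export
classify_events <- function(track, network, radius = 200, t_max = NULL,
                            traj_id = NA_integer_, ...) {
  cand <- detect_approaches(track, network, radius = radius)
  if (!nrow(cand)) {
    return(data.frame(traj_id = integer(), int_id = integer(),
                      t_approach_s = numeric(), outcome = character(),
                      pause_s = numeric(), mt_before = integer(),
                      mt_after = integer(), indeterminate = logical()))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    classify_event(cand[i, ], track, network, radius = radius,
                   t_max = t_max, ...)
  }))
  cbind(traj_id = traj_id, out)
}

#' Summarise intersection outcome fractions
#'
#' @param events data frame of classified events ([classify_events()] rows,
#'   possibly concatenated over an ensemble).
#' @return list with `counts`, `fractions` (over classified events; sums to 1
#'   exactly), `n_classified`, `n_indeterminate`.
#' @export
summarize_event_fractions <- function(events) {
  if (is.null(events) || nrow(events) == 0) stop("no events to summarise")
  cls <- events[!events$indeterminate & !is.na(events$outcome), , drop = FALSE]
  lev <- c("PASS", "SWITCH", "PAUSE", "DISSOCIATE")
  counts <- table(factor(cls$outcome, levels = lev))
  n <- sum(counts)
  if (n == 0) stop("no classified events")
  list(counts = counts, fractions = as.numeric(counts) / n,
       outcome_levels = lev, n_classified = n,
       n_indeterminate = sum(events$indeterminate))
}

#' Total path length across switch events, and the predicted reach
#'
#' Each switch starts a new independent run on a new microtubule, so a single
#' molecule's expected reach is the median run length times (number of
#' switches + 1); the realized effective path is the sum of the per-track run
#' lengths.
#'
#' @param run_lengths per-run lengths, um (non-negative).
#' @return `effective_path_length`: their sum, um.
#' @export
effective_path_length <- function(run_lengths) {
  if (any(run_lengths < 0)) stop("run lengths must be non-negative")
  sum(run_lengths)
}

#' @rdname effective_path_length
#' @param median_run median run length, um.
#' @param n_switches number of track switches.
#' @return `predicted_reach`: `median_run * (n_switches + 1)`, um.
#' @export
predicted_reach <- function(median_run, n_switches) {
  if (median_run < 0 || n_switches < 0) stop("inputs must be non-negative")
  median_run * (n_switches + 1)
}
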