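# Track segmentation into motility states.
#
# The original assays classified motor behaviour by eye on kymographs; here
# the classification is an explicit threshold algorithm on the position
# series: a sliding-window least-squares velocity separates stationary from
# moving points, stationary stretches become pauses (or end dwells near the
# plus end), and moving stretches become processive segments when their
# velocity sign is consistent and their mean-squared displacement scales
# super-diffusively, otherwise diffusive.

# least-squares slope with its standard error, without summary.lm's noise
# (a zero-residual fit is a legitimate case for noiseless synthetic tracks)
ls_slope <- function(t, y) {
  n <- length(y)
  if (n < 2) return(c(NA_real_, NA_real_))
  tm <- t - mean(t)
  sxx <- sum(tm^2)
  if (sxx == 0) return(c(NA_real_, NA_real_))
  b <- sum(tm * y) / sxx
  if (n == 2) return(c(b, NA_real_))
  rss <- sum((y - mean(y) - b * tm)^2)
  c(b, sqrt(max(rss, 0) / (n - 2) / sxx))
}

# least-squares slope of y vs t over a centred sliding window, via cumulative
# sums; edge windows are truncated.
rolling_slope <- function(t, y, w) {
  n <- length(y)
  h1 <- (w - 1) %/% 2
  h2 <- w - 1 - h1
  lo <- pmax(seq_len(n) - h1, 1)
  hi <- pmin(seq_len(n) + h2, n)
  cs <- function(x) c(0, cumsum(x))
  St <- cs(t); Sy <- cs(y); Stt <- cs(t * t); Sty <- cs(t * y)
  m <- hi - lo + 1
  st <- St[hi + 1] - St[lo]
  sy <- Sy[hi + 1] - Sy[lo]
  stt <- Stt[hi + 1] - Stt[lo]
  sty <- Sty[hi + 1] - Sty[lo]
  den <- m * stt - st^2
  num <- m * sty - st * sy
  ifelse(den > 0, num / den, 0)
}

# A processive motor advances by nearly the same displacement every frame;
# a diffusive excursion that happens to be straight over a few frames does
# not. Votes on interval speeds (edges trimmed: they may straddle a pause or
# state change): at least 70% must share the sign and lie within
# [0.4, 2.5]x the median interval speed.
uniform_stepping <- function(t, pos) {
  iv <- diff(pos) / diff(t)
  if (length(iv) < 2) return(TRUE)
  core <- if (length(iv) >= 3) iv[2:(length(iv) - 1)] else iv
  sgn <- sign(sum(core))
  if (sgn == 0) return(FALSE)
  med <- stats::median(abs(core))
  if (med == 0) return(FALSE)
  ok <- sign(core) == sgn & abs(core) >= 0.4 * med & abs(core) <= 2.5 * med
  mean(ok) >= 0.7
}

# RMS residual around the least-squares line (um)
line_resid_rms <- function(t, y) {
  n <- length(y)
  if (n < 3) return(0)
  tm <- t - mean(t)
  sxx <- sum(tm^2)
  if (sxx == 0) return(0)
  b <- sum(tm * y) / sxx
  sqrt(mean((y - mean(y) - b * tm)^2))
}

# MSD scaling exponent alpha from a log-log fit over short lags;
# ~2 for ballistic motion, ~1 for diffusion, 0 for an immobile trace.
msd_exponent <- function(pos, max_lag = NULL) {
  n <- length(pos)
  if (is.null(max_lag)) max_lag <- max(2L, min(4L, n - 1L))
  lags <- seq_len(min(max_lag, n - 1L))
  msd <- vapply(lags, function(k) mean((pos[(k + 1):n] - pos[1:(n - k)])^2),
                numeric(1))
  keep <- msd > 0
  if (sum(keep) < 2) return(0)
  stats::coef(stats::lm(log(msd[keep]) ~ log(lags[keep])))[[2]]
}

#' Segment a motor track into motility-state segments
#'
#' @param track a `trajectory` object or a data frame with columns `t_s`,
#'   `arc_pos_um` and optionally `mt_id` (points at a constant frame
#'   interval).
#' @param cfg a [seg_config()] object.
#' @param network the [build_network()] the track lives on; needed to label
#'   end dwells and to sign velocities by microtubule polarity. Without it,
#'   increasing arc position counts as plus-end-directed and no end dwells
#'   are assigned.
#' @return An object of class `segmented_track`: list with `points`, `dt`,
#'   `cfg` and `segments` (data frame `start_idx, end_idx, state, mt_id,
#'   duration_s, net_disp_um, velocity_nm_s, velocity_se_nm_s`). Segments
#'   tile the attached track without overlap.
#' @export
segment_track <- function(track, cfg = seg_config(), network = NULL) {
  pts <- if (inherits(track, "trajectory")) track$points else as.data.frame(track)
  if (!all(c("t_s", "arc_pos_um") %in% names(pts))) {
    stop("track must have columns t_s and arc_pos_um")
  }
  if (is.null(pts$mt_id)) pts$mt_id <- 1L
  n <- nrow(pts)
  if (n < cfg$window) stop("track too short: fewer points than the window")
  dt <- stats::median(diff(pts$t_s))

  labels <- character(n)
  # segment each microtubule-constant chunk independently (a track switch
  # always terminates a segment)
  ch <- rle(pts$mt_id)
  ends <- cumsum(ch$lengths)
  starts <- ends - ch$lengths + 1
  for (c_i in seq_along(starts)) {
    idx <- starts[c_i]:ends[c_i]
    labels[idx] <- classify_chunk(pts$t_s[idx], pts$arc_pos_um[idx],
                                  pts$mt_id[idx][1], cfg, dt, network)
  }

  # collapse into segments
  r <- rle(labels)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1
  segs <- data.frame(start_idx = seg_start, end_idx = seg_end,
                     state = r$values,
                     mt_id = pts$mt_id[seg_start],
                     stringsAsFactors = FALSE)
  segs$duration_s <- pts$t_s[segs$end_idx] - pts$t_s[segs$start_idx]
  segs$net_disp_um <- pts$arc_pos_um[segs$end_idx] -
    pts$arc_pos_um[segs$start_idx]
  vel <- t(vapply(seq_len(nrow(segs)), function(i) {
    if (!segs$state[i] %in% c("PROCESSIVE_PLUS", "PROCESSIVE_MINUS")) {
      return(c(NA_real_, NA_real_))
    }
    ii <- segs$start_idx[i]:segs$end_idx[i]
    ls_slope(pts$t_s[ii], pts$arc_pos_um[ii]) * 1000
  }, numeric(2)))
  segs$velocity_nm_s <- vel[, 1]
  segs$velocity_se_nm_s <- vel[, 2]

  structure(list(points = pts, segments = segs, dt = dt, cfg = cfg,
                 network = network),
            class = "segmented_track")
}

classify_chunk <- function(t, pos, mt, cfg, dt, network) {
  n <- length(pos)
  if (n < cfg$window) {
    v <- if (n >= 2) (pos[n] - pos[1]) / (t[n] - t[1]) * 1000 else 0
    return(rep(if (abs(v) >= cfg$v_pause_thresh) {
      if (v > 0) "PROCESSIVE_PLUS" else "PROCESSIVE_MINUS"
    } else "PAUSED", n))
  }
  v <- rolling_slope(t, pos, cfg$window) * 1000 # nm/s
  near_end <- rep(FALSE, n)
  if (!is.null(network)) {
    len <- mt_length(network, mt)
    near_end <- pos >= len - cfg$end_radius / 1000
  }

  # Stationarity from single-interval displacements: the windowed slope
  # smears pause boundaries by half a window, which would bias pause
  # durations short; a run of j slow intervals spans j * dt of the track and
  # estimates the pause duration without that bias.
  iv <- abs(diff(pos)) / diff(t) * 1000 # nm/s per interval
  slow_iv <- iv < cfg$v_pause_thresh
  stationary <- rep(FALSE, n)
  r_iv <- rle(slow_iv)
  ihi <- cumsum(r_iv$lengths)
  ilo <- ihi - r_iv$lengths + 1
  lab <- rep(NA_character_, n)
  for (k in seq_along(ilo)) {
    if (!r_iv$values[k]) next
    idx <- ilo[k]:(ihi[k] + 1) # frames spanned by the slow intervals
    dur <- t[idx[length(idx)]] - t[idx[1]]
    if (dur < cfg$min_pause_dur) next
    stationary[idx] <- TRUE
    lab[idx] <- if (all(near_end[idx])) "END_DWELL" else "PAUSED"
  }

  # moving stretches: split by windowed-velocity sign
  mov <- which(!stationary)
  if (length(mov)) {
    br <- c(0, which(diff(mov) > 1), length(mov))
    for (b in seq_len(length(br) - 1)) {
      idx <- mov[(br[b] + 1):br[b + 1]]
      sr <- rle(sign(v[idx]))
      shi <- cumsum(sr$lengths)
      slo <- shi - sr$lengths + 1
      for (m in seq_along(slo)) {
        jdx <- idx[slo[m]:shi[m]]
        sdur <- t[jdx[length(jdx)]] - t[jdx[1]]
        alpha <- if (length(jdx) >= 4) msd_exponent(pos[jdx]) else 0
        straight <- line_resid_rms(t[jdx], pos[jdx]) * 1000 <= cfg$max_resid_nm
        lab[jdx] <- if (sdur >= cfg$min_proc_dur &&
                        alpha >= cfg$msd_alpha_proc && straight &&
                        uniform_stepping(t[jdx], pos[jdx])) {
          if (sr$values[m] > 0) "PROCESSIVE_PLUS" else "PROCESSIVE_MINUS"
        } else {
          "DIFFUSIVE"
        }
      }
    }
  }
  # A single-frame moving blip between two pauses is below anything a
  # kymograph scorer would resolve as a run; fold it into the pause.
  lab <- absorb_pause_stubs(lab, dt)

  # Rescue pass: a straight, sign-consistent moving stretch below
  # min_proc_dur is still a (short) processive run when it is the motor's
  # first act after attachment, or the continuation of a run across a pause;
  # left as DIFFUSIVE it would truncate the run-length sample from below.
  lab <- rescue_short_runs(lab, t, pos, cfg)

  # unresolved short stationary stretches inherit the previous state
  if (anyNA(lab)) {
    for (i in seq_len(n)) {
      if (is.na(lab[i])) lab[i] <- if (i > 1) lab[i - 1] else NA
    }
    for (i in rev(seq_len(n))) {
      if (is.na(lab[i])) lab[i] <- lab[i + 1]
    }
    if (anyNA(lab)) lab[is.na(lab)] <- "PAUSED"
  }
  lab
}

absorb_pause_stubs <- function(lab, dt) {
  r <- rle(ifelse(is.na(lab), "NA", lab))
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  ns <- length(lo)
  if (ns < 3) return(lab)
  for (k in 2:(ns - 1)) {
    if (r$values[k] %in% c("PAUSED", "END_DWELL")) next
    if (r$lengths[k] <= 1 &&
        r$values[k - 1] %in% c("PAUSED", "END_DWELL") &&
        r$values[k + 1] %in% c("PAUSED", "END_DWELL")) {
      lab[lo[k]:hi[k]] <- r$values[k - 1]
    }
  }
  lab
}

rescue_short_runs <- function(lab, t, pos, cfg) {
  proc <- c("PROCESSIVE_PLUS", "PROCESSIVE_MINUS")
  r <- rle(ifelse(is.na(lab), "NA", lab))
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  ns <- length(lo)
  for (k in seq_len(ns)) {
    if (r$values[k] != "DIFFUSIVE") next
    at_start <- lo[k] == 1
    after_run_pause <- k > 2 && r$values[k - 1] == "PAUSED" &&
      r$values[k - 2] %in% proc
    if (!at_start && !after_run_pause) next
    # include the interval into the next frame so 1-frame stretches have a
    # measurable displacement
    idx <- lo[k]:min(hi[k] + 1, length(pos))
    if (length(idx) < 2) next
    iv <- diff(pos[idx]) / diff(t[idx]) * 1000
    sgn <- sign(iv[1])
    if (sgn == 0) next
    ok <- sign(iv) == sgn & abs(iv) >= cfg$v_pause_thresh &
      abs(iv) <= 1.2 * 550 # generous speed ceiling; walks regularly exceed it
    # maximal consistent prefix: the run part of the stretch, before any
    # diffusive wandering takes over
    j <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
    if (j < 1) next
    jdx <- idx[1]:(idx[1] + j)
    if (line_resid_rms(t[jdx], pos[jdx]) * 1000 > cfg$max_resid_nm) next
    state <- if (sgn > 0) "PROCESSIVE_PLUS" else "PROCESSIVE_MINUS"
    if (after_run_pause && r$values[k - 2] != state) next
    lab[idx[1]:min(idx[1] + j - 1, hi[k])] <- state
  }
  lab
}

#' @export
print.segmented_track <- function(x, ...) {
  tb <- table(x$segments$state)
  cat(sprintf("Segmented track: %d points, %d segments (%s)\n",
              nrow(x$points), nrow(x$segments),
              paste(names(tb), tb, sep = ":", collapse = ", ")))
  invisible(x)
}
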