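# Fluorescence rendering: stepwise photobleaching of a multi-fluorophore
# motor, and kymograph images.

#' Simulate the fluorescence intensity trace of a trajectory
#'
#' Each of the motor's fluorophores is independently dark from the start with
#' probability `p_prebleached` and otherwise bleaches after an exponential
#' lifetime (rate `bleach_rate`). The noiseless intensity is a non-increasing
#' staircase `n_active * unit_intensity` with at most `n_fluor` equal-height
#' downward steps; Gaussian noise of sd `noise_sd` is added on top.
#'
#' @param traj a [simulate_trajectory()] result (or a data frame with a `t_s`
#'   column).
#' @param fluor a [fluor_model()].
#' @param seed integer seed.
#' @return The trajectory's points with `n_active_fluor` and `intensity_au`
#'   filled in; the bleach times are attached as attribute `bleach_times`.
#' @export
simulate_intensity_trace <- function(traj, fluor, seed = 1L) {
  stopifnot(inherits(fluor, "fluor_model"))
  pts <- if (inherits(traj, "trajectory")) traj$points else as.data.frame(traj)
  n <- nrow(pts)
  with_seed(seed, {
    pre <- stats::runif(fluor$n_fluor) < fluor$p_prebleached
    life <- ifelse(pre, 0,
                   if (fluor$bleach_rate > 0) {
                     stats::rexp(fluor$n_fluor, fluor$bleach_rate)
                   } else {
                     rep(Inf, fluor$n_fluor)
                   })
    active <- vapply(pts$t_s, function(tt) sum(life > tt), integer(1))
    noise <- if (fluor$noise_sd > 0) stats::rnorm(n, 0, fluor$noise_sd) else 0
    pts$n_active_fluor <- active
    pts$intensity_au <- active * fluor$unit_intensity + noise
    attr(pts, "bleach_times") <- sort(life[is.finite(life) & life > 0])
    pts
  })
}

#' Render a kymograph from trajectories on one microtubule
#'
#' Space-time image (rows = space along the microtubule, columns = frames).
#' Each frame deposits a 1-D Gaussian spot of width `psf_sigma` at every
#' motor's arc position, scaled by its intensity (or 1 if the trajectory has
#' no intensity channel), on top of a constant background with optional
#' Gaussian noise.
#'
#' @param trajs list of trajectories (or a single one); only points on `mt_id`
#'   are drawn.
#' @param mt_id microtubule id to draw.
#' @param network the network, for the microtubule length.
#' @param pixel_size pixel size, nm.
#' @param frame_interval column spacing, s.
#' @param t_max kymograph duration, s.
#' @param psf_sigma Gaussian spot sigma, nm.
#' @param background,noise_sd background level and noise sd, a.u.
#' @param seed seed for the noise.
#' @return An object of class `kymograph`: list with `image` (space x time
#'   matrix), `pixel_size_nm`, `frame_interval_s`, `mt_id`.
#' @export
render_kymograph <- function(trajs, mt_id, network, pixel_size = 100,
                             frame_interval = 0.5, t_max = NULL,
                             psf_sigma = 150, background = 10, noise_sd = 0,
                             seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  len_um <- mt_length(network, mt_id)
  if (is.na(len_um)) stop("mt_id not present in network")
  if (is.null(t_max)) {
    t_max <- max(c(frame_interval,
                   vapply(trajs, function(tr) {
                     p <- if (inherits(tr, "trajectory")) tr$points else tr
                     if (nrow(p)) max(p$t_s) else 0
                   }, numeric(1))))
  }
  npix <- ceiling(len_um * 1000 / pixel_size) + 1
  nfrm <- floor(t_max / frame_interval) + 1
  px_centers <- (seq_len(npix) - 1) * pixel_size # nm from minus end
  img <- matrix(background, nrow = npix, ncol = nfrm)

  for (tr in trajs) {
    p <- if (inherits(tr, "trajectory")) tr$points else as.data.frame(tr)
    p <- p[p$mt_id == mt_id, , drop = FALSE]
    if (!nrow(p)) next
    cols <- round(p$t_s / frame_interval) + 1
    keep <- cols >= 1 & cols <= nfrm
    p <- p[keep, , drop = FALSE]; cols <- cols[keep]
    amp <- p$intensity_au
    amp[is.na(amp)] <- 1
    for (i in seq_len(nrow(p))) {
      mu <- p$arc_pos_um[i] * 1000
      spot <- exp(-0.5 * ((px_centers - mu) / psf_sigma)^2)
      img[, cols[i]] <- img[, cols[i]] + amp[i] * spot
    }
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow = npix))
  }
  structure(list(image = img, pixel_size_nm = pixel_size,
                 frame_interval_s = frame_interval, mt_id = mt_id),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d px x %d frames (%g nm/px, %g s/frame), mt %d\n",
              nrow(x$image), ncol(x$image), x$pixel_size_nm,
              x$frame_interval_s, x$mt_id))
  invisible(x)
}
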