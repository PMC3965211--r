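# Stochastic state-machine simulation of single motors on microtubule
# networks.
#
# A motor attaches at a uniformly random lattice position, picks a direction
# (plus-end with probability p_plus; minus-directed runs never reverse), and
# moves processively at a per-run velocity drawn from a truncated Gaussian.
# Pauses arrive as a Poisson process per um of processive path, with
# truncated-exponential durations. The processive run length is drawn from an
# exponential parameterised by its median. On reaching the plus end the motor
# either detaches or dwells (exponential median end_dwell_med) and then roams
# the end-proximal lattice diffusively. When the run budget is exhausted
# mid-lattice the motor enters a weakly bound diffusive "linger" state whose
# detachment rate is calibrated so that the median of total residency equals
# the configured residency_med (see motility_params()). At intersections a
# processive motor entering the capture radius draws one of four outcomes
# (pass / switch / pause / dissociate); switching relocates it to the crossing
# microtubule without ever leaving the lattice.

MOTOR_STATES <- c("PROCESSIVE_PLUS", "PROCESSIVE_MINUS", "DIFFUSIVE",
                  "PAUSED", "END_DWELL", "DETACHED")

#' Simulate one motor trajectory on a microtubule network
#'
#' @param params a [motility_params()] object.
#' @param network an [build_network()] object.
#' @param t_max observation window, s.
#' @param dt frame interval, s (0.5 s = 2 fps).
#' @param seed integer seed; the trajectory is a pure function of
#'   `(params, network, t_max, dt, seed)`.
#' @return An object of class `trajectory`: list with `points` (data frame
#'   `t_s, mt_id, arc_pos_um, x_um, y_um, state, n_active_fluor,
#'   intensity_au`), the frame interval `dt`, `seed`, `params_used`,
#'   `censored` (still attached at `t_max`) and a `truth` list holding the
#'   generator's own record of runs, pauses, end dwells, residency and
#'   intersection encounters (used as the oracle in recovery tests).
#' @export
simulate_trajectory <- function(params, network, t_max = 180, dt = 0.5,
                                seed = 1L) {
  stopifnot(inherits(params, "motility_params"), inherits(network, "mt_network"))
  if (dt <= 0) stop("dt must be > 0")
  if (t_max <= dt) stop("t_max must exceed dt")
  if (nrow(network$mts) < 1) stop("network must contain >= 1 microtubule")
  with_seed(seed, simulate_trajectory_impl(params, network, t_max, dt, seed))
}

simulate_trajectory_impl <- function(p, network, t_max, dt, seed) {
  eps <- 1e-9
  R <- p$capture_radius_nm / 1000 # um

  phases <- list()
  runs <- list(); pauses <- list(); dwells <- list(); encounters <- list()

  add_phase <- function(t0, t1, type, mt, arc0, v = 0, walk = NULL) {
    phases[[length(phases) + 1]] <<- list(t0 = t0, t1 = t1, type = type,
                                          mt = mt, arc0 = arc0, v = v,
                                          walk = walk)
  }

  draw_velocity <- function() {
    vm <- p$v_mixture
    v <- if (!is.null(vm)) {
      if (stats::runif(1) < vm$weight) {
        rtrunc_norm(1, vm$slow_med, vm$slow_sd, 0, p$v_max)
      } else {
        rtrunc_norm(1, vm$fast_med, vm$fast_sd, 0, p$v_max)
      }
    } else if (dirsign > 0) {
      rtrunc_norm(1, p$v_plus_med, p$v_sd, p$v_min, p$v_max)
    } else {
      rtrunc_norm(1, p$v_minus_med, p$v_sd, p$v_min, p$v_max)
    }
    v / 1000 # um/s
  }

  # Reflected diffusive walk recorded at the global frame grid within
  # (t0, t1], plus the phase end point; returns list(t, arc).
  diffusive_walk <- function(t0, t1, arc0, len) {
    k0 <- floor(t0 / dt) + 1
    k1 <- floor(t1 / dt)
    ft <- if (k1 >= k0) (k0:k1) * dt else numeric()
    tt <- ft[ft > t0 + eps & ft < t1 - eps]
    tt <- c(tt, t1)
    gaps <- diff(c(t0, tt))
    incr <- stats::rnorm(length(gaps), 0, sqrt(2 * p$D_diff * pmax(gaps, 0)))
    raw <- arc0 + cumsum(incr)
    # fold into [0, len] (reflection)
    z <- raw %% (2 * len)
    z[z > len] <- 2 * len - z[z > len]
    list(t = tt, arc = z)
  }

  censored <- FALSE
  detach_reason <- NA_character_
  t_detach <- NA_real_

  # --- static motors (lattice-inhibited scenario) ---------------------------
  if (p$p_static > 0 && stats::runif(1) < p$p_static) {
    mt <- sample.int(nrow(network$mts), 1, prob = network$mts$length_um)
    arc <- stats::runif(1, 0, network$mts$length_um[mt])
    add_phase(0, t_max, "PAUSED", mt, arc)
    return(finish_trajectory(phases, list(
      static = TRUE, direction = NA_character_, runs = NULL, pauses = NULL,
      dwells = numeric(), encounters = NULL, residency_s = NA_real_,
      censored = TRUE, detach_reason = "none"),
      network, t_max, dt, seed, p, censored = TRUE, t_detach = NA_real_))
  }

  mt <- sample.int(nrow(network$mts), 1, prob = network$mts$length_um)
  len <- network$mts$length_um[mt]
  arc <- stats::runif(1, 0, len)
  dirsign <- if (stats::runif(1) < p$p_plus) 1 else -1
  direction <- if (dirsign > 0) "plus" else "minus"
  run_med <- if (dirsign > 0) p$run_len_med_plus else p$run_len_med_minus
  linger_rate <- if (dirsign > 0) p$linger_rate_plus else p$linger_rate_minus

  t <- 0
  mode <- "RUN"
  consumed_int <- NA_integer_

  # per-run state
  v_run <- NA_real_; L_rem <- NA_real_; L_drawn <- NA_real_
  d_pause <- Inf; t_mode_rem <- Inf
  run_t0 <- 0; run_len_done <- 0

  new_run <- function() {
    v_run <<- draw_velocity()
    L_drawn <<- stats::rexp(1, rate_from_median(run_med))
    L_rem <<- L_drawn
    d_pause <<- if (p$pause_rate > 0) stats::rexp(1, p$pause_rate) else Inf
    t_mode_rem <<- if (p$p_mode_switch > 0) stats::rexp(1, p$p_mode_switch) else Inf
    run_t0 <<- t
    run_len_done <<- 0
  }
  end_run <- function(end_type, reached_end = FALSE) {
    runs[[length(runs) + 1]] <<- data.frame(
      v_nm_s = v_run * 1000 * dirsign, L_drawn_um = L_drawn,
      length_um = run_len_done, reached_end = reached_end,
      end_type = end_type, t0 = run_t0, t1 = t)
  }
  detach <- function(reason) {
    detach_reason <<- reason
    t_detach <<- t
    mode <<- "DETACHED"
  }

  new_run()

  while (mode != "DETACHED" && t < t_max - eps) {
    len <- network$mts$length_um[mt]

    if (mode == "RUN") {
      # candidate distances (um) to the next event
      d_end <- if (dirsign > 0) len - arc else arc
      d_mode <- v_run * t_mode_rem
      # intersections on this microtubule
      # outcomes resolve at the crossing point itself; the capture radius
      # provides hysteresis so a resolved crossing does not re-trigger until
      # the motor has moved away from it
      ion <- intersections_on_mt(network, mt)
      d_int <- Inf; int_row <- NULL
      if (nrow(ion)) {
        for (k in seq_len(nrow(ion))) {
          if (!is.na(consumed_int) && ion$int_id[k] == consumed_int) next
          dk <- (ion$arc_um[k] - arc) * dirsign
          if (dk >= 0 && dk < d_int) { d_int <- dk; int_row <- ion[k, ] }
        }
      }
      d_next <- min(L_rem, d_pause, d_end, d_int, d_mode)
      # clip to the observation window
      d_avail <- v_run * (t_max - t)
      if (d_next > d_avail + eps) {
        add_phase(t, t_max, proc_state(dirsign), mt, arc, v = dirsign * v_run)
        arc <- arc + dirsign * d_avail
        run_len_done <- run_len_done + d_avail
        t <- t_max
        end_run("t_max")
        censored <- TRUE
        break
      }

      t1 <- t + d_next / v_run
      if (d_next > eps) {
        add_phase(t, t1, proc_state(dirsign), mt, arc, v = dirsign * v_run)
      }
      arc <- arc + dirsign * d_next
      run_len_done <- run_len_done + d_next
      L_rem <- L_rem - d_next
      d_pause <- d_pause - d_next
      t_mode_rem <- t_mode_rem - d_next / v_run
      t <- t1
      # leaving the capture radius re-arms the last intersection
      if (!is.na(consumed_int)) {
        ci <- intersections_on_mt(network, mt)
        ci <- ci[ci$int_id == consumed_int, ]
        if (nrow(ci) == 0 || abs(arc - ci$arc_um[1]) > R + eps) {
          consumed_int <- NA_integer_
        }
      }

      if (d_next == d_int && !is.null(int_row)) {
        outcome <- sample(c("PASS", "SWITCH", "PAUSE", "DISSOCIATE"), 1,
                          prob = p$intersection_probs)
        encounters[[length(encounters) + 1]] <- data.frame(
          t_s = t, int_id = int_row$int_id, mt_from = mt,
          mt_to = if (outcome == "SWITCH") int_row$other_mt else mt,
          outcome = outcome)
        consumed_int <- int_row$int_id
        if (outcome == "PASS") {
          # keep walking on the same microtubule
        } else if (outcome == "SWITCH") {
          end_run("switch")
          mt <- int_row$other_mt
          arc <- int_row$other_arc_um
          new_run() # a switch starts a new independent run
        } else if (outcome == "PAUSE") {
          # pauses for more than 5 s and does not continue
          dur <- 5 + stats::rexp(1, rate_from_median(p$pause_dur_med))
          t1 <- min(t + dur, t_max)
          add_phase(t, t1, "PAUSED", mt, arc)
          t <- t1
          end_run("intersection_pause")
          if (t >= t_max - eps) censored <- TRUE else detach("intersection_pause")
        } else {
          end_run("intersection_dissociate")
          detach("intersection_dissociate")
        }
      } else if (d_next == d_pause) {
        dur <- rtrunc_exp(1, p$pause_rexp_rate, p$pause_dur_min, p$pause_dur_max)
        t1 <- min(t + dur, t_max)
        add_phase(t, t1, "PAUSED", mt, arc)
        pauses[[length(pauses) + 1]] <- data.frame(
          t0 = t, dur_drawn = dur, dur_realized = t1 - t)
        t <- t1
        if (t >= t_max - eps) { end_run("t_max"); censored <- TRUE; break }
        d_pause <- if (p$pause_rate > 0) stats::rexp(1, p$pause_rate) else Inf
      } else if (d_next == d_end) {
        if (dirsign > 0) {
          arc <- len
          end_run("plus_end", reached_end = TRUE)
          if (stats::runif(1) < p$p_detach_at_end) {
            detach("end_detach")
          } else {
            dwell <- p$end_dwell_min +
              stats::rexp(1, rate_from_median(p$end_dwell_med - p$end_dwell_min))
            t1 <- min(t + dwell, t_max)
            add_phase(t, t1, "END_DWELL", mt, arc)
            dwells[[length(dwells) + 1]] <- data.frame(
              t0 = t, dur_drawn = dwell, dur_realized = t1 - t)
            t <- t1
            if (t >= t_max - eps) { censored <- TRUE; break }
            mode <- "LINGER"
          }
        } else {
          arc <- 0
          end_run("minus_end", reached_end = TRUE)
          detach("minus_end_detach")
        }
      } else if (d_next == L_rem) {
        end_run("run_end")
        mode <- "LINGER"
      } else if (d_next == d_mode) {
        end_run("mode_switch")
        mode <- "EPISODE_DIFF"
      }
    } else if (mode == "LINGER") {
      # weakly bound diffusive state; detachment rate calibrated so that the
      # median of total residency equals residency_med
      W <- stats::rexp(1, linger_rate)
      t1 <- min(t + W, t_max)
      if (t1 > t + eps) {
        wk <- diffusive_walk(t, t1, arc, len)
        add_phase(t, t1, "DIFFUSIVE", mt, arc, walk = wk)
        arc <- wk$arc[length(wk$arc)]
      }
      t <- t1
      if (t >= t_max - eps) { censored <- TRUE; break }
      detach("linger_detach")
    } else if (mode == "EPISODE_DIFF") {
      # episodic interconversion: diffusive episode, then a fresh run
      dur <- stats::rexp(1, p$p_mode_switch)
      t1 <- min(t + dur, t_max)
      if (t1 > t + eps) {
        wk <- diffusive_walk(t, t1, arc, len)
        add_phase(t, t1, "DIFFUSIVE", mt, arc, walk = wk)
        arc <- wk$arc[length(wk$arc)]
      }
      t <- t1
      if (t >= t_max - eps) { censored <- TRUE; break }
      mode <- "RUN"
      new_run()
    }
  }
  if (mode != "DETACHED" && t >= t_max - eps) censored <- TRUE

  truth <- list(
    static = FALSE, direction = direction,
    runs = if (length(runs)) do.call(rbind, runs) else NULL,
    pauses = if (length(pauses)) do.call(rbind, pauses) else NULL,
    dwells = if (length(dwells)) do.call(rbind, dwells) else NULL,
    encounters = if (length(encounters)) do.call(rbind, encounters) else NULL,
    residency_s = if (censored) NA_real_ else t_detach,
    censored = censored, detach_reason = detach_reason)
  finish_trajectory(phases, truth, network, t_max, dt, seed, p,
                    censored, t_detach)
}

proc_state <- function(dirsign) {
  if (dirsign > 0) "PROCESSIVE_PLUS" else "PROCESSIVE_MINUS"
}

# Sample the phase list on the frame grid and assemble the trajectory object.
finish_trajectory <- function(phases, truth, network, t_max, dt, seed, params,
                              censored, t_detach) {
  t_end <- if (censored) t_max else t_detach
  if (length(phases) == 0) {
    points <- data.frame(t_s = numeric(), mt_id = integer(),
                         arc_pos_um = numeric(), x_um = numeric(),
                         y_um = numeric(), state = character(),
                         n_active_fluor = integer(), intensity_au = numeric())
    return(structure(list(points = points, dt = dt, t_max = t_max,
                          seed = seed, params_used = params, truth = truth,
                          censored = censored),
                     class = "trajectory"))
  }
  ft <- seq(0, t_end + 1e-12, by = dt)
  ft <- ft[ft <= t_end + 1e-9]
  starts <- vapply(phases, `[[`, numeric(1), "t0")
  idx <- findInterval(ft, starts)
  idx[idx < 1] <- 1
  n <- length(ft)
  mt_id <- integer(n); arc <- numeric(n); state <- character(n)
  for (i in seq_len(n)) {
    ph <- phases[[idx[i]]]
    mt_id[i] <- ph$mt
    state[i] <- ph$type
    arc[i] <- if (ph$type %in% c("PROCESSIVE_PLUS", "PROCESSIVE_MINUS")) {
      ph$arc0 + ph$v * (ft[i] - ph$t0)
    } else if (ph$type == "DIFFUSIVE") {
      j <- which(abs(ph$walk$t - ft[i]) < 1e-9)
      if (length(j)) ph$walk$arc[j[1]] else ph$arc0
    } else {
      ph$arc0
    }
  }
  arc <- pmin(pmax(arc, 0), network$mts$length_um[mt_id])
  xy <- arc_to_xy(network, mt_id, arc)
  points <- data.frame(t_s = ft, mt_id = mt_id, arc_pos_um = arc,
                       x_um = xy[, 1], y_um = xy[, 2], state = state,
                       n_active_fluor = NA_integer_, intensity_au = NA_real_)
  structure(list(points = points, dt = dt, t_max = t_max, seed = seed,
                 params_used = params, truth = truth, censored = censored),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Motor trajectory: %d frames at dt = %g s, %s, %s\n",
              nrow(x$points), x$dt,
              if (isTRUE(x$truth$static)) "static" else
                paste0(x$truth$direction, "-directed"),
              if (x$censored) "censored at window end" else
                sprintf("detached at %.1f s (%s)", x$truth$residency_s,
                        x$truth$detach_reason)))
  invisible(x)
}

#' Simulate an ensemble of motor trajectories
#'
#' Child seeds are derived from `seed` by a fixed affine rule
#' (`(1009 * seed + i) mod (2^31 - 1)`), so the ensemble is reproducible,
#' each member equals a direct [simulate_trajectory()] call with its derived
#' seed, and ensembles started from nearby seeds do not share child streams.
#'
#' @inheritParams simulate_trajectory
#' @param n number of trajectories.
#' @return A list of `trajectory` objects (class `trajectory_ensemble`).
#' @export
simulate_ensemble <- function(params, network, n, seed = 1L, t_max = 180,
                              dt = 0.5) {
  stopifnot(n >= 1)
  out <- lapply(seq_len(n), function(i) {
    simulate_trajectory(params, network, t_max = t_max, dt = dt,
                        seed = derive_seed(seed, i))
  })
  class(out) <- c("trajectory_ensemble", "list")
  out
}

#' Derive the i-th child seed from a base seed
#' @param seed base seed.
#' @param i child index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(i)) %% 2147483647)
}
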