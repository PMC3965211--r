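# End-to-end pipeline: simulate -> analyse -> fit for a chosen scenario,
# emitting a machine-readable report.

#' Run the full simulate/analyse/fit pipeline for a scenario
#'
#' Scenarios:
#' \describe{
#'   \item{default}{motility ensemble on a single long microtubule; reports
#'     the velocity / run-length / residency / pause / end-dwell medians,
#'     pause frequency and plus-end fraction.}
#'   \item{tpx2}{lattice-inhibited condition (70% static motors, bimodal
#'     velocities) against an internal control; reports the normalized motile
#'     fraction and the two mixture component medians.}
#'   \item{trap}{trap trace with detachment detection; reports event count,
#'     maximum and mean detected load, and the load RMS error versus truth.}
#'   \item{bleach}{photobleaching ensemble; reports the step-count histogram,
#'     modal count and inferred copy number.}
#'   \item{binding}{Poisson bead-binding series plus co-sedimentation;
#'     reports lambda, the preferred Poisson order and the fitted Kd.}
#' }
#'
#' @param config a `run_config` ([read_config()] / [as_run_config()]), or a
#'   plain list accepted by [as_run_config()].
#' @return list of class `pipeline_report`; written as `report.json` under
#'   `config$out_dir` when set, together with the scenario's tables.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  seed <- config$seed
  report <- list(scenario = config$scenario, seed = seed,
                 config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("kinetrax")))

  network <- if (!is.null(config$network)) {
    build_network(lapply(seq_len(nrow(config$network)), function(i) {
      list(c(config$network$minus_x_um[i], config$network$minus_y_um[i]),
           c(config$network$plus_x_um[i], config$network$plus_y_um[i]))
    }))
  } else {
    build_network(list(list(c(0, 0), c(60, 0))))
  }

  res <- switch(
    config$scenario,
    default = {
      ens <- simulate_ensemble(config$params, network, config$n_tracks,
                               seed = seed, t_max = config$t_max_s,
                               dt = config$dt_s)
      an <- analyze_tracks(ens, network, cfg = config$seg)
      sm <- motility_summary(an, seed = derive_seed(seed, 999))
      list(
        velocity_median_nm_s = sm$velocity$median,
        velocity_median_sem = sm$velocity$median_sem,
        run_length_median_um = sm$run_length$median,
        run_length_median_sem = sm$run_length$median_sem,
        residency_median_s = sm$residency$median,
        residency_median_sem = sm$residency$median_sem,
        pause_duration_median_s = sm$pause_duration$median,
        end_dwell_median_s = if (!is.null(sm$end_dwell)) sm$end_dwell$median
                             else NA_real_,
        pause_frequency_per_um = sm$pause_frequency$mean,
        pause_frequency_sd = sm$pause_frequency$sd,
        plus_fraction = sm$plus_fraction,
        n_tracks = config$n_tracks, n_runs = sm$n_runs,
        n_pauses = sm$n_pauses, n_directional = sm$n_directional)
    },
    tpx2 = {
      ctrl_params <- motility_params()
      cond <- simulate_ensemble(config$params, network, config$n_tracks,
                                seed = seed, t_max = config$t_max_s,
                                dt = config$dt_s)
      ctrl <- simulate_ensemble(ctrl_params, network, config$n_tracks,
                                seed = derive_seed(seed, 5000),
                                t_max = config$t_max_s, dt = config$dt_s)
      an_c <- analyze_tracks(cond, network, cfg = config$seg)
      an_0 <- analyze_tracks(ctrl, network, cfg = config$seg)
      len <- sum(network$mts$length_um)
      mf <- motile_fraction(an_c$metrics, len, an_0$metrics, len)
      vels <- unlist(lapply(an_c$segmented, function(s) {
        s$segments$velocity_nm_s[s$segments$state == "PROCESSIVE_PLUS"]
      }))
      mix <- fit_two_gaussian(vels, seed = derive_seed(seed, 999))
      list(motile_fraction = mf$motile_fraction,
           mixture_medians_nm_s = mix$params$component_medians,
           mixture_means_nm_s = mix$params$means,
           mixture_weights = mix$params$weights,
           n_velocities = mix$n)
    },
    trap = {
      tr <- simulate_trap_trace(config$trap, t_max = 60, seed = seed)
      ev <- detect_detachments(boxcar_filter(tr), config$trap)
      tru <- tr$truth[tr$truth$type == "processive", , drop = FALSE]
      err <- if (nrow(ev) && nrow(tru)) {
        vapply(seq_len(nrow(ev)), function(i) {
          ev$load_pN[i] - tru$load_pN[which.min(abs(tru$t_detach - ev$t_s[i]))]
        }, numeric(1))
      } else numeric()
      list(n_events = nrow(ev),
           max_load_pN = if (nrow(ev)) max(ev$load_pN) else NA_real_,
           mean_load_pN = if (nrow(ev)) mean(ev$load_pN) else NA_real_,
           load_rms_error_pN = if (length(err)) sqrt(mean(err^2)) else NA_real_,
           n_true_engagements = nrow(tru))
    },
    bleach = {
      n_traces <- min(config$n_tracks, 250L)
      fits <- lapply(seq_len(n_traces), function(i) {
        tt <- seq(0, 75, by = 0.25)
        pts <- simulate_intensity_trace(data.frame(t_s = tt), config$fluor,
                                        seed = derive_seed(seed, i))
        detect_steps(pts$intensity_au, t = pts$t_s)
      })
      sc <- summarize_step_counts(fits)
      list(step_histogram = as.list(sc$histogram),
           modal_count = sc$modal_count,
           inferred_copy_number = sc$inferred_copy_number,
           n_traces = n_traces)
    },
    binding = {
      concs <- c(0.25, 0.5, 1, 2, 4, 8)
      series <- simulate_bead_binding(0.4, concs, n_beads = 200, seed = seed)
      pf <- fit_poisson_binding(series)
      cos <- simulate_cosed(490, bmax = 1, seed = derive_seed(seed, 17))
      kd <- fit_kd(cos)
      list(lambda_per_conc = unname(pf$lam_per_conc[pf$preferred_order]),
           preferred_order = pf$preferred_order,
           kd_nM = kd$kd_nM, kd_se_nM = kd$kd_se_nM, bmax = kd$bmax)
    })

  report$results <- res
  report <- structure(report, class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(unclass(report),
                  file.path(config$out_dir, "report.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: scenario '%s', seed %d\n", x$scenario, x$seed))
  utils::str(x$results, give.attr = FALSE)
  invisible(x)
}

# md5 of the canonical JSON serialisation of the raw configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  raw <- config$raw %||% list()
  raw <- raw[setdiff(names(raw), c("out_dir", "log_level"))]
  ord <- raw[order(names(raw))]
  jsonlite::write_json(ord, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
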