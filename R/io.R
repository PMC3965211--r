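# File I/O: trajectory tables, networks, kymographs (16-bit TIFF + JSON
# sidecar), result JSON, and the run configuration.
#
# CSV dialect: comma-separated, '.' decimal, UTF-8, header mandatory.
# Numeric fields are written with 17 significant digits so a write/read
# round trip is exact.

TRACK_COLUMNS <- c("t_s", "traj_id", "mt_id", "arc_pos_um", "x_um", "y_um",
                   "state", "intensity_au")

write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write trajectories to a CSV track table
#'
#' @param trajs a `trajectory`, a list of them, or a points data frame
#'   already containing a `traj_id` column.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  df <- if (is.data.frame(trajs)) trajs else {
    do.call(rbind, lapply(seq_along(trajs), function(i) {
      p <- if (inherits(trajs[[i]], "trajectory")) trajs[[i]]$points
           else as.data.frame(trajs[[i]])
      cbind(traj_id = i, p)
    }))
  }
  df <- df[, TRACK_COLUMNS]
  write_csv_full(df, path)
  invisible(path)
}

#' Read a track table CSV
#'
#' @param path CSV with columns `t_s, traj_id, mt_id, arc_pos_um, x_um, y_um,
#'   state, intensity_au` (intensity may be missing).
#' @return list of per-trajectory data frames, named by `traj_id`.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(TRACK_COLUMNS, "intensity_au")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("track table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (is.null(df$intensity_au)) df$intensity_au <- NA_real_
  split_df <- split(df, df$traj_id)
  for (tr in split_df) {
    if (is.unsorted(tr$t_s, strictly = TRUE)) {
      stop("data error: non-monotone time in trajectory ", tr$traj_id[1])
    }
  }
  split_df
}

#' Write / read a microtubule network CSV
#'
#' Columns: `mt_id, minus_x_um, minus_y_um, plus_x_um, plus_y_um`.
#'
#' @param network an `mt_network`.
#' @param path CSV path.
#' @return `write_network`: the path, invisibly; `read_network`: an
#'   `mt_network` (intersections recomputed from the geometry).
#' @export
write_network <- function(network, path) {
  write_csv_full(network$mts[, c("mt_id", "minus_x_um", "minus_y_um",
                                 "plus_x_um", "plus_y_um")], path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- utils::read.csv(path)
  need <- c("mt_id", "minus_x_um", "minus_y_um", "plus_x_um", "plus_y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("network schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df <- df[order(df$mt_id), ]
  build_network(lapply(seq_len(nrow(df)), function(i) {
    list(c(df$minus_x_um[i], df$minus_y_um[i]),
         c(df$plus_x_um[i], df$plus_y_um[i]))
  }))
}

#' Write / read a kymograph as 16-bit grayscale TIFF with a JSON sidecar
#'
#' Intensities are clipped to `[0, 65535]` and rounded; pixel size and frame
#' interval go into `<path>.json`.
#'
#' @param kymo a `kymograph`.
#' @param path TIFF path.
#' @return `write_kymograph`: the path, invisibly; `read_kymograph`: a
#'   `kymograph` with integer intensities.
#' @export
write_kymograph <- function(kymo, path) {
  img <- round(pmin(pmax(kymo$image, 0), 65535))
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_nm = kymo$pixel_size_nm,
                            frame_interval_s = kymo$frame_interval_s,
                            mt_id = kymo$mt_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(image = img, pixel_size_nm = meta$pixel_size_nm,
                 frame_interval_s = meta$frame_interval_s,
                 mt_id = meta$mt_id),
            class = "kymograph")
}

#' Write an analysis result list as JSON
#'
#' @param x list of results (numbers, vectors, nested lists).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

CONFIG_KEYS <- list(
  top = c("seed", "scenario", "n_tracks", "t_max_s", "dt_s", "out_dir",
          "log_level", "params", "fluor", "trap", "seg", "network"),
  params = c("v_plus_med", "v_sd", "v_max", "v_min", "v_minus_med",
             "run_len_med_plus", "run_len_med_minus", "residency_med",
             "pause_rate", "pause_dur_med", "pause_dur_max", "pause_dur_min",
             "end_dwell_med", "p_detach_at_end", "p_plus", "D_diff",
             "p_mode_switch", "intersection_probs", "p_static", "v_mixture",
             "capture_radius_nm"),
  fluor = c("n_fluor", "bleach_rate", "unit_intensity", "noise_sd",
            "p_prebleached"),
  trap = c("stiffness", "step_size", "stepping_rate", "detach_load_low",
           "detach_load_high", "sample_rate", "noise_sd", "rebind",
           "rebind_wait_mean", "p_diffusive", "tpx2_static"),
  seg = c("window", "v_pause_thresh", "min_pause_dur", "min_proc_dur",
          "msd_alpha_proc", "max_resid_nm", "end_radius"))

#' Read and validate a JSON run configuration
#'
#' The configuration mirrors the parameter containers field by field
#' (`params` -> [motility_params()], `fluor` -> [fluor_model()], `trap` ->
#' [trap_params()], `seg` -> [seg_config()]); unknown keys anywhere are
#' rejected.
#'
#' @param path JSON file.
#' @return list of class `run_config` with `seed`, `scenario` and the
#'   constructed parameter objects.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_run_config(cfg)
}

#' Validate a configuration list (see [read_config()])
#' @param cfg named list.
#' @return list of class `run_config`.
#' @export
as_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), CONFIG_KEYS$top)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in c("params", "fluor", "trap", "seg")) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), CONFIG_KEYS[[blk]])
      if (length(bad)) {
        stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
      }
    }
  }
  scenario <- cfg$scenario %||% "default"
  if (!scenario %in% c("default", "tpx2", "trap", "bleach", "binding")) {
    stop("unknown scenario: ", scenario)
  }
  pargs <- as.list(cfg$params %||% list())
  if (scenario == "tpx2") {
    if (is.null(pargs$p_static)) pargs$p_static <- 0.7
    if (is.null(pargs$v_mixture)) {
      pargs$v_mixture <- list(weight = 0.6, slow_med = 42.1, fast_med = 114.9)
    }
  }
  structure(list(
    seed = as.integer(cfg$seed %||% 1L),
    scenario = scenario,
    n_tracks = cfg$n_tracks %||% 500L,
    t_max_s = cfg$t_max_s %||% 180,
    dt_s = cfg$dt_s %||% 0.5,
    out_dir = cfg$out_dir,
    log_level = cfg$log_level %||% "info",
    params = do.call(motility_params, pargs),
    fluor = do.call(fluor_model, as.list(cfg$fluor %||% list())),
    trap = do.call(trap_params, as.list(cfg$trap %||% list())),
    seg = do.call(seg_config, as.list(cfg$seg %||% list())),
    network = cfg$network,
    raw = cfg), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
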