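# Disk formats: multi-page 16-bit TIFF kymograph + JSON sidecar, CSV series,
# TSV ground truth and tracks, YAML run configuration.

TIFF_SCALE <- 65535

#' Write a simulated trace bundle to a directory
#'
#' Writes `kymo.tif` (one page per channel, 16-bit, counts scaled by the
#' sidecar's `intensity_scale`), `kymo.json` (pixel size, line time, channel
#' names, force schedule, seed, scale), `series.csv`
#' (`time_s,force_pN,length_um`), `truth.tsv`, and `config.yaml` (the
#' resolved generation parameters and package version).
#'
#' @param trace an [simulate_trace()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace_bundle <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- trace$kymo$channels
  mx <- max(vapply(chans, max, numeric(1)), 1)
  if (mx >= TIFF_SCALE) {
    abort("intensities exceed the 16-bit TIFF range")
  }
  pages <- lapply(chans, function(m) round(m) / TIFF_SCALE)
  tiff::writeTIFF(pages, file.path(dir, "kymo.tif"), bits.per.sample = 16)
  sidecar <- list(pixel_size_um = trace$kymo$pixel_size_um,
                  line_time_s = trace$kymo$line_time_s,
                  channels = names(chans),
                  intensity_scale = TIFF_SCALE,
                  force_schedule = as.list(trace$schedule),
                  seed = trace$seed,
                  offset_um = trace$offset_um)
  jsonlite::write_json(sidecar, file.path(dir, "kymo.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(trace$series, file.path(dir, "series.csv"))
  readr::write_tsv(trace$truth, file.path(dir, "truth.tsv"))
  cfg <- list(
    package_version = as.character(utils::packageVersion("unwindr")),
    template = unclass(trace$template),
    condition = unclass(trace$condition),
    imaging = unclass(trace$imaging),
    uni_direction = trace$uni_direction,
    seed = trace$seed)
  cfg$condition$initiation_force <-
    as.list(stats::setNames(as.numeric(trace$condition$initiation_force),
                            names(trace$condition$initiation_force)))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a trace bundle from disk
#'
#' @param dir directory written by [write_trace_bundle()].
#' @return a list with `kymo`, `series`, `truth`, `schedule`, `seed`,
#'   `offset_um`, usable by [analyze_trace()].
#' @export
read_trace_bundle <- function(dir) {
  sidecar_path <- file.path(dir, "kymo.json")
  if (!file.exists(sidecar_path)) {
    abort(sprintf("not a trace bundle: missing sidecar %s", sidecar_path))
  }
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tryCatch(tiff::readTIFF(file.path(dir, "kymo.tif"), all = TRUE),
                    error = function(e) {
                      abort(paste0("unreadable kymograph TIFF: ",
                                   conditionMessage(e)))
                    })
  scale <- sidecar$intensity_scale %||% TIFF_SCALE
  chans <- lapply(pages, function(p) round(p * scale))
  names(chans) <- sidecar$channels
  series <- readr::read_csv(file.path(dir, "series.csv"),
                            show_col_types = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE)
  } else NULL
  list(kymo = kymograph(chans, sidecar$pixel_size_um, sidecar$line_time_s),
       series = series, truth = truth,
       schedule = as_tibble(sidecar$force_schedule),
       seed = sidecar$seed, offset_um = sidecar$offset_um)
}

#' Read or write force-extension points
#'
#' CSV with header `force_pN,extension_nm`.
#'
#' @param path file path.
#' @return a tibble (`read_force_extension`).
#' @export
read_force_extension <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("force_pN", "extension_nm") %in% names(d))) {
    abort("expected columns force_pN, extension_nm")
  }
  d
}

#' @rdname read_force_extension
#' @param data a data frame with `force_pN`, `extension_nm`.
#' @export
write_force_extension <- function(data, path) {
  readr::write_csv(data[, c("force_pN", "extension_nm")], path)
  invisible(path)
}

# allowed run-config keys, per section
.config_schema <- list(
  template = c("preset", "total_bp", "nick_positions", "label"),
  condition = c("preset", "velocity_uni_mean", "velocity_uni_sd",
                "velocity_bi_mean", "velocity_bi_sd", "p_bidirectional",
                "initiation_force", "events_per_molecule_mean",
                "rewind_rate_bps", "p_continue", "spot_channel", "label"),
  imaging = c("pixel_size_um", "line_time_s", "psf_sigma_um", "dsdna_counts",
              "background_counts", "spot_counts_per_knt", "duration_s",
              "noise", "length_noise_um", "bead_margin_px"),
  protocol = c("force_pN", "duration_s"),
  analysis = c("threshold", "threshold_frac", "bead_margin_px",
               "motion_threshold_px", "r2_min", "min_frac", "min_lines",
               "min_width_px", "max_gap_lines", "max_jump_px", "min_snr"),
  run = c("seed", "out_dir", "uni_direction"))

#' Read a run configuration
#'
#' Flat YAML with sections `template`, `condition`, `imaging`, `protocol`,
#' `analysis`, `run`. Unknown sections or keys are rejected so typos cannot
#' silently change an analysis. The configuration round-trips losslessly
#' through [write_run_config()].
#'
#' @param path YAML file path.
#' @return a named list of sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  extra <- setdiff(names(cfg), names(.config_schema))
  if (length(extra)) {
    abort(paste0("unknown config section(s): ", paste(extra, collapse = ", ")))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad)) {
      abort(paste0("unknown key(s) in [", sec, "]: ",
                   paste(bad, collapse = ", ")))
    }
  }
  cfg
}

#' @rdname read_run_config
#' @param config a config list as returned by [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# build simulate_trace() arguments from a run config
config_to_args <- function(cfg) {
  template <- if (!is.null(cfg$template$preset)) {
    template_preset(cfg$template$preset)
  } else {
    template_spec(cfg$template$total_bp,
                  cfg$template$nick_positions %||% integer(0),
                  cfg$template$label %||% "custom")
  }
  condition <- if (!is.null(cfg$condition$preset)) {
    sim_condition_preset(cfg$condition$preset)
  } else {
    cnd <- cfg$condition
    cnd$initiation_force <- unlist(cnd$initiation_force)
    do.call(sim_condition, cnd)
  }
  imaging <- do.call(imaging_params, cfg$imaging %||% list())
  schedule <- if (!is.null(cfg$protocol)) {
    force_schedule(unlist(cfg$protocol$force_pN),
                   unlist(cfg$protocol$duration_s))
  } else force_schedule(30, imaging$duration_s)
  list(template = template, condition = condition, imaging = imaging,
       schedule = schedule, seed = cfg$run$seed %||% 1L,
       uni_direction = cfg$run$uni_direction %||% "random")
}
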