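# Plain-text interchange: voxel x time CSV for series, CSV for designs
# and gain tables, YAML for scenario configs, JSON for psychometric fits.

#' Write / read a laminar series as CSV
#'
#' Portable voxel x time table: one row per voxel, one column per frame
#' (named `f<index>`), preceded by a `region` column; frame timing and
#' labels go to a JSON sidecar (`<path>.meta.json`).
#'
#' @param series A [laminar_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "laminar_series"))
  df <- data.frame(region = series$voxel_region %||%
                     rep(NA_character_, nrow(series$data)),
                   series$data)
  names(df)[-1] <- paste0("f", seq_len(ncol(series$data)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(frame_times = series$frame_times,
                            frame_labels = series$frame_labels,
                            run = series$run, meta = series$meta),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  laminar_series(as.matrix(df[, -1, drop = FALSE]),
                 frame_times = meta$frame_times,
                 frame_labels = meta$frame_labels,
                 run = meta$run, voxel_region = df$region,
                 meta = as.list(meta$meta))
}

#' Write / read a block design as CSV
#'
#' @param design A [block_design()].
#' @param path CSV path; timing attributes go to `<path>.meta.json`.
#' @return `path` / a `block_design`.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  jsonlite::write_json(list(paired_tr = attr(design, "paired_tr"),
                            n_pairs = attr(design, "n_pairs"),
                            conditions = attr(design, "conditions")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(condition = "character"))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(df, paired_tr = meta$paired_tr,
            frame_dt = meta$paired_tr / 2,
            n_pairs = meta$n_pairs,
            run_length = meta$n_pairs * meta$paired_tr,
            conditions = meta$conditions,
            class = c("block_design", "data.frame"))
}

#' Scenario specification to / from YAML
#'
#' @param scenario A [scenario_spec()].
#' @param path YAML path.
#' @return `path` / a `scenario_spec`.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_spec"))
  obj <- list(name = scenario$name,
              gains = lapply(stats::setNames(REGIONS, REGIONS), function(rg) {
                lapply(stats::setNames(THETAS, paste0("theta", THETAS)),
                       function(th) as.list(stats::setNames(
                         scenario$gains[rg, , th], LAYERS)))
              }),
              noise_sd = scenario$noise_sd,
              drift_amp = scenario$drift_amp,
              bold_scale = scenario$bold_scale,
              bold_bias = scenario$bold_bias, seed = scenario$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  gains <- array(NA_real_, c(3, 3, 3),
                 dimnames = list(REGIONS, LAYERS, THETAS))
  for (rg in REGIONS) {
    for (th in THETAS) {
      gains[rg, , th] <- unlist(obj$gains[[rg]][[paste0("theta", th)]])[LAYERS]
    }
  }
  scenario_spec(obj$name, gains = gains, noise_sd = obj$noise_sd,
                drift_amp = obj$drift_amp, bold_scale = obj$bold_scale,
                bold_bias = obj$bold_bias, seed = obj$seed)
}

#' Write a psychometric fit as JSON
#'
#' @param fit A [fit_weibull()] result.
#' @param path JSON path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "weibull_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a laminar series as a 4D NIfTI volume
#'
#' Arranges the column-model voxel grid into an image plane and writes an
#' x-by-y-by-1-by-time NIfTI file (requires the optional RNifti package).
#'
#' @param series A [laminar_series()].
#' @param model The matching [build_column_model()].
#' @param path Output `.nii` path.
#' @export
write_series_nifti <- function(series, model, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_series_nifti requires the RNifti package")
  }
  v <- model$voxels
  h <- model$geometry$voxel_size
  ix <- as.integer(round((v$x - min(v$x)) / h)) + 1L
  iy <- as.integer(round((v$y - min(v$y)) / h)) + 1L
  # region planes stacked along x to keep a single 2D slice
  offs <- (match(v$region, unique(v$region)) - 1L) * (max(ix) + 2L)
  ix <- ix + offs
  arr <- array(0, c(max(ix), max(iy), 1L, ncol(series$data)))
  for (t in seq_len(ncol(series$data))) {
    arr[cbind(ix, iy, 1L, t)] <- series$data[, t]
  }
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(h, h, h,
                                                     diff(series$frame_times)[1])),
                     path)
  invisible(path)
}
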