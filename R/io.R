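#' Write an image series as 4D NIfTI with a JSON sidecar
#'
#' The in-memory axis order is `(t, y, x)`; on disk the conventional NIfTI
#' `(x, y, z = 1, t)` order is used. Pixel spacing (mm) and the frame
#' interval (s) are stored in the NIfTI pixdim; exact frame times and the
#' reconstruction provenance go to a `.json` sidecar next to the image.
#'
#' @param series an [image_series()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  nt <- dim(series$frames)[1]
  arr <- aperm(series$frames, c(3, 2, 1))          # (x, y, t)
  dim(arr) <- c(dim(arr)[1], dim(arr)[2], 1L, nt)  # (x, y, z, t)
  dt <- if (nt > 1) series$frame_times_s[2] - series$frame_times_s[1] else 1
  img <- RNifti::asNifti(arr, pixdim = c(series$pixel_mm, series$pixel_mm,
                                         1, dt))
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(pixel_mm = series$pixel_mm,
                            frame_times_s = series$frame_times_s,
                            provenance = series$provenance),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image series written by [write_image_series()]
#'
#' @param path NIfTI file path; the JSON sidecar is read when present,
#'   otherwise frame times are rebuilt from the pixdim time step.
#' @return an [image_series()].
#' @export
read_image_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI image: ", path)
  arr <- aperm(array(as.numeric(img), dim = d)[, , 1, , drop = FALSE],
               c(4, 2, 1, 3))
  dim(arr) <- dim(arr)[1:3]
  pd <- attr(img, "pixdim")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    image_series(arr, meta$pixel_mm, meta$frame_times_s,
                 as.list(meta$provenance))
  } else {
    image_series(arr, pd[1], (seq_len(d[4]) - 0.5) * pd[4])
  }
}

# phantom_config <-> plain list (YAML-serialisable)
config_to_list <- function(config) {
  list(matrix = config$matrix, pixel_mm = config$pixel_mm,
       n_frames = config$n_frames, frame_dt_s = config$frame_dt_s,
       noise_sigma = config$noise_sigma,
       edge_blur_sigma_mm = config$edge_blur_sigma_mm,
       seed = config$seed,
       motion = list(amplitude_mm = config$motion$amplitude_mm,
                     period_s = config$motion$period_s,
                     phase_rad = config$motion$phase_rad),
       vessels = lapply(config$vessels, function(v)
         list(label = v$label, center_mm = v$center_mm,
              radius_mm = v$radius_mm,
              baseline_intensity = v$baseline_intensity,
              peak_enhancement = v$peak_enhancement,
              bolus = list(t0_s = v$bolus$t0_s, alpha = v$bolus$alpha,
                           tp_s = v$bolus$tp_s,
                           recirculation_fraction =
                             v$bolus$recirculation_fraction))))
}

config_from_list <- function(x) {
  vessels <- lapply(x$vessels, function(v)
    vessel_spec(v$label, unlist(v$center_mm), v$radius_mm,
                v$baseline_intensity, v$peak_enhancement,
                bolus_params(v$bolus$t0_s, v$bolus$alpha, v$bolus$tp_s,
                             v$bolus$recirculation_fraction)))
  phantom_config(matrix = unlist(x$matrix), pixel_mm = x$pixel_mm,
                 n_frames = x$n_frames, frame_dt_s = x$frame_dt_s,
                 vessels = vessels,
                 motion = motion_params(unlist(x$motion$amplitude_mm),
                                        x$motion$period_s,
                                        x$motion$phase_rad),
                 noise_sigma = x$noise_sigma,
                 edge_blur_sigma_mm = x$edge_blur_sigma_mm, seed = x$seed)
}

#' Write a phantom configuration as YAML
#' @param config a [phantom_config()].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(inherits(config, "phantom_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Read a phantom configuration from YAML
#' @param path `.yaml` path written by [write_phantom_config()].
#' @return a [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  config_from_list(yaml::read_yaml(path))
}

#' Write a phantom (movie, ground truth, configuration) to disk
#'
#' Writes `<prefix>.nii` (4D movie with mm/s pixdim),
#' `<prefix>_truth.json` (per-vessel ground truth) and
#' `<prefix>_config.yaml`.
#'
#' @param phantom a [generate_phantom()] result.
#' @param prefix output path prefix.
#' @return the three file paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  ser <- image_series(phantom$movie, phantom$config$pixel_mm,
                      phantom$frame_times_s + phantom$config$frame_dt_s / 2,
                      provenance = list(scheme = "phantom"))
  nii <- paste0(prefix, ".nii")
  write_image_series(ser, nii)
  truth <- paste0(prefix, "_truth.json")
  jsonlite::write_json(phantom$ground_truth, truth, auto_unbox = TRUE,
                       digits = NA)
  cfg <- paste0(prefix, "_config.yaml")
  write_phantom_config(phantom$config, cfg)
  invisible(c(movie = nii, truth = truth, config = cfg))
}

#' Write ROI and profile definitions as JSON
#' @param rois named list of [roi_spec()].
#' @param profiles named list of profile definitions
#'   (`from_px`, `to_px`), same names as `rois`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_roi_definitions <- function(rois, profiles, path) {
  stopifnot(identical(names(rois), names(profiles)))
  x <- lapply(names(rois), function(nm) {
    e <- list(name = nm, center_px = rois[[nm]]$center_px,
              radius_px = rois[[nm]]$radius_px,
              profile_from_px = profiles[[nm]]$from_px,
              profile_to_px = profiles[[nm]]$to_px)
    if (!is.null(profiles[[nm]]$wall_mm))
      e$profile_wall_mm <- profiles[[nm]]$wall_mm
    e
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROI and profile definitions from JSON
#' @param path `.json` path written by [write_roi_definitions()].
#' @return list with `rois` and `profiles` named lists.
#' @export
read_roi_definitions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  rois <- list(); profiles <- list()
  for (e in x) {
    rois[[e$name]] <- roi_spec(unlist(e$center_px), e$radius_px)
    profiles[[e$name]] <- list(from_px = unlist(e$profile_from_px),
                               to_px = unlist(e$profile_to_px))
    if (!is.null(e$profile_wall_mm))
      profiles[[e$name]]$wall_mm <- e$profile_wall_mm
  }
  list(rois = rois, profiles = profiles)
}

#' Write a metrics report as CSV and JSON
#' @param report a [compute_metrics()] report.
#' @param prefix output path prefix (writes `<prefix>.csv` and
#'   `<prefix>.json`).
#' @return the two paths, invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  csv <- paste0(prefix, ".csv"); jsn <- paste0(prefix, ".json")
  utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(report), jsn, digits = NA)
  invisible(c(csv = csv, json = jsn))
}

#' Read a metrics report CSV
#' @param path `.csv` path written by [write_metrics_report()].
#' @return a `metrics_report` data frame.
#' @export
read_metrics_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Build a rating table from long-format reader scores
#'
#' Expects one row per (subject, reader) with an ordinal score; typically
#' read from a CSV with columns `subject`, `reader`, `score` (plus
#' optional `sequence`/`item` columns the caller filters on beforehand).
#'
#' @param scores data frame, or path to a CSV file.
#' @param levels score levels defining the table columns (default the
#'   4-point Likert levels 1:4).
#' @return a [rating_table()].
#' @export
rating_table_from_scores <- function(scores, levels = 1:4) {
  if (is.character(scores)) {
    if (!file.exists(scores)) stop("no such file: ", scores)
    scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  }
  if (!all(c("subject", "score") %in% names(scores)))
    stop("scores need 'subject' and 'score' columns")
  if (!all(scores$score %in% levels))
    stop("scores outside the given levels")
  tab <- table(factor(scores$subject),
               factor(scores$score, levels = levels))
  rating_table(unclass(as.matrix(tab)))
}
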