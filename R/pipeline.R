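#' Measure every frond image in a directory or file list
#'
#' Runs the full image-to-measurements chain (segmentation, cleaning, contour
#' tracing, resampling, symmetry and size measures) on each image. Images
#' that fail extraction are kept as rows flagged `excluded` with `NA`
#' measures, so downstream exclusion analyses see them; the run continues
#' past unreadable files.
#'
#' @param images Character vector of image paths, or a single directory (all
#'   `.png`/`.tif`/`.tiff` files inside are used).
#' @param metadata Optional data frame joined by `frond_id` (file name without
#'   extension); typically carries `parent_id`, `parental_age_days`, `shelf`.
#' @param n_points Number of outline reference points (even, default 200).
#' @param calibration mm per pixel (default 1: pixel units).
#' @return Tibble with one row per image: `frond_id`, the measure columns of
#'   [measure_outline()], `area_px` (diagnostic pixel-count area),
#'   `otsu_threshold`, `n_components_removed`, `n_holes_filled`, `excluded`,
#'   `note`.
#' @export
measure_fronds <- function(images, metadata = NULL, n_points = 200L,
                           calibration = 1) {
  if (length(images) == 1L && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)
  }
  if (!length(images)) stop("no input images found")
  rows <- purrr::map(images, function(path) {
    id <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      img <- read_frond_image(path)
      mask <- extract_mask(img)
      cleaned <- clean_mask(mask)
      tr <- trace_boundary(cleaned)
      if (isTRUE(attr(tr, "degenerate"))) stop("mask reduced to a single pixel")
      outline <- resample_outline(tr, n_points = n_points)
      m <- measure_outline(outline, calibration = calibration)
      dplyr::mutate(m,
        frond_id = id, .before = 1,
        area_px = sum(cleaned),
        otsu_threshold = attr(mask, "threshold"),
        n_components_removed = attr(cleaned, "n_removed"),
        n_holes_filled = attr(cleaned, "n_filled"),
        excluded = FALSE, note = NA_character_)
    }, error = function(e) {
      tibble::tibble(frond_id = id, area_mm2 = NA_real_, perimeter_mm = NA_real_,
                     circularity = NA_real_, csm = NA_real_,
                     csm_forced = NA_real_, axis_angle = NA_real_,
                     self_intersecting = NA, area_px = NA_real_,
                     otsu_threshold = NA_real_,
                     n_components_removed = NA_real_, n_holes_filled = NA_real_,
                     excluded = TRUE, note = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(metadata)) {
    out <- dplyr::left_join(out, tibble::as_tibble(metadata), by = "frond_id")
  }
  out
}

#' Run configuration for the command-line pipeline
#'
#' Assembles (and validates) the key-value configuration used by
#' [run_measure()] and [run_analysis()]. A YAML config file can override the
#' defaults; explicit arguments override the file.
#'
#' @param input Input directory of images, or a cohort/measurements CSV.
#' @param out_dir Output directory.
#' @param metadata Optional metadata CSV path.
#' @param n_points Outline reference points (even, >= 4).
#' @param calibration mm per pixel (> 0).
#' @param seed Integer seed for any stochastic stage.
#' @param config_file Optional YAML file with any of the above keys.
#' @return Named list of validated settings.
#' @export
run_config <- function(input = NULL, out_dir = "frondsym_out", metadata = NULL,
                       n_points = 200L, calibration = 1, seed = 1L,
                       config_file = NULL) {
  cfg <- list(input = input, out_dir = out_dir, metadata = metadata,
              n_points = n_points, calibration = calibration, seed = seed)
  if (!is.null(config_file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the 'yaml' package")
    }
    file_cfg <- yaml::read_yaml(config_file)
    explicit <- names(match.call())[-1]   # flags passed by the caller win
    for (k in setdiff(intersect(names(file_cfg), names(cfg)), explicit)) {
      cfg[[k]] <- file_cfg[[k]]
    }
    for (k in setdiff(names(file_cfg), names(cfg))) {
      warning("ignoring unknown config key: ", k)
    }
  }
  stopifnot(cfg$n_points >= 4L, cfg$n_points %% 2L == 0L, cfg$calibration > 0)
  cfg
}

manifest_entry <- function(path) {
  list(file = basename(path), md5 = unname(tools::md5sum(path)))
}

write_manifest <- function(out_dir, cfg, files, stage) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("frondsym")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    outputs = lapply(files, manifest_entry))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the measurement stage of the pipeline
#'
#' Measures all images under `config$input` (joined to `config$metadata` if
#' given), writes `measurements.csv` and a JSON manifest to
#' `config$out_dir`.
#'
#' @param config A list from [run_config()].
#' @return Path of the measurements CSV, invisibly.
#' @export
run_measure <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- if (!is.null(config$metadata)) {
    utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  }
  m <- measure_fronds(config$input, metadata = meta,
                      n_points = config$n_points,
                      calibration = config$calibration)
  csv <- file.path(config$out_dir, "measurements.csv")
  utils::write.csv(m, csv, row.names = FALSE)
  write_manifest(config$out_dir, config, list(csv), "measure")
  invisible(csv)
}

#' Run the statistical stage of the pipeline
#'
#' Reads a cohort CSV (`config$input`; schema of [simulate_cohort()] or the
#' output of [run_measure()] joined to metadata), runs [analyze_cohort()],
#' and writes per-response model tables, prediction-curve CSVs, residual
#' diagnostics (PNG) and a manifest to `config$out_dir`.
#'
#' @param config A list from [run_config()].
#' @param responses Measurement columns to analyze (defaults to those present
#'   among the five standard measures).
#' @return The `cohort_analysis` object, invisibly.
#' @export
run_analysis <- function(config,
                         responses = c("area_mm2", "perimeter_mm",
                                       "circularity", "csm", "csm_forced")) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- utils::read.csv(config$input, stringsAsFactors = FALSE)
  need <- c("parent_id", "parental_age_days", "shelf")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("cohort CSV is missing column(s): ",
                         paste(miss, collapse = ", "))
  responses <- intersect(responses, names(data))
  if (!length(responses)) stop("cohort CSV contains none of the measure columns")
  fit <- analyze_cohort(data, responses = responses)
  files <- list()
  for (r in fit$responses) {
    tpath <- file.path(config$out_dir, paste0("model_table_", r$response, ".csv"))
    utils::write.csv(tibble::as_tibble(r$model_table), tpath, row.names = FALSE)
    cpath <- file.path(config$out_dir, paste0("curve_", r$response, ".csv"))
    utils::write.csv(r$curve, cpath, row.names = FALSE)
    residual_diagnostics(r$best_fit, dir = config$out_dir,
                         prefix = paste0("diag_", r$response))
    files <- c(files, tpath, cpath)
  }
  if (!is.null(fit$exclusion)) {
    epath <- file.path(config$out_dir, "model_table_exclusion.csv")
    utils::write.csv(fit$exclusion$table, epath, row.names = FALSE)
    ecurve <- file.path(config$out_dir, "curve_exclusion.csv")
    utils::write.csv(fit$exclusion$curve, ecurve, row.names = FALSE)
    files <- c(files, epath, ecurve)
  }
  write_manifest(config$out_dir, config, files, "analyze")
  invisible(fit)
}
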