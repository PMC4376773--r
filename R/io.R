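#' Load a grayscale image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG and maps intensities to
#' [0, 1] by bit depth. Multi-channel images with identical channels are
#' collapsed; genuinely multi-channel input is an error.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return intensity matrix in [0, 1].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop2(sprintf("file not found: %s", path), "scmseg_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
                         tif = , tiff = tiff::readTIFF(path),
                         png = png::readPNG(path),
                         stop2(sprintf("unsupported format: .%s", ext),
                               "scmseg_format_error")),
                  error = function(e) {
                    if (inherits(e, "scmseg_error")) stop(e)
                    stop2(sprintf("cannot read '%s': %s", path,
                                  conditionMessage(e)), "scmseg_io_error")
                  })
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    flat <- matrix(img, ncol = ch)
    if (any(apply(flat, 1, function(v) diff(range(v)) > 0)))
      stop2("multi-channel image is not supported", "scmseg_format_error")
    img <- img[, , 1L]
  }
  as_intensity_matrix(img)
}

#' Write a grayscale frame as 16-bit TIFF
#' @param image intensity matrix in [0, 1].
#' @param path output path.
#' @export
write_frame <- function(image, path) {
  tiff::writeTIFF(clip01(image), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write a 16-bit label mask TIFF
#'
#' Labels are stored as raw 16-bit sample values (0 = background) and
#' round-trip exactly for label counts up to 65535.
#'
#' @param mask integer label mask.
#' @param path file path.
#' @return `load_mask`: integer matrix.
#' @export
write_mask <- function(mask, path) {
  storage.mode(mask) <- "integer"
  if (max(mask) > 65535L)
    stop2("more than 65535 labels cannot be stored in 16 bits",
          "scmseg_io_error")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
load_mask <- function(path) {
  if (!file.exists(path))
    stop2(sprintf("file not found: %s", path), "scmseg_io_error")
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

#' Write the boolean active-FOV mask as TIFF
#' @param fov an `active_fov`.
#' @param path output path.
#' @export
write_fov <- function(fov, path) {
  tiff::writeTIFF(fov$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

report_row <- function(report) {
  vals <- unclass(report)
  vals <- vals[!vapply(vals, is.list, TRUE)]
  as.data.frame(lapply(vals, function(v)
    if (is.numeric(v)) round(v, 4L) else v))
}

#' Write evaluation / morphometrics reports
#'
#' Writes one report (or a list of reports, one row per image) as CSV with
#' a fixed column order, or as JSON. Floats are written at 4 decimals.
#'
#' @param report a report object or list of same-class reports.
#' @param path output path.
#' @param format "csv" or "json" (default from the file extension).
#' @export
write_report <- function(report, path,
                         format = tolower(tools::file_ext(path))) {
  reports <- if (inherits(report, c("evaluation_report",
                                    "morphometrics_report")))
    list(report) else report
  rows <- if (length(reports)) {
    do.call(rbind, lapply(reports, report_row))
  } else {
    # empty batch: header-only output with the evaluation-report columns
    proto <- c("object_tp", "object_fn", "object_fp", "pixel_tp",
               "pixel_fp", "pixel_fn", "pixel_tn", "object_sensitivity",
               "pixel_sensitivity", "pixel_specificity", "f_measure")
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(proto)),
                                  proto))
  }
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop2(sprintf("unsupported report format '%s'", format),
          "scmseg_format_error")
  }
  invisible(path)
}

#' Read / write a run configuration
#'
#' A run configuration bundles every tunable of the pipeline (SCM
#' parameters, filter and growth policies, image-model settings, seed) and
#' round-trips losslessly through YAML or JSON.
#'
#' @param params,filter_policy,growth_policy,image_model,seed components.
#' @return `run_config`: a named list of class `run_config`.
#' @export
run_config <- function(params = scm_parameters(),
                       filter_policy = scmseg::filter_policy(),
                       growth_policy = scmseg::growth_policy(),
                       image_model = image_model_config(),
                       seed = 7L) {
  structure(list(params = unclass(params),
                 filter_policy = unclass(filter_policy),
                 growth_policy = unclass(growth_policy),
                 image_model = unclass(image_model),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path file path (.yaml/.yml or .json).
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  x$params$W <- as.numeric(x$params$W)   # matrices flatten column-major
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop2("config must be .yaml/.yml or .json", "scmseg_format_error")
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else stop2("config must be .yaml/.yml or .json",
                  "scmseg_format_error")
  cfg <- run_config(
    params = do.call(scm_parameters,
                     c(x$params[c("f", "g", "h", "max_iter")],
                       list(W = matrix(as.numeric(x$params$W), 3, 3)))),
    filter_policy = do.call(filter_policy, x$filter_policy),
    growth_policy = do.call(growth_policy, x$growth_policy),
    image_model = do.call(image_model_config, x$image_model),
    seed = x$seed)
  cfg
}
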