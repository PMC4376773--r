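#' Configuration of the synthetic epithelium image model
#'
#' The image model emulates reflectance confocal frames of epithelial
#' tissue: non-overlapping circular nuclei with truncated 2-D Gaussian
#' intensity profiles over a Gaussian-white-noise background. Nuclear size
#' and density follow measurements from oral mucosa: by default 750 nuclei
#' of 90 px^2 (~8 um equivalent diameter at 0.75 um/px) in a 1000 x 1000 px
#' frame. The nuclear-to-background contrast ratio (mean nuclear intensity /
#' mean background intensity) is the control parameter; sweeping it from 2.6
#' down to 1.6 emulates the contrast loss with imaging depth.
#'
#' Contrast is adjusted by jointly scaling the nuclear signal down and the
#' background up: background mean and noise sd default to 0.25 and 0.05 at
#' contrast 2.0 and are rescaled by sqrt(2 / contrast) per level, so half of
#' a log-contrast step is carried by each side.
#'
#' @param frame_size pixels per side of the square frame.
#' @param n_objects number of nuclei.
#' @param object_area nuclear footprint, px^2.
#' @param contrast target nuclear-to-background intensity ratio (> 1).
#' @param background_mean background intensity in [0, 1]; default scales
#'   with contrast as described above.
#' @param background_variance background noise variance; default scales
#'   with contrast.
#' @param peak_jitter relative spread of per-nucleus peak intensity
#'   (multiplicative, uniform in 1 +/- peak_jitter).
#' @param pixel_scale um per pixel.
#' @param seed RNG seed; identical config + seed gives bit-identical frames.
#' @return an object of class `image_model_config`.
#' @export
image_model_config <- function(frame_size = 1000L, n_objects = 750L,
                               object_area = 90L, contrast = 2.0,
                               background_mean = NULL,
                               background_variance = NULL,
                               peak_jitter = 0.1, pixel_scale = 0.75,
                               seed = 1L) {
  if (!(contrast > 1)) stop2("'contrast' must be > 1", "scmseg_config_error")
  if (pixel_scale <= 0) stop2("'pixel_scale' must be > 0",
                              "scmseg_config_error")
  frame_size <- as.integer(frame_size)
  n_objects <- as.integer(n_objects)
  object_area <- as.integer(object_area)
  if (frame_size < 1L || n_objects < 0L || object_area < 1L)
    stop2("frame_size/object_area must be positive; n_objects >= 0",
          "scmseg_config_error")
  if (n_objects * object_area >= 0.5 * frame_size^2)
    stop2("objects would cover >= half the frame (over-dense configuration)",
          "scmseg_config_error")
  sc <- sqrt(2.0 / contrast)
  if (is.null(background_mean)) background_mean <- 0.25 * sc
  if (is.null(background_variance)) background_variance <- (0.05 * sc)^2
  s3 <- 3 * sqrt(background_variance)
  if (background_mean <= 0 || background_mean + s3 > 1 ||
      background_mean - s3 < 0)
    stop2("background mean +/- 3 sd must stay within [0, 1]",
          "scmseg_config_error")
  if (peak_jitter < 0 || peak_jitter >= 1)
    stop2("'peak_jitter' must be in [0, 1)", "scmseg_config_error")
  structure(list(frame_size = frame_size, n_objects = n_objects,
                 object_area = object_area, contrast = contrast,
                 background_mean = background_mean,
                 background_variance = background_variance,
                 peak_jitter = peak_jitter, pixel_scale = pixel_scale,
                 seed = as.integer(seed)),
            class = "image_model_config")
}

# the `area` integer offsets closest to the origin: an exact-area raster disk
disk_footprint <- function(area) {
  r <- ceiling(sqrt(area / pi)) + 2L
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- g$dx^2 + g$dy^2
  o <- order(d2, g$dy, g$dx)[seq_len(area)]
  cbind(dx = g$dx[o], dy = g$dy[o], d2 = d2[o])
}

#' Place non-overlapping object centres by rejection sampling
#'
#' Draws `n` centres uniformly inside the frame (respecting `margin` from
#' the border) such that every pairwise Euclidean distance is at least
#' `min_separation`. Uses the current RNG state.
#'
#' @param n number of centres.
#' @param frame_size pixels per side.
#' @param min_separation minimum pairwise centre distance, px; at least
#'   twice the nominal object radius keeps disks disjoint.
#' @param margin minimum distance of a centre from each frame edge
#'   (default: half the separation, keeping footprints inside the frame).
#' @param max_attempts rejection-sampling budget before signalling an
#'   over-dense configuration.
#' @return n x 2 integer matrix of (row, col) centres.
#' @export
place_nonoverlapping_centers <- function(n, frame_size, min_separation,
                                         margin = ceiling(min_separation / 2),
                                         max_attempts = 200L * n + 1000L) {
  n <- as.integer(n)
  if (n == 0L) return(matrix(integer(0), 0L, 2L,
                             dimnames = list(NULL, c("row", "col"))))
  lo <- 1L + as.integer(margin)
  hi <- as.integer(frame_size) - as.integer(margin)
  if (hi < lo)
    stop2("frame too small for the requested margin",
          "scmseg_placement_error")
  cr <- numeric(n); cc <- numeric(n)
  placed <- 0L
  d2min <- min_separation^2
  for (att in seq_len(max_attempts)) {
    r <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    c <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    if (placed > 0L) {
      i <- seq_len(placed)
      if (min((cr[i] - r)^2 + (cc[i] - c)^2) < d2min) next
    }
    placed <- placed + 1L
    cr[placed] <- r; cc[placed] <- c
    if (placed == n) break
  }
  if (placed < n)
    stop2(sprintf(
      "placed only %d of %d centres in %d attempts (over-dense configuration)",
      placed, n, max_attempts), "scmseg_placement_error")
  cbind(row = as.integer(cr), col = as.integer(cc))
}

#' Generate a synthetic epithelium frame with ground truth
#'
#' Composes Gaussian white-noise background and `n_objects` truncated
#' Gaussian nuclear bumps on disjoint disk footprints, then calibrates the
#' global bump amplitude by a short fixed-point iteration against
#' [measure_contrast()] so the realized (post-clipping) contrast matches
#' `config$contrast`. The bump sigma puts the footprint edge at ~2 sigma
#' from the peak; per-nucleus peaks get multiplicative jitter.
#'
#' @param config an [image_model_config()].
#' @return list with elements `image` (matrix in [0, 1]), `labels` (integer
#'   ground-truth label mask, one label per nucleus), `centers`,
#'   `nominal_radius` and `config`.
#' @export
generate_frame <- function(config = image_model_config()) {
  stopifnot(inherits(config, "image_model_config"))
  set.seed(config$seed)
  fs <- config$frame_size
  bg_sd <- sqrt(config$background_variance)
  img <- matrix(rnorm(fs * fs, config$background_mean, bg_sd), fs, fs)
  labels <- matrix(0L, fs, fs)
  nominal_radius <- sqrt(config$object_area / pi)
  if (config$n_objects > 0L) {
    fp <- disk_footprint(config$object_area)
    sigma <- nominal_radius / 2           # footprint edge at ~2 sigma
    gprof <- exp(-fp[, "d2"] / (2 * sigma^2))
    rmax <- sqrt(max(fp[, "d2"]))
    min_sep <- 2 * ceiling(rmax) + 1      # guarantees disjoint footprints
    centers <- place_nonoverlapping_centers(config$n_objects, fs, min_sep,
                                            margin = ceiling(rmax) + 1L)
    peak0 <- config$background_mean * (config$contrast - 1) / mean(gprof)
    bump <- matrix(0, fs, fs)
    for (k in seq_len(nrow(centers))) {
      idx <- cbind(centers[k, 1L] + fp[, "dx"], centers[k, 2L] + fp[, "dy"])
      jit <- runif(1, 1 - config$peak_jitter, 1 + config$peak_jitter)
      bump[idx] <- peak0 * jit * gprof
      labels[idx] <- k
    }
    # calibrate amplitude against the realized, clipped contrast
    s <- 1
    for (it in 1:4) {
      m <- measure_contrast(clip01(img + s * bump), labels)
      s <- s * (config$contrast - 1) / max(m - 1, 1e-9)
    }
    img <- img + s * bump
  } else {
    centers <- matrix(integer(0), 0L, 2L,
                      dimnames = list(NULL, c("row", "col")))
  }
  list(image = clip01(img), labels = labels, centers = centers,
       nominal_radius = nominal_radius, config = config)
}

#' Measure nuclear-to-background contrast
#'
#' Mean intensity over all labelled object pixels divided by the mean over
#' all unlabelled (background) pixels.
#'
#' @param image intensity matrix.
#' @param labels label mask of the same shape (0 = background).
#' @return the contrast ratio.
#' @export
measure_contrast <- function(image, labels) {
  image <- as_intensity_matrix(image)
  check_same_shape(image, labels, c("image", "labels"))
  obj <- labels > 0L
  n_obj <- sum(obj)
  if (n_obj == 0L || n_obj == length(labels))
    stop2("need at least one object pixel and one background pixel",
          "scmseg_degenerate_error")
  mb <- mean(image[!obj])
  if (mb <= 0)
    stop2("background mean intensity is zero", "scmseg_degenerate_error")
  mean(image[obj]) / mb
}
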