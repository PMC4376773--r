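#' Iterative SCM filter policy
#'
#' Controls the gamma-correction filtering driven by the SCM pulse outputs.
#' Only the first six pulse iterations are analysed. Connected objects in
#' the early iterations (bright features) that exceed
#' `large_area_threshold` are darkened with `gamma_darken`; objects in the
#' late iterations (dim features) whose area lies within
#' `small_area_range` and whose eccentricity is at most
#' `eccentricity_limit` -- i.e. small, round, nucleus-shaped -- are
#' brightened with `gamma_brighten`. All other pixels pass unchanged.
#'
#' @param n_passes number of successive filter passes in the pipeline.
#' @param early_iters pulse iterations (within 1..6) checked for large
#'   saturated areas.
#' @param late_iters pulse iterations (within 1..6) checked for dim
#'   nucleus-shaped objects.
#' @param large_area_threshold px^2 above which early-iteration objects are
#'   darkened.
#' @param small_area_range length-2 px^2 range of late-iteration objects to
#'   brighten.
#' @param eccentricity_limit maximum eccentricity of objects to brighten
#'   (0 = circle).
#' @param gamma_darken exponent > 1 applied to darken.
#' @param gamma_brighten exponent in (0, 1) applied to brighten.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(n_passes = 2L, early_iters = c(1L, 2L),
                          late_iters = c(4L, 5L, 6L),
                          large_area_threshold = 1000,
                          small_area_range = c(30, 200),
                          eccentricity_limit = 0.85,
                          gamma_darken = 1.5, gamma_brighten = 0.6) {
  if (!all(early_iters %in% 1:6) || !all(late_iters %in% 1:6))
    stop2("filter iteration ranges must lie within 1..6",
          "scmseg_config_error")
  if (!(gamma_darken > 1 && gamma_brighten > 0 && gamma_brighten < 1))
    stop2("need gamma_darken > 1 > gamma_brighten > 0",
          "scmseg_config_error")
  if (length(small_area_range) != 2L || diff(small_area_range) < 0)
    stop2("'small_area_range' must be an increasing length-2 range",
          "scmseg_config_error")
  structure(list(n_passes = as.integer(n_passes),
                 early_iters = as.integer(early_iters),
                 late_iters = as.integer(late_iters),
                 large_area_threshold = large_area_threshold,
                 small_area_range = small_area_range,
                 eccentricity_limit = eccentricity_limit,
                 gamma_darken = gamma_darken,
                 gamma_brighten = gamma_brighten),
            class = "filter_policy")
}

#' Mask growth policy
#'
#' Controls how the initial mask (regional minima of the time matrix) is
#' grown by annexing successively later pulse iterations. An object stops
#' growing when annexing the next iteration would push it past
#' `area_limit` or `eccentricity_limit`.
#'
#' The default area limit equals the nominal nuclear footprint (90 px^2 at
#' the reference magnification), which keeps the grown objects tight
#' around nuclei: looser limits annex the noisy halo pulsing just after
#' each nuclear rim and measurably degrade pixel specificity.
#'
#' @param area_limit maximum object area, px^2.
#' @param eccentricity_limit maximum object eccentricity in [0, 1].
#' @param minima_connectivity 4 or 8, for regional minima and growth.
#' @return an object of class `growth_policy`.
#' @export
growth_policy <- function(area_limit = 90, eccentricity_limit = 0.9,
                          minima_connectivity = 8L) {
  if (area_limit <= 0) stop2("'area_limit' must be > 0",
                             "scmseg_config_error")
  if (eccentricity_limit < 0 || eccentricity_limit > 1)
    stop2("'eccentricity_limit' must be in [0, 1]", "scmseg_config_error")
  if (!minima_connectivity %in% c(4L, 8L))
    stop2("'minima_connectivity' must be 4 or 8", "scmseg_config_error")
  structure(list(area_limit = area_limit,
                 eccentricity_limit = eccentricity_limit,
                 minima_connectivity = as.integer(minima_connectivity)),
            class = "growth_policy")
}

#' Remove the dark image background, keeping the active field of view
#'
#' When tissue does not fill the whole frame, the empty background must be
#' excluded before computing the nuclear-to-cytoplasmic ratio, or the ratio
#' is erroneously low. The background is assumed to be a large contiguous
#' area of dark pixels: a threshold is computed with Otsu's method, scaled
#' by `scale`, and only large below-threshold connected regions touching
#' the frame border are removed. Small dark specks inside the tissue are
#' retained.
#'
#' @param image intensity matrix in [0, 1].
#' @param scale factor applied to the Otsu threshold (0 < scale <= 1).
#' @param min_region_frac minimum area of a removable background region, as
#'   a fraction of the frame.
#' @return an object of class `active_fov`: list with `mask` (logical,
#'   TRUE = tissue) and `area` (px^2).
#' @export
remove_background <- function(image, scale = 0.5, min_region_frac = 0.05) {
  image <- as_intensity_matrix(image)
  if (!(scale > 0 && scale <= 1))
    stop2("'scale' must be in (0, 1]", "scmseg_config_error")
  full <- function() structure(list(mask = matrix(TRUE, nrow(image),
                                                  ncol(image)),
                                    area = length(image)),
                               class = "active_fov")
  if (diff(range(image)) == 0) {
    warning("constant image: degenerate histogram, keeping full-frame FOV")
    return(full())
  }
  thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1)) * scale
  cand <- image < thr
  if (!any(cand)) return(full())
  lab <- label_components_cpp(cand, 8L)
  areas <- tabulate(lab[lab > 0L])
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  big <- which(areas > min_region_frac * length(image))
  bg_labels <- intersect(big, border[border > 0L])
  if (length(bg_labels) == 0L) return(full())
  mask <- !matrix(lab %in% bg_labels, nrow(image), ncol(image))
  structure(list(mask = mask, area = sum(mask)), class = "active_fov")
}

# min-max normalization over the active FOV; non-FOV pixels are set to 0
normalize_fov <- function(image, fov) {
  v <- image[fov$mask]
  r <- range(v)
  out <- if (diff(r) == 0) matrix(0, nrow(image), ncol(image))
         else clip01((image - r[1]) / diff(r))
  out[!fov$mask] <- 0
  out
}

#' One SCM filtering pass
#'
#' Runs the SCM, measures area and eccentricity of the connected objects in
#' each of the first six pulse iterations, and remaps the image intensities
#' with gamma corrections: large early-pulsing (bright, saturated) objects
#' are darkened, small round late-pulsing (dim, nucleus-shaped) objects are
#' brightened. Repeated passes sharpen nuclei against clutter before the
#' final segmentation.
#'
#' @param image intensity matrix in [0, 1].
#' @param params [scm_parameters()].
#' @param policy [filter_policy()].
#' @return filtered image, still in [0, 1].
#' @export
scm_filter_pass <- function(image, params = scm_parameters(),
                            policy = filter_policy()) {
  image <- as_intensity_matrix(image)
  check_normalized(image)
  tm <- scm_time_matrix(image, params)
  darken <- matrix(FALSE, nrow(image), ncol(image))
  brighten <- matrix(FALSE, nrow(image), ncol(image))
  for (n in policy$early_iters) {
    lab <- label_components_cpp(tm == n, 8L)
    if (max(lab) == 0L) next
    st <- label_shape_stats_cpp(lab)
    sel <- which(st[, "area"] > policy$large_area_threshold)
    if (length(sel)) darken <- darken | matrix(lab %in% sel, nrow(lab))
  }
  for (n in policy$late_iters) {
    lab <- label_components_cpp(tm == n, 8L)
    if (max(lab) == 0L) next
    st <- label_shape_stats_cpp(lab)
    sel <- which(st[, "area"] >= policy$small_area_range[1] &
                 st[, "area"] <= policy$small_area_range[2] &
                 st[, "ecc"] <= policy$eccentricity_limit)
    if (length(sel)) brighten <- brighten | matrix(lab %in% sel, nrow(lab))
  }
  out <- image
  out[darken] <- image[darken]^policy$gamma_darken
  out[brighten] <- image[brighten]^policy$gamma_brighten
  out
}

#' Build a segmentation mask from a time matrix
#'
#' The initial mask is the set of regional minima of the time matrix (the
#' earliest-pulsing plateaus, i.e. the bright nuclear cores); each seed is
#' then grown by annexing adjacent pixels of successively later pulse
#' iterations until annexing the next iteration would push the object past
#' the area or eccentricity limit. Seeds never merge; sentinel
#' (never-pulsed) pixels are never annexed.
#'
#' @param tm integer time matrix from [scm_time_matrix()].
#' @param policy [growth_policy()].
#' @param sentinel sentinel value (defaults to the matrix attribute).
#' @return integer label mask.
#' @export
build_segmentation_mask <- function(tm, policy = growth_policy(),
                                    sentinel = tm_sentinel(tm)) {
  stopifnot(is.matrix(tm))
  storage.mode(tm) <- "integer"
  seeds <- regional_minima_cpp(tm, sentinel, policy$minima_connectivity)
  if (max(seeds) == 0L) return(seeds)
  grow_mask_cpp(tm, seeds, sentinel, policy$area_limit,
                policy$eccentricity_limit, policy$minima_connectivity)
}

#' Full SCM nuclei segmentation pipeline
#'
#' End-to-end automated segmentation: (1) rescale the raw image to [0, 1];
#' (2) remove the dark background, keeping the active field of view (FOV);
#' (3) min-max normalize over the FOV; (4) apply `n_passes` of the SCM
#' gamma-correction filter; (5) compute the final time matrix; (6) build
#' the segmentation mask by growing the regional minima; (7) restrict
#' objects to the FOV and, if a classifier is supplied, remove objects
#' classified as likely false positives.
#'
#' @param image raw grayscale matrix (any nonnegative range).
#' @param params [scm_parameters()].
#' @param filter_policy [filter_policy()].
#' @param growth_policy [growth_policy()].
#' @param classifier optional `scm_classifier` from [train_classifier()].
#' @param otsu_scale scale factor for the background-removal threshold.
#' @return an object of class `scm_segmentation`: list with `labels`
#'   (integer mask, contiguous labels), `fov` (`active_fov`),
#'   `time_matrix`, and `image` (the [0, 1]-rescaled input).
#' @export
scm_segment <- function(image, params = scm_parameters(),
                        filter_policy = scmseg::filter_policy(),
                        growth_policy = scmseg::growth_policy(),
                        classifier = NULL, otsu_scale = 0.5) {
  image <- as_intensity_matrix(image)
  r <- range(image)
  img0 <- if (r[1] < 0 || r[2] > 1) {
    if (diff(r) == 0) matrix(0, nrow(image), ncol(image))
    else (image - r[1]) / diff(r)
  } else image
  fov <- remove_background(img0, scale = otsu_scale)
  S <- normalize_fov(img0, fov)
  for (p in seq_len(filter_policy$n_passes))
    S <- scm_filter_pass(S, params, filter_policy)
  tm <- scm_time_matrix(S, params)
  sent <- tm_sentinel(tm)
  tm[!fov$mask] <- sent
  attr(tm, "sentinel") <- sent
  mask <- build_segmentation_mask(tm, growth_policy, sent)
  mask[!fov$mask] <- 0L
  mask <- relabel_mask(mask)
  if (!is.null(classifier))
    mask <- filter_objects(classifier, mask, img0)
  structure(list(labels = mask, fov = fov, time_matrix = tm, image = img0),
            class = "scm_segmentation")
}
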