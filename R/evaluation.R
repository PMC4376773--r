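#' Nuclear-to-cytoplasmic ratio
#'
#' Total object area divided by the remaining area of the active field of
#' view: A / (fov_area - A). Rises with nuclear density and is an indicator
#' of epithelial precancer.
#'
#' @param mask integer label mask (or logical).
#' @param fov_area area of the active FOV in px^2.
#' @return the ratio.
#' @export
compute_ncr <- function(mask, fov_area) {
  a <- sum(mask > 0L)
  if (a > fov_area)
    stop2("object area exceeds the FOV area", "scmseg_input_error")
  if (a == fov_area)
    stop2("objects fill the whole FOV (division by zero)",
          "scmseg_degenerate_error")
  a / (fov_area - a)
}

#' Nuclear morphometrics of a label mask
#'
#' Per-object pixel areas are converted to um^2 with the pixel scale; the
#' mean diameter is derived from the mean area as 2 sqrt(mean_area / pi)
#' (nuclei are irregular, so a diameter is only meaningful through the
#' equivalent circle).
#'
#' @param mask integer label mask.
#' @param pixel_scale um per pixel.
#' @return an object of class `morphometrics_report`: `n_objects`, `ncr`
#'   (NA unless `fov_area` given), `mean_area`/`area_std` (um^2),
#'   `mean_diameter` (um), `pixel_scale`.
#' @param fov_area optional FOV area (px^2) for the NCR.
#' @export
morphometrics <- function(mask, pixel_scale = 0.75, fov_area = NULL) {
  if (pixel_scale <= 0)
    stop2("'pixel_scale' must be > 0", "scmseg_config_error")
  storage.mode(mask) <- "integer"
  areas_px <- tabulate(mask[mask > 0L])
  areas_px <- areas_px[areas_px > 0L]
  n <- length(areas_px)
  if (n == 0L) {
    rep0 <- list(n_objects = 0L, ncr = if (is.null(fov_area)) NA_real_ else 0,
                 mean_area = 0, area_std = 0, mean_diameter = 0,
                 pixel_scale = pixel_scale)
    return(structure(rep0, class = "morphometrics_report"))
  }
  areas_um <- areas_px * pixel_scale^2
  mean_area <- mean(areas_um)
  structure(list(
    n_objects = n,
    ncr = if (is.null(fov_area)) NA_real_ else compute_ncr(mask, fov_area),
    mean_area = mean_area,
    area_std = if (n > 1L) stats::sd(areas_um) else 0,
    mean_diameter = 2 * sqrt(mean_area / pi),
    pixel_scale = pixel_scale), class = "morphometrics_report")
}

#' Pixel-based F-measure
#'
#' Harmonic mean of pixel-based sensitivity and pixel-based specificity,
#' 2 s p / (s + p).
#'
#' @param sens,spec fractions in [0, 1], not both zero.
#' @return the F-measure.
#' @export
f_measure <- function(sens, spec) {
  if (sens == 0 && spec == 0)
    stop2("F-measure undefined at (0, 0)", "scmseg_degenerate_error")
  2 * sens * spec / (sens + spec)
}

#' Evaluate a segmentation against a gold-standard mask
#'
#' Object level: a gold object is a true positive if any of its pixels is
#' covered by any predicted object, otherwise a false negative; a predicted
#' object overlapping no gold object is a false positive (a predicted
#' object overlapping several gold objects credits each of them). Pixel
#' level: TP/FP/FN by set intersection/difference of the object pixel
#' sets; true negatives are the active FOV less the TP, FP and FN pixels.
#'
#' @param pred integer label mask of predicted objects.
#' @param gold integer gold-standard label mask.
#' @param fov_area area of the active FOV, px^2.
#' @return an object of class `evaluation_report` with the object/pixel
#'   confusion counts, `object_sensitivity`, `pixel_sensitivity`,
#'   `pixel_specificity` and `f_measure`.
#' @export
evaluate_segmentation <- function(pred, gold, fov_area = length(pred)) {
  check_same_shape(pred, gold, c("pred", "gold"))
  storage.mode(pred) <- "integer"
  storage.mode(gold) <- "integer"
  P <- pred > 0L; G <- gold > 0L
  pixel_tp <- sum(P & G)
  pixel_fp <- sum(P & !G)
  pixel_fn <- sum(!P & G)
  pixel_tn <- fov_area - pixel_tp - pixel_fp - pixel_fn
  gold_labels <- unique(gold[G])
  covered <- unique(gold[P & G])
  object_tp <- length(covered)
  object_fn <- length(gold_labels) - object_tp
  pred_labels <- unique(pred[P])
  object_fp <- length(setdiff(pred_labels, unique(pred[P & G])))
  object_sensitivity <- if (length(gold_labels))
    object_tp / length(gold_labels) else NA_real_
  pixel_sensitivity <- if (pixel_tp + pixel_fn > 0)
    pixel_tp / (pixel_tp + pixel_fn) else NA_real_
  pixel_specificity <- if (pixel_tn + pixel_fp > 0)
    pixel_tn / (pixel_tn + pixel_fp) else NA_real_
  fm <- if (!is.na(pixel_sensitivity) && !is.na(pixel_specificity) &&
            (pixel_sensitivity + pixel_specificity) > 0)
    f_measure(pixel_sensitivity, pixel_specificity) else NA_real_
  structure(list(object_tp = object_tp, object_fn = object_fn,
                 object_fp = object_fp,
                 pixel_tp = pixel_tp, pixel_fp = pixel_fp,
                 pixel_fn = pixel_fn, pixel_tn = pixel_tn,
                 object_sensitivity = object_sensitivity,
                 pixel_sensitivity = pixel_sensitivity,
                 pixel_specificity = pixel_specificity,
                 f_measure = fm),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Segmentation evaluation\n")
  cat(sprintf("  objects: TP %d  FN %d  FP %d  (sensitivity %.4f)\n",
              x$object_tp, x$object_fn, x$object_fp, x$object_sensitivity))
  cat(sprintf("  pixels:  TP %d  FP %d  FN %d  TN %d\n",
              x$pixel_tp, x$pixel_fp, x$pixel_fn, x$pixel_tn))
  cat(sprintf("  pixel sensitivity %.4f  specificity %.4f  F-measure %.4f\n",
              x$pixel_sensitivity, x$pixel_specificity, x$f_measure))
  invisible(x)
}

#' @export
print.morphometrics_report <- function(x, ...) {
  cat("Nuclear morphometrics\n")
  cat(sprintf("  objects: %d   NCR: %s\n", x$n_objects,
              ifelse(is.na(x$ncr), "NA", sprintf("%.4f", x$ncr))))
  cat(sprintf("  area: %.2f +/- %.2f um^2   diameter: %.2f um\n",
              x$mean_area, x$area_std, x$mean_diameter))
  invisible(x)
}

#' Colour-coded sensitivity map
#'
#' Overlays the confusion classes on an RGB image: green = true-positive
#' pixels (in both masks), blue = false negatives (gold only), red = false
#' positives (predicted only); elsewhere the grayscale source (or black).
#'
#' @param pred,gold label masks of the same shape.
#' @param image optional grayscale background in [0, 1].
#' @return numeric array rows x cols x 3 in [0, 1].
#' @export
sensitivity_map <- function(pred, gold, image = NULL) {
  check_same_shape(pred, gold, c("pred", "gold"))
  P <- pred > 0L; G <- gold > 0L
  base <- if (is.null(image)) matrix(0, nrow(pred), ncol(pred))
          else clip01(as_intensity_matrix(image))
  check_same_shape(base, pred, c("image", "pred"))
  rch <- base; gch <- base; bch <- base
  tp <- P & G; fn <- G & !P; fp <- P & !G
  rch[tp] <- 0; gch[tp] <- 1; bch[tp] <- 0
  rch[fn] <- 0; gch[fn] <- 0; bch[fn] <- 1
  rch[fp] <- 1; gch[fp] <- 0; bch[fp] <- 0
  array(c(rch, gch, bch), dim = c(nrow(pred), ncol(pred), 3L))
}

#' Contrast sweep of the full pipeline on the image model
#'
#' For each contrast level, generates `replicates` synthetic frames (seeds
#' seed, seed+1, ...), runs the full pipeline (optionally with a trained
#' classifier), evaluates against the ground truth and tabulates mean and
#' sd of object sensitivity, pixel sensitivity and pixel specificity,
#' together with the F-measure, object count and NCR.
#'
#' @param levels contrast levels.
#' @param replicates frames per level.
#' @param seed base RNG seed.
#' @param classifier optional `scm_classifier`.
#' @param config_args extra arguments to [image_model_config()].
#' @param params,filter_policy,growth_policy pipeline settings.
#' @return data.frame, one row per level, ordered by increasing contrast.
#' @export
contrast_sweep <- function(levels = c(2.6, 2.4, 2.2, 2.0, 1.8, 1.6),
                           replicates = 3L, seed = 7L, classifier = NULL,
                           config_args = list(),
                           params = scm_parameters(),
                           filter_policy = scmseg::filter_policy(),
                           growth_policy = scmseg::growth_policy()) {
  stopifnot(length(levels) > 0L, replicates >= 1L)
  levels <- sort(levels)
  rows <- lapply(levels, function(ct) {
    os <- ps <- sp <- fm <- no <- nc <- numeric(replicates)
    for (r in seq_len(replicates)) {
      cfg <- do.call(image_model_config,
                     c(list(contrast = ct, seed = seed + r - 1L),
                       config_args))
      fr <- generate_frame(cfg)
      seg <- scm_segment(fr$image, params = params,
                         filter_policy = filter_policy,
                         growth_policy = growth_policy,
                         classifier = classifier)
      ev <- evaluate_segmentation(seg$labels, fr$labels, seg$fov$area)
      os[r] <- ev$object_sensitivity
      ps[r] <- ev$pixel_sensitivity
      sp[r] <- ev$pixel_specificity
      fm[r] <- ev$f_measure
      no[r] <- max(seg$labels)
      nc[r] <- compute_ncr(seg$labels, seg$fov$area)
    }
    data.frame(contrast = ct,
               object_sens = mean(os), object_sens_sd = stats::sd(os),
               pixel_sens = mean(ps), pixel_sens_sd = stats::sd(ps),
               pixel_spec = mean(sp), pixel_spec_sd = stats::sd(sp),
               f_measure = mean(fm), n_objects = mean(no), ncr = mean(nc))
  })
  do.call(rbind, rows)
}
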