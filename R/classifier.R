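FEATURE_NAMES <- c("area", "eccentricity", "extent", "solidity",
                   "fg_mean", "fg_std", "bg_mean", "bg_std")

#' Extract per-object feature vectors
#'
#' Computes, for every labelled object, the 8-dimensional feature vector
#' used by the false-positive classifier: area (px^2), eccentricity of the
#' moment-matched ellipse, extent (area / bounding-box area), solidity
#' (area / convex-hull area), and mean/standard deviation of intensity over
#' the object pixels (foreground) and over a peripheral background ring
#' (pixels within a 3 px dilation of the object, excluding object pixels of
#' any label).
#'
#' Conventions for degenerate shapes: a 1-pixel object has eccentricity 0,
#' extent 1 and solidity 1; collinear-pixel objects have eccentricity 1.
#'
#' @param mask integer label mask.
#' @param image intensity matrix of the same shape.
#' @return data.frame with one row per label (ordered by label): column
#'   `label` plus the 8 features.
#' @export
extract_features <- function(mask, image) {
  image <- as_intensity_matrix(image)
  check_same_shape(mask, image, c("mask", "image"))
  storage.mode(mask) <- "integer"
  empty <- as.data.frame(c(list(label = integer(0)),
                           stats::setNames(rep(list(numeric(0)),
                                               length(FEATURE_NAMES)),
                                           FEATURE_NAMES)))
  pos <- which(mask > 0L)
  if (length(pos) == 0L) return(empty)
  st <- object_feature_stats_cpp(mask, image, 3)
  labs <- which(st[, "area"] > 0)
  solidity <- pmin(1, st[labs, "area"] / pmax(st[labs, "hull_area"], 1))
  bbox_area <- (st[labs, "rmax"] - st[labs, "rmin"] + 1) *
               (st[labs, "cmax"] - st[labs, "cmin"] + 1)
  data.frame(label = labs,
             area = st[labs, "area"],
             eccentricity = st[labs, "ecc"],
             extent = st[labs, "area"] / bbox_area,
             solidity = solidity,
             fg_mean = st[labs, "fg_mean"],
             fg_std = st[labs, "fg_sd"],
             bg_mean = st[labs, "bg_mean"],
             bg_std = st[labs, "bg_sd"],
             row.names = NULL)
}

# stratified 70/15/15 split with exact total sizes floor(.7 n) / floor(.15 n)
# / remainder; largest-remainder allocation per class, seeded by the caller.
split_70_15_15 <- function(y) {
  n <- length(y)
  n_tr <- floor(0.70 * n)
  n_val <- floor(0.15 * n)
  alloc <- function(avail_counts, total) {
    quota <- avail_counts * total / sum(avail_counts)
    base <- floor(quota)
    extra <- total - sum(base)
    if (extra > 0) {
      o <- order(quota - base, decreasing = TRUE)
      base[o[seq_len(extra)]] <- base[o[seq_len(extra)]] + 1
    }
    base
  }
  classes <- sort(unique(y))
  by_class <- lapply(classes, function(cl) sample(which(y == cl)))
  counts <- vapply(by_class, length, 1L)
  tr_c <- alloc(counts, n_tr)
  val_c <- alloc(counts - tr_c, n_val)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (k in seq_along(classes)) {
    s <- by_class[[k]]
    idx$train <- c(idx$train, s[seq_len(tr_c[k])])
    idx$val <- c(idx$val, s[seq_len(val_c[k]) + tr_c[k]])
    idx$test <- c(idx$test, s[-seq_len(tr_c[k] + val_c[k])])
  }
  idx
}

xent <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the false-positive object classifier
#'
#' Trains a small feed-forward neural network (one hidden layer, logistic
#' output) that separates true nuclear objects from likely false positives
#' using the 8 features of [extract_features()]. Objects are split
#' 70/15/15 (stratified, seeded) into training, validation and independent
#' test sets; training uses early stopping on the validation
#' cross-entropy. Features are standardized with training-split statistics.
#'
#' @param features data.frame or matrix holding the 8 feature columns.
#' @param labels logical (or 0/1) vector: TRUE for true nuclear objects.
#' @param seed RNG seed: split and weight initialization are reproducible.
#' @param hidden hidden-layer size.
#' @param decay L2 weight decay.
#' @param chunk epochs per early-stopping check.
#' @param patience consecutive non-improving checks before stopping.
#' @param max_epochs overall epoch cap.
#' @param threshold posterior probability above which an object is kept by
#'   [filter_objects()]. The default is deliberately strict (0.85):
#'   keeping a borderline non-nucleus costs specificity over the whole
#'   frame, whereas true nuclei sit near probability 1.
#' @return an object of class `scm_classifier` with the fitted network,
#'   standardization constants and training metadata (`$meta`: split sizes,
#'   seed, validation and test accuracy).
#' @export
train_classifier <- function(features, labels, seed = 1L, hidden = 10L,
                             decay = 1e-4, chunk = 25L, patience = 3L,
                             max_epochs = 500L, threshold = 0.85) {
  x <- as.matrix(as.data.frame(features)[, FEATURE_NAMES])
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1)))
    stop2("'labels' must be logical or 0/1", "scmseg_input_error")
  if (length(y) != nrow(x))
    stop2("features and labels length mismatch", "scmseg_input_error")
  if (length(y) < 20L)
    stop2("need at least 20 labelled objects", "scmseg_too_few_samples")
  if (length(unique(y)) < 2L)
    stop2("need both classes present to train", "scmseg_single_class")
  set.seed(seed)
  sp <- split_70_15_15(y)
  ctr <- colMeans(x[sp$train, , drop = FALSE])
  scl <- apply(x[sp$train, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ztr <- z[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  zva <- z[sp$val, , drop = FALSE];  yva <- y[sp$val]
  zte <- z[sp$test, , drop = FALSE]; yte <- y[sp$test]
  wts <- NULL; best <- Inf; best_fit <- NULL; bad <- 0L
  for (ep in seq(chunk, max_epochs, by = chunk)) {
    fit <- if (is.null(wts))
      nnet::nnet(ztr, ytr, size = hidden, entropy = TRUE, decay = decay,
                 maxit = chunk, trace = FALSE)
    else
      nnet::nnet(ztr, ytr, size = hidden, entropy = TRUE, decay = decay,
                 maxit = chunk, Wts = wts, trace = FALSE)
    wts <- fit$wts
    vloss <- xent(yva, as.numeric(predict(fit, zva)))
    if (vloss < best - 1e-6) {
      best <- vloss; best_fit <- fit; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  val_acc <- mean((as.numeric(predict(best_fit, zva)) >= threshold) == yva)
  test_acc <- mean((as.numeric(predict(best_fit, zte)) >= threshold) == yte)
  structure(list(net = best_fit, center = ctr, scale = scl,
                 threshold = threshold,
                 meta = list(n = length(y),
                             split = c(train = length(sp$train),
                                       val = length(sp$val),
                                       test = length(sp$test)),
                             seed = seed, val_loss = best,
                             val_acc = val_acc, test_acc = test_acc)),
            class = "scm_classifier")
}

#' @export
predict.scm_classifier <- function(object, features, ...) {
  x <- as.matrix(as.data.frame(features)[, FEATURE_NAMES])
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.numeric(predict(object$net, z))
}

#' Remove objects classified as likely false positives
#'
#' Applies the trained classifier to every object of a label mask and
#' deletes the objects classified negative; surviving labels are
#' re-indexed contiguously. Never creates pixels: the output object pixel
#' set is a subset of the input's.
#'
#' @param classifier an `scm_classifier` from [train_classifier()].
#' @param mask integer label mask.
#' @param image intensity matrix of the same shape.
#' @return filtered, relabelled mask.
#' @export
filter_objects <- function(classifier, mask, image) {
  if (!inherits(classifier, "scm_classifier") || is.null(classifier$net))
    stop2("'classifier' is not a trained scm_classifier",
          "scmseg_untrained_error")
  feats <- extract_features(mask, image)
  if (nrow(feats) == 0L) {
    storage.mode(mask) <- "integer"
    return(mask)
  }
  keep <- feats$label[predict(classifier, feats) >= classifier$threshold]
  out <- mask
  out[!(mask %in% keep)] <- 0L
  relabel_mask(out)
}

#' Serialize / deserialize a trained classifier
#'
#' Writes the classifier to a single portable JSON file: metadata header
#' (split sizes, seed, accuracies, standardization constants) plus the
#' network architecture and weights. `read_classifier()` reconstructs an
#' object whose predictions are identical.
#'
#' @param classifier an `scm_classifier`.
#' @param path file path (.json).
#' @return `read_classifier`: an `scm_classifier`.
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "scm_classifier"))
  net <- classifier$net
  payload <- list(
    format = "scmseg_classifier",
    version = 1L,
    meta = classifier$meta,
    center = classifier$center,
    scale = classifier$scale,
    threshold = classifier$threshold,
    net = net[c("n", "nunits", "nconn", "conn", "nsunits", "decay",
                "entropy", "softmax", "censored", "wts")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "scmseg_classifier"))
    stop2("not an scmseg classifier file", "scmseg_format_error")
  net <- x$net
  net$n <- as.integer(net$n)
  net$nunits <- as.integer(net$nunits)
  net$nconn <- as.integer(net$nconn)
  net$conn <- as.integer(net$conn)
  net$nsunits <- as.integer(net$nsunits)
  class(net) <- "nnet"
  meta <- x$meta
  meta$split <- unlist(meta$split)
  structure(list(net = net, center = unlist(x$center),
                 scale = unlist(x$scale), threshold = x$threshold,
                 meta = meta),
            class = "scm_classifier")
}

#' Match predicted objects to ground truth
#'
#' `match_objects_to_truth()` applies the any-pixel rule: a predicted
#' object matches if any of its pixels overlaps any ground-truth object.
#' `truth_overlap_fraction()` returns, per predicted object, the fraction
#' of its pixels lying inside ground-truth objects.
#'
#' @param pred integer label mask of predicted objects.
#' @param gold integer ground-truth label mask.
#' @return logical (resp. numeric) vector over the distinct predicted
#'   labels (ascending).
#' @export
match_objects_to_truth <- function(pred, gold) {
  truth_overlap_fraction(pred, gold) > 0
}

#' @rdname match_objects_to_truth
#' @export
truth_overlap_fraction <- function(pred, gold) {
  check_same_shape(pred, gold, c("pred", "gold"))
  storage.mode(pred) <- "integer"
  labs <- sort(unique(pred[pred > 0L]))
  if (length(labs) == 0L) return(numeric(0))
  areas <- tabulate(pred[pred > 0L], nbins = max(labs))
  inside <- tabulate(pred[pred > 0L & gold > 0L], nbins = max(labs))
  (inside / pmax(areas, 1L))[labs]
}

#' Train the classifier on synthetic frames
#'
#' Generates labelled synthetic frames across several contrast levels, runs
#' the (classifier-free) segmentation pipeline on each, labels every
#' segmented object by whether it overlaps a ground-truth nucleus, and
#' trains the false-positive classifier on the pooled objects. This stands
#' in for a manually segmented training database when working with the
#' image model.
#'
#' Training labels emulate a curated database: an object is labelled a
#' true nucleus only when the majority (at least `pos_overlap`) of its
#' pixels lie inside a ground-truth nucleus; objects with zero overlap are
#' negatives; partial overlaps below the cutoff (typically noise specks
#' that happen to touch a nucleus) are ambiguous and are excluded from
#' training. Raw segmentation output is additionally dominated by tiny
#' noise-speck objects — negatives can outnumber true nuclei by two orders
#' of magnitude, which makes the network collapse to the majority class —
#' so negatives are subsampled (seeded) to `neg_ratio` per positive per
#' frame.
#'
#' @param contrasts contrast levels of the training frames.
#' @param seed RNG seed (frame k uses seed + k).
#' @param config_args extra arguments passed to [image_model_config()].
#' @param params,filter_policy,growth_policy pipeline settings.
#' @param neg_ratio maximum negatives kept per positive, per frame.
#' @param pos_overlap minimum ground-truth overlap fraction of a positive.
#' @param ... passed on to [train_classifier()].
#' @return an `scm_classifier`.
#' @export
train_synthetic_classifier <- function(contrasts = c(2.6, 2.4, 2.2, 2.0,
                                                     1.8, 1.6),
                                       seed = 7L, config_args = list(),
                                       params = scm_parameters(),
                                       filter_policy = scmseg::filter_policy(),
                                       growth_policy = scmseg::growth_policy(),
                                       neg_ratio = 4, pos_overlap = 0.8,
                                       ...) {
  feats <- list(); labs <- list()
  for (k in seq_along(contrasts)) {
    cfg <- do.call(image_model_config,
                   c(list(contrast = contrasts[k], seed = seed + k),
                     config_args))
    fr <- generate_frame(cfg)
    seg <- scm_segment(fr$image, params = params,
                       filter_policy = filter_policy,
                       growth_policy = growth_policy)
    f <- extract_features(seg$labels, seg$image)
    if (nrow(f) == 0L) next
    ov <- truth_overlap_fraction(seg$labels, fr$labels)
    keep <- ov == 0 | ov >= pos_overlap     # drop ambiguous partials
    f <- f[keep, , drop = FALSE]
    y <- ov[keep] >= pos_overlap
    neg <- which(!y)
    keep_neg <- min(length(neg), ceiling(neg_ratio * max(sum(y), 1L)))
    if (length(neg) > keep_neg) {
      set.seed(seed + 1000L + k)
      drop <- neg[-sample.int(length(neg), keep_neg)]
      f <- f[-drop, , drop = FALSE]
      y <- y[-drop]
    }
    feats[[k]] <- f
    labs[[k]] <- y
  }
  train_classifier(do.call(rbind, feats), unlist(labs), seed = seed, ...)
}
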