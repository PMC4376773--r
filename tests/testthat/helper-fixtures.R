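# Small-frame image-model configuration used across tests: same nuclear
# density as the full-size model (45 * 90 / 250^2 ~ 750 * 90 / 1000^2) so
# pipeline behaviour transfers, at a fraction of the cost.
small_config <- function(contrast = 2.0, seed = 3L, n_objects = 45L, ...) {
  image_model_config(frame_size = 250L, n_objects = n_objects,
                     contrast = contrast, seed = seed, ...)
}

# Independent scalar oracle for the firing time of an isolated neuron
# (zero coupling): iterates the recurrence U(n) = f U(n-1) + S,
# E(n) = g E(n-1), fire when U(n) > E(n-1). Returns max_iter + 1 if the
# neuron never fires.
oracle_fire_time <- function(S, f = 0.928, g = 1.078, max_iter = 40L) {
  U <- 0; E <- 1
  for (n in seq_len(max_iter)) {
    U <- f * U + S
    if (U > E) return(n)
    E <- g * E
  }
  max_iter + 1L
}

# Brute-force confusion-matrix oracle: per-object and per-pixel double
# loops, no set algebra shared with evaluate_segmentation().
oracle_confusion <- function(pred, gold, fov_area) {
  gold_ids <- setdiff(sort(unique(as.vector(gold))), 0L)
  pred_ids <- setdiff(sort(unique(as.vector(pred))), 0L)
  obj_tp <- 0L
  for (g in gold_ids) {
    hit <- FALSE
    for (i in seq_len(nrow(gold))) for (j in seq_len(ncol(gold)))
      if (gold[i, j] == g && pred[i, j] > 0L) hit <- TRUE
    obj_tp <- obj_tp + as.integer(hit)
  }
  obj_fp <- 0L
  for (p in pred_ids) {
    hit <- FALSE
    for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred)))
      if (pred[i, j] == p && gold[i, j] > 0L) hit <- TRUE
    obj_fp <- obj_fp + as.integer(!hit)
  }
  ptp <- pfp <- pfn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] > 0L && gold[i, j] > 0L) ptp <- ptp + 1L
    if (pred[i, j] > 0L && gold[i, j] == 0L) pfp <- pfp + 1L
    if (pred[i, j] == 0L && gold[i, j] > 0L) pfn <- pfn + 1L
  }
  list(object_tp = obj_tp, object_fn = length(gold_ids) - obj_tp,
       object_fp = obj_fp, pixel_tp = ptp, pixel_fp = pfp, pixel_fn = pfn,
       pixel_tn = fov_area - ptp - pfp - pfn)
}

# random label mask: a few rectangles of distinct labels
random_mask <- function(n = 32L, k = 3L) {
  m <- matrix(0L, n, n)
  for (l in seq_len(k)) {
    r <- sort(sample.int(n, 2L)); c <- sort(sample.int(n, 2L))
    m[r[1]:r[2], c[1]:c[2]] <- l
  }
  m
}

# Independent oracle for the rasterized convex-hull area of a pixel set:
# grDevices::chull polygon + vectorised half-plane rasterization. chull
# returns the hull clockwise; the sign test accepts either orientation.
oracle_convex_area <- function(rows, cols) {
  n <- length(rows)
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) <= 2L) return(n)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) <= 2L) return(n)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  gr <- seq(min(rows), max(rows))
  gc <- seq(min(cols), max(cols))
  px <- rep(gr, times = length(gc))
  py <- rep(gc, each = length(gr))
  m <- length(h)
  sgn <- 0
  cr <- matrix(0, length(px), m)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    cr[, k] <- (hx[k2] - hx[k]) * (py - hy[k]) -
               (hy[k2] - hy[k]) * (px - hx[k])
  }
  inside_ccw <- rowSums(cr >= -1e-9) == m
  inside_cw <- rowSums(cr <= 1e-9) == m
  max(sum(inside_ccw), sum(inside_cw), n)
}

# rasterized disk mask of radius r centred in a square frame
disk_mask <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, "+")
  matrix(as.integer(d2 <= r^2), n, n)
}
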