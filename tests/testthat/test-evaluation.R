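test_that("NCR follows the area ratio definition", {
  m <- matrix(0L, 10, 10)
  m[1:5, ] <- 1L
  expect_equal(compute_ncr(m, 100), 1.0)           # equal split
  expect_equal(compute_ncr(matrix(0L, 5, 5), 25), 0.0)
  m2 <- matrix(0L, 40, 40)
  m2[1:10, 1:10] <- 1L
  expect_equal(compute_ncr(m2, 1100), 0.1)         # 100 / (1100 - 100)
  expect_error(compute_ncr(matrix(1L, 2, 2), 4),
               class = "scmseg_degenerate_error")
})

test_that("morphometrics converts areas and derives diameter from area", {
  m <- matrix(0L, 30, 30)
  m[1:9, 1:10] <- 1L                               # 90 px^2 object
  rep <- morphometrics(m, pixel_scale = 0.75)
  expect_equal(rep$n_objects, 1L)
  expect_equal(rep$mean_area, 90 * 0.75^2)         # 50.625 um^2
  expect_equal(rep$mean_diameter, 2 * sqrt(50.625 / pi), tolerance = 1e-12)
  expect_equal(round(rep$mean_diameter, 2), 8.03)
  expect_equal(rep$area_std, 0)

  m2 <- matrix(0L, 30, 30)
  m2[1:10, 1:10] <- 1L
  m2[15:24, 15:24] <- 2L
  rep2 <- morphometrics(m2, pixel_scale = 2)
  expect_equal(rep2$n_objects, 2L)
  expect_equal(rep2$mean_area, 100 * 4)
  expect_equal(rep2$area_std, 0)

  rep0 <- morphometrics(matrix(0L, 5, 5))
  expect_equal(rep0$n_objects, 0L)
  expect_equal(rep0$mean_area, 0)
})

test_that("object count equals the number of distinct labels", {
  set.seed(31)
  m <- random_mask(32L, 4L)
  expect_equal(morphometrics(m)$n_objects,
               length(setdiff(unique(as.vector(m)), 0L)))
})

test_that("F-measure is the harmonic mean with the documented edge cases", {
  expect_equal(f_measure(1, 1), 1.0)
  expect_equal(f_measure(0.5, 1.0), 2 / 3)
  expect_equal(f_measure(0, 0.9), 0.0)
  expect_error(f_measure(0, 0), class = "scmseg_degenerate_error")
  # symmetric, and bounded by min and max of the arguments
  for (i in 1:20) {
    s <- runif(1); p <- runif(1)
    expect_equal(f_measure(s, p), f_measure(p, s))
    expect_gte(f_measure(s, p), 0.999999 * min(s, p))
    expect_lte(f_measure(s, p), max(s, p) * 1.000001)
  }
})

test_that("identity and empty predictions give the boundary metrics", {
  set.seed(17)
  g <- random_mask(20L, 3L)
  ev <- evaluate_segmentation(g, g, 400)
  expect_equal(ev$object_sensitivity, 1)
  expect_equal(ev$pixel_sensitivity, 1)
  expect_equal(ev$pixel_specificity, 1)
  expect_equal(ev$f_measure, 1)
  ev0 <- evaluate_segmentation(matrix(0L, 20, 20), g, 400)
  expect_equal(ev0$object_sensitivity, 0)
  expect_equal(ev0$pixel_specificity, 1)
})

test_that("the any-pixel rule credits partial overlaps", {
  gold <- matrix(0L, 10, 10)
  gold[3, 1:10] <- 1L                       # one 10-px gold object
  pred <- matrix(0L, 10, 10)
  pred[3:7, 5] <- 1L                        # overlaps 1 gold px, 4 outside
  ev <- evaluate_segmentation(pred, gold, 100)
  expect_equal(ev$object_tp, 1L)
  expect_equal(ev$object_fn, 0L)
  expect_equal(ev$object_fp, 0L)            # overlapping object is not FP
  expect_equal(ev$pixel_sensitivity, 0.1)
  expect_equal(ev$pixel_fp, 4L)
  expect_equal(ev$pixel_tn, 100L - 1L - 4L - 9L)
})

test_that("evaluation equals the brute-force confusion oracle", {
  set.seed(23)
  for (i in 1:40) {
    pred <- random_mask(16L, sample(0:3, 1))
    gold <- random_mask(16L, sample(1:3, 1))
    ev <- evaluate_segmentation(pred, gold, 256)
    or <- oracle_confusion(pred, gold, 256)
    expect_equal(ev[names(or)], or, ignore_attr = TRUE)
  }
})

test_that("confusion counts always partition the FOV", {
  set.seed(29)
  for (i in 1:10) {
    pred <- random_mask(24L)
    gold <- random_mask(24L)
    ev <- evaluate_segmentation(pred, gold, 576)
    expect_equal(ev$pixel_tp + ev$pixel_fp + ev$pixel_fn + ev$pixel_tn, 576)
    expect_equal(ev$object_tp + ev$object_fn,
                 length(setdiff(unique(as.vector(gold)), 0L)))
  }
})

test_that("sensitivity maps colour the confusion classes", {
  gold <- matrix(0L, 10, 10)
  gold[3, 1:10] <- 1L
  pred <- matrix(0L, 10, 10)
  pred[3:7, 5] <- 1L
  sm <- sensitivity_map(pred, gold)
  green <- sm[, , 2] == 1 & sm[, , 1] == 0 & sm[, , 3] == 0
  blue  <- sm[, , 3] == 1 & sm[, , 1] == 0 & sm[, , 2] == 0
  red   <- sm[, , 1] == 1 & sm[, , 2] == 0 & sm[, , 3] == 0
  expect_equal(sum(green), 1L)
  expect_equal(sum(blue), 9L)
  expect_equal(sum(red), 4L)
  sm2 <- sensitivity_map(gold, gold)
  expect_equal(sum(sm2[, , 3] == 1 & sm2[, , 1] == 0), 0L)  # no blue
  sm3 <- sensitivity_map(matrix(0L, 10, 10), gold)
  expect_equal(sum(sm3[, , 3] == 1), sum(gold > 0L))
  expect_error(sensitivity_map(pred, matrix(0L, 5, 5)),
               class = "scmseg_shape_error")
})
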