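test_that("disk objects have the analytic shape features", {
  d <- disk_mask(25L)
  img <- matrix(0.2, nrow(d), ncol(d))
  img[d > 0L] <- 0.7                        # uniform disk intensity
  f <- extract_features(d, img)
  expect_equal(nrow(f), 1L)
  expect_length(setdiff(names(f), "label"), 8L)
  expect_lt(f$eccentricity, 0.05)
  expect_gt(f$solidity, 0.97)
  expect_equal(f$extent, pi / 4, tolerance = 0.05)
  expect_equal(f$fg_std, 0)
  expect_equal(f$fg_mean, 0.7)
  expect_equal(f$bg_mean, 0.2)              # ring sits in the background
})

test_that("degenerate shapes follow the documented conventions", {
  m <- matrix(0L, 9, 9)
  m[5, 5] <- 1L                             # 1-px object
  m[2, 2:6] <- 2L                           # collinear 5-px object
  f <- extract_features(m, matrix(0.5, 9, 9))
  expect_equal(f$area, c(1, 5))
  expect_equal(f$eccentricity[1], 0)
  expect_equal(f$extent[1], 1)
  expect_equal(f$solidity[1], 1)
  expect_equal(f$eccentricity[2], 1)
  expect_equal(f$solidity[2], 1)
})

test_that("solidity uses the rasterized convex-hull area", {
  set.seed(40)
  for (i in 1:15) {
    # random blobby object: union of a few disks
    m <- matrix(0L, 40, 40)
    for (k in 1:3) {
      at <- sample(10:30, 2)
      d2 <- outer((1:40 - at[1])^2, (1:40 - at[2])^2, "+")
      m[d2 <= sample(4:25, 1)] <- 1L
    }
    f <- extract_features(m, matrix(0.5, 40, 40))
    idx <- which(m == 1L)
    hull <- oracle_convex_area((idx - 1L) %% 40L + 1L,
                               (idx - 1L) %/% 40L + 1L)
    expect_equal(f$solidity, min(1, sum(m) / hull), tolerance = 1e-8)
  }
})

test_that("feature extraction is permutation-equivariant under relabeling", {
  set.seed(41)
  m <- random_mask(28L, 3L)
  img <- matrix(runif(28 * 28), 28, 28)
  f1 <- extract_features(m, img)
  # swap labels 1 and 3
  m2 <- m
  m2[m == 1L] <- 3L
  m2[m == 3L] <- 1L
  f2 <- extract_features(m2, img)
  expect_equal(f1[f1$label == 1L, -1], f2[f2$label == 3L, -1],
               ignore_attr = TRUE)
  expect_equal(f1[f1$label == 3L, -1], f2[f2$label == 1L, -1],
               ignore_attr = TRUE)
  expect_equal(nrow(extract_features(matrix(0L, 10, 10),
                                     matrix(0.1, 10, 10))), 0L)
})

make_cluster_features <- function(n, gap = 6) {
  half <- n %/% 2
  base <- data.frame(area = rnorm(n, 100, 5),
                     eccentricity = runif(n, 0, 0.5),
                     extent = runif(n, 0.5, 0.9),
                     solidity = runif(n, 0.8, 1),
                     fg_mean = rnorm(n, 0.5, 0.02),
                     fg_std = rnorm(n, 0.05, 0.005),
                     bg_mean = rnorm(n, 0.25, 0.02),
                     bg_std = rnorm(n, 0.05, 0.005))
  lab <- rep(c(TRUE, FALSE), c(half, n - half))
  base$fg_mean[!lab] <- base$fg_mean[!lab] - gap * 0.02
  base$area[!lab] <- base$area[!lab] - gap * 5
  list(features = base, labels = lab)
}

test_that("well-separated clusters train to near-perfect held-out accuracy", {
  set.seed(43)
  d <- make_cluster_features(1800L)
  clf <- train_classifier(d$features, d$labels, seed = 5)
  expect_gte(clf$meta$test_acc, 0.95)
  expect_equal(unname(clf$meta$split), c(1260L, 270L, 270L))  # 70/15/15
})

test_that("training is reproducible under a fixed seed", {
  set.seed(44)
  d <- make_cluster_features(200L)
  c1 <- train_classifier(d$features, d$labels, seed = 9)
  c2 <- train_classifier(d$features, d$labels, seed = 9)
  expect_identical(c1$meta, c2$meta)
  expect_identical(c1$net$wts, c2$net$wts)
})

test_that("degenerate training inputs are rejected", {
  set.seed(45)
  d <- make_cluster_features(100L)
  expect_error(train_classifier(d$features, rep(TRUE, 100L), seed = 1),
               class = "scmseg_single_class")
  expect_error(train_classifier(d$features[1:10, ], d$labels[1:10], seed = 1),
               class = "scmseg_too_few_samples")
})

test_that("object filtering removes only classified-false objects", {
  set.seed(46)
  d <- make_cluster_features(400L)
  clf <- train_classifier(d$features, d$labels, seed = 3)
  # masks: two nucleus-like disks and nothing else
  m <- matrix(0L, 40, 40)
  dm <- disk_mask(5L, pad = 1L)
  m[2:14, 2:14][dm > 0L] <- 1L
  m[22:34, 22:34][dm > 0L] <- 2L
  img <- matrix(0.25, 40, 40)
  img[m > 0L] <- 0.5
  out <- filter_objects(clf, m, img)
  # never creates pixels
  expect_true(all(out[m == 0L] == 0L))
  # empty masks pass through
  e <- filter_objects(clf, matrix(0L, 10, 10), matrix(0.2, 10, 10))
  expect_equal(max(e), 0L)
  expect_error(filter_objects(structure(list(), class = "lm"), m, img),
               class = "scmseg_untrained_error")
})

test_that("ground-truth matching follows the any-pixel rule", {
  pred <- matrix(0L, 10, 10)
  pred[1:2, 1:2] <- 1L
  pred[8:9, 8:9] <- 2L
  gold <- matrix(0L, 10, 10)
  gold[2, 2] <- 1L                          # touches pred object 1 only
  expect_equal(match_objects_to_truth(pred, gold), c(TRUE, FALSE))
})

test_that("classifier round-trips through serialization", {
  set.seed(47)
  d <- make_cluster_features(200L)
  clf <- train_classifier(d$features, d$labels, seed = 2)
  path <- tempfile(fileext = ".json")
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  p1 <- predict(clf, d$features)
  p2 <- predict(clf2, d$features)
  expect_equal(p1, p2, tolerance = 1e-10)
})
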