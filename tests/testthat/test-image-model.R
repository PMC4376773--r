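test_that("centre placement honours count, separation and frame bounds", {
  expect_equal(nrow(place_nonoverlapping_centers(0L, 100, 12)), 0L)
  set.seed(1)
  min_sep <- 2 * ceiling(sqrt(90 / pi))
  ctr <- place_nonoverlapping_centers(60L, 250, min_sep)
  expect_equal(nrow(ctr), 60L)
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  expect_true(all(d >= min_sep))           # exhaustive pairwise check
  margin <- ceiling(min_sep / 2)
  expect_true(all(ctr >= 1 + margin & ctr <= 250 - margin))
})

test_that("geometrically impossible placements fail cleanly", {
  set.seed(1)
  expect_error(place_nonoverlapping_centers(2L, 10, 20),
               class = "scmseg_placement_error")
  expect_error(place_nonoverlapping_centers(500L, 40, 10,
                                            max_attempts = 2000L),
               class = "scmseg_placement_error")
})

test_that("generated frames have exact object counts and footprints", {
  fr <- generate_frame(small_config(seed = 9))
  labs <- setdiff(unique(as.vector(fr$labels)), 0L)
  expect_length(labs, 45L)
  areas <- tabulate(fr$labels[fr$labels > 0L])
  expect_true(all(abs(areas - 90L) <= 1L))
  expect_true(all(fr$image >= 0 & fr$image <= 1))
})

test_that("generation is bit-identical under a fixed config and seed", {
  a <- generate_frame(small_config(seed = 4))
  b <- generate_frame(small_config(seed = 4))
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c <- generate_frame(small_config(seed = 5))
  expect_false(identical(a$image, c$image))
})

test_that("background-only configuration yields pure noise and empty labels", {
  cfg <- small_config(n_objects = 0L, seed = 2)
  fr <- generate_frame(cfg)
  expect_equal(max(fr$labels), 0L)
  tol <- 3 * sqrt(cfg$background_variance) / cfg$frame_size
  expect_lt(abs(mean(fr$image) - cfg$background_mean), tol * 10)
})

test_that("measured contrast matches constant-region arithmetic", {
  img <- matrix(0.4, 10, 10)
  lab <- matrix(0L, 10, 10)
  lab[3:5, 3:5] <- 1L
  img[lab > 0L] <- 0.8
  expect_equal(measure_contrast(img, lab), 2.0)
  expect_equal(measure_contrast(matrix(0.5, 10, 10), lab), 1.0)
  expect_error(measure_contrast(img, matrix(0L, 10, 10)),
               class = "scmseg_degenerate_error")
  expect_error(measure_contrast(img, matrix(1L, 10, 10)),
               class = "scmseg_degenerate_error")
})

test_that("realized contrast tracks the configured level across the sweep", {
  measured <- vapply(c(1.6, 2.0, 2.6), function(ct) {
    fr <- generate_frame(small_config(contrast = ct, seed = 21))
    measure_contrast(fr$image, fr$labels)
  }, 1.0)
  expect_true(all(abs(measured - c(1.6, 2.0, 2.6)) < 0.05))
  expect_true(all(diff(measured) > 0))     # strictly increasing
})

test_that("invalid model configurations are rejected", {
  expect_error(image_model_config(contrast = 1.0),
               class = "scmseg_config_error")
  expect_error(image_model_config(frame_size = 100, n_objects = 100,
                                  object_area = 90),
               class = "scmseg_config_error")
  expect_error(image_model_config(background_mean = 0.9,
                                  background_variance = 0.01),
               class = "scmseg_config_error")
  expect_error(image_model_config(pixel_scale = 0),
               class = "scmseg_config_error")
})
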