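test_that("zero-input neuron never accumulates activity or fires", {
  p <- scm_parameters()
  st <- scm_state(c(1L, 1L))
  S <- matrix(0, 1, 1)
  for (i in 1:20) st <- scm_iterate(st, S, p)
  expect_equal(st$U[1, 1], 0)
  expect_false(st$fired[1, 1])
  tm <- scm_time_matrix(S, p)
  expect_equal(tm[1, 1], p$max_iter + 1L)
})

test_that("isolated saturated neuron follows the scalar recurrence", {
  p <- scm_parameters(W = matrix(0, 3, 3))
  st <- scm_state(c(1L, 1L))
  S <- matrix(1, 1, 1)
  st <- scm_iterate(st, S, p)
  expect_equal(st$U[1, 1], 1)          # S (1 - f^1) / (1 - f)
  expect_equal(st$Y[1, 1], 0)          # 1 < E(0) = 1 is not a pulse
  st <- scm_iterate(st, S, p)
  expect_equal(st$U[1, 1], 1.928)      # S (1 - f^2) / (1 - f)
  expect_equal(st$Y[1, 1], 1)          # 1.928 > E(1) = 1.078
  expect_equal(st$first_fire[1, 1], 2L)
})

test_that("firing times match the scalar recurrence oracle without coupling", {
  p <- scm_parameters(W = matrix(0, 3, 3))
  S_vals <- seq(0.02, 1, length.out = 50)
  S <- matrix(S_vals, 5, 10)
  tm <- scm_time_matrix(S, p)
  expected <- vapply(S_vals, oracle_fire_time, 1L)
  expect_equal(as.vector(tm), expected)
  # S = 1 fires at 2, S = 0.5 at 3
  expect_equal(tm[S == 1], 2L)
  expect_equal(tm[S == 0.5], 3L)
})

test_that("without coupling, brighter pixels never fire later", {
  p <- scm_parameters(W = matrix(0, 3, 3))
  S_vals <- sort(runif(64))
  tm <- scm_time_matrix(matrix(S_vals, 8, 8), p)
  expect_true(all(diff(as.vector(tm)) <= 0L))
})

test_that("uniform image fires in a single iteration", {
  p <- scm_parameters()
  tm <- scm_time_matrix(matrix(0.8, 12, 12), p)
  expect_length(unique(as.vector(tm)), 1L)
  expect_lt(tm[1, 1], p$max_iter + 1L)
})

test_that("neurons fire at most once and contribute output only when firing", {
  set.seed(42)
  p <- scm_parameters()
  S <- matrix(runif(100, 0.3, 1), 10, 10)
  st <- scm_state(dim(S))
  n_firings <- matrix(0L, 10, 10)
  for (i in 1:25) {
    st <- scm_iterate(st, S, p)
    n_firings <- n_firings + (st$Y > 0)
    # output is only nonzero at the firing iteration itself
    expect_true(all(st$first_fire[st$Y > 0] == st$n))
  }
  expect_true(all(n_firings <= 1L))
  expect_true(all(st$fired[n_firings == 1L]))
})

test_that("vectorised iterate and compiled time matrix agree", {
  set.seed(7)
  p <- scm_parameters(max_iter = 25L)
  S <- matrix(runif(20 * 20), 20, 20)
  tm <- scm_time_matrix(S, p)
  st <- scm_state(dim(S))
  for (i in seq_len(p$max_iter)) st <- scm_iterate(st, S, p)
  ff <- st$first_fire
  ff[is.na(ff)] <- p$max_iter + 1L
  expect_equal(as.vector(tm), as.vector(ff))
})

test_that("neighbour coupling never delays firing", {
  set.seed(11)
  S <- matrix(runif(15 * 15, 0.3, 1), 15, 15)
  tm0 <- scm_time_matrix(S, scm_parameters(W = matrix(0, 3, 3)))
  tm1 <- scm_time_matrix(S, scm_parameters())
  expect_true(all(tm1 <= tm0))
})

test_that("time matrices are deterministic", {
  set.seed(5)
  S <- matrix(runif(30 * 30), 30, 30)
  expect_identical(scm_time_matrix(S), scm_time_matrix(S))
})

test_that("malformed inputs are rejected", {
  p <- scm_parameters()
  expect_error(scm_time_matrix(matrix(1.5, 2, 2), p),
               class = "scmseg_normalization_error")
  expect_error(scm_iterate(scm_state(c(3L, 3L)), matrix(0.5, 2, 2), p),
               class = "scmseg_shape_error")
  expect_error(scm_parameters(f = 1.2), class = "scmseg_config_error")
  expect_error(scm_parameters(W = matrix(1, 3, 3)),
               class = "scmseg_config_error")
})
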