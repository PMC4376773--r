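#' Spiking cortical model parameters
#'
#' Parameter set of the spiking cortical model (SCM) neuron, a simplified
#' pulse-coupled neural network. Each pixel is one neuron with internal
#' activity U, dynamic threshold E and binary output Y, updated per iteration
#' n as
#' \deqn{U(n) = f U(n-1) + S \sum_{kl} W_{kl} Y_{kl}(n-1) + S}
#' \deqn{Y(n) = 1 \textrm{ if } U(n) > E(n-1), \textrm{ else } 0}
#' \deqn{E(n) = g E(n-1) + h Y(n)}
#' where S is the input intensity in [0, 1] and W weights the outputs of the
#' 8-neighbours. The defaults are the values tuned for nuclei in reflectance
#' confocal images. Neurons are fire-once: after a neuron pulses its output
#' is frozen at 0 and its state is no longer updated.
#'
#' Note that with g > 1 the threshold grows geometrically while U is bounded
#' by S/(1-f), so sufficiently dim pixels never pulse; such pixels receive
#' the sentinel value in the time matrix.
#'
#' @param f decay coefficient of the internal activity (0 < f < 1).
#' @param g decay coefficient of the dynamic threshold (> 0).
#' @param h amplitude added to the threshold when a neuron fires (> 0).
#' @param W 3x3 nonnegative neighbour weight matrix with zero centre.
#' @param max_iter iteration cap; unfired pixels get sentinel max_iter + 1.
#' @return an object of class `scm_parameters`.
#' @export
scm_parameters <- function(f = 0.928, g = 1.078, h = 1.4,
                           W = matrix(c(0.0125, 0.025, 0.0125,
                                        0.025,  0,     0.025,
                                        0.0125, 0.025, 0.0125), 3, 3),
                           max_iter = 40L) {
  if (!(is.numeric(f) && length(f) == 1L && f > 0 && f < 1))
    stop2("'f' must be a scalar in (0, 1)", "scmseg_config_error")
  if (!(is.numeric(g) && length(g) == 1L && g > 0))
    stop2("'g' must be a positive scalar", "scmseg_config_error")
  if (!(is.numeric(h) && length(h) == 1L && h > 0))
    stop2("'h' must be a positive scalar", "scmseg_config_error")
  if (!(is.matrix(W) && all(dim(W) == c(3L, 3L)) && all(W >= 0) &&
        W[2, 2] == 0))
    stop2("'W' must be a 3x3 nonnegative matrix with zero centre",
          "scmseg_config_error")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop2("'max_iter' must be >= 1", "scmseg_config_error")
  structure(list(f = f, g = g, h = h, W = W, max_iter = max_iter),
            class = "scm_parameters")
}

check_normalized <- function(S) {
  if (min(S) < 0 || max(S) > 1)
    stop2("input image must be normalized to [0, 1]",
          "scmseg_normalization_error")
  invisible(TRUE)
}

#' Initial SCM network state
#'
#' U and Y start at 0 and the threshold E at 1, so with inputs in [0, 1] the
#' brightest pixels pulse first and the pulse order follows intensity.
#'
#' @param dims integer vector c(rows, cols).
#' @return an object of class `scm_state`.
#' @export
scm_state <- function(dims) {
  z <- matrix(0, dims[1], dims[2])
  structure(list(U = z, E = z + 1, Y = z,
                 fired = matrix(FALSE, dims[1], dims[2]),
                 first_fire = matrix(NA_integer_, dims[1], dims[2]),
                 n = 0L),
            class = "scm_state")
}

# zero-padded 3x3 weighted sum of the neighbour outputs
weighted_neighbor_sum <- function(Y, W) {
  nr <- nrow(Y); nc <- ncol(Y)
  out <- matrix(0, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      w <- W[di + 2, dj + 2]
      if (w == 0) next
      if (max(1, 1 - di) > min(nr, nr - di) ||
          max(1, 1 - dj) > min(nc, nc - dj)) next
      ti <- max(1, 1 - di):min(nr, nr - di)
      tj <- max(1, 1 - dj):min(nc, nc - dj)
      out[ti, tj] <- out[ti, tj] + w * Y[ti + di, tj + dj]
    }
  }
  out
}

#' Advance the SCM network by one iteration
#'
#' Reference (vectorised R) implementation of a single network update. The
#' heavy lifting for whole images is done by [scm_time_matrix()]; this
#' function exposes the per-iteration state for inspection and testing.
#'
#' @param state an `scm_state`.
#' @param S input image, normalized to [0, 1], same shape as the state.
#' @param params an `scm_parameters` object.
#' @return the updated `scm_state` (iteration counter advanced by one).
#' @export
scm_iterate <- function(state, S, params = scm_parameters()) {
  stopifnot(inherits(state, "scm_state"), inherits(params, "scm_parameters"))
  S <- as_intensity_matrix(S, "S")
  check_same_shape(state$U, S, c("state", "S"))
  check_normalized(S)
  nb <- weighted_neighbor_sum(state$Y, params$W)
  U <- params$f * state$U + S * nb + S
  U[state$fired] <- state$U[state$fired]            # frozen after firing
  fire <- (U > state$E) & !state$fired              # compare against E(n-1)
  Y <- matrix(0, nrow(S), ncol(S))
  Y[fire] <- 1
  E <- params$g * state$E + params$h * Y
  E[state$fired] <- state$E[state$fired]
  n <- state$n + 1L
  ff <- state$first_fire
  ff[fire] <- n
  structure(list(U = U, E = E, Y = Y, fired = state$fired | fire,
                 first_fire = ff, n = n),
            class = "scm_state")
}

#' Compute the SCM time matrix of an image
#'
#' Runs the fire-once SCM until every neuron has pulsed or `max_iter` is
#' reached and records, per pixel, the iteration at which its neuron first
#' pulsed. Bright image features pulse early, dim ones late; pixels whose
#' neurons never pulse receive the sentinel value `max_iter + 1`. The time
#' matrix is the composite image on which both the iterative filter and the
#' segmentation mask construction operate.
#'
#' @param S input image, normalized to [0, 1].
#' @param params an `scm_parameters` object.
#' @return integer matrix of first-pulse iteration indices with attribute
#'   `sentinel` (= `max_iter + 1`).
#' @export
scm_time_matrix <- function(S, params = scm_parameters()) {
  stopifnot(inherits(params, "scm_parameters"))
  S <- as_intensity_matrix(S, "S")
  check_normalized(S)
  tm <- scm_time_matrix_cpp(S, params$f, params$g, params$h, params$W,
                            params$max_iter)
  attr(tm, "sentinel") <- params$max_iter + 1L
  tm
}

tm_sentinel <- function(tm, params = NULL) {
  s <- attr(tm, "sentinel")
  if (is.null(s)) s <- if (is.null(params)) max(tm) else params$max_iter + 1L
  as.integer(s)
}
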