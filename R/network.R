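#' Linear network outputs
#'
#' The network is a single linear layer: `u = W x`, applied column-wise when
#' `x` is a batch.
#'
#' @param W `N_u x N_x` synaptic strength matrix.
#' @param x input vector of length `N_x` or an `N_x x T` batch.
#' @return Output vector of length `N_u` or an `N_u x T` batch.
#' @export
outputs <- function(W, x) {
  W <- as.matrix(W)
  if (is.matrix(x)) {
    if (nrow(x) != ncol(W)) stop_dim("nrow(x) must equal ncol(W)")
    W %*% x
  } else {
    if (length(x) != ncol(W)) stop_dim("length(x) must equal ncol(W)")
    drop(W %*% x)
  }
}

#' Global gating factor
#'
#' The scalar third factor of the learning rule: the summed negative log
#' prior density of the outputs, `E(u) = sum_i -log p0(u_i)`. For a batch it
#' is computed per column.
#'
#' @param u output vector or `N_u x T` batch.
#' @param prior an [new_prior()] object.
#' @return A scalar, or a length-`T` vector for a batch.
#' @export
global_factor <- function(u, prior) {
  stopifnot(inherits(prior, "eghr_prior"))
  e <- prior$neg_log_density(u)
  if (is.matrix(u)) colSums(e) else sum(e)
}

#' Calibrated gating threshold
#'
#' The threshold `E0` that separates the Hebbian regime (`E(u) < E0`) from
#' the anti-Hebbian regime. The output scale matches the source scale when
#' `E0 = <-log p0(s)> + 1`, i.e. `n_sources * per_unit_entropy + 1`; for the
#' unit Laplace prior the per-unit entropy is `1 + log(2)/2`.
#'
#' @param prior an [new_prior()] object with an analytic `per_unit_entropy`.
#' @param n_sources number of output units the threshold is calibrated for.
#' @return The scalar threshold.
#' @export
default_E0 <- function(prior, n_sources) {
  stopifnot(inherits(prior, "eghr_prior"))
  if (!is.numeric(n_sources) || n_sources < 0 || n_sources != floor(n_sources)) {
    stop_bad_arg("n_sources must be a non-negative integer")
  }
  if (!is.finite(prior$per_unit_entropy)) {
    stop_bad_arg(paste0(
      "prior '", prior$name, "' has no analytic per-unit entropy; ",
      "estimate <-log p0(s)> by Monte Carlo and pass E0 explicitly"))
  }
  n_sources * prior$per_unit_entropy + 1
}

#' One error-gated Hebbian update
#'
#' The three-factor rule: `W' = W + eta * <(E0 - E(u)) g(u) x^T>` with
#' `u = W x`, the expectation realized as the mean over the columns of the
#' batch `X`. The update is the negative stochastic gradient of the cost
#' `L = <(E(u) - E0)^2>/2` (see [eghr_cost()]); it is Hebbian whenever the
#' global factor is below threshold and anti-Hebbian above it.
#'
#' @param W `N_u x N_x` synaptic matrix.
#' @param X `N_x x T` input batch (a vector is treated as one column).
#' @param prior an [new_prior()] object.
#' @param E0 gating threshold (see [default_E0()]).
#' @param eta learning rate.
#' @return The updated matrix `W'`.
#' @export
eghr_step <- function(W, X, prior, E0, eta) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  if (ncol(X) == 0) stop_bad_arg("batch must be non-empty")
  if (!is.numeric(eta) || eta <= 0) stop_bad_arg("eta must be positive")
  U <- W %*% X
  pref <- E0 - global_factor(U, prior)      # length T
  G <- prior$g(U)
  dW <- (G * rep(pref, each = nrow(U))) %*% t(X) / ncol(X)
  W2 <- W + eta * dW
  if (!all(is.finite(W2))) {
    abort(sprintf(
      "non-finite synaptic update (max|W|=%.3g, max|prefactor|=%.3g); reduce eta",
      max(abs(W)), max(abs(pref))), class = "eghr_divergence")
  }
  W2
}

#' Cost of output dependency
#'
#' `L = <(E(u) - E0)^2>/2`, averaged over the columns of the output batch.
#' Minimizing `L` by gradient descent yields the error-gated Hebbian update.
#'
#' @param U `N_u x T` output batch (a vector is treated as one column).
#' @inheritParams eghr_step
#' @return Non-negative scalar.
#' @export
eghr_cost <- function(U, prior, E0) {
  if (!is.matrix(U)) U <- matrix(U, ncol = 1)
  if (ncol(U) == 0) stop_bad_arg("batch must be non-empty")
  mean((global_factor(U, prior) - E0)^2) / 2
}

#' Initialize a network state
#'
#' Synaptic strengths start from small i.i.d. normal values.
#'
#' @param n_u number of output units.
#' @param n_x number of input units.
#' @param seed integer seed; `NULL` for the ambient RNG.
#' @param scale entry standard deviation of the initial `W` (default 0.1).
#' @return An object of class `eghr_network`: list with `W`, `step`,
#'   `rng_seed`.
#' @export
init_network <- function(n_u, n_x, seed = NULL, scale = 0.1) {
  check_count(n_u, "n_u"); check_count(n_x, "n_x")
  if (n_u > n_x) {
    warn("n_u > n_x: more outputs than inputs is an unusual configuration")
  }
  if (scale == 0) warn("scale = 0 gives a zero initial W (degenerate)")
  W <- with_seed_if(seed, matrix(rnorm(n_u * n_x, sd = scale), n_u, n_x))
  structure(list(W = W, step = 0L, rng_seed = seed), class = "eghr_network")
}

#' @export
print.eghr_network <- function(x, ...) {
  cat(sprintf("<eghr_network> W: %d x %d, step %d\n",
              nrow(x$W), ncol(x$W), x$step))
  invisible(x)
}
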