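#' Conventional ICA baselines
#'
#' Multiplicative-update ICA algorithms of the form
#' `W' = (I + eta F(u, x)) W`, included as the contrast class to the
#' error-gated Hebbian rule: because each update multiplies `W` on the left
#' by an `N_u x N_u` factor, every iterate stays inside the row space of the
#' initial matrix `W0` (see [row_space_preserved()]) and the class cannot
#' perform dimensionality reduction, only separate the already-compressed
#' signal `W0 x`.
#'
#' `natural_gradient_step()` uses `F = I - <g(u) u^T>` (which also
#' represents the infomax rule, sharing its fixed points and stability);
#' `nonholonomic_step()` uses `F = <diag(g(u) * u) - g(u) u^T>`, whose
#' diagonal is exactly zero.
#'
#' @param W `N_u x N_x` unmixing matrix (square in the classical setting;
#'   rectangular allowed to demonstrate the row-space limitation).
#' @param X `N_x x T` input batch (a vector is treated as one column).
#' @param prior an [new_prior()] object supplying the nonlinearity `g`.
#' @param eta learning rate.
#' @return The updated matrix.
#' @export
natural_gradient_step <- function(W, X, prior, eta) {
  F_mat <- diag(nrow(W)) - score_outer(W, X, prior)
  multiplicative_update(W, F_mat, eta)
}

#' @rdname natural_gradient_step
#' @export
nonholonomic_step <- function(W, X, prior, eta) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  U <- W %*% X
  G <- prior$g(U)
  so <- tcrossprod(G, U) / ncol(X)
  F_mat <- diag(rowMeans(G * U), nrow(W)) - so
  multiplicative_update(W, F_mat, eta)
}

score_outer <- function(W, X, prior) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  U <- W %*% X
  tcrossprod(prior$g(U), U) / ncol(X)
}

multiplicative_update <- function(W, F_mat, eta) {
  if (!is.numeric(eta) || eta < 0) stop_bad_arg("eta must be non-negative")
  W2 <- (diag(nrow(W)) + eta * F_mat) %*% W
  if (!all(is.finite(W2))) {
    abort("non-finite baseline update; reduce eta", class = "eghr_divergence")
  }
  W2
}

#' ICA mixture model
#'
#' A bank of `k_count` ICA models for multi-context separation: each model
#' `k` keeps the pseudo-inverse `(W^k)+` of its unmixing matrix and updates
#' it by `(W^k)+ <- (W^k)+ (I + eta z_k (I - g(u) u^T))` with `u` computed
#' from model `k`'s own unmixing matrix and `z_k` the responsibility of
#' model `k` for the current sample. Because the update multiplies the
#' pseudo-inverse on the right by an `N_u x N_u` factor, the column space of
#' each `(W^k)+` is preserved — the transpose analogue of the row-space
#' limitation.
#'
#' `responsibilities()` uses the standard mixture likelihood
#' `z_k` proportional to `|det W^k| prod_i p0((W^k x)_i)` (adopted from the
#' ICA-mixture literature; the quoted update law leaves it unspecified),
#' normalized to sum to one; when every likelihood underflows to zero the
#' responsibilities fall back to uniform with a warning.
#'
#' @param W_list list of initial square `N_u x N_u` unmixing matrices.
#' @return `ica_mixture_state()`: an object of class `ica_mixture` holding
#'   the pseudo-inverse list.
#' @export
ica_mixture_state <- function(W_list) {
  stopifnot(is.list(W_list), length(W_list) >= 1)
  pinvs <- lapply(W_list, function(W) {
    W <- as.matrix(W)
    if (nrow(W) != ncol(W)) stop_bad_arg("mixture models must be square")
    solve(W)
  })
  structure(list(pinv_W_list = pinvs, k_count = length(pinvs)),
            class = "ica_mixture")
}

#' @rdname ica_mixture_state
#' @param state an `ica_mixture` state.
#' @param x single input vector (length `N_u` in the square setting).
#' @param prior an [new_prior()] object.
#' @export
responsibilities <- function(x, state, prior) {
  stopifnot(inherits(state, "ica_mixture"))
  loglik <- vapply(state$pinv_W_list, function(P) {
    W <- solve(P)
    u <- drop(W %*% x)
    determinant(W, logarithm = TRUE)$modulus - sum(prior$neg_log_density(u))
  }, numeric(1))
  m <- max(loglik)
  if (!is.finite(m)) {
    warn("all mixture likelihoods vanished; using uniform responsibilities")
    return(rep(1 / state$k_count, state$k_count))
  }
  z <- exp(loglik - m)
  z / sum(z)
}

#' @rdname ica_mixture_state
#' @param z responsibility vector (defaults to [responsibilities()]).
#' @param eta learning rate.
#' @export
ica_mixture_step <- function(state, x, prior, eta, z = NULL) {
  stopifnot(inherits(state, "ica_mixture"))
  if (is.null(z)) z <- responsibilities(x, state, prior)
  n <- length(x)
  state$pinv_W_list <- lapply(seq_len(state$k_count), function(k) {
    P <- state$pinv_W_list[[k]]
    if (z[k] == 0) return(P)
    W <- solve(P)
    u <- drop(W %*% x)
    factor_k <- diag(n) + eta * z[k] * (diag(n) - tcrossprod(prior$g(u), u))
    P2 <- P %*% factor_k
    if (!all(is.finite(P2)) || !is.finite(determinant(P2)$modulus)) {
      abort("singular pseudo-inverse update in the ICA mixture",
            class = "eghr_divergence")
    }
    P2
  })
  state
}

#' Does a matrix stay in the row space of another?
#'
#' `TRUE` when every row of `W` lies in the row space of `W0` (within a
#' relative singular-value tolerance): the numerical rank of the vertically
#' stacked pair equals the rank of `W0` alone. The multiplicative ICA
#' baselines satisfy this for any number of steps from `W0`; the error-gated
#' rule with redundant inputs does not, which is what lets it reduce
#' dimensionality.
#'
#' @param W,W0 matrices with the same number of columns.
#' @param tol relative singular-value tolerance.
#' @return Logical scalar.
#' @export
row_space_preserved <- function(W, W0, tol = 1e-8) {
  W <- as.matrix(W); W0 <- as.matrix(W0)
  if (ncol(W) != ncol(W0)) stop_dim("W and W0 must have the same ncol")
  numeric_rank(rbind(W, W0), tol = tol) == numeric_rank(W0, tol = tol)
}
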