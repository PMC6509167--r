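#' Existence of a multi-context BSS solution
#'
#' A synaptic matrix solving every context at once (`W A^(k)` a signed
#' permutation for all `k`) exists for generic mixings if and only if the
#' horizontally concatenated block `(A^(1), ..., A^(C))` has full column
#' rank `C * N_s`. This implies the capacity conditions `N_x >= C * N_s`
#' (inputs at least contexts times sources) and `N_u >= N_s`.
#'
#' @param A_list list of `N_x x N_s` context mixing matrices.
#' @param n_u output dimension (optional; reported against `N_u >= N_s`).
#' @param tol relative singular-value tolerance for the numerical rank.
#' @return A list: `exists` (logical), `rank`, `required_rank`,
#'   `capacity_ok` (`N_x >= C * N_s`), `output_ok` (`N_u >= N_s`, `NA` when
#'   `n_u` is missing).
#' @export
multicontext_solution_exists <- function(A_list, n_u = NULL, tol = 1e-10) {
  if (!is.list(A_list) || length(A_list) == 0) {
    stop_bad_arg("A_list must be a non-empty list of matrices")
  }
  A_list <- lapply(A_list, as.matrix)
  n_x <- nrow(A_list[[1]])
  n_s <- ncol(A_list[[1]])
  block <- do.call(cbind, A_list)
  required <- length(A_list) * n_s
  r <- numeric_rank(block, tol = tol)
  list(
    exists = (r == required),
    rank = r,
    required_rank = required,
    capacity_ok = n_x >= required,
    output_ok = if (is.null(n_u)) NA else n_u >= n_s
  )
}

#' Reference multi-context solution from the SVD
#'
#' Constructs a synaptic matrix `W` with `W A0 = Omega` (a prescribed signed
#' permutation) and `W A1 = O` exactly, provided the concatenated block
#' `(A0, A1)` has full column rank. Writing the singular value decomposition
#' `(A0, A1) = U S V^T` and splitting the rows of `V^T` between the `A0` and
#' `A1` columns, the solution is `W = (Omega, O) V S^{-1} U^T`; any valid
#' choice of the orthogonal completion gives the same products with `A0` and
#' `A1`, which is what is verified. The construction is self-checked by
#' direct multiplication on every call.
#'
#' @param A0 `N_x x N_s` time-invariant (or single-context) component.
#' @param A1 optional `N_x x N_R` component to be annihilated.
#' @param omega target signed permutation (`N_s x N_s`), default identity.
#' @param tol verification tolerance for the self-check.
#' @return The `N_s x N_x` matrix `W`.
#' @export
reference_solution <- function(A0, A1 = NULL, omega = NULL, tol = 1e-8) {
  A0 <- as.matrix(A0)
  n_s <- ncol(A0)
  if (is.null(omega)) omega <- diag(n_s)
  M <- if (is.null(A1)) A0 else cbind(A0, as.matrix(A1))
  if (numeric_rank(M) < ncol(M)) {
    ex <- multicontext_solution_exists(list(M))
    abort(sprintf(
      "no exact solution: (A0, A1) has rank %d < %d (full column rank required)",
      ex$rank, ncol(M)), class = "eghr_no_solution")
  }
  sv <- svd(M)
  target <- cbind(omega, matrix(0, n_s, ncol(M) - n_s))
  W <- target %*% sv$v %*% diag(1 / sv$d, length(sv$d)) %*% t(sv$u)
  # post-condition self-check
  err0 <- max(abs(W %*% A0 - omega))
  err1 <- if (is.null(A1)) 0 else max(abs(W %*% as.matrix(A1)))
  if (max(err0, err1) > tol) {
    abort(sprintf(
      "reference solution failed its self-check (errors %.3g, %.3g)",
      err0, err1), class = "eghr_no_solution")
  }
  W
}

#' Linear-stability coefficients of the BSS fixed point
#'
#' The curvature of the cost around a separating fixed point is governed by
#' per-unit coefficients `Phi_ii = cov[-log p0(s_i), g'(s_i) s_i^2]` and
#' cross terms
#' `Phi_ij = cov[-log p0(s_i), g'(s_i)] <s_j^2> + cov[-log p0(s_j), s_j^2] <g'(s_i)>`
#' (the unpaired factors entering as expectations). For the non-smooth
#' Laplace prior, `g'` is a distributional derivative; it is approximated by
#' replacing `sign(u)` with `tanh(u / beta)` (`beta = smoothing`) and, in
#' [phi_extrapolated()], extrapolating `beta -> 0` linearly.
#'
#' Analytic values are available for the matched cases: unit-Laplace sources
#' with the Laplace prior give `(Phi_ii, Phi_ij) = (0, 2)` (the
#' delta-function mass of `g'` sits where `s^2` vanishes, killing the
#' diagonal term, while `<g'> = 2` and `cov[sqrt(2)|s|, s^2] = 2` combine
#' with `cov[sqrt(2)|s|, g'] -> -2` to give 2 off-diagonal); unit-Gaussian
#' sources with the Gaussian prior give `(1, 1)`.
#'
#' @param prior an [new_prior()] object.
#' @param source_sampler function `n -> n` i.i.d. draws from one unit's
#'   source marginal (default: the prior's matched sampler).
#' @param n_units number of source units (coefficients are estimated per
#'   unit; units are i.i.d.).
#' @param method `"monte_carlo"` or `"analytic"` (matched Laplace/Gaussian
#'   only).
#' @param n_samples Monte-Carlo sample size per unit.
#' @param smoothing `beta` for the smoothed `g'` (required when `g'` is
#'   distributional).
#' @param seed integer seed; `NULL` for the ambient RNG.
#' @return An object of class `stability_coefficients`: `phi_diag` (length
#'   `n_units`), `phi_offdiag` (`n_units x n_units`, diagonal `NA`),
#'   `method`, `n_samples`.
#' @export
phi_coefficients <- function(prior, source_sampler = NULL, n_units = 2,
                             method = c("monte_carlo", "analytic"),
                             n_samples = 1e5, smoothing = 0.01, seed = NULL) {
  stopifnot(inherits(prior, "eghr_prior"))
  method <- match.arg(method)
  check_count(n_units, "n_units")
  if (method == "analytic") {
    vals <- switch(prior$name,
      laplace = c(diag = 0, off = 2),
      gaussian = c(diag = 1, off = 1),
      stop_bad_arg(paste0("no analytic coefficients for prior '", prior$name,
                          "'; use method = 'monte_carlo'"))
    )
    off <- matrix(vals[["off"]], n_units, n_units)
    diag(off) <- NA_real_
    return(structure(
      list(phi_diag = rep(vals[["diag"]], n_units), phi_offdiag = off,
           method = "analytic", n_samples = NULL),
      class = "stability_coefficients"))
  }
  if (is.null(source_sampler)) source_sampler <- prior$sampler
  if (is.null(source_sampler)) {
    stop_bad_arg("source_sampler required (prior has no matched sampler)")
  }
  if (is.null(prior$gprime)) stop_bad_arg("prior has no gprime")
  if (prior$name == "laplace" && smoothing <= 0) {
    stop_bad_arg("smoothing > 0 required for the non-smooth Laplace prior")
  }
  with_seed_if(seed, {
    s <- lapply(seq_len(n_units), function(i) source_sampler(n_samples))
    e <- lapply(s, prior$neg_log_density)
    gp <- lapply(s, function(si) prior$gprime(si, smoothing))
    phi_diag <- vapply(seq_len(n_units), function(i) {
      cov(e[[i]], gp[[i]] * s[[i]]^2)
    }, numeric(1))
    cov_e_gp <- vapply(seq_len(n_units),
                       function(i) cov(e[[i]], gp[[i]]), numeric(1))
    cov_e_s2 <- vapply(seq_len(n_units),
                       function(j) cov(e[[j]], s[[j]]^2), numeric(1))
    mean_s2 <- vapply(s, function(sj) mean(sj^2), numeric(1))
    mean_gp <- vapply(gp, mean, numeric(1))
    off <- outer(cov_e_gp, mean_s2) + outer(mean_gp, cov_e_s2, function(a, b) b * a)
    diag(off) <- NA_real_
    structure(
      list(phi_diag = phi_diag, phi_offdiag = off,
           method = "monte_carlo", n_samples = n_samples),
      class = "stability_coefficients")
  })
}

#' @rdname phi_coefficients
#' @param betas decreasing sequence of smoothing values; coefficients are
#'   fitted linearly in `beta` and reported at the `beta = 0` intercept.
#' @export
phi_extrapolated <- function(prior, source_sampler = NULL, n_units = 2,
                             betas = c(0.1, 0.03, 0.01), n_samples = 1e5,
                             seed = NULL) {
  ests <- lapply(seq_along(betas), function(k) {
    phi_coefficients(prior, source_sampler, n_units,
                     method = "monte_carlo", n_samples = n_samples,
                     smoothing = betas[k],
                     seed = if (is.null(seed)) NULL else seed + k)
  })
  intercept <- function(y) {
    if (length(betas) == 1) return(y[1])
    unname(coef(stats::lm(y ~ betas))[1])
  }
  phi_diag <- vapply(seq_len(n_units), function(i) {
    intercept(vapply(ests, function(e) e$phi_diag[i], numeric(1)))
  }, numeric(1))
  off <- matrix(NA_real_, n_units, n_units)
  for (i in seq_len(n_units)) for (j in seq_len(n_units)) {
    if (i != j) {
      off[i, j] <- intercept(
        vapply(ests, function(e) e$phi_offdiag[i, j], numeric(1)))
    }
  }
  structure(
    list(phi_diag = phi_diag, phi_offdiag = off,
         method = "monte_carlo", n_samples = n_samples),
    class = "stability_coefficients")
}

#' @export
print.stability_coefficients <- function(x, ...) {
  cat(sprintf("<stability_coefficients> (%s) Phi_ii: %s\n", x$method,
              paste(sprintf("%.3f", x$phi_diag), collapse = " ")))
  invisible(x)
}

#' Linear-stability verdict
#'
#' A separating fixed point is linearly stable when and only when every
#' `Phi_ii > -1` and every pair satisfies `Phi_ij * Phi_ji > 1`.
#'
#' @param phi a [phi_coefficients()] result.
#' @return A list: `stable` (logical), `violated_diag` (indices with
#'   `Phi_ii <= -1`), `violated_pairs` (two-column matrix of pairs with
#'   `Phi_ij * Phi_ji <= 1`).
#' @export
linear_stability <- function(phi) {
  stopifnot(inherits(phi, "stability_coefficients"))
  bad_diag <- which(phi$phi_diag <= -1)
  n <- length(phi$phi_diag)
  bad_pairs <- NULL
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      if (phi$phi_offdiag[i, j] * phi$phi_offdiag[j, i] <= 1) {
        bad_pairs <- rbind(bad_pairs, c(i, j))
      }
    }
  }
  list(
    stable = length(bad_diag) == 0 && is.null(bad_pairs),
    violated_diag = bad_diag,
    violated_pairs = bad_pairs
  )
}

#' Monte-Carlo residual of the learning rule at a candidate fixed point
#'
#' Estimates the Frobenius norm of the expected update
#' `<(E0 - E(u)) g(u) x^T>` under fresh matched sources mixed through the
#' given model. At a true separating solution the expectation is zero, so
#' the estimate decays as `O(1/sqrt(n_samples))`; at a generic `W` it
#' converges to a positive constant.
#'
#' @param W `N_u x N_x` synaptic matrix.
#' @param mixing an `eghr_mixing` object of kind `static`, or a bare mixing
#'   matrix.
#' @param prior an [new_prior()] object (its matched sampler generates the
#'   sources).
#' @param E0 gating threshold; default [default_E0()] for `nrow(W)` units.
#' @param n_samples Monte-Carlo batch size.
#' @param seed integer seed; `NULL` for the ambient RNG.
#' @return Non-negative scalar.
#' @export
fixed_point_residual <- function(W, mixing, prior, E0 = NULL,
                                 n_samples = 1e4, seed = NULL) {
  A <- if (inherits(mixing, "eghr_mixing")) {
    if (mixing$kind != "static") {
      stop_bad_arg("fixed_point_residual expects a static mixing")
    }
    mixing$A
  } else {
    as.matrix(mixing)
  }
  if (is.null(E0)) E0 <- default_E0(prior, nrow(W))
  with_seed_if(seed, {
    S <- matrix(prior$sampler(ncol(A) * n_samples), nrow = ncol(A))
    X <- A %*% S
    U <- W %*% X
    pref <- E0 - global_factor(U, prior)
    G <- prior$g(U)
    upd <- (G * rep(pref, each = nrow(U))) %*% t(X) / n_samples
    sqrt(sum(upd^2))
  })
}
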