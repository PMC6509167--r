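#' Source-to-output transform matrix
#'
#' `K = W A` is the net linear map from hidden sources to network outputs;
#' for unit-variance independent sources it equals the covariance matrix
#' between sources and outputs, `Cov(u, s)`. BSS succeeds when `K` is the
#' identity up to permutations and sign flips.
#'
#' @param W `N_u x N_x` synaptic matrix.
#' @param A `N_x x N_s` mixing matrix.
#' @return The `N_u x N_s` transform matrix.
#' @export
transform_matrix <- function(W, A) {
  W <- as.matrix(W); A <- as.matrix(A)
  if (ncol(W) != nrow(A)) stop_dim("ncol(W) must equal nrow(A)")
  W %*% A
}

#' BSS error of a transform matrix
#'
#' For every column `j` of `K` the confusion ratio is the second-largest to
#' largest absolute entry, `eps_j^c = |K_{i'' j}| / |K_{i' j}|`; per-row
#' ratios `eps_i^r` are defined analogously. The total error is
#' `sum_j eps_j^c / (2 N_s) + sum_i eps_i^r / (2 N_u)`. It lies in `[0, 1]`
#' and is zero exactly when each row and each column has a single nonzero
#' entry — a one-to-one source-to-output mapping.
#'
#' Edge cases: a single row (or column) has no competitor, so its ratio is 0;
#' an all-zero row or column has an undefined ratio and is scored 1 (maximal
#' confusion), so dead outputs are penalized rather than ignored.
#'
#' @param K `N_u x N_s` transform matrix (see [transform_matrix()]).
#' @return A list of class `bss_error_report`: `per_column_ratios`,
#'   `per_row_ratios`, `total`.
#' @export
bss_error <- function(K) {
  K <- abs(as.matrix(K))
  eps_c <- apply(K, 2, second_to_first_ratio)
  eps_r <- apply(K, 1, second_to_first_ratio)
  total <- sum(eps_c) / (2 * length(eps_c)) + sum(eps_r) / (2 * length(eps_r))
  structure(
    list(per_column_ratios = eps_c, per_row_ratios = eps_r, total = total),
    class = "bss_error_report"
  )
}

second_to_first_ratio <- function(v) {
  if (length(v) < 2) return(0)
  i1 <- which.max(v)                      # ties broken by lowest index
  top <- v[i1]
  if (top == 0) return(1)                 # dead row/column
  max(v[-i1]) / top
}

#' @export
print.bss_error_report <- function(x, ...) {
  cat(sprintf("<bss_error_report> total %.4f (columns %s; rows %s)\n",
              x$total,
              paste(sprintf("%.3f", x$per_column_ratios), collapse = " "),
              paste(sprintf("%.3f", x$per_row_ratios), collapse = " ")))
  invisible(x)
}

#' Frobenius overlap between a synaptic matrix and a mixing component
#'
#' `|W A|_F = sqrt(sum_{ij} (W A)_{ij}^2)`, used to track how strongly the
#' learned `W` projects onto a mixing component: the time-varying-mixing
#' solution drives the overlap with the time-variant component to zero while
#' the overlap with the time-invariant component stays finite.
#'
#' @inheritParams transform_matrix
#' @return Non-negative scalar.
#' @export
frobenius_overlap <- function(W, A) {
  sqrt(sum(transform_matrix(W, A)^2))
}

#' Match outputs to sources up to permutation and sign
#'
#' ICA recovers sources only up to reordering and sign flips. This resolves
#' the ambiguity greedily: repeatedly take the globally largest remaining
#' `|K_{ij}|` among unassigned rows and columns, pair output `i` with source
#' `j`, and record the sign of the entry. For square `K` the residual is
#' `|K - P diag(signs)|_F` where `P diag(signs)` is the matched signed
#' permutation.
#'
#' @param K `N_u x N_s` transform matrix with `N_u >= N_s`.
#' @return A list: `permutation` (`permutation[j]` is the output matched to
#'   source `j`), `signs` (per source), `residual` (`NA` for non-square `K`).
#' @export
match_permutation_signs <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) < ncol(K)) stop_bad_arg("K must have N_u >= N_s")
  n_s <- ncol(K)
  absK <- abs(K)
  perm <- integer(n_s)
  signs <- numeric(n_s)
  for (step in seq_len(n_s)) {
    ij <- arrayInd(which.max(absK), dim(absK))
    i <- ij[1]; j <- ij[2]
    perm[j] <- i
    signs[j] <- if (K[i, j] >= 0) 1 else -1
    absK[i, ] <- -Inf
    absK[, j] <- -Inf
  }
  residual <- NA_real_
  if (nrow(K) == ncol(K)) {
    target <- matrix(0, nrow(K), ncol(K))
    target[cbind(perm, seq_len(n_s))] <- signs
    residual <- sqrt(sum((K - target)^2))
  }
  list(permutation = perm, signs = signs, residual = residual)
}

#' Principal-component projection of a matrix trajectory
#'
#' Flattens each snapshot of a matrix trajectory (e.g. the synaptic matrix
#' `W` recorded during training), centers across snapshots, and projects onto
#' the leading principal components — the visualization used to display the
#' approach of `W` to the task's null space.
#'
#' @param snapshots list of equally shaped matrices.
#' @param n_components number of components to keep.
#' @return A list: `coordinates` (`length(snapshots) x n_components`),
#'   `variance_fractions` (per component, summing to at most 1).
#' @export
pca_projection <- function(snapshots, n_components = 2) {
  if (!is.list(snapshots) || length(snapshots) < 2) {
    stop_bad_arg("need at least two snapshots")
  }
  X <- t(vapply(snapshots, as.numeric, numeric(length(snapshots[[1]]))))
  n_components <- min(n_components, nrow(X) - 1, ncol(X))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  fr <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  list(
    coordinates = p$x[, seq_len(n_components), drop = FALSE],
    variance_fractions = fr[seq_len(n_components)]
  )
}
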