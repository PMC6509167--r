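# shared helpers for the test suite

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_lte(max(abs(a - b)), tol)
}

# a random signed permutation matrix of size n
random_signed_permutation <- function(n) {
  P <- diag(n)[sample(n), , drop = FALSE]
  P * sample(c(-1, 1), n, replace = TRUE)
}

# finite-difference gradient of the EGHR cost with respect to W
fd_cost_gradient <- function(W, X, prior, E0, h = 1e-6) {
  g <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      Wp <- W; Wp[i, j] <- Wp[i, j] + h
      Wm <- W; Wm[i, j] <- Wm[i, j] - h
      g[i, j] <- (eghr_cost(Wp %*% X, prior, E0) -
                    eghr_cost(Wm %*% X, prior, E0)) / (2 * h)
    }
  }
  g
}
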