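test_that("solution existence tracks the rank of the concatenated block", {
  r1 <- multicontext_solution_exists(list(diag(2)))
  expect_true(r1$exists)
  expect_equal(c(r1$rank, r1$required_rank), c(2, 2))
  # two generic square contexts cannot fit: rank bounded by N_x = 2 < 4
  r2 <- multicontext_solution_exists(list(sample_mixing_matrix(2, 2, seed = 1),
                                          sample_mixing_matrix(2, 2, seed = 2)))
  expect_false(r2$exists)
  expect_equal(c(r2$rank, r2$required_rank), c(2, 4))
  expect_false(r2$capacity_ok)
  # two random 6 x 2 contexts fit almost surely
  r3 <- multicontext_solution_exists(list(sample_mixing_matrix(6, 2, seed = 3),
                                          sample_mixing_matrix(6, 2, seed = 4)),
                                     n_u = 2)
  expect_true(r3$exists)
  expect_equal(c(r3$rank, r3$required_rank), c(4, 4))
  expect_true(r3$capacity_ok)
  expect_true(r3$output_ok)
  expect_error(multicontext_solution_exists(list()),
               class = "eghr_invalid_argument")
})

test_that("existence matches the capacity condition on random instances", {
  withr::local_seed(55)
  for (rep in 1:10) {
    C <- sample(2:4, 1); n_s <- sample(1:3, 1)
    n_x <- sample(2:14, 1)
    A_list <- lapply(seq_len(C), function(k) matrix(rnorm(n_x * n_s), n_x, n_s))
    r <- multicontext_solution_exists(A_list)
    # for generic matrices existence is exactly the capacity condition
    expect_equal(r$exists, n_x >= C * n_s)
    expect_equal(r$capacity_ok, n_x >= C * n_s)
  }
})

test_that("existence is invariant to context order and signed permutations", {
  A_list <- lapply(1:2, function(k) sample_mixing_matrix(7, 2, seed = k))
  base <- multicontext_solution_exists(A_list)
  swapped <- multicontext_solution_exists(rev(A_list))
  expect_equal(swapped$exists, base$exists)
  expect_equal(swapped$rank, base$rank)
  withr::local_seed(6)
  P <- random_signed_permutation(2)
  perm <- multicontext_solution_exists(list(A_list[[1]] %*% P, A_list[[2]]))
  expect_equal(perm$rank, base$rank)
})

test_that("the SVD construction annihilates A1 while inverting A0", {
  expect_matrix_equal(reference_solution(diag(2)), diag(2))
  A0 <- sample_mixing_matrix(6, 2, seed = 5)
  A1 <- sample_mixing_matrix(6, 2, seed = 6)
  W <- reference_solution(A0, A1)
  expect_lt(max(abs(W %*% A0 - diag(2))), 1e-8)
  expect_lt(max(abs(W %*% A1)), 1e-8)
  omega <- matrix(c(0, -1, 1, 0), 2, 2)
  W2 <- reference_solution(A0, A1, omega = omega)
  expect_matrix_equal(W2 %*% A0, omega, tol = 1e-8)
  # rank-deficient block has no solution
  expect_error(reference_solution(A0, cbind(A0[, 1] * 2, A0[, 2] - A0[, 1])),
               class = "eghr_no_solution")
})

test_that("stability coefficients of the matched Laplace case are (0, 2)", {
  phi <- phi_extrapolated(laplace_prior(), n_units = 2,
                          betas = c(0.1, 0.03, 0.01), n_samples = 2e5,
                          seed = 7)
  expect_true(all(abs(phi$phi_diag) < 0.1))
  offs <- phi$phi_offdiag[!is.na(phi$phi_offdiag)]
  expect_true(all(abs(offs - 2) < 0.15))
  # product > 1 and diagonal > -1: the separating solution is stable
  verdict <- linear_stability(phi)
  expect_true(verdict$stable)
  # analytic shortcut agrees
  an <- phi_coefficients(laplace_prior(), method = "analytic", n_units = 2)
  expect_equal(an$phi_diag, c(0, 0))
  expect_equal(an$phi_offdiag[1, 2], 2)
})

test_that("matched Gaussian coefficients follow fourth-moment arithmetic", {
  # g(u) = u, g' = 1: Phi_ii = Var(s^2)/2 = 1 for unit-variance Gaussians
  phi <- phi_coefficients(gaussian_prior(), n_units = 2,
                          method = "monte_carlo", n_samples = 4e5, seed = 9)
  expect_true(all(abs(phi$phi_diag - 1) < 0.1))
  expect_true(all(abs(phi$phi_offdiag[!is.na(phi$phi_offdiag)] - 1) < 0.1))
  # the Gaussian case sits exactly on the stability boundary
  an <- phi_coefficients(gaussian_prior(), method = "analytic")
  expect_false(linear_stability(an)$stable)
})

test_that("stability verdicts flag the violating entries", {
  phi <- structure(
    list(phi_diag = c(0, -1.5),
         phi_offdiag = matrix(c(NA, 2, 2, NA), 2, 2),
         method = "analytic", n_samples = NULL),
    class = "stability_coefficients")
  v <- linear_stability(phi)
  expect_false(v$stable)
  expect_equal(v$violated_diag, 2L)
  phi$phi_diag <- c(0, 0)
  phi$phi_offdiag <- matrix(c(NA, 1.0, 0.5, NA), 2, 2)
  v2 <- linear_stability(phi)
  expect_false(v2$stable)
  expect_equal(v2$violated_pairs, rbind(c(1, 2)))
})

test_that("distributional derivatives demand smoothing", {
  expect_error(phi_coefficients(laplace_prior(), method = "monte_carlo",
                                n_samples = 100, smoothing = 0),
               class = "eghr_invalid_argument")
  expect_error(laplace_prior()$gprime(0.1, 0),
               class = "eghr_invalid_argument")
})
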