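test_that("network outputs are the weighted input sums", {
  expect_equal(outputs(diag(2), c(3, -1)), c(3, -1))
  expect_equal(outputs(matrix(c(1, 0, 1, 0, 0, 1), 2, 3), c(1, 2, 3)),
               c(3, 3))
  X <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(6), 2, 3)
  expect_equal(dim(outputs(W, X)), c(2, 4))
  expect_error(outputs(W, c(1, 2)), class = "eghr_dimension_mismatch")
})

test_that("the global factor is the summed negative log prior", {
  pr <- laplace_prior()
  expect_equal(global_factor(c(0, 0), pr), log(2))
  expect_equal(global_factor(c(1, -1), pr), 2 * sqrt(2) + log(2))
  # additivity across units
  a <- 0.73
  expect_equal(global_factor(c(a, a), pr), 2 * global_factor(a, pr))
  # batch form computes one value per column
  U <- cbind(c(0, 0), c(1, -1))
  expect_equal(global_factor(U, pr), c(log(2), 2 * sqrt(2) + log(2)))
})

test_that("the calibrated threshold matches the analytic source entropy", {
  pr <- laplace_prior()
  expect_equal(default_E0(pr, 2), 3 + log(2))
  expect_equal(default_E0(pr, 10), 11 + 5 * log(2))
  expect_equal(default_E0(pr, 0), 1)
  # oracle: <-log p0(s)> per unit by numerical integration under p0
  dens <- function(s) exp(-sqrt(2) * abs(s)) / sqrt(2)
  ent <- integrate(function(s) (sqrt(2) * abs(s) + 0.5 * log(2)) * dens(s),
                   -Inf, Inf)$value
  expect_equal(default_E0(pr, 2), 2 * ent + 1, tolerance = 1e-6)
  no_ent <- new_prior("custom", function(u) u^2, function(u) 2 * u)
  expect_error(default_E0(no_ent, 2), "Monte")
})

test_that("the cost penalizes squared deviation of the global factor", {
  pr <- laplace_prior()
  E0 <- 3 + log(2)
  u_at_E0 <- c((E0 - log(2)) / (2 * sqrt(2)), (E0 - log(2)) / (2 * sqrt(2)))
  expect_equal(eghr_cost(cbind(u_at_E0, u_at_E0), pr, E0), 0)
  # one column at E0 + 2 gives (2)^2/2 = 2
  u2 <- c((E0 + 2 - log(2)) / (2 * sqrt(2)), (E0 + 2 - log(2)) / (2 * sqrt(2)))
  expect_equal(eghr_cost(u2, pr, E0), 2)
  # columns at E0 + {1, 3} give (1 + 9)/4
  u1 <- u_at_E0 + 1 / (2 * sqrt(2))
  u3 <- u_at_E0 + 3 / (2 * sqrt(2))
  expect_equal(eghr_cost(cbind(u1, u3), pr, E0), 2.5)
})

test_that("a single update matches the hand-evaluated three-factor rule", {
  pr <- laplace_prior()
  # u = (1,-1): prefactor E0 - E = 3 - 2*sqrt(2), g(u) = sqrt(2)*(1,-1)
  W2 <- eghr_step(diag(2), c(1, -1), pr, 3 + log(2), eta = 1)
  coeff <- (3 - 2 * sqrt(2)) * sqrt(2)
  expect_matrix_equal(W2 - diag(2),
                      coeff * matrix(c(1, -1, -1, 1), 2, 2), tol = 1e-12)
  # batch whose global factor sits exactly at threshold leaves W unchanged
  E0 <- global_factor(c(0.5, 0.5), pr)
  W <- diag(2)
  expect_identical(eghr_step(W, cbind(c(0.5, 0.5), c(-0.5, -0.5)), pr, E0,
                             eta = 0.1), W)
})

test_that("the update is the negative gradient of the cost", {
  pr <- laplace_prior()
  withr::local_seed(42)
  for (rep in 1:5) {
    n_u <- sample(2:4, 1); n_x <- sample(n_u:4, 1); B <- sample(2:8, 1)
    W <- matrix(rnorm(n_u * n_x, sd = 0.6), n_u, n_x)
    X <- matrix(rnorm(n_x * B), n_x, B)
    E0 <- default_E0(pr, n_u)
    upd <- eghr_step(W, X, pr, E0, eta = 1) - W
    fd <- fd_cost_gradient(W, X, pr, E0)
    expect_lt(max(abs(upd + fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("a reference solution is a fixed point in the large-batch limit", {
  pr <- laplace_prior()
  A <- sample_mixing_matrix(6, 2, seed = 31)
  W <- reference_solution(A)
  res <- vapply(c(1e3, 1e4, 1e5), function(n) {
    fixed_point_residual(W, A, pr, n_samples = n, seed = 17)
  }, numeric(1))
  # residual * sqrt(n) roughly constant: log-log slope near -1/2
  slope <- coef(lm(log(res) ~ log(c(1e3, 1e4, 1e5))))[2]
  expect_lt(abs(slope + 0.5), 0.2)
  # a generic W keeps a bias: residual does not vanish with n
  W_bad <- matrix(rnorm(12, sd = 0.5), 2, 6)
  res_bad <- vapply(c(1e3, 1e5), function(n) {
    fixed_point_residual(W_bad, A, pr, n_samples = n, seed = 17)
  }, numeric(1))
  expect_gt(res_bad[2], res_bad[1] / 3)
})

test_that("network initialization is seeded and validates its arguments", {
  n1 <- init_network(2, 6, seed = 8)
  expect_identical(n1$W, init_network(2, 6, seed = 8)$W)
  expect_equal(dim(n1$W), c(2, 6))
  expect_warning(init_network(2, 6, seed = 1, scale = 0), "zero")
  expect_warning(init_network(5, 2, seed = 1), "unusual")
})

test_that("training with zero learning rate leaves the synapses untouched", {
  fx <- make_fixture("tiny_two_context", seed = 3)
  fx$cfg$eta <- 0
  fx$schedule <- make_context_schedule(2, 2, 1e3, "alternating")
  fit <- train_eghr(fx$net, fx$sources_gen, fx$mixing, fx$schedule,
                    fx$prior, fx$cfg)
  expect_identical(fit$W, fx$net$W)
})

test_that("training solves a tiny two-context problem and calibrates scale", {
  fx <- make_fixture("tiny_two_context", seed = 1)
  fit <- train_eghr(fx$net, fx$sources_gen, fx$mixing, fx$schedule,
                    fx$prior, fx$cfg)
  final <- dplyr::slice_tail(fit$trajectory, n = 1)
  expect_lt(final$bss_ctx1, 0.1)
  expect_lt(final$bss_ctx2, 0.1)
  # with the calibrated E0 the output scale matches the unit source scale
  expect_lt(abs(final$output_var - 1), 0.1)
  # cost is non-negative throughout and decreases in moving average
  expect_true(all(fit$trajectory$cost >= 0))
  n <- nrow(fit$trajectory)
  expect_lt(mean(tail(fit$trajectory$cost, 3)),
            mean(head(fit$trajectory$cost, 3)))
  # trajectory bookkeeping: equal-length series, snapshots aligned
  expect_length(fit$snapshots, n)
})

test_that("square ICA recovers a signed permutation on Laplace sources", {
  A <- sample_mixing_matrix(2, 2, seed = 12)
  fit <- train_eghr(
    init_network(2, 2, seed = 13),
    laplace_source_gen(2),
    static_mixing(A),
    prior = laplace_prior(),
    cfg = train_config(eta = 1e-4, batch_size = 100, n_steps = 4e5,
                       record_every = 1e5, eta_final = 1e-5, seed = 14))
  K <- transform_matrix(fit$W, A)
  m <- match_permutation_signs(K)
  expect_lt(m$residual, 0.1)
})

test_that("divergent training aborts with a diagnostic", {
  fx <- make_fixture("tiny_two_context", seed = 2)
  fx$cfg$eta <- 0.5
  expect_error(
    train_eghr(fx$net, fx$sources_gen, fx$mixing, fx$schedule,
               fx$prior, fx$cfg),
    class = "eghr_divergence")
})

test_that("tidy, glance and autoplot summarize a fit", {
  fx <- make_fixture("tiny_two_context", seed = 1)
  fx$schedule <- make_context_schedule(2, 2, 2e3, "alternating")
  fx$cfg$record_every <- 1e3
  fit <- train_eghr(fx$net, fx$sources_gen, fx$mixing, fx$schedule,
                    fx$prior, fx$cfg)
  long <- tidy(fit)
  expect_true(all(c("step", "metric", "value") %in% names(long)))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_steps, 4e3)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_synaptic_trajectory(fit), "ggplot")
})
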