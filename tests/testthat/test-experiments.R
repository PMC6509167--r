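test_that("experiment configs resolve defaults, overrides and errors", {
  cfg <- experiment_config("two_context")
  expect_equal(cfg$params$eta, 4e-6)
  expect_equal(cfg$params$n_x, 6)
  expect_equal(cfg$native$eta, 4e-6)
  cfg2 <- experiment_config("two_context", eta = 1e-5,
                            overrides = list(n_sessions = 4))
  expect_equal(cfg2$params$eta, 1e-5)
  expect_equal(cfg2$params$n_sessions, 4)
  expect_error(experiment_config("two_context", overrides = list(bogus = 1)),
               class = "eghr_invalid_argument")
  expect_error(experiment_config("two_context", scale = 0),
               class = "eghr_invalid_argument")
  expect_error(experiment_config("no_such_experiment"))
  # proportional scaling keeps the capacity margin
  sc <- experiment_config("hundred_context", scale = 0.2)
  expect_gte(sc$params$n_x, sc$params$n_contexts * sc$params$n_s)
})

test_that("YAML configs round-trip and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: two_context", "seed: 9", "eta: 2.0e-6",
               "overrides:", "  n_sessions: 6"), path)
  cfg <- load_config(path)
  expect_equal(cfg$name, "two_context")
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$params$eta, 2e-6)
  expect_equal(cfg$params$n_sessions, 6)
  writeLines(c("name: two_context", "learningrate: 1"), path)
  expect_error(load_config(path), class = "eghr_invalid_argument")
  writeLines("seed: 3", path)
  expect_error(load_config(path), class = "eghr_invalid_argument")
})

test_that("infeasible scaled dimensions are refused with the capacity rule", {
  expect_error(
    run_experiment("hundred_context",
                   overrides = list(n_contexts = 10, n_s = 4, n_x = 30,
                                    n_sessions = 2, session_length = 100)),
    "capacity")
})

test_that("trajectories round-trip through the CSV pair", {
  fx <- make_fixture("tiny_two_context", seed = 5)
  fx$schedule <- make_context_schedule(2, 2, 2e3, "alternating")
  fx$cfg$record_every <- 1e3
  fit <- train_eghr(fx$net, fx$sources_gen, fx$mixing, fx$schedule,
                    fx$prior, fx$cfg)
  base <- file.path(withr::local_tempdir(), "traj")
  write_trajectory(fit, base)
  back <- read_trajectory(base)
  expect_equal(back$trajectory, fit$trajectory, tolerance = 1e-15)
  expect_length(back$snapshots, length(fit$snapshots))
  expect_matrix_equal(back$snapshots[[3]], fit$snapshots[[3]], tol = 0)
  # header layout is stable: step/session/cost + per-context error columns
  header <- readLines(paste0(base, ".csv"), n = 1)
  expect_equal(strsplit(header, ",")[[1]],
               c("step", "session", "cost", "output_var",
                 "bss_ctx1", "bss_ctx2", "bss_mean"))
})

test_that("fixtures are registered, seeded and constructed as advertised", {
  fx1 <- make_fixture("tiny_two_context", seed = 4)
  fx2 <- make_fixture("tiny_two_context", seed = 4)
  expect_identical(fx1$net$W, fx2$net$W)
  expect_identical(fx1$mixing$A_list, fx2$mixing$A_list)
  rd <- make_fixture("rank_deficient")
  expect_false(rd$exists$exists)
  tr <- make_fixture("tiny_rotating", seed = 2)
  expect_equal(tr$mixing$kind, "time_varying")
  # the lazily evaluated rotation agrees with the explicit trajectory
  x <- mix(tr$mixing, diag(2), t_offset = 5)
  Rs <- rotation_trajectory(sqrt(2) * pi / 100, 6)
  expect_matrix_equal(x[, 1], (tr$A0 + tr$A1 %*% Rs[, , 5])[, 1], tol = 1e-12)
  expect_matrix_equal(x[, 2], (tr$A0 + tr$A1 %*% Rs[, , 6])[, 2], tol = 1e-12)
  expect_error(make_fixture("no_such_fixture"))
})

test_that("experiments are seed-deterministic end to end", {
  ov <- list(session_length = 2e3, n_sessions = 4, record_every = 1e3)
  r1 <- run_experiment("two_context", seed = 6, overrides = ov)
  r2 <- run_experiment("two_context", seed = 6, overrides = ov)
  expect_identical(r1$final_bss, r2$final_bss)
  expect_identical(r1$fit$W, r2$fit$W)
  expect_identical(r1$fit$trajectory$cost, r2$fit$trajectory$cost)
  # report numbers recompute from the final state
  expect_equal(r1$final_bss,
               vapply(r1$fit$mixing$A_list, function(A) {
                 bss_error(transform_matrix(r1$fit$W, A))$total
               }, numeric(1)))
})

test_that("experiment artifacts are written when an output dir is set", {
  out <- withr::local_tempdir()
  cfg <- experiment_config("two_context", seed = 2, out = out,
                           overrides = list(session_length = 1e3,
                                            n_sessions = 2,
                                            record_every = 1e3))
  run_experiment(cfg)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "trajectory_snapshots.csv")))
  rep <- jsonlite::read_json(file.path(out, "report.json"))
  expect_length(rep$final_bss, 2)
})

test_that("training context vectors lie on the simplex", {
  for (n in c(2, 4)) {
    vs <- training_context_vectors(n)
    expect_length(vs, 10)
    expect_true(all(vapply(vs, sum, numeric(1)) == 1))
    expect_true(all(unlist(vs) >= 0))
  }
  expect_error(training_context_vectors(3), class = "eghr_invalid_argument")
})
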