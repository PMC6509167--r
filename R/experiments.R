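#' Experiment configurations
#'
#' Five named protocols cover the studied regimes. Native protocol values
#' are the defaults; `scale` shrinks dimensions, context counts and session
#' lengths proportionally (preserving the capacity margin `N_x >= C * N_s`),
#' and any resolved parameter can be overridden explicitly.
#'
#' * `two_context`: two alternating contexts, `N_s = 2` sources, `N_x = 6`
#'   inputs, `eta = 4e-6`.
#' * `hundred_context`: `C = 100` random contexts per session, `N_s = 10`,
#'   `N_x = 2000`, sessions of `1e5` steps for 600 sessions, `eta = 1e-5`.
#' * `rotating`: time-varying mixing `A0 + A1 R(t)` with a 2-d rotation of
#'   angular frequency `omega = sqrt(2) * pi / 100` per step (variant
#'   `"ou"`: the four coefficients of `R(t)` follow Ornstein-Uhlenbeck
#'   processes), `eta = 1e-5`.
#' * `songlike_moving`: songlike sources through `6 x 2` components with a
#'   rotation whose angular frequency switches among `{-0.1 pi, 0, 0.1 pi}`
#'   with per-step probability `1/8820`, `eta = 1e-7`, native length
#'   `4410 * 6000` steps.
#' * `context_vector_generalization`: mixing `A0 + sum_k A_k v_k` from
#'   centered random components; ten fixed training context vectors, one
#'   drawn per session; generalization measured on 20 random test vectors
#'   drawn from the simplex (`sum(v) = 1`). Native size `100 x 10` with four
#'   components, `eta = 2e-7`, 120 sessions.
#'
#' @param name experiment name (see above).
#' @param scale multiplier in `(0, 1]` applied to the native dimensions and
#'   session lengths.
#' @param seed integer seed for the whole experiment.
#' @param eta learning-rate override (`NULL` keeps the protocol value).
#' @param out optional output directory for [run_experiment()] artifacts.
#' @param overrides named list overriding any resolved parameter.
#' @return A list of class `eghr_experiment_config` with the resolved
#'   parameters in `$params` and the native protocol values in `$native`.
#' @export
experiment_config <- function(name = c("two_context", "hundred_context",
                                       "rotating", "songlike_moving",
                                       "context_vector_generalization"),
                              scale = 1, seed = 1, eta = NULL, out = NULL,
                              overrides = list()) {
  name <- match.arg(name)
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    stop_bad_arg("scale must be in (0, 1]")
  }
  native <- native_params(name)
  params <- scale_params(name, native, scale)
  if (!is.null(eta)) params$eta <- eta
  if (length(overrides)) {
    bad <- setdiff(names(overrides), c(names(params), "variant"))
    if (length(bad)) {
      stop_bad_arg(paste0("unknown override keys: ",
                          paste(bad, collapse = ", ")))
    }
    params[names(overrides)] <- overrides
  }
  structure(
    list(name = name, scale = scale, seed = seed, out = out,
         params = params, native = native),
    class = "eghr_experiment_config"
  )
}

native_params <- function(name) {
  switch(name,
    two_context = list(
      n_s = 2, n_x = 6, n_contexts = 2, eta = 4e-6, eta_final = NULL,
      # session length / count are not part of the printed protocol; these
      # defaults are validated by the convergence criterion only
      session_length = 5e4, n_sessions = 24,
      batch_size = 100, record_every = 5e3, eval_batch = 2000
    ),
    hundred_context = list(
      n_s = 10, n_x = 2000, n_contexts = 100, eta = 1e-5, eta_final = 1e-6,
      session_length = 1e5, n_sessions = 600,
      batch_size = 200, record_every = 1e5, eval_batch = 2000
    ),
    rotating = list(
      n_s = 2, n_x = 6, n_r = 2, eta = 1e-5, eta_final = NULL,
      omega = sqrt(2) * pi / 100, variant = "rotation",
      tau = 1e-3, dt = 1e-6,
      n_steps = 1e6, batch_size = 50, record_every = 1e4, eval_batch = 2000
    ),
    songlike_moving = list(
      n_s = 2, n_x = 6, n_r = 2, eta = 1e-7, eta_final = NULL,
      omegas = c(-0.1 * pi, 0, 0.1 * pi), p_switch = 1 / 8820,
      sample_rate = 4410, noise_scale = 0.1,
      n_steps = 4410 * 6000, batch_size = 50, record_every = 4410 * 60,
      eval_batch = 2000
    ),
    context_vector_generalization = list(
      n_s = 10, n_x = 100, n_components = 4, eta = 2e-7, eta_final = NULL,
      session_length = 4410 * 600, n_sessions = 120,
      n_test_vectors = 20,
      batch_size = 100, record_every = 4410 * 600, eval_batch = 2000
    )
  )
}

scale_params <- function(name, native, scale) {
  if (scale == 1) return(native)
  p <- native
  shrink <- function(x, floor_at) max(floor_at, round(x * scale))
  if (name == "two_context") {
    p$session_length <- shrink(native$session_length, 1e3)
    p$record_every <- shrink(native$record_every, 500)
  } else if (name == "hundred_context") {
    p$n_contexts <- shrink(native$n_contexts, 2)
    p$n_s <- shrink(native$n_s, 2)
    p$n_x <- max(2 * p$n_contexts * p$n_s, round(native$n_x * scale))
    p$session_length <- shrink(native$session_length, 1e3)
    p$n_sessions <- shrink(native$n_sessions, 20)
    p$record_every <- p$session_length
  } else if (name %in% c("rotating", "songlike_moving")) {
    p$n_steps <- shrink(native$n_steps, 1e4)
    p$record_every <- shrink(native$record_every, 500)
  } else {
    p$n_s <- shrink(native$n_s, 2)
    p$n_x <- shrink(native$n_x, 10 * p$n_s)
    p$n_components <- max(2, round(native$n_components * min(1, 2 * scale)))
    p$session_length <- shrink(native$session_length, 2e3)
    p$n_sessions <- shrink(native$n_sessions, 20)
    p$record_every <- p$session_length
  }
  p
}

#' @export
print.eghr_experiment_config <- function(x, ...) {
  cat(sprintf("<eghr_experiment_config> %s (scale %.3g, seed %d)\n",
              x$name, x$scale, x$seed))
  utils::str(x$params, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Training context vectors for the generalization protocol
#'
#' For four components, the ten fixed training vectors of the protocol
#' (vertices and midpoints of the 3-simplex edges); for two components, ten
#' evenly spaced vectors on the 1-simplex. All satisfy `sum(v) = 1`.
#'
#' @param n_components number of context-dependent components.
#' @return A list of context vectors.
#' @export
training_context_vectors <- function(n_components) {
  if (n_components == 4) {
    lapply(list(
      c(1, 0, 0, 0), c(.5, .5, 0, 0), c(0, 1, 0, 0), c(0, .5, .5, 0),
      c(0, 0, 1, 0), c(0, 0, .5, .5), c(0, 0, 0, 1), c(.5, 0, 0, .5),
      c(.5, 0, .5, 0), c(0, .5, 0, .5)), identity)
  } else if (n_components == 2) {
    lapply(seq(0, 1, length.out = 10), function(a) c(a, 1 - a))
  } else {
    stop_bad_arg("training vectors are defined for 2 or 4 components")
  }
}

#' Run a named experiment
#'
#' Resolves the configuration, builds the generators and mixing model, runs
#' the trainer, evaluates the protocol's metrics, and (when `out` is set)
#' writes the trajectory table and a JSON report. Deterministic given the
#' config seed. Refuses per-context protocols whose scaled dimensions
#' violate the capacity condition `N_x >= C * N_s`.
#'
#' @param cfg an [experiment_config()] (or a name passed through to it).
#' @param ... passed to [experiment_config()] when `cfg` is a name.
#' @return An object of class `eghr_report`.
#' @export
run_experiment <- function(cfg, ...) {
  if (is.character(cfg)) cfg <- experiment_config(cfg, ...)
  stopifnot(inherits(cfg, "eghr_experiment_config"))
  p <- cfg$params
  t_start <- Sys.time()
  res <- switch(cfg$name,
    two_context = run_multi_context(cfg, p),
    hundred_context = run_multi_context(cfg, p),
    rotating = run_time_varying(cfg, p),
    songlike_moving = run_time_varying(cfg, p),
    context_vector_generalization = run_generalization(cfg, p)
  )
  res$wall_seconds <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  res$config <- cfg
  res <- structure(res, class = "eghr_report")
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(res$fit, file.path(cfg$out, "trajectory"))
    jsonlite::write_json(report_numbers(res),
                         file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

run_multi_context <- function(cfg, p) {
  if (p$n_x < p$n_contexts * p$n_s) {
    stop_bad_arg(sprintf(
      "capacity condition violated: N_x = %d < C * N_s = %d; no multi-context solution exists",
      p$n_x, p$n_contexts * p$n_s))
  }
  A_list <- lapply(seq_len(p$n_contexts), function(k) {
    sample_mixing_matrix(p$n_x, p$n_s, seed = cfg$seed * 1000 + k)
  })
  mixing <- per_context_mixing(A_list)
  schedule <- make_context_schedule(
    p$n_contexts, p$n_sessions, p$session_length,
    mode = if (cfg$name == "two_context") "alternating" else "uniform_random",
    seed = cfg$seed + 1)
  net <- init_network(p$n_s, p$n_x, seed = cfg$seed + 2)
  fit <- train_eghr(
    net, laplace_source_gen(p$n_s), mixing, schedule,
    prior = laplace_prior(),
    cfg = train_config(eta = p$eta, batch_size = p$batch_size,
                       record_every = p$record_every,
                       eval_batch = p$eval_batch,
                       eta_final = p$eta_final, seed = cfg$seed + 3))
  final <- vapply(A_list,
                  function(A) bss_error(transform_matrix(fit$W, A))$total,
                  numeric(1))
  dom <- dominant_magnitudes(fit$W, A_list)
  out <- list(fit = fit, final_bss = final, dominant = dom)
  if (cfg$name == "two_context") {
    out$retention <- retention_summary(fit$trajectory, schedule)
  }
  out
}

# |K| dominant entries per row and per column, across contexts
dominant_magnitudes <- function(W, A_list) {
  per_ctx <- lapply(A_list, function(A) {
    K <- abs(transform_matrix(W, A))
    c(apply(K, 1, max), apply(K, 2, max))
  })
  all_dom <- unlist(per_ctx)
  sub_dom <- unlist(lapply(A_list, function(A) {
    K <- abs(transform_matrix(W, A))
    c(apply(K, 1, function(v) sort(v, decreasing = TRUE)[2]),
      apply(K, 2, function(v) sort(v, decreasing = TRUE)[2]))
  }))
  list(values = all_dom, mean = mean(all_dom), min = min(all_dom),
       max = max(all_dom), max_subdominant = max(sub_dom))
}

# BSS error for context 1 at the start of its first exposure vs. its first
# re-exposure after the other context (memory retention)
retention_summary <- function(traj, schedule) {
  ctx <- schedule$context_of_session
  reexp <- which(ctx == ctx[1])[2]
  if (is.na(reexp)) return(NULL)
  col <- paste0("bss_ctx", ctx[1])
  at_session_start <- function(s) {
    t0 <- (s - 1) * schedule$session_length
    row <- which.min(abs(traj$step - t0))
    traj[[col]][row]
  }
  list(first_exposure_start = at_session_start(1),
       reexposure_start = at_session_start(reexp))
}

run_time_varying <- function(cfg, p) {
  A0 <- sample_mixing_matrix(p$n_x, p$n_s, seed = cfg$seed * 1000 + 1)
  A1 <- sample_mixing_matrix(p$n_x, p$n_r, seed = cfg$seed * 1000 + 2)
  variant <- p$variant %||% "rotation"
  if (cfg$name == "songlike_moving") {
    omega_seq <- markov_switching_omega(p$n_steps, p$omegas, p$p_switch,
                                        seed = cfg$seed + 10)
    theta <- cumsum(omega_seq)
    R <- rotation_fun(theta)
    sources <- songlike_source_gen(p$n_s, p$sample_rate, p$noise_scale)
  } else if (variant == "ou") {
    Rarr <- ou_matrix_process(p$n_r, p$n_s, tau = p$tau,
                              n_steps = p$n_steps, dt = p$dt,
                              seed = cfg$seed + 10)
    R <- Rarr
    sources <- laplace_source_gen(p$n_s)
  } else {
    theta <- p$omega * seq_len(p$n_steps)
    R <- rotation_fun(theta)
    sources <- laplace_source_gen(p$n_s)
  }
  mixing <- time_varying_mixing(A0, A1, R)
  net <- init_network(p$n_s, p$n_x, seed = cfg$seed + 2)
  fit <- train_eghr(
    net, sources, mixing, schedule = NULL, prior = laplace_prior(),
    cfg = train_config(eta = p$eta, batch_size = p$batch_size,
                       n_steps = p$n_steps, record_every = p$record_every,
                       eval_batch = p$eval_batch,
                       eta_final = p$eta_final, seed = cfg$seed + 3))
  K <- transform_matrix(fit$W, A0)
  list(
    fit = fit,
    final_bss = bss_error(K)$total,
    overlap_A0 = frobenius_overlap(fit$W, A0),
    overlap_A1 = frobenius_overlap(fit$W, A1),
    signed_perm_residual = match_permutation_signs(K)$residual
  )
}

# lazily evaluated 2x2 rotation trajectory from a phase sequence
rotation_fun <- function(theta) {
  force(theta)
  function(t) {
    out <- array(0, c(2, 2, length(t)))
    th <- theta[t]
    out[1, 1, ] <- cos(th); out[1, 2, ] <- -sin(th)
    out[2, 1, ] <- sin(th); out[2, 2, ] <- cos(th)
    out
  }
}

run_generalization <- function(cfg, p) {
  comp <- centered_mixing_components(p$n_x, p$n_s, p$n_components,
                                     seed = cfg$seed * 1000 + 1)
  train_v <- training_context_vectors(p$n_components)
  A_list <- lapply(train_v, function(v) {
    context_vector_mixing(comp$A0, comp$deps, v)
  })
  mixing <- per_context_mixing(A_list)
  schedule <- make_context_schedule(length(A_list), p$n_sessions,
                                    p$session_length,
                                    mode = "uniform_random",
                                    seed = cfg$seed + 1)
  net <- init_network(p$n_s, p$n_x, seed = cfg$seed + 2)
  fit <- train_eghr(
    net, laplace_source_gen(p$n_s), mixing, schedule,
    prior = laplace_prior(),
    cfg = train_config(eta = p$eta, batch_size = p$batch_size,
                       record_every = p$record_every,
                       eval_batch = p$eval_batch,
                       eta_final = p$eta_final, seed = cfg$seed + 3))
  test_v <- with_seed_if(cfg$seed + 4, {
    lapply(seq_len(p$n_test_vectors), function(i) {
      v <- runif(p$n_components)
      v / sum(v)
    })
  })
  test_err_of <- function(W) {
    vapply(test_v, function(v) {
      A <- context_vector_mixing(comp$A0, comp$deps, v)
      bss_error(transform_matrix(W, A))$total
    }, numeric(1))
  }
  test_final <- test_err_of(fit$W)
  # test-error learning curve, recomputed from the recorded snapshots
  test_curve <- vapply(fit$snapshots,
                       function(W) mean(test_err_of(W)), numeric(1))
  train_final <- vapply(A_list,
                        function(A) bss_error(transform_matrix(fit$W, A))$total,
                        numeric(1))
  list(
    fit = fit,
    components = comp,
    final_bss = train_final,
    test_bss = test_final,
    test_bss_curve = tibble::tibble(
      step = fit$trajectory$step[seq_along(test_curve)],
      test_bss_mean = test_curve),
    overlap_A0 = frobenius_overlap(fit$W, comp$A0),
    overlap_deps = vapply(comp$deps,
                          function(D) frobenius_overlap(fit$W, D), numeric(1))
  )
}

report_numbers <- function(res) {
  keep <- res[setdiff(names(res), c("fit", "config", "components",
                                    "test_bss_curve"))]
  keep$final_bss <- unname(keep$final_bss)
  lapply(keep, function(x) if (is.list(x)) x else unname(x))
}

#' @export
print.eghr_report <- function(x, ...) {
  cat(sprintf("<eghr_report> %s (%.1f s)\n", x$config$name, x$wall_seconds))
  cat(sprintf("  final BSS error: mean %.4f, max %.4f\n",
              mean(x$final_bss), max(x$final_bss)))
  if (!is.null(x$test_bss)) {
    cat(sprintf("  test BSS error (unseen contexts): mean %.4f\n",
                mean(x$test_bss)))
  }
  if (!is.null(x$overlap_A1)) {
    cat(sprintf("  overlaps: |WA0|_F = %.3f, |WA1|_F = %.4f\n",
                x$overlap_A0, x$overlap_A1))
  }
  if (!is.null(x$retention)) {
    cat(sprintf("  retention: first-exposure start %.3f -> re-exposure start %.3f\n",
                x$retention$first_exposure_start,
                x$retention$reexposure_start))
  }
  invisible(x)
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized top-level keys: `name` (required), `scale`, `seed`, `eta`,
#' `out`, and `overrides` (a map of resolved-parameter overrides). Unknown
#' top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- c("name", "scale", "seed", "eta", "out", "overrides")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop_bad_arg(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  if (is.null(raw$name)) stop_bad_arg("config must set 'name'")
  experiment_config(
    name = raw$name,
    scale = raw$scale %||% 1,
    seed = raw$seed %||% 1,
    eta = raw$eta,
    out = raw$out,
    overrides = raw$overrides %||% list()
  )
}

#' Write and read a training trajectory
#'
#' The trajectory table is written as CSV; the recorded `W` snapshots go to
#' a sidecar CSV in long form (`snapshot, row, col, value`). The pair
#' round-trips losslessly through [read_trajectory()] (values are printed at
#' full double precision).
#'
#' @param fit an `eghr_fit` (or a list with `trajectory` and `snapshots`).
#' @param path base path without extension; `<path>.csv` and
#'   `<path>_snapshots.csv` are written.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(fit, path) {
  traj <- fit$trajectory
  if (is.null(traj) || nrow(traj) == 0) stop_bad_arg("empty trajectory")
  utils::write.csv(format_full(traj), paste0(path, ".csv"),
                   row.names = FALSE, quote = FALSE)
  snaps <- fit$snapshots
  if (length(snaps)) {
    long <- purrr::map_dfr(seq_along(snaps), function(i) {
      W <- snaps[[i]]
      tibble::tibble(
        snapshot = i,
        row = rep(seq_len(nrow(W)), ncol(W)),
        col = rep(seq_len(ncol(W)), each = nrow(W)),
        value = as.numeric(W))
    })
    utils::write.csv(format_full(long), paste0(path, "_snapshots.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

format_full <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), optional = TRUE)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- tibble::as_tibble(utils::read.csv(paste0(path, ".csv")))
  snap_path <- paste0(path, "_snapshots.csv")
  snaps <- list()
  if (file.exists(snap_path)) {
    long <- utils::read.csv(snap_path)
    snaps <- lapply(split(long, long$snapshot), function(d) {
      matrix(d$value[order(d$col, d$row)], max(d$row), max(d$col))
    })
    names(snaps) <- NULL
  }
  list(trajectory = traj, snapshots = snaps)
}

#' Miniature seeded problem instances for tests and demos
#'
#' * `"tiny_two_context"`: `N_s = 2`, `N_x = 6`, two alternating contexts,
#'   sized to train to a low BSS error in seconds.
#' * `"tiny_rotating"`: a short rotating-mixture instance.
#' * `"rank_deficient"`: two contexts whose concatenated mixing block cannot
#'   have full column rank (`N_x < C * N_s`), so no multi-context solution
#'   exists.
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return A list with the generators, mixing model, schedule, network and
#'   train config needed to run the instance (fields vary by fixture).
#' @export
make_fixture <- function(name = c("tiny_two_context", "tiny_rotating",
                                  "rank_deficient"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    tiny_two_context = {
      A_list <- lapply(1:2, function(k) {
        sample_mixing_matrix(6, 2, seed = seed * 100 + k)
      })
      list(
        mixing = per_context_mixing(A_list),
        schedule = make_context_schedule(2, 14, 2e4, "alternating"),
        net = init_network(2, 6, seed = seed + 1),
        sources_gen = laplace_source_gen(2),
        prior = laplace_prior(),
        cfg = train_config(eta = 4e-5, batch_size = 100,
                           record_every = 2e4, eval_batch = 1000,
                           seed = seed + 2)
      )
    },
    tiny_rotating = {
      A0 <- sample_mixing_matrix(6, 2, seed = seed * 100 + 1)
      A1 <- sample_mixing_matrix(6, 2, seed = seed * 100 + 2)
      n_steps <- 2e5
      list(
        mixing = time_varying_mixing(
          A0, A1, rotation_fun(sqrt(2) * pi / 100 * seq_len(n_steps))),
        A0 = A0, A1 = A1,
        net = init_network(2, 6, seed = seed + 1),
        sources_gen = laplace_source_gen(2),
        prior = laplace_prior(),
        cfg = train_config(eta = 4e-5, batch_size = 50, n_steps = n_steps,
                           record_every = 1e4, eval_batch = 1000,
                           seed = seed + 2)
      )
    },
    rank_deficient = {
      A_list <- lapply(1:2, function(k) {
        sample_mixing_matrix(2, 2, seed = seed * 100 + k)
      })
      list(mixing = per_context_mixing(A_list),
           exists = multicontext_solution_exists(A_list))
    }
  )
}

#' Compact desktop-scale protocol presets
#'
#' Ready-made [experiment_config()]s sized so that every protocol trains to
#' convergence on one CPU core in seconds to a few minutes while preserving
#' the structure of the native protocols: the multi-context preset keeps the
#' capacity margin `N_x = 2 C N_s` of the native setup at a tenth of the
#' contexts, and the annealed learning rates end an order of magnitude below
#' their starting value so the converged synapses sit at a low stochastic
#' noise floor. These are the instances used by the package's worked
#' examples; exact problem sizes are listed in the methods vignette.
#'
#' @param name experiment name (see [experiment_config()]).
#' @param seed integer seed.
#' @param variant for `rotating`: `"rotation"` or `"ou"`.
#' @return An `eghr_experiment_config`.
#' @export
compact_protocol <- function(name, seed = 1, variant = "rotation") {
  switch(name,
    two_context = experiment_config(
      "two_context", seed = seed,
      overrides = list(session_length = 2e5, n_sessions = 16,
                       record_every = 2e4)),
    hundred_context = experiment_config(
      "hundred_context", seed = seed,
      overrides = list(n_contexts = 10, n_s = 4, n_x = 80,
                       session_length = 1e4, n_sessions = 600,
                       batch_size = 200, record_every = 1e5,
                       eta = 1e-5, eta_final = 1e-6)),
    rotating = experiment_config(
      "rotating", seed = seed,
      overrides = list(variant = variant, eta_final = 1e-6)),
    songlike_moving = experiment_config(
      "songlike_moving", seed = seed,
      overrides = list(n_steps = 4410 * 1200, eta = 5e-6, eta_final = 5e-7,
                       record_every = 4410 * 12)),
    context_vector_generalization = experiment_config(
      "context_vector_generalization", seed = seed,
      overrides = list(n_s = 4, n_x = 40, n_components = 2,
                       session_length = 1e4, n_sessions = 300,
                       batch_size = 200, record_every = 5e4,
                       eta = 1e-5, eta_final = 1e-6)),
    stop_bad_arg(paste0("unknown protocol: ", name))
  )
}
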