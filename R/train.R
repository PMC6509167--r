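#' Training configuration
#'
#' @param eta per-sample learning rate; the batch update uses the batch mean
#'   of the per-sample updates scaled by `eta * batch_size`, so a batched run
#'   traverses the same average trajectory as the online rule at rate `eta`.
#' @param batch_size samples per update (1 recovers the pure online rule).
#' @param eta_final optional final per-sample learning rate: when set, the
#'   rate decays geometrically from `eta` to `eta_final` over the run
#'   (Robbins-Monro-style annealing, which lowers the stochastic noise floor
#'   of the converged synapses); `NULL` keeps `eta` constant.
#' @param n_steps total training samples (ignored when a schedule is given:
#'   then the schedule's sessions define the length).
#' @param record_every recording cadence in samples.
#' @param E0 gating threshold, or `"auto"` for [default_E0()] with the
#'   network's own output dimension (the agent knows only `N_u`).
#' @param eval_batch fresh samples drawn for each metric recording (metrics
#'   never reuse the training batch).
#' @param keep_snapshots record `W` at every recording point (needed for the
#'   principal-component trajectory plots).
#' @param seed integer seed for the whole run; `NULL` for the ambient RNG.
#' @return A list of class `eghr_train_config`.
#' @export
train_config <- function(eta, batch_size = 100, n_steps = NULL,
                         record_every = NULL, E0 = "auto",
                         eval_batch = 1000, keep_snapshots = TRUE,
                         eta_final = NULL, seed = NULL) {
  if (!is.numeric(eta) || eta < 0) stop_bad_arg("eta must be >= 0")
  if (!is.null(eta_final) &&
      (!is.numeric(eta_final) || eta_final <= 0 || eta_final > eta)) {
    stop_bad_arg("eta_final must be in (0, eta]")
  }
  check_count(batch_size, "batch_size")
  structure(
    list(eta = eta, batch_size = batch_size, n_steps = n_steps,
         record_every = record_every, E0 = E0, eval_batch = eval_batch,
         keep_snapshots = keep_snapshots, eta_final = eta_final, seed = seed),
    class = "eghr_train_config"
  )
}

#' Source generators for the trainer
#'
#' The trainer pulls sources batchwise through a generator
#' `function(n, t_start)` returning an `N_s x n` matrix for global time
#' steps `t_start, ..., t_start + n - 1`. `laplace_source_gen()` draws white
#' unit-Laplace trains from the ambient RNG (so the trainer's single seed
#' governs them); `songlike_source_gen()` returns the deterministic songlike
#' waveform for those time indices plus ambient-RNG Laplace noise,
#' approximately standardized using the long-run moments of the waveform.
#'
#' @param n_sources number of source rows.
#' @param sample_rate,noise_scale see [make_songlike_sources()].
#' @return A function `(n, t_start) -> N_s x n matrix`.
#' @export
laplace_source_gen <- function(n_sources) {
  force(n_sources)
  function(n, t_start = 1) {
    matrix(rlaplace_unit(n_sources * n), nrow = n_sources)
  }
}

#' @rdname laplace_source_gen
#' @param calibration_steps steps used once, up front, to estimate the
#'   waveform's mean and variance for standardization.
#' @export
songlike_source_gen <- function(n_sources, sample_rate = 4410,
                                noise_scale = 0.1,
                                calibration_steps = 2e5) {
  ref <- make_songlike_sources(n_sources, calibration_steps,
                               sample_rate = sample_rate, seed = 1,
                               noise_scale = 0)
  # raw (pre-normalization) waveform moments for streaming standardization
  raw <- songlike_raw(n_sources, seq_len(calibration_steps), sample_rate)
  mu <- rowMeans(raw)
  sd_raw <- apply(raw, 1, sd)
  function(n, t_start = 1) {
    w <- songlike_raw(n_sources, t_start + seq_len(n) - 1, sample_rate)
    w <- (w - mu) / sd_raw
    if (noise_scale > 0) {
      w <- w + noise_scale *
        matrix(rlaplace_unit(n_sources * n), nrow = n_sources)
      w <- w / sqrt(1 + noise_scale^2)
    }
    w
  }
}

# the deterministic chirp waveform at arbitrary time indices
songlike_raw <- function(n_sources, t_idx, sample_rate) {
  t <- (t_idx - 1) / sample_rate
  out <- matrix(0, n_sources, length(t))
  for (i in seq_len(n_sources)) {
    f0 <- 320 * 1.31^(i - 1)
    syl <- 2.1 + 0.6 * i
    env <- pmax(0, sin(2 * pi * syl * t))^2
    glide <- 1 + 0.12 * sin(2 * pi * 0.37 * syl * t + i)
    phase <- 2 * pi * f0 * glide * t
    out[i, ] <- env * (sin(phase) + 0.5 * sin(2 * phase + 0.7 * i) +
                         0.25 * sin(3 * phase + 1.3 * i))
  }
  out
}

#' Train a network with the error-gated Hebbian rule
#'
#' Iterates [eghr_step()] over freshly generated source batches mixed
#' through the given model, following the context schedule when one is
#' given. Metrics are recorded every `record_every` samples on a fresh
#' evaluation batch: the cost, the BSS error of `K^(k) = W A^(k)` for every
#' context (per-context mixing), or of `K = W A0` plus the Frobenius
#' overlaps with each component (time-varying mixing).
#'
#' @param net an [init_network()] state.
#' @param sources_gen a source generator, e.g. [laplace_source_gen()].
#' @param mixing an `eghr_mixing` model.
#' @param schedule an `eghr_schedule` (required for per-context mixing).
#' @param prior an [new_prior()] object.
#' @param cfg a [train_config()].
#' @return An object of class `eghr_fit`: final `W`, the recorded
#'   `trajectory` tibble, `snapshots` (list of `W`), and the run metadata.
#' @export
train_eghr <- function(net, sources_gen, mixing, schedule = NULL,
                       prior = laplace_prior(), cfg) {
  stopifnot(inherits(net, "eghr_network"), inherits(mixing, "eghr_mixing"),
            inherits(cfg, "eghr_train_config"))
  if (mixing$kind == "per_context" && is.null(schedule)) {
    stop_bad_arg("per-context mixing requires a context schedule")
  }
  W <- net$W
  n_u <- nrow(W)
  if (ncol(W) != mixing$n_x) {
    stop_dim(sprintf("ncol(W)=%d but the mixing has N_x=%d",
                     ncol(W), mixing$n_x))
  }
  E0 <- if (identical(cfg$E0, "auto")) default_E0(prior, n_u) else cfg$E0
  total <- if (!is.null(schedule)) {
    length(schedule$context_of_session) * schedule$session_length
  } else {
    cfg$n_steps
  }
  if (is.null(total)) stop_bad_arg("n_steps required when no schedule is given")
  record_every <- cfg$record_every %||% max(1, floor(total / 200))
  session_length <- if (!is.null(schedule)) schedule$session_length else total

  runner <- function() {
    rows <- list()
    snaps <- list()
    t <- 0L
    next_record <- 0L                     # record at t = 0 too
    while (t < total) {
      if (t >= next_record) {
        rec <- record_metrics(W, mixing, schedule, prior, E0, sources_gen,
                              cfg$eval_batch, t, session_length)
        rows[[length(rows) + 1L]] <- rec
        if (cfg$keep_snapshots) snaps[[length(snaps) + 1L]] <- W
        next_record <- next_record + record_every
      }
      in_session <- session_length - (t %% session_length)
      B <- min(cfg$batch_size, in_session, total - t)
      S <- sources_gen(B, t + 1L)
      X <- mix(mixing, S, schedule, t_offset = t + 1L)
      if (cfg$eta > 0) {
        eta_t <- if (is.null(cfg$eta_final)) {
          cfg$eta
        } else {
          cfg$eta * (cfg$eta_final / cfg$eta)^(t / total)
        }
        # batch mean times batch size: the accumulated online updates of the
        # same B samples at per-sample rate eta_t
        W <- tryCatch(
          eghr_step(W, X, prior, E0, eta_t * B),
          eghr_divergence = function(e) {
            abort(sprintf("training diverged at step %d (eta=%.3g): %s",
                          t, cfg$eta, conditionMessage(e)),
                  class = "eghr_divergence")
          })
        if (max(abs(W)) > 1e6) {
          abort(sprintf("training diverged at step %d (eta=%.3g): max|W| > 1e6",
                        t, cfg$eta), class = "eghr_divergence")
        }
      }
      t <- t + B
    }
    rec <- record_metrics(W, mixing, schedule, prior, E0, sources_gen,
                          cfg$eval_batch, t, session_length)
    rows[[length(rows) + 1L]] <- rec
    if (cfg$keep_snapshots) snaps[[length(snaps) + 1L]] <- W
    list(rows = rows, snaps = snaps, W = W, t = t)
  }
  res <- with_seed_if(cfg$seed, runner())

  traj <- dplyr::bind_rows(res$rows)
  structure(
    list(W = res$W,
         network = structure(list(W = res$W, step = res$t,
                                  rng_seed = cfg$seed),
                             class = "eghr_network"),
         trajectory = traj,
         snapshots = res$snaps,
         config = cfg, E0 = E0, mixing = mixing, schedule = schedule,
         prior = prior, n_steps = res$t),
    class = "eghr_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

record_metrics <- function(W, mixing, schedule, prior, E0, sources_gen,
                           eval_batch, t, session_length) {
  # evaluate on the trailing window so the final record stays inside the
  # schedule / trajectory horizon
  t0 <- max(0L, t - as.integer(eval_batch)) + 1L
  S <- sources_gen(eval_batch, t0)
  X <- mix(mixing, S, schedule, t_offset = t0)
  U <- W %*% X
  cost <- eghr_cost(U, prior, E0)
  base <- tibble::tibble(
    step = t,
    session = (max(t - 1, 0)) %/% session_length + 1,
    cost = cost,
    output_var = mean(apply(U, 1, var))
  )
  if (mixing$kind == "per_context") {
    errs <- vapply(mixing$A_list,
                   function(A) bss_error(transform_matrix(W, A))$total,
                   numeric(1))
    for (k in seq_along(errs)) base[[paste0("bss_ctx", k)]] <- errs[k]
    base$bss_mean <- mean(errs)
  } else if (mixing$kind == "time_varying") {
    base$bss <- bss_error(transform_matrix(W, mixing$A0))$total
    base$overlap_A0 <- frobenius_overlap(W, mixing$A0)
    base$overlap_A1 <- frobenius_overlap(W, mixing$A1)
  } else {
    base$bss <- bss_error(transform_matrix(W, mixing$A))$total
  }
  base
}

#' @export
print.eghr_fit <- function(x, ...) {
  cat(sprintf("<eghr_fit> W: %d x %d, %d samples, E0=%.3f\n",
              nrow(x$W), ncol(x$W), x$n_steps, x$E0))
  final <- dplyr::slice_tail(x$trajectory, n = 1)
  bss_cols <- grep("^bss", names(final), value = TRUE)
  cat(sprintf("  final cost %.4g; final BSS error: %s\n", final$cost,
              paste(sprintf("%s=%.4f", bss_cols,
                            as.numeric(final[1, bss_cols])),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy a training trajectory
#'
#' @param x an `eghr_fit`.
#' @param ... unused.
#' @return A long tibble with columns `step`, `session`, `metric`, `value`.
#' @method tidy eghr_fit
#' @export
tidy.eghr_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory,
                      cols = -c("step", "session"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x an `eghr_fit`.
#' @param ... unused.
#' @return A one-row tibble: sample count, learning rate, threshold, final
#'   cost, final mean BSS error, and mean output variance at the end.
#' @method glance eghr_fit
#' @export
glance.eghr_fit <- function(x, ...) {
  final <- dplyr::slice_tail(x$trajectory, n = 1)
  bss_cols <- grep("^bss", names(final), value = TRUE)
  tibble::tibble(
    n_steps = x$n_steps,
    eta = x$config$eta,
    E0 = x$E0,
    final_cost = final$cost,
    final_bss_error = mean(as.numeric(final[1, bss_cols])),
    final_output_var = final$output_var
  )
}

#' Plot the learning curves of a fit
#'
#' BSS error (per context where applicable) and cost against training step.
#'
#' @param object an `eghr_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot eghr_fit
#' @export
autoplot.eghr_fit <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::filter(long, grepl("^(bss|cost|overlap)", .data$metric))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ sub("_.*", "", metric), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "training step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synaptic trajectory in principal-component coordinates
#'
#' Projects the recorded `W` snapshots onto their leading two principal
#' components — the null-space visualization of the learning dynamics.
#'
#' @param fit an `eghr_fit` trained with `keep_snapshots = TRUE`.
#' @return A ggplot object.
#' @export
plot_synaptic_trajectory <- function(fit) {
  stopifnot(inherits(fit, "eghr_fit"))
  proj <- pca_projection(fit$snapshots, 2)
  df <- tibble::tibble(
    pc1 = proj$coordinates[, 1],
    pc2 = proj$coordinates[, 2],
    step = fit$trajectory$step[seq_len(nrow(proj$coordinates))]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$step)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * proj$variance_fractions[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * proj$variance_fractions[2])) +
    ggplot2::theme_minimal()
}
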