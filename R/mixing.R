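#' Sample a random mixing matrix
#'
#' Draws an `n_x x n_s` mixing matrix with i.i.d. normal entries of standard
#' deviation `scale`. The undercomplete convention `n_x >= n_s` is enforced:
#' the BSS task needs at least as many inputs as sources. The result is full
#' column rank (resampled in the measure-zero event that it is not).
#'
#' @param n_x input dimension (rows).
#' @param n_s source dimension (columns).
#' @param seed integer seed; `NULL` for the ambient RNG.
#' @param scale entry standard deviation.
#' @return An `n_x x n_s` matrix of rank `n_s`.
#' @export
sample_mixing_matrix <- function(n_x, n_s, seed = NULL, scale = 1) {
  check_count(n_x, "n_x"); check_count(n_s, "n_s")
  if (n_x < n_s) {
    stop_bad_arg("n_x must be >= n_s (undercomplete mixing requirement)")
  }
  if (!is.numeric(scale) || scale <= 0) stop_bad_arg("scale must be positive")
  with_seed_if(seed, {
    A <- matrix(rnorm(n_x * n_s, sd = scale), n_x, n_s)
    while (numeric_rank(A) < n_s) {
      A <- matrix(rnorm(n_x * n_s, sd = scale), n_x, n_s)
    }
    A
  })
}

#' Two-dimensional rotation matrix
#'
#' @param angle rotation angle in radians.
#' @return The 2x2 matrix `(cos a, -sin a; sin a, cos a)` (determinant 1).
#' @export
rotation_matrix <- function(angle) {
  if (!is.numeric(angle) || length(angle) != 1 || !is.finite(angle)) {
    stop_bad_arg("angle must be a finite number")
  }
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}

#' Rotation-matrix trajectory from a per-step angular-frequency sequence
#'
#' Integrates the angular frequency to a phase (`theta_t = sum_{t' <= t}
#' omega_{t'}`, starting from `theta_1 = omega_1`) and returns the 2x2
#' rotation matrices as a `2 x 2 x n_steps` array. A scalar `omega` gives the
#' uniformly rotating mixture; a sequence from [markov_switching_omega()]
#' gives the piecewise-rotating one.
#'
#' @param omega scalar angular frequency (radians per step) or a per-step
#'   sequence.
#' @param n_steps number of steps (required when `omega` is scalar).
#' @return A `2 x 2 x n_steps` array of rotation matrices.
#' @export
rotation_trajectory <- function(omega, n_steps = length(omega)) {
  if (length(omega) == 1) omega <- rep(omega, n_steps)
  if (length(omega) != n_steps) {
    stop_bad_arg("length(omega) must equal n_steps")
  }
  theta <- cumsum(omega)
  out <- array(0, c(2, 2, n_steps))
  out[1, 1, ] <- cos(theta); out[1, 2, ] <- -sin(theta)
  out[2, 1, ] <- sin(theta); out[2, 2, ] <- cos(theta)
  out
}

#' Ornstein-Uhlenbeck trajectories for a matrix of slow mixing coefficients
#'
#' Each of the `rows x cols` entries follows an independent mean-reverting OU
#' process `dr = -(r/tau) dt + sqrt(2/tau) dB`, discretized by
#' Euler-Maruyama with step `dt`, so the stationary law is `N(0, 1)` and the
#' lag-k autocorrelation is `exp(-k dt / tau)`. Entries are initialized from
#' the stationary law. The default `dt` makes `tau` span 1000 steps, keeping
#' the mixing dynamics slow relative to the white sources, as the
#' time-varying-mixing theory requires.
#'
#' @param rows,cols dimensions of the coefficient matrix.
#' @param tau OU time constant (same time unit as `dt`).
#' @param n_steps number of steps to simulate.
#' @param dt Euler-Maruyama step; must satisfy `dt < tau`.
#' @param seed integer seed; `NULL` for the ambient RNG.
#' @return A `rows x cols x n_steps` array.
#' @export
ou_matrix_process <- function(rows, cols, tau = 1e-3, n_steps, dt = tau / 1000,
                              seed = NULL) {
  check_count(rows, "rows"); check_count(cols, "cols")
  check_count(n_steps, "n_steps")
  if (!is.numeric(tau) || tau <= 0) stop_bad_arg("tau must be positive")
  if (!is.numeric(dt) || dt <= 0) stop_bad_arg("dt must be positive")
  if (dt >= tau) {
    stop_bad_arg("dt must be smaller than tau (Euler-Maruyama stability)")
  }
  a <- 1 - dt / tau
  sig <- sqrt(2 * dt / tau)
  with_seed_if(seed, {
    k <- rows * cols
    out <- matrix(0, k, n_steps)
    r <- rnorm(k)                      # stationary start
    shocks <- matrix(rnorm(k * n_steps, sd = sig), k, n_steps)
    for (t in seq_len(n_steps)) {
      r <- a * r + shocks[, t]
      out[, t] <- r
    }
    array(out, c(rows, cols, n_steps))
  })
}

#' Markov-switching angular-frequency sequence
#'
#' At every step, with probability `p_switch` the angular frequency is
#' redrawn uniformly from `omegas` (possibly landing on the current value);
#' otherwise it is held. Defaults are the three-state set
#' `{-0.1*pi, 0, 0.1*pi}` rad/step with redraw probability `1/8820`.
#'
#' @param n_steps sequence length.
#' @param omegas candidate angular frequencies (radians per step).
#' @param p_switch per-step redraw probability in `[0, 1]`.
#' @param seed integer seed; `NULL` for the ambient RNG.
#' @return Numeric vector of length `n_steps`.
#' @export
markov_switching_omega <- function(n_steps,
                                   omegas = c(-0.1 * pi, 0, 0.1 * pi),
                                   p_switch = 1 / 8820, seed = NULL) {
  check_count(n_steps, "n_steps")
  if (length(omegas) == 0) stop_bad_arg("omegas must be non-empty")
  if (!is.numeric(p_switch) || p_switch < 0 || p_switch > 1) {
    stop_bad_arg("p_switch must be a probability in [0, 1]")
  }
  with_seed_if(seed, {
    draws <- sample(omegas, n_steps, replace = TRUE)
    keep <- runif(n_steps) >= p_switch
    keep[1] <- FALSE                   # first value is always a fresh draw
    idx <- seq_len(n_steps)
    idx[keep] <- NA
    # carry the last redraw forward
    filled <- cummax_na(idx)
    draws[filled]
  })
}

cummax_na <- function(idx) {
  last <- idx[1]
  for (t in seq_along(idx)) {
    if (is.na(idx[t])) idx[t] <- last else last <- idx[t]
  }
  idx
}

# ---------------------------------------------------------------------------
# Mixing models

#' Mixing models: static, per-context and time-varying
#'
#' A mixing model describes how hidden sources become sensory inputs,
#' `x = A s`. Three regimes are supported:
#'
#' * `static_mixing(A)`: one fixed `N_x x N_s` matrix.
#' * `per_context_mixing(A_list)`: one matrix per context `k`; which context
#'   is active at each time step is decided by a [make_context_schedule()]
#'   schedule passed to [mix()] or the trainer.
#' * `time_varying_mixing(A0, A1, R)`: `A(t) = A0 + A1 R(t)` with a
#'   time-invariant component `A0` (`N_x x N_s`), a time-varying loading
#'   `A1` (`N_x x N_R`), and a slow trajectory `R` given as an
#'   `N_R x N_s x T` array (e.g. from [rotation_trajectory()] or
#'   [ou_matrix_process()]) or as a function `t_indices -> array`.
#'
#' @param A,A0,A1 numeric matrices (see above for shapes).
#' @param A_list list of `N_x x N_s` matrices, one per context.
#' @param R trajectory of the time-varying coefficients.
#' @return An object of class `eghr_mixing`.
#' @export
static_mixing <- function(A) {
  A <- as.matrix(A)
  structure(list(kind = "static", A = A, n_x = nrow(A), n_s = ncol(A)),
            class = "eghr_mixing")
}

#' @rdname static_mixing
#' @export
per_context_mixing <- function(A_list) {
  if (!is.list(A_list) || length(A_list) == 0) {
    stop_bad_arg("A_list must be a non-empty list of matrices")
  }
  A_list <- lapply(A_list, as.matrix)
  dims <- vapply(A_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_dim("all context matrices must share the same N_x x N_s shape")
  }
  structure(
    list(kind = "per_context", A_list = A_list,
         n_x = dims[1, 1], n_s = dims[2, 1], n_contexts = length(A_list)),
    class = "eghr_mixing"
  )
}

#' @rdname static_mixing
#' @export
time_varying_mixing <- function(A0, A1, R) {
  A0 <- as.matrix(A0); A1 <- as.matrix(A1)
  if (nrow(A0) != nrow(A1)) {
    stop_dim("A0 and A1 must have the same number of rows (N_x)")
  }
  if (is.list(R)) R <- simplify2array(R)
  if (is.array(R) && length(dim(R)) == 3) {
    if (dim(R)[1] != ncol(A1) || dim(R)[2] != ncol(A0)) {
      stop_dim(sprintf(
        "R slices must be %d x %d (N_R x N_s), got %d x %d",
        ncol(A1), ncol(A0), dim(R)[1], dim(R)[2]))
    }
    R_arr <- R
    R_fun <- function(t) {
      if (any(t > dim(R_arr)[3])) {
        stop_bad_arg("R trajectory shorter than requested time index")
      }
      R_arr[, , t, drop = FALSE]
    }
    horizon <- dim(R_arr)[3]
  } else if (is.function(R)) {
    R_fun <- R
    horizon <- Inf
  } else {
    stop_bad_arg("R must be a 3-d array, a list of matrices, or a function")
  }
  structure(
    list(kind = "time_varying", A0 = A0, A1 = A1, R = R_fun,
         horizon = horizon, n_x = nrow(A0), n_s = ncol(A0), n_r = ncol(A1)),
    class = "eghr_mixing"
  )
}

#' @export
print.eghr_mixing <- function(x, ...) {
  cat(sprintf("<eghr_mixing> kind=%s, N_x=%d, N_s=%d", x$kind, x$n_x, x$n_s))
  if (x$kind == "per_context") cat(sprintf(", C=%d", x$n_contexts))
  cat("\n")
  invisible(x)
}

#' Mixing matrix for a given context vector
#'
#' Combines a context-independent component with context-dependent
#' components weighted by the context vector:
#' `A(v) = A0 + sum_k deps[[k]] * v[k]`.
#'
#' @param A0 context-independent `N_x x N_s` matrix.
#' @param deps list of context-dependent matrices, same shape as `A0`.
#' @param v numeric context vector, one weight per element of `deps`.
#' @return The combined `N_x x N_s` mixing matrix.
#' @export
context_vector_mixing <- function(A0, deps, v) {
  A0 <- as.matrix(A0)
  if (!is.list(deps)) stop_bad_arg("deps must be a list of matrices")
  if (length(v) != length(deps)) {
    stop_dim("length(v) must equal length(deps)")
  }
  A <- A0
  for (k in seq_along(deps)) {
    D <- as.matrix(deps[[k]])
    if (!all(dim(D) == dim(A0))) {
      stop_dim("all context-dependent matrices must match dim(A0)")
    }
    A <- A + v[k] * D
  }
  A
}

#' Centered random context components sharing a common feature
#'
#' Draws `n_components` random context matrices `Ahat_k`, sets the shared
#' component `A0` to their mean and the context-dependent components to the
#' centered residuals `A_k = Ahat_k - A0`. By construction the
#' context-dependent components sum exactly to the zero matrix, so they carry
#' no feature common to all contexts; the common feature lives entirely in
#' `A0`. Used with [context_vector_mixing()] for the generalization
#' experiments.
#'
#' @inheritParams sample_mixing_matrix
#' @param n_components number of context matrices to draw.
#' @return A list with elements `A0` (the mean matrix) and `deps` (list of
#'   the centered components).
#' @export
centered_mixing_components <- function(n_x, n_s, n_components = 4,
                                       seed = NULL, scale = 1) {
  check_count(n_components, "n_components")
  if (n_x < n_s) {
    stop_bad_arg("n_x must be >= n_s (undercomplete mixing requirement)")
  }
  with_seed_if(seed, {
    hats <- lapply(seq_len(n_components), function(k) {
      sample_mixing_matrix(n_x, n_s, seed = NULL, scale = scale)
    })
    A0 <- Reduce(`+`, hats) / n_components
    deps <- lapply(hats, function(h) h - A0)
    list(A0 = A0, deps = deps)
  })
}

# ---------------------------------------------------------------------------
# Context schedules

#' Context schedule over training sessions
#'
#' Assigns one context (an index into the mixing model's matrix list) to each
#' training session. `alternating` cycles `1, 2, ..., C, 1, 2, ...`;
#' `uniform_random` draws each session's context uniformly from `1:C`.
#'
#' @param n_contexts number of contexts `C`.
#' @param n_sessions number of sessions.
#' @param session_length time steps per session.
#' @param mode `"alternating"` or `"uniform_random"`.
#' @param seed integer seed (used by `uniform_random`); `NULL` for the
#'   ambient RNG.
#' @return An object of class `eghr_schedule` with fields
#'   `context_of_session`, `session_length`, `mode`.
#' @export
make_context_schedule <- function(n_contexts, n_sessions, session_length,
                                  mode = c("alternating", "uniform_random"),
                                  seed = NULL) {
  check_count(n_contexts, "n_contexts")
  check_count(n_sessions, "n_sessions")
  check_count(session_length, "session_length")
  mode <- match.arg(mode)
  ctx <- switch(mode,
    alternating = rep_len(seq_len(n_contexts), n_sessions),
    uniform_random = with_seed_if(seed, {
      sample.int(n_contexts, n_sessions, replace = TRUE)
    })
  )
  structure(
    list(context_of_session = ctx, session_length = session_length,
         mode = mode, n_contexts = n_contexts),
    class = "eghr_schedule"
  )
}

#' @export
print.eghr_schedule <- function(x, ...) {
  cat(sprintf("<eghr_schedule> %d sessions x %d steps, C=%d, mode=%s\n",
              length(x$context_of_session), x$session_length,
              x$n_contexts, x$mode))
  invisible(x)
}

# context active at global time steps t (1-based)
context_at <- function(schedule, t) {
  session <- (t - 1) %/% schedule$session_length + 1
  if (any(session > length(schedule$context_of_session))) {
    stop_bad_arg("time index beyond the end of the schedule")
  }
  schedule$context_of_session[session]
}

# ---------------------------------------------------------------------------
# Mixing application

#' Mix hidden sources into sensory inputs
#'
#' Applies the generative process column-wise: `x(t) = A s(t)` for static
#' mixing, `x(t) = A^(k(t)) s(t)` under a context schedule, and
#' `x(t) = (A0 + A1 R(t)) s(t)` for time-varying mixing. `t_offset` shifts
#' the global time index so that successive batches of a long run can be
#' mixed piecewise (column `j` of `sources` is taken to be time
#' `t_offset + j - 1`).
#'
#' @param model an `eghr_mixing` object.
#' @param sources `N_s x T` source matrix.
#' @param schedule an `eghr_schedule` (required for per-context mixing).
#' @param t_offset global time index of the first column (default 1).
#' @return The `N_x x T` input matrix.
#' @export
mix <- function(model, sources, schedule = NULL, t_offset = 1) {
  stopifnot(inherits(model, "eghr_mixing"))
  sources <- as.matrix(sources)
  if (nrow(sources) != model$n_s) {
    stop_dim(sprintf("sources have %d rows but the model expects N_s=%d",
                     nrow(sources), model$n_s))
  }
  T_len <- ncol(sources)
  switch(model$kind,
    static = model$A %*% sources,
    per_context = {
      if (is.null(schedule)) {
        stop_bad_arg("per-context mixing requires a context schedule")
      }
      ctx <- context_at(schedule, t_offset + seq_len(T_len) - 1)
      x <- matrix(0, model$n_x, T_len)
      for (k in unique(ctx)) {
        cols <- which(ctx == k)
        x[, cols] <- model$A_list[[k]] %*% sources[, cols, drop = FALSE]
      }
      x
    },
    time_varying = {
      t_idx <- t_offset + seq_len(T_len) - 1
      R <- model$R(t_idx)
      # rs[i, t] = sum_j R[i, j, t] * s[j, t], vectorized over t
      rs <- matrix(0, model$n_r, T_len)
      for (i in seq_len(model$n_r)) {
        for (j in seq_len(model$n_s)) {
          rs[i, ] <- rs[i, ] + R[i, j, ] * sources[j, ]
        }
      }
      model$A0 %*% sources + model$A1 %*% rs
    }
  )
}

# numerical rank via singular values (tolerance relative to the largest)
numeric_rank <- function(M, tol = 1e-10) {
  sv <- svd(M, nu = 0, nv = 0)$d
  if (length(sv) == 0 || sv[1] == 0) return(0L)
  sum(sv > tol * sv[1])
}
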