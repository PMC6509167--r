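#' Sample i.i.d. unit-Laplace source trains
#'
#' Hidden sources of the BSS task: each of the `n_sources` rows is an i.i.d.
#' train from the zero-mean, unit-variance Laplace density
#' `p(s) = exp(-sqrt(2)|s|)/sqrt(2)`, independent across rows and time steps.
#' One row per source, one column per time step.
#'
#' @param n_sources number of hidden sources (rows).
#' @param n_steps number of time steps (columns).
#' @param seed integer seed for reproducibility; `NULL` uses the ambient RNG
#'   state (as the trainer does when drawing successive batches).
#' @return An `n_sources x n_steps` numeric matrix.
#' @examples
#' s <- sample_laplace_sources(2, 1e4, seed = 1)
#' rowMeans(s)        # near 0
#' apply(s, 1, var)   # near 1
#' @export
sample_laplace_sources <- function(n_sources, n_steps, seed = NULL) {
  check_count(n_sources, "n_sources")
  check_count(n_steps, "n_steps")
  with_seed_if(seed, {
    matrix(rlaplace_unit(n_sources * n_steps), nrow = n_sources)
  })
}

#' Deterministic songlike source trains
#'
#' A stand-in for natural birdsong recordings: each source is a deterministic
#' amplitude-modulated multi-harmonic chirp with a distinct fundamental
#' frequency and syllable rhythm, optionally perturbed by additive Laplace
#' white noise, and finally normalized per row to zero mean and unit
#' variance. The waveforms are temporally structured and mutually
#' near-independent, unlike the white Laplace trains of
#' [sample_laplace_sources()], which is the property that matters for the
#' time-varying mixing experiments.
#'
#' @inheritParams sample_laplace_sources
#' @param sample_rate nominal sampling rate in Hz used to convert the chirp
#'   frequencies to per-step phase increments (default 4410).
#' @param noise_scale standard-deviation multiple of the additive Laplace
#'   noise before normalization; 0 gives the pure deterministic waveform.
#' @return An `n_sources x n_steps` matrix with exact zero row means and unit
#'   row variances.
#' @export
make_songlike_sources <- function(n_sources, n_steps, sample_rate = 4410,
                                  seed = NULL, noise_scale = 0.1) {
  check_count(n_sources, "n_sources")
  check_count(n_steps, "n_steps")
  if (!is.numeric(noise_scale) || noise_scale < 0) {
    stop_bad_arg("noise_scale must be a non-negative number")
  }
  t <- (seq_len(n_steps) - 1) / sample_rate
  out <- matrix(0, n_sources, n_steps)
  for (i in seq_len(n_sources)) {
    f0 <- 320 * 1.31^(i - 1)            # distinct fundamental per source
    syl <- 2.1 + 0.6 * i                # syllable (envelope) rate, Hz
    env <- pmax(0, sin(2 * pi * syl * t))^2
    # slow frequency glide within each syllable, as in a chirped song note
    glide <- 1 + 0.12 * sin(2 * pi * 0.37 * syl * t + i)
    phase <- 2 * pi * f0 * glide * t
    wave <- env * (sin(phase) + 0.5 * sin(2 * phase + 0.7 * i) +
                     0.25 * sin(3 * phase + 1.3 * i))
    out[i, ] <- wave
  }
  if (noise_scale > 0) {
    noise <- with_seed_if(seed, {
      matrix(rlaplace_unit(n_sources * n_steps), nrow = n_sources)
    })
    out <- out + noise_scale * noise
  }
  # exact per-row standardization (zero mean, unit variance)
  out <- out - rowMeans(out)
  sds <- sqrt(rowSums(out^2) / (n_steps - 1))
  out / sds
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    stop_bad_arg(sprintf("%s must be a positive integer, got %s",
                         name, deparse(substitute(x))))
  }
  invisible(x)
}
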