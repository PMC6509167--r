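#' Prior models for the agent's source belief
#'
#' A prior model bundles the per-unit negative log-density `-log p0(u)`, its
#' derivative `g(u)` (the score-like nonlinearity of the learning rule), a
#' smoothable second derivative `gprime(u, smoothing)`, and the analytic
#' per-unit entropy `<-log p0(s)>` under the matched source distribution.
#' The entropy enters the calibration of the gating threshold `E0` via
#' [default_E0()].
#'
#' `laplace_prior()` is the zero-mean unit-variance Laplace density
#' `p0(u) = exp(-sqrt(2)|u|)/sqrt(2)`, the standard sparse prior for
#' super-Gaussian sources: `-log p0(u) = sqrt(2)|u| + log(2)/2`,
#' `g(u) = sqrt(2) sign(u)` (subgradient 0 at the origin), per-unit entropy
#' `1 + log(2)/2`. Its `g` is non-smooth, so `gprime` is only available in a
#' smoothed form: `sign(u)` is replaced by `tanh(u / beta)` with
#' `beta = smoothing > 0`, giving
#' `gprime(u, beta) = sqrt(2)/beta * sech(u/beta)^2`, which converges to the
#' distributional derivative `2 sqrt(2) delta(u)` as `beta -> 0`.
#'
#' `gaussian_prior()` is the unit-variance Gaussian:
#' `-log p0(u) = u^2/2 + log(2*pi)/2`, `g(u) = u`, `gprime = 1`, per-unit
#' entropy `(1 + log(2*pi))/2`. It is included as the classical
#' non-identifiable reference case, not as a recommended prior for BSS.
#'
#' @param name character scalar naming the prior.
#' @param neg_log_density vectorized function `u -> -log p0(u)` per unit.
#' @param g vectorized derivative of `neg_log_density`.
#' @param gprime function `(u, smoothing)` returning the derivative of `g`,
#'   possibly smoothed; may be `NULL` when unavailable.
#' @param per_unit_entropy analytic value of `<-log p0(s)>` per unit under
#'   the matched source distribution, or `NA` when no closed form is known.
#' @param sampler function `n -> n` i.i.d. draws from the matched source
#'   distribution (uses the ambient RNG), or `NULL`.
#' @return An object of class `eghr_prior`.
#' @examples
#' pr <- laplace_prior()
#' pr$neg_log_density(0)        # log(2)/2
#' pr$g(c(-2, 0, 3))            # sqrt(2) * c(-1, 0, 1)
#' @export
new_prior <- function(name, neg_log_density, g, gprime = NULL,
                      per_unit_entropy = NA_real_, sampler = NULL) {
  stopifnot(is.character(name), is.function(neg_log_density), is.function(g))
  structure(
    list(
      name = name,
      neg_log_density = neg_log_density,
      g = g,
      gprime = gprime,
      per_unit_entropy = per_unit_entropy,
      sampler = sampler
    ),
    class = "eghr_prior"
  )
}

#' @rdname new_prior
#' @export
laplace_prior <- function() {
  new_prior(
    name = "laplace",
    neg_log_density = function(u) sqrt(2) * abs(u) + 0.5 * log(2),
    g = function(u) sqrt(2) * sign(u),
    gprime = function(u, smoothing) {
      if (smoothing <= 0) {
        stop_bad_arg(
          "gprime of the Laplace prior is distributional; smoothing > 0 required"
        )
      }
      sqrt(2) / smoothing / cosh(u / smoothing)^2
    },
    per_unit_entropy = 1 + 0.5 * log(2),
    sampler = function(n) rlaplace_unit(n)
  )
}

#' @rdname new_prior
#' @export
gaussian_prior <- function() {
  new_prior(
    name = "gaussian",
    neg_log_density = function(u) 0.5 * u^2 + 0.5 * log(2 * pi),
    g = function(u) u,
    gprime = function(u, smoothing = 0) rep(1, length(u)),
    per_unit_entropy = 0.5 * (1 + log(2 * pi)),
    sampler = function(n) rnorm(n)
  )
}

#' @export
print.eghr_prior <- function(x, ...) {
  cat("<eghr_prior> ", x$name,
      if (is.finite(x$per_unit_entropy)) {
        sprintf(" (per-unit entropy %.4f)", x$per_unit_entropy)
      },
      "\n", sep = "")
  invisible(x)
}

# unit-variance Laplace draws (scale b = 1/sqrt(2)) from the ambient RNG
rlaplace_unit <- function(n) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}
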