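# Zero-inflated Beta (ZIB) distribution on [0, 1): a point mass at zero
# with probability zi mixed with a Beta distribution on (0, 1)
# parameterized by its mean mu and precision phi, so that
# alpha = mu * phi and beta = (1 - mu) * phi.

#' Zero-inflated Beta parameters
#'
#' Constructor and validator for the (zi, mu, phi) parameterization of the
#' zero-inflated Beta distribution: `zi` is the probability of an exact
#' zero, and conditional on a non-zero the value follows
#' Beta(mu * phi, (1 - mu) * phi), i.e. a Beta with mean `mu` and
#' precision `phi`.
#'
#' @param zi Zero-inflation probability in \[0, 1\].
#' @param mu Beta mean in (0, 1).
#' @param phi Beta precision (> 0); larger values concentrate the Beta
#'   component around `mu`.
#' @return A list of class `zib_params`.
#' @examples
#' zib_params(zi = 0.2, mu = 0.55, phi = 8)
#' @export
zib_params <- function(zi, mu, phi) {
  if (!is.numeric(zi) || length(zi) != 1 || is.na(zi) || zi < 0 || zi > 1) {
    abort("`zi` must be a single number in [0, 1]", class = "db_param_error")
  }
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu <= 0 || mu >= 1) {
    abort("`mu` must be a single number in (0, 1)", class = "db_param_error")
  }
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi <= 0) {
    abort("`phi` must be a single positive number", class = "db_param_error")
  }
  structure(list(zi = zi, mu = mu, phi = phi), class = "zib_params")
}

as_zib_params <- function(x) {
  if (inherits(x, "zib_params")) return(x)
  zib_params(x$zi, x$mu, x$phi)
}

#' @export
print.zib_params <- function(x, ...) {
  cat(sprintf("<zib_params> zi = %.4g, mu = %.4g, phi = %.4g (mean rate %.4g)\n",
              x$zi, x$mu, x$phi, (1 - x$zi) * x$mu))
  invisible(x)
}

#' Zero-inflated Beta log density
#'
#' Log density of the zero-inflated Beta mixture: `log(zi)` for an exact
#' zero, and `log(1 - zi) + log dBeta(y; mu * phi, (1 - mu) * phi)` for
#' `y` in (0, 1). Discard rates are expressed as tonnes of discards per
#' tonnes of total catch, so `y = 1` (pure discarding) is outside the
#' model's support and must be clamped upstream (see [fit_gear_model()],
#' which clamps to `1 - 1e-6`).
#'
#' @param y Observed rate(s) in \[0, 1). Vectorized.
#' @param params A [zib_params()] object.
#' @return Log density, same length as `y`.
#' @examples
#' zib_logpdf(0, zib_params(0.25, 0.5, 2))   # log(0.25)
#' zib_logpdf(0.5, zib_params(0, 0.5, 2))    # Beta(1,1) is uniform: 0
#' @export
zib_logpdf <- function(y, params) {
  params <- as_zib_params(params)
  if (any(is.na(y)) || any(y < 0) || any(y > 1)) {
    abort("`y` must lie in [0, 1)", class = "db_domain_error")
  }
  if (any(y == 1)) {
    abort(
      "`y` = 1 is outside the zero-inflated Beta support; clamp rates of 1 to 1 - 1e-6 before evaluation",
      class = "db_domain_error"
    )
  }
  out <- numeric(length(y))
  zero <- y == 0
  out[zero] <- log(params$zi)
  if (any(!zero)) {
    a <- params$mu * params$phi
    b <- (1 - params$mu) * params$phi
    out[!zero] <- log1p(-params$zi) + dbeta(y[!zero], a, b, log = TRUE)
  }
  out
}

#' Expected value of a zero-inflated Beta distribution
#'
#' The expected discard rate under the mixture: `(1 - zi) * mu`. This is
#' the gear-level quantity propagated to unobserved fisheries.
#'
#' @inheritParams zib_logpdf
#' @return The mean, a number in \[0, 1).
#' @examples
#' zib_mean(zib_params(0.2, 0.5, 4))  # 0.4
#' @export
zib_mean <- function(params) {
  params <- as_zib_params(params)
  (1 - params$zi) * params$mu
}

#' Sample from a zero-inflated Beta distribution
#'
#' Each draw is 0 with probability `zi` and otherwise a
#' Beta(mu * phi, (1 - mu) * phi) variate. Draws are clamped strictly
#' below 1 so they remain valid discard rates.
#'
#' @inheritParams zib_logpdf
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` values in \[0, 1).
#' @export
sample_zib <- function(params, n, seed = NULL) {
  params <- as_zib_params(params)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive count", class = "db_param_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  a <- params$mu * params$phi
  b <- (1 - params$mu) * params$phi
  zero <- runif(n) < params$zi
  out <- numeric(n)
  n_pos <- sum(!zero)
  if (n_pos > 0) out[!zero] <- pmin(rbeta(n_pos, a, b), 1 - 1e-12)
  out
}
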