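# Posterior interval summaries: highest-density intervals for rates,
# equal-tailed intervals for levels.

new_interval <- function(lo, hi, mass, kind) {
  tibble(lo = lo, hi = hi, mass = mass, kind = kind)
}

check_draws <- function(draws, min_n = 20L) {
  if (!is.numeric(draws) || any(!is.finite(draws))) {
    abort("`draws` must be a finite numeric vector", class = "db_param_error")
  }
  if (length(draws) < min_n) {
    abort(
      paste0("at least ", min_n, " draws are required (got ", length(draws), ")"),
      class = "db_sample_size_error"
    )
  }
  invisible(draws)
}

#' Highest posterior density interval
#'
#' The shortest contiguous window over the sorted draws containing
#' `ceiling(mass * n)` values. Among windows of equal minimal width the one
#' with the smallest lower bound is returned. An HDI is the natural summary
#' for skewed posteriors such as discard rates near zero.
#'
#' @param draws Numeric vector of posterior / Monte Carlo draws (>= 20).
#' @param mass Nominal probability mass in (0, 1); default 0.95.
#' @return A one-row tibble with columns `lo`, `hi`, `mass`, `kind`
#'   (`"hdi"`).
#' @examples
#' set.seed(1)
#' hdi(rnorm(1e4), 0.95)
#' @export
hdi <- function(draws, mass = 0.95) {
  check_draws(draws)
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    abort("`mass` must be a single probability in (0, 1)", class = "db_param_error")
  }
  x <- sort(draws)
  n <- length(x)
  w <- ceiling(mass * n)
  k <- n - w + 1L
  widths <- x[w:n] - x[1:k]
  i <- which.min(widths)  # first minimum: smallest lower bound among ties
  new_interval(x[i], x[i + w - 1L], mass, "hdi")
}

#' Equal-tailed credible interval
#'
#' The interval between the (1 - mass)/2 and 1 - (1 - mass)/2 empirical
#' quantiles of the draws, with linear interpolation
#' ([stats::quantile()] type 7). Used for discard levels (tonnages).
#'
#' @inheritParams hdi
#' @return A one-row tibble with columns `lo`, `hi`, `mass`, `kind`
#'   (`"equal-tailed"`).
#' @export
equal_tailed <- function(draws, mass = 0.95) {
  check_draws(draws)
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    abort("`mass` must be a single probability in (0, 1)", class = "db_param_error")
  }
  q <- quantile(draws, probs = c((1 - mass) / 2, 1 - (1 - mass) / 2),
                names = FALSE, type = 7)
  new_interval(q[1], q[2], mass, "equal-tailed")
}
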