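# ggplot2 displays for the two result types: stratum estimates (dot +
# interval, the conventional way gear- or area-level discard rates are
# shown) and gear posteriors (marginal densities).

#' Plot stratum estimates
#'
#' Dot-and-interval plot of stratified discard estimates: the mean
#' discard rate with its 95% HDI (`what = "rate"`) or the mean discard
#' level with its 95% CI (`what = "level"`), one row per stratum, sorted
#' by the mean.
#'
#' @param object A `stratum_estimates` tibble from [aggregate_discards()].
#' @param what `"rate"` or `"level"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stratum_estimates
#' @export
autoplot.stratum_estimates <- function(object, what = c("rate", "level"), ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  if (what == "rate") {
    df <- df %>%
      mutate(mid = 100 * .data$mean_rate, lo = 100 * .data$rate_hdi_lo,
             hi = 100 * .data$rate_hdi_hi)
    xlab <- "Discard rate (% of total catch, 95% HDI)"
  } else {
    df <- df %>%
      mutate(mid = .data$mean_level_t / 1e3, lo = .data$level_ci_lo / 1e3,
             hi = .data$level_ci_hi / 1e3)
    xlab <- "Discard level (kt, 95% CI)"
  }
  df$stratum_label <- stats::reorder(df$stratum_label, df$mid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$stratum_label)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_fisheries),
                        colour = "#2c7fb8") +
    ggplot2::scale_size_area(max_size = 6, name = "fisheries") +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a gear posterior
#'
#' Marginal posterior densities of the zero-inflation probability, Beta
#' mean, Beta precision and the derived mean discard rate.
#'
#' @param object A `gear_posterior` from [fit_gear_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gear_posterior
#' @export
autoplot.gear_posterior <- function(object, ...) {
  d <- object$draws %>%
    mutate(mean_rate = (1 - .data$zi) * .data$mu) %>%
    tidyr::pivot_longer(c("zi", "mu", "phi", "mean_rate"),
                        names_to = "param", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "#2c7fb8", alpha = 0.4, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(
      title = paste0("Posterior: ", object$gear_type %||% "gear"),
      x = NULL, y = "density"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
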