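# Bayesian fitting of gear-specific zero-inflated Beta models with a
# self-contained adaptive random-walk Metropolis sampler.
#
# The model is intercept-only per gear, sampled on the unconstrained scale
# theta = (logit(zi), logit(mu), log(phi)). Because the ZIB likelihood
# factorizes, the weighted log-likelihood is computed from four sufficient
# statistics (zero weight, positive weight, sum w*log y, sum w*log(1-y)),
# making each posterior evaluation O(1) in the number of observations.

#' Prior configuration for gear-level zero-inflated Beta models
#'
#' Weakly informative defaults on the unconstrained scale:
#' `logit(zi) ~ Normal(0, 1.5)`, `logit(mu) ~ Normal(0, 1.5)`,
#' `log(phi) ~ Normal(log 10, 1)`. The logit-Normal(0, 1.5) priors are
#' close to uniform on (0, 1) while discouraging the extreme boundaries;
#' the log-Normal prior on the precision centres on moderately dispersed
#' Beta components. `zi_prior = "flat"` replaces the logit-Normal on `zi`
#' with a uniform prior on the probability scale (useful for calibration
#' checks against the conjugate Beta-Binomial zero-count posterior).
#'
#' @param zi_logit,mu_logit Length-2 numeric `(mean, sd)` of the Normal
#'   prior on the logit scale.
#' @param log_phi Length-2 numeric `(mean, sd)` of the Normal prior on
#'   `log(phi)`.
#' @param zi_prior `"logit_normal"` (default) or `"flat"` (uniform on
#'   \[0, 1\]).
#' @return A list of class `zib_priors`.
#' @export
zib_priors <- function(zi_logit = c(0, 1.5), mu_logit = c(0, 1.5),
                       log_phi = c(log(10), 1),
                       zi_prior = c("logit_normal", "flat")) {
  zi_prior <- match.arg(zi_prior)
  stopifnot(length(zi_logit) == 2, length(mu_logit) == 2, length(log_phi) == 2,
            zi_logit[2] > 0, mu_logit[2] > 0, log_phi[2] > 0)
  structure(list(zi_logit = zi_logit, mu_logit = mu_logit, log_phi = log_phi,
                 zi_prior = zi_prior),
            class = "zib_priors")
}

#' Sampler configuration for the adaptive random-walk Metropolis
#'
#' Defaults follow common practice for short, well-mixing chains on a
#' three-parameter posterior: 4 chains of 2,000 iterations with the first
#' 1,000 discarded as warmup. Proposal standard deviations are adapted
#' per parameter during warmup only, in batches, towards an acceptance
#' rate of 0.44 (the component-wise optimum, inside the 0.3--0.5 band);
#' after warmup the step sizes are frozen so the chain is a valid Markov
#' chain.
#'
#' @param chains Number of chains.
#' @param iter Total iterations per chain (including warmup).
#' @param warmup Warmup iterations per chain (adaptation window).
#' @param init_step Initial proposal standard deviations for
#'   `(logit zi, logit mu, log phi)`.
#' @param target_accept Target acceptance rate for adaptation.
#' @param adapt_batch Batch size (iterations) between step-size updates.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4L, iter = 2000L, warmup = 1000L,
                         init_step = c(0.6, 0.6, 0.6),
                         target_accept = 0.44, adapt_batch = 50L) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 0, length(init_step) == 3,
            all(init_step > 0), target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), init_step = init_step,
                 target_accept = target_accept,
                 adapt_batch = as.integer(adapt_batch)),
            class = "mcmc_control")
}

# Sufficient statistics of the weighted ZIB likelihood.
zib_suffstats <- function(rate, weight) {
  zero <- rate == 0
  list(
    w0 = sum(weight[zero]),
    wp = sum(weight[!zero]),
    s1 = sum(weight[!zero] * log(rate[!zero])),
    s2 = sum(weight[!zero] * log1p(-rate[!zero]))
  )
}

# Log posterior on the unconstrained scale, closed over sufficient stats.
zib_logpost_factory <- function(ss, priors) {
  force(ss); force(priors)
  flat_zi <- priors$zi_prior == "flat"
  function(theta) {
    zi  <- plogis(theta[1])
    mu  <- plogis(theta[2])
    phi <- exp(theta[3])
    a <- mu * phi
    b <- (1 - mu) * phi
    ll <- 0
    if (ss$w0 > 0) ll <- ll + ss$w0 * log(zi)
    if (ss$wp > 0) {
      ll <- ll + ss$wp * log1p(-zi) +
        (a - 1) * ss$s1 + (b - 1) * ss$s2 - ss$wp * lbeta(a, b)
    }
    lp <- if (flat_zi) {
      # uniform on zi: Jacobian of the logistic transform
      log(zi) + log1p(-zi)
    } else {
      dnorm(theta[1], priors$zi_logit[1], priors$zi_logit[2], log = TRUE)
    }
    lp <- lp +
      dnorm(theta[2], priors$mu_logit[1], priors$mu_logit[2], log = TRUE) +
      dnorm(theta[3], priors$log_phi[1], priors$log_phi[2], log = TRUE)
    ll + lp
  }
}

run_chain <- function(logpost, init, control, chain_seed) {
  set.seed(chain_seed)
  n_par <- length(init)
  theta <- init
  lp <- logpost(theta)
  if (is.nan(lp)) {
    abort(paste0("NaN log-posterior at initial state (",
                 paste(signif(theta, 6), collapse = ", "), ")"),
          class = "db_sampler_error")
  }
  step <- control$init_step
  draws <- matrix(NA_real_, nrow = control$iter, ncol = n_par)
  acc <- integer(n_par)
  batch <- 0L
  for (it in seq_len(control$iter)) {
    for (p in seq_len(n_par)) {
      prop <- theta
      prop[p] <- theta[p] + rnorm(1, 0, step[p])
      lp_prop <- logpost(prop)
      if (is.nan(lp_prop)) {
        abort(paste0("NaN log-posterior at state (",
                     paste(signif(prop, 6), collapse = ", "), ")"),
              class = "db_sampler_error")
      }
      if (log(runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        acc[p] <- acc[p] + 1L
      }
    }
    if (it <= control$warmup && it %% control$adapt_batch == 0L) {
      batch <- batch + 1L
      delta <- min(0.25, 1 / sqrt(batch))
      rate <- acc / control$adapt_batch
      step <- step * exp(delta * (rate - control$target_accept))
      acc <- integer(n_par)
    }
    draws[it, ] <- theta
  }
  draws[(control$warmup + 1):control$iter, , drop = FALSE]
}

# Split-R-hat (each chain halved) for a draws matrix (iterations x chains).
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  split <- cbind(mat[seq_len(half), , drop = FALSE],
                 mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  w <- mean(vars)
  b <- nn * var(means)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# Effective sample size across split chains (Geyer initial monotone
# positive sequence, as used by modern samplers).
ess <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  split <- cbind(mat[seq_len(half), , drop = FALSE],
                 mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  vars <- apply(split, 2, var)
  w <- mean(vars)
  if (w == 0) return(m * nn)
  b <- nn * var(colMeans(split))
  var_plus <- (nn - 1) / nn * w + b / nn
  lag_max <- min(nn - 2L, 500L)
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(split[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  # combined autocorrelation at lags 0..lag_max (Stan-style), then Geyer
  # initial monotone positive sequence over consecutive lag pairs
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  n_pairs <- length(rho) %/% 2L
  if (n_pairs == 0) return(m * nn)
  p <- rho[seq_len(2 * n_pairs)]
  pair_sums <- p[c(TRUE, FALSE)] + p[c(FALSE, TRUE)]
  pos <- which(pair_sums <= 0)
  k <- if (length(pos) == 0) n_pairs else pos[1] - 1L
  if (k == 0) return(m * nn)
  ps <- cummin(pair_sums[seq_len(k)])
  tau <- -1 + 2 * sum(ps)
  min(max(m * nn / max(tau, 1e-12), 1), m * nn)
}

#' Fit a Bayesian zero-inflated Beta model for one gear type
#'
#' Fits an intercept-only zero-inflated Beta model to the discard-rate
#' observations of a single gear type, by adaptive random-walk Metropolis
#' on the unconstrained scale (logit for `zi` and `mu`, log for `phi`).
#' The weighted log-likelihood is the sum of `weight * zib_logpdf(rate)`
#' over observations. Multiple records for one fishery enter individually.
#' With zero observations the posterior reproduces the prior.
#'
#' Observations equal to 1 are clamped to `1 - 1e-6` with a warning: the
#' model has zero-inflation only, not one-inflation.
#'
#' @param observations Data frame with columns `rate` (in \[0, 1\]) and
#'   optionally `weight` (> 0, default 1) and `gear_type` (must be a
#'   single value if present). May have zero rows.
#' @param priors A [zib_priors()] configuration.
#' @param control An [mcmc_control()] configuration.
#' @param seed Integer seed; chain seeds are derived from it.
#' @return An object of class `gear_posterior`: a list with elements
#'   `gear_type`, `draws` (tibble with columns `chain`, `iter`, `zi`,
#'   `mu`, `phi`, post-warmup only), `diagnostics` (tibble with
#'   per-parameter split R-hat and effective sample size), `n_obs`,
#'   `converged` (all split R-hat <= 1.01) and `accepted` (`converged`
#'   and at least 1,000 pooled draws).
#' @examples
#' obs <- tibble::tibble(rate = sample_zib(zib_params(0.2, 0.5, 6), 200, seed = 1))
#' fit <- fit_gear_model(obs, control = mcmc_control(chains = 2, iter = 600, warmup = 300))
#' glance(fit)
#' @export
fit_gear_model <- function(observations, priors = zib_priors(),
                           control = mcmc_control(), seed = 1L) {
  observations <- as_tibble(observations)
  gear <- if ("gear_type" %in% names(observations) && nrow(observations) > 0) {
    g <- unique(observations$gear_type)
    if (length(g) != 1) {
      abort("observations must all share one gear_type", class = "db_param_error")
    }
    g
  } else {
    NA_character_
  }
  if (!"weight" %in% names(observations)) observations$weight <- 1
  rate <- observations$rate
  weight <- observations$weight
  if (any(rate < 0 | rate > 1)) {
    abort("rates must lie in [0, 1]", class = "db_validation_error")
  }
  if (any(weight <= 0)) {
    abort("weights must be positive", class = "db_validation_error")
  }
  if (any(rate == 1)) {
    warn("observed rate(s) of 1 clamped to 1 - 1e-6 (model is zero-inflated only)")
    rate[rate == 1] <- 1 - 1e-6
  }
  pos <- rate[rate > 0]
  if (length(pos) > 1 && length(unique(pos)) == 1) {
    warn("all interior observations identical; Beta precision is informed mainly by its prior")
  }

  ss <- zib_suffstats(rate, weight)
  logpost <- zib_logpost_factory(ss, priors)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, control$chains)
  chains <- vector("list", control$chains)
  for (c_i in seq_len(control$chains)) {
    set.seed(chain_seeds[c_i])
    init <- c(
      rnorm(1, priors$zi_logit[1], priors$zi_logit[2] / 2),
      rnorm(1, priors$mu_logit[1], priors$mu_logit[2] / 2),
      rnorm(1, priors$log_phi[1], priors$log_phi[2] / 2)
    )
    chains[[c_i]] <- run_chain(logpost, init, control, chain_seeds[c_i])
  }

  n_keep <- control$iter - control$warmup
  param_names <- c("zi", "mu", "phi")
  # diagnostics on the sampled (unconstrained) scale
  diag_tbl <- tibble(
    param = param_names,
    rhat = vapply(1:3, function(p) {
      split_rhat(sapply(chains, function(ch) ch[, p]))
    }, numeric(1)),
    ess = vapply(1:3, function(p) {
      ess(sapply(chains, function(ch) ch[, p]))
    }, numeric(1))
  )

  draws <- purrr::map2_dfr(chains, seq_along(chains), function(ch, id) {
    tibble(
      chain = id,
      iter = seq_len(n_keep),
      zi = plogis(ch[, 1]),
      mu = plogis(ch[, 2]),
      phi = exp(ch[, 3])
    )
  })

  converged <- all(diag_tbl$rhat <= 1.01)
  structure(
    list(
      gear_type = gear,
      draws = draws,
      diagnostics = diag_tbl,
      n_obs = nrow(observations),
      converged = converged,
      accepted = converged && nrow(draws) >= 1000,
      priors = priors,
      control = control,
      seed = seed
    ),
    class = "gear_posterior"
  )
}

#' @export
print.gear_posterior <- function(x, ...) {
  cat(sprintf("<gear_posterior> gear: %s | n_obs: %d | draws: %d | converged: %s\n",
              x$gear_type, x$n_obs, nrow(x$draws), x$converged))
  print(tidy(x))
  invisible(x)
}

#' Tidy a gear posterior
#'
#' One row per parameter (`zi`, `mu`, `phi`, and the derived mean discard
#' rate `mean_rate = (1 - zi) * mu`) with posterior mean, standard
#' deviation, 95% HDI and convergence diagnostics.
#'
#' @param x A `gear_posterior` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gear_posterior
#' @export
tidy.gear_posterior <- function(x, ...) {
  d <- x$draws
  vals <- list(zi = d$zi, mu = d$mu, phi = d$phi,
               mean_rate = (1 - d$zi) * d$mu)
  purrr::imap_dfr(vals, function(v, nm) {
    iv <- hdi(v, 0.95)
    diag_row <- x$diagnostics[x$diagnostics$param == nm, ]
    tibble(
      term = nm,
      estimate = mean(v),
      std.error = stats::sd(v),
      hdi_lo = iv$lo,
      hdi_hi = iv$hi,
      rhat = if (nrow(diag_row)) diag_row$rhat else NA_real_,
      ess = if (nrow(diag_row)) diag_row$ess else NA_real_
    )
  })
}

#' Glance at a gear posterior
#'
#' @param x A `gear_posterior` object.
#' @param ... Unused.
#' @return A one-row tibble with the gear label, sample sizes, posterior
#'   mean discard rate, worst split R-hat / smallest effective sample
#'   size, and convergence flags.
#' @method glance gear_posterior
#' @export
glance.gear_posterior <- function(x, ...) {
  tibble(
    gear_type = x$gear_type,
    n_obs = x$n_obs,
    n_draws = nrow(x$draws),
    mean_rate = mean((1 - x$draws$zi) * x$draws$mu),
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess),
    converged = x$converged,
    accepted = x$accepted
  )
}

#' Export / import posterior draws as CSV
#'
#' One row per retained draw with columns `chain`, `iter`, `zi`, `mu`,
#' `phi`.
#'
#' @param posterior A `gear_posterior` object.
#' @param path Output CSV path.
#' @return `write_posterior_draws()` returns `path` invisibly;
#'   `read_posterior_draws()` returns the draws tibble.
#' @export
write_posterior_draws <- function(posterior, path) {
  readr::write_csv(posterior$draws, path)
  invisible(path)
}

#' @rdname write_posterior_draws
#' @export
read_posterior_draws <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    chain = readr::col_integer(), iter = readr::col_integer(),
    zi = readr::col_double(), mu = readr::col_double(),
    phi = readr::col_double()
  ))
}
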