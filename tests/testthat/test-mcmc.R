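# Bayesian gear-model fitting: likelihood equivalence, prior recovery,
# parameter recovery, conjugate cross-check, determinism.

test_that("the sufficient-statistic log posterior equals the direct weighted zib_logpdf sum", {
  set.seed(12)
  rate <- c(0, 0, sample_zib(zib_params(0, 0.4, 6), 8))
  weight <- runif(10, 0.5, 3)
  ss <- discardbench:::zib_suffstats(rate, weight)
  priors <- zib_priors()
  lp <- discardbench:::zib_logpost_factory(ss, priors)
  for (theta in list(c(0, 0, 1), c(-1, 0.5, 2), c(1.5, -2, 0.3))) {
    p <- zib_params(plogis(theta[1]), plogis(theta[2]), exp(theta[3]))
    direct <- sum(weight * zib_logpdf(rate, p)) +
      dnorm(theta[1], 0, 1.5, log = TRUE) +
      dnorm(theta[2], 0, 1.5, log = TRUE) +
      dnorm(theta[3], log(10), 1, log = TRUE)
    expect_equal(lp(theta), direct, tolerance = 1e-12)
  }
})

test_that("with no observations the posterior reproduces the prior", {
  fit <- fit_gear_model(empty_observations(),
                        control = mcmc_control(chains = 4, iter = 1500, warmup = 500),
                        seed = 21)
  # prior on logit(zi) is Normal(0, 1.5), symmetric: E[zi] = 0.5
  prior_draws <- plogis(rnorm(2e5, 0, 1.5))
  mc_se <- stats::sd(fit$draws$zi) / sqrt(min(fit$diagnostics$ess))
  expect_lt(abs(mean(fit$draws$zi) - mean(prior_draws)), 4 * mc_se + 0.01)
  expect_gte(nrow(fit$draws), 1000)
})

test_that("parameters are recovered from simulated data", {
  truth <- zib_params(0.2, 0.55, 8)
  obs <- tibble::tibble(
    gear_type = "bottom otter trawl",
    rate = sample_zib(truth, 500, seed = 314)
  )
  fit <- fit_gear_model(obs, seed = 271)
  s <- tidy(fit)
  est <- setNames(s$estimate, s$term)
  expect_lt(abs(est[["zi"]] - truth$zi), 0.05)
  expect_lt(abs(est[["mu"]] - truth$mu), 0.05)
  expect_lt(abs(est[["phi"]] - truth$phi) / truth$phi, 0.30)
  expect_true(all(fit$draws$zi >= 0 & fit$draws$zi <= 1))
  expect_true(all(fit$draws$mu > 0 & fit$draws$mu < 1))
  expect_true(all(fit$draws$phi > 0))
})

test_that("the zero-inflation posterior matches the conjugate Beta-Binomial under a flat prior", {
  # k zeros out of n with a uniform prior on zi: posterior mean (k+1)/(n+2)
  set.seed(55)
  k <- 7; n <- 25
  obs <- tibble::tibble(rate = c(rep(0, k), rbeta(n - k, 2, 3)))
  fit <- fit_gear_model(obs, priors = zib_priors(zi_prior = "flat"), seed = 99)
  expected <- (k + 1) / (n + 2)
  zi_ess <- fit$diagnostics$ess[fit$diagnostics$param == "zi"]
  mc_se <- stats::sd(fit$draws$zi) / sqrt(zi_ess)
  expect_lt(abs(mean(fit$draws$zi) - expected), 4 * mc_se + 0.005)
})

test_that("fits are deterministic given seed and config, and edge cases warn", {
  obs <- tibble::tibble(rate = sample_zib(zib_params(0.1, 0.3, 5), 60, seed = 8))
  f1 <- fit_gear_model(obs, control = mcmc_control(2, 400, 200), seed = 31)
  f2 <- fit_gear_model(obs, control = mcmc_control(2, 400, 200), seed = 31)
  expect_identical(f1$draws, f2$draws)

  expect_warning(
    fit_gear_model(tibble::tibble(rate = rep(0.4, 10)),
                   control = mcmc_control(2, 300, 150), seed = 3),
    "identical"
  )
  expect_warning(
    fit_gear_model(tibble::tibble(rate = c(0.2, 1)),
                   control = mcmc_control(2, 300, 150), seed = 3),
    "clamped"
  )
  expect_error(
    fit_gear_model(tibble::tibble(rate = c(0.2, 0.4),
                                  gear_type = c("gillnet", "handline"))),
    class = "db_param_error"
  )
})

test_that("posterior draws round-trip through CSV", {
  obs <- tibble::tibble(gear_type = "gillnet",
                        rate = sample_zib(zib_params(0.2, 0.3, 6), 40, seed = 2))
  fit <- fit_gear_model(obs, control = mcmc_control(2, 400, 200), seed = 17)
  path <- file.path(withr::local_tempdir(), "draws.csv")
  write_posterior_draws(fit, path)
  back <- read_posterior_draws(path)
  expect_equal(as.data.frame(back), as.data.frame(fit$draws), tolerance = 1e-12)
  g <- glance(fit)
  expect_identical(g$gear_type, "gillnet")
  expect_identical(g$n_draws, nrow(fit$draws))
})
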