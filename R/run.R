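# End-to-end pipeline driver: read and validate the four input tables,
# fit one zero-inflated Beta model per gear appearing in tier 3, assign
# rates, propagate, aggregate over all four stratification schemes, and
# write the output tables plus a machine-readable run manifest.

#' Run configuration
#'
#' Collects everything a pipeline run needs: the four input table paths,
#' the assessment period, the number of Monte Carlo draws, the master
#' seed, sampler and prior settings, the rate cap and the output
#' directory. Can be read from a YAML file with [read_run_config()].
#'
#' @param landings,allocation_keys,observations,policy_rates Input CSV
#'   paths.
#' @param output_dir Directory for output tables and the manifest.
#' @param period Years of the assessment period.
#' @param n_draws Monte Carlo draws (>= 100).
#' @param seed Master seed; all other seeds are derived from it.
#' @param priors A [zib_priors()] object.
#' @param mcmc An [mcmc_control()] object.
#' @param rate_cap Rate cap for the rate-to-level conversion.
#' @param tier3_mode Gear-model tier mode passed to [assign_rates()]:
#'   `"gear_mean"` (default) or `"posterior_predictive"`.
#' @param allow_nonconverged Keep going when a gear fit fails the split
#'   R-hat <= 1.01 check (default FALSE: error).
#' @return A list of class `run_config`.
#' @export
run_config <- function(landings, allocation_keys, observations, policy_rates,
                       output_dir, period = default_vocab()$period,
                       n_draws = 4000L, seed = 1L,
                       priors = zib_priors(), mcmc = mcmc_control(),
                       rate_cap = 0.99,
                       tier3_mode = c("gear_mean", "posterior_predictive"),
                       allow_nonconverged = FALSE) {
  tier3_mode <- match.arg(tier3_mode)
  if (n_draws < 100) {
    abort("`n_draws` must be at least 100", class = "db_config_error")
  }
  paths <- c(landings = landings, allocation_keys = allocation_keys,
             observations = observations, policy_rates = policy_rates)
  missing_p <- paths[!file.exists(paths)]
  if (length(missing_p) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing_p, collapse = ", ")),
          class = "db_config_error")
  }
  structure(list(landings = landings, allocation_keys = allocation_keys,
                 observations = observations, policy_rates = policy_rates,
                 output_dir = output_dir, period = period,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 priors = priors, mcmc = mcmc, rate_cap = rate_cap,
                 tier3_mode = tier3_mode,
                 allow_nonconverged = isTRUE(allow_nonconverged)),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML run-configuration file with keys matching
#'   the `run_config()` arguments (`priors` and `mcmc` as nested maps).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  priors <- do.call(zib_priors, raw$priors %||% list())
  mcmc <- do.call(mcmc_control, raw$mcmc %||% list())
  period <- if (is.null(raw$period)) default_vocab()$period else {
    seq.int(raw$period$start, raw$period$end)
  }
  run_config(
    landings = resolve(raw$landings),
    allocation_keys = resolve(raw$allocation_keys),
    observations = resolve(raw$observations),
    policy_rates = resolve(raw$policy_rates),
    output_dir = raw$output_dir %||% file.path(base, "output"),
    period = period,
    n_draws = raw$n_draws %||% 4000L,
    seed = raw$seed %||% 1L,
    priors = priors, mcmc = mcmc,
    rate_cap = raw$rate_cap %||% 0.99,
    tier3_mode = raw$tier3_mode %||% "gear_mean",
    allow_nonconverged = raw$allow_nonconverged %||% FALSE
  )
}

#' Run the full discard-estimation pipeline
#'
#' Executes the whole chain — input validation, landings allocation,
#' per-gear Bayesian zero-inflated Beta fits for the gears needed by the
#' gear-model tier, three-tier rate assignment, Monte Carlo propagation
#' and stratified aggregation — and writes one stratum table per
#' stratification scheme (global, FAO area, gear type, target group), a
#' per-gear posterior summary, a tier-accounting table and a JSON
#' manifest recording seeds, configuration and convergence diagnostics.
#' On failure, partial outputs are removed.
#'
#' @param config A [run_config()] (or a path to a YAML config file).
#' @return Invisibly, a list with `estimates` (named list of
#'   stratum-estimate tibbles), `posteriors`, `tier_summary`, `manifest`
#'   and `output_files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written) > 0) unlink(written), add = TRUE)

  inform("[fao_io] reading input tables")
  landings <- read_landings(config$landings, period = config$period)
  keys <- read_allocation_keys(config$allocation_keys)
  observations <- read_observations(config$observations)
  policy <- read_policy_rates(config$policy_rates)

  inform("[estimation_pipeline] allocating landings to fisheries")
  fisheries <- allocate_landings(landings, keys, period = config$period)

  # gears needing a model: those of fisheries with neither an observation
  # nor a policy match
  probe <- assign_tiers_only(fisheries, observations, policy)
  model_gears <- sort(unique(probe$gear_type[probe$tier == "gear_model"]))

  set.seed(config$seed)
  gear_seeds <- setNames(sample.int(.Machine$integer.max - 1L,
                                    length(model_gears)), model_gears)
  posteriors <- list()
  for (g in model_gears) {
    inform(paste0("[zib_inference] fitting gear model: ", g))
    obs_g <- observations[observations$gear_type == g, ]
    fit <- fit_gear_model(obs_g, priors = config$priors, control = config$mcmc,
                          seed = gear_seeds[[g]])
    if (!fit$converged && !config$allow_nonconverged) {
      abort(paste0("[zib_inference] gear model for '", g,
                   "' failed convergence (max split R-hat = ",
                   signif(max(fit$diagnostics$rhat), 4), ")"),
            class = "db_convergence_error")
    }
    posteriors[[g]] <- fit
  }

  inform("[estimation_pipeline] assigning rates and propagating uncertainty")
  assign_seed <- sample.int(.Machine$integer.max - 1L, 1)
  assignments <- assign_rates(fisheries, observations, policy, posteriors,
                              n_draws = config$n_draws, seed = assign_seed,
                              rate_cap = config$rate_cap,
                              tier3_mode = config$tier3_mode)
  draws <- propagate(fisheries, assignments, n_draws = config$n_draws)

  stratum_types <- c("global", "fao_area", "gear_type", "target_group")
  estimates <- lapply(setNames(stratum_types, stratum_types), function(st) {
    aggregate_discards(fisheries, draws, stratum_type = st)
  })

  out <- function(name) file.path(config$output_dir, name)
  for (st in stratum_types) {
    f <- out(paste0("stratum_", st, ".csv"))
    write_stratum_table(estimates[[st]], f)
    written <- c(written, f)
  }
  gear_summary <- purrr::map_dfr(posteriors, glance)
  f <- out("gear_posteriors.csv")
  readr::write_csv(gear_summary, f)
  written <- c(written, f)
  tiers <- tier_summary(assignments)
  f <- out("tier_accounting.csv")
  readr::write_csv(tiers, f)
  written <- c(written, f)

  manifest <- list(
    package_version = as.character(utils::packageVersion("discardbench")),
    seed = config$seed,
    gear_seeds = as.list(gear_seeds),
    assign_seed = assign_seed,
    n_draws = config$n_draws,
    period = range(config$period),
    rate_cap = config$rate_cap,
    tier3_mode = config$tier3_mode,
    n_fisheries = nrow(fisheries),
    tier_counts = setNames(as.list(tiers$n_fisheries), tiers$tier),
    tier_catch_shares = setNames(as.list(tiers$catch_share), tiers$tier),
    gear_diagnostics = lapply(posteriors, function(p) {
      list(max_rhat = max(p$diagnostics$rhat),
           min_ess = min(p$diagnostics$ess),
           n_obs = p$n_obs, converged = p$converged)
    }),
    outputs = basename(written)
  )
  f <- out("manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, f)

  ok <- TRUE
  invisible(list(estimates = estimates, posteriors = posteriors,
                 tier_summary = tiers, manifest = manifest,
                 output_files = written))
}

# tier classification without drawing rates (used to find which gears
# need a fitted model before fitting anything)
assign_tiers_only <- function(fisheries, observations, policy) {
  key_cols <- c("flag_state", "gear_type", "target_group", "fao_area")
  if (!"weight" %in% names(observations)) observations$weight <- 1
  obs_means <- observations %>%
    group_by(across(all_of(key_cols))) %>%
    summarise(obs_rate = weighted.mean(.data$rate, .data$weight), .groups = "drop")
  fx <- fisheries %>% left_join(obs_means, by = key_cols)
  tier <- character(nrow(fx))
  for (i in seq_len(nrow(fx))) {
    tier[i] <- if (!is.na(fx$obs_rate[i])) {
      "observed"
    } else if (!is.null(match_policy_rate(fx$flag_state[i], fx$gear_type[i],
                                          fx$fao_area[i], policy))) {
      "policy"
    } else {
      "gear_model"
    }
  }
  fx$tier <- tier
  fx
}

#' One-line global headline summary
#'
#' Renders the global estimate the way assessment headlines are usually
#' phrased: total catch (landings + mean discard level) with its CI
#' (landings plus the discard-level CI bounds, since landings are treated
#' as known), the discard rate as a percentage with its 95% HDI, and the
#' discard level in million tonnes with its 95% CI. Rates are shown to
#' 0.1 percentage point and masses to 0.1 million tonnes; underlying CSVs
#' keep full precision.
#'
#' @param global_estimates Global stratum-estimate tibble (one row), or a
#'   path to a stratum CSV containing the global row.
#' @return The headline string, invisibly; it is also printed.
#' @export
summarize_headline <- function(global_estimates) {
  if (is.character(global_estimates)) {
    global_estimates <- read_stratum_table(global_estimates)
  }
  g <- dplyr::filter(as_tibble(global_estimates), .data$stratum_type == "global")
  if (nrow(g) != 1) {
    abort("expected exactly one global stratum row", class = "db_param_error")
  }
  mt <- 1e6
  landings <- g$total_landings_t
  catch <- landings + g$mean_level_t
  line <- sprintf(
    paste0("Of an annual mean total catch of %.1f million tonnes ",
           "(95%% CI: %.1f-%.1f), %.1f%% (95%% HDI: %.1f-%.1f%%) or ",
           "%.1f million tonnes (95%% CI: %.1f-%.1f) was discarded annually."),
    catch / mt,
    (landings + g$level_ci_lo) / mt, (landings + g$level_ci_hi) / mt,
    100 * g$mean_rate, 100 * g$rate_hdi_lo, 100 * g$rate_hdi_hi,
    g$mean_level_t / mt, g$level_ci_lo / mt, g$level_ci_hi / mt
  )
  cat(line, "\n", sep = "")
  invisible(line)
}
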