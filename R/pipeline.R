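# The estimation chain: allocate landings to fisheries, assign a discard
# rate to every fishery through the three-tier scheme, propagate rate
# uncertainty by Monte Carlo, and aggregate to stratified rates and
# levels. Landings are treated as fixed (known without error); all
# uncertainty in discard totals comes from the discard rates.

#' Allocate landings cells to fisheries
#'
#' Distributes each landings cell (flag state x species item x area, per
#' year) over its target fisheries according to the allocation-key
#' fractions, then averages each fishery's allocated tonnage over the
#' period years. Total allocated tonnage is checked to equal the input
#' tonnage to 1e-6 relative tolerance. Fisheries that end up with zero
#' landings are dropped.
#'
#' @param landings Landings tibble from [read_landings()].
#' @param keys Allocation-key tibble from [read_allocation_keys()].
#' @param period Integer vector of years to average over.
#' @param on_unallocated `"error"` (default) rejects landings cells with
#'   no allocation key; `"bucket"` routes them, with a warning, to an
#'   `"unspecified gear"` fishery of the same flag state and area.
#' @return A tibble of fisheries: `flag_state`, `gear_type`,
#'   `target_group`, `fao_area`, `mean_annual_landings_t`.
#' @export
allocate_landings <- function(landings, keys, period = default_vocab()$period,
                              on_unallocated = c("error", "bucket")) {
  on_unallocated <- match.arg(on_unallocated)
  landings <- as_tibble(landings)
  keys <- as_tibble(keys)
  cell_cols <- c("flag_state", "species_item", "fao_area")
  orphans <- anti_join(landings, keys, by = cell_cols) %>%
    distinct(across(all_of(cell_cols)))
  if (nrow(orphans) > 0) {
    if (on_unallocated == "error") {
      abort(paste0("landings cell(s) without allocation key: ",
                   paste(head(paste(orphans$flag_state, orphans$species_item,
                                    orphans$fao_area, sep = "/"), 10),
                         collapse = "; ")),
            class = "db_alloc_error")
    }
    warn(paste0(nrow(orphans), " landings cell(s) routed to the 'unspecified gear' bucket"))
    bucket <- orphans %>%
      mutate(gear_type = "unspecified gear",
             target_group = "miscellaneous coastal fishes",
             fraction = 1)
    keys <- bind_rows(keys, bucket)
  }
  sums <- keys %>%
    group_by(across(all_of(cell_cols))) %>%
    summarise(total = sum(.data$fraction), .groups = "drop")
  if (any(abs(sums$total - 1) > 1e-9)) {
    abort("allocation fractions do not sum to 1 for at least one cell",
          class = "db_key_error")
  }
  n_years <- length(unique(period))
  alloc <- landings %>%
    left_join(keys, by = cell_cols, relationship = "many-to-many") %>%
    mutate(alloc_t = .data$retained_tonnes * .data$fraction)
  total_in <- sum(landings$retained_tonnes)
  total_out <- sum(alloc$alloc_t)
  if (total_in > 0 && abs(total_out - total_in) / total_in > 1e-6) {
    abort(sprintf("allocation lost mass: %.10g in, %.10g out", total_in, total_out),
          class = "db_alloc_error")
  }
  alloc %>%
    group_by(.data$flag_state, .data$gear_type, .data$target_group, .data$fao_area) %>%
    summarise(mean_annual_landings_t = sum(.data$alloc_t) / n_years,
              .groups = "drop") %>%
    filter(.data$mean_annual_landings_t > 0) %>%
    arrange(.data$flag_state, .data$gear_type, .data$target_group, .data$fao_area)
}

match_policy_rate <- function(flag_state, gear_type, fao_area, policy) {
  hit <- policy[policy$flag_state == flag_state &
                  (is.na(policy$gear_type) | policy$gear_type == gear_type) &
                  (is.na(policy$fao_area) | policy$fao_area == fao_area), ,
                drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  spec <- 1L + !is.na(hit$gear_type) + !is.na(hit$fao_area)
  best <- hit[spec == max(spec), , drop = FALSE]
  if (nrow(best) > 1) {
    abort(paste0("conflicting policy rules of equal specificity for ",
                 flag_state, "/", gear_type, "/", fao_area),
          class = "db_policy_ambiguity_error")
  }
  best$rate
}

#' Assign discard rates to fisheries (three-tier scheme)
#'
#' Every fishery receives a sequence of `n_draws` discard rates by the
#' first applicable tier:
#'
#' * `observed` — the fishery has its own discard-rate record(s); the
#'   constant rate is the weighted mean of its observations.
#' * `policy` — a policy rule matches the fishery's flag state (the most
#'   specific of flag+gear+area, flag+gear, flag wins); the constant
#'   policy rate is used.
#' * `gear_model` — otherwise, `n_draws` rates are drawn by sampling
#'   parameter draws (with replacement) from the gear's posterior and
#'   taking the expected rate `(1 - zi) * mu` of each. The same posterior
#'   draw is applied to every such fishery of the gear within a Monte
#'   Carlo draw, so rates are comonotone within a gear.
#'
#' Two gear-model modes are available. The default, `"gear_mean"`,
#' imputes the gear-level expected rate, so intervals quantify
#' uncertainty about that mean only. `"posterior_predictive"` instead
#' draws an individual rate per fishery and draw from the zero-inflated
#' Beta with the sampled parameters; intervals then also carry the
#' between-fishery variability of unobserved fisheries, which is the
#' appropriate uncertainty for the realized total of a finite set of
#' fisheries (and is wider).
#'
#' @param fisheries Fishery tibble from [allocate_landings()].
#' @param observations Observation tibble from [read_observations()].
#' @param policy Policy-rate tibble from [read_policy_rates()].
#' @param posteriors Named list of `gear_posterior` objects, one per gear
#'   type occurring among tier-3 fisheries.
#' @param n_draws Number of Monte Carlo draws (identical for all
#'   fisheries; deterministic tiers yield constant sequences).
#' @param seed Integer seed for the posterior resampling.
#' @param rate_cap Upper cap on any rate (default 0.99) keeping the
#'   rate-to-level conversion finite.
#' @param tier3_mode `"gear_mean"` (default) or `"posterior_predictive"`;
#'   see Details.
#' @return A tibble with the fishery key columns, `fishery`, `tier` and a
#'   list-column `rate_draws`; tier counts and catch shares are attached
#'   as attribute `"tier_summary"` (see [tier_summary()]).
#' @export
assign_rates <- function(fisheries, observations, policy, posteriors,
                         n_draws = 4000L, seed = 1L, rate_cap = 0.99,
                         tier3_mode = c("gear_mean", "posterior_predictive")) {
  tier3_mode <- match.arg(tier3_mode)
  fisheries <- as_tibble(fisheries)
  observations <- as_tibble(observations)
  if (!"weight" %in% names(observations)) observations$weight <- 1
  n_draws <- as.integer(n_draws)

  key_cols <- c("flag_state", "gear_type", "target_group", "fao_area")
  obs_means <- observations %>%
    group_by(across(all_of(key_cols))) %>%
    summarise(obs_rate = weighted.mean(.data$rate, .data$weight), .groups = "drop")
  fx <- fisheries %>%
    left_join(obs_means, by = key_cols) %>%
    mutate(fishery = fishery_id(.data$flag_state, .data$gear_type,
                                .data$target_group, .data$fao_area))

  tier <- character(nrow(fx))
  const_rate <- rep(NA_real_, nrow(fx))
  for (i in seq_len(nrow(fx))) {
    if (!is.na(fx$obs_rate[i])) {
      tier[i] <- "observed"
      const_rate[i] <- min(fx$obs_rate[i], rate_cap)
    } else {
      pr <- match_policy_rate(fx$flag_state[i], fx$gear_type[i], fx$fao_area[i],
                              policy)
      if (!is.null(pr)) {
        tier[i] <- "policy"
        const_rate[i] <- min(pr, rate_cap)
      } else {
        tier[i] <- "gear_model"
      }
    }
  }

  model_gears <- sort(unique(fx$gear_type[tier == "gear_model"]))
  missing_gears <- setdiff(model_gears, names(posteriors))
  if (length(missing_gears) > 0) {
    abort(paste0("no fitted gear model for gear type(s): ",
                 paste(missing_gears, collapse = ", ")),
          class = "db_missing_model_error")
  }
  set.seed(seed)
  # posterior parameter draws are shared by all tier-3 fisheries of a gear
  # within a Monte Carlo draw (comonotone rates within gear)
  gear_param_idx <- lapply(setNames(model_gears, model_gears), function(g) {
    sample.int(nrow(posteriors[[g]]$draws), n_draws, replace = TRUE)
  })
  gear_rate_draws <- lapply(setNames(model_gears, model_gears), function(g) {
    d <- posteriors[[g]]$draws
    idx <- gear_param_idx[[g]]
    pmin((1 - d$zi[idx]) * d$mu[idx], rate_cap)
  })

  rate_draws <- vector("list", nrow(fx))
  for (i in seq_len(nrow(fx))) {
    rate_draws[[i]] <- if (tier[i] != "gear_model") {
      rep(const_rate[i], n_draws)
    } else if (tier3_mode == "gear_mean") {
      gear_rate_draws[[fx$gear_type[i]]]
    } else {
      # posterior predictive: an individual ZIB rate per fishery and draw
      d <- posteriors[[fx$gear_type[i]]]$draws
      idx <- gear_param_idx[[fx$gear_type[i]]]
      zi <- d$zi[idx]; mu <- d$mu[idx]; phi <- d$phi[idx]
      r <- ifelse(runif(n_draws) < zi, 0,
                  rbeta(n_draws, mu * phi, (1 - mu) * phi))
      pmin(r, rate_cap)
    }
  }

  out <- fx %>%
    select(all_of(key_cols), "fishery", "mean_annual_landings_t") %>%
    mutate(tier = tier, rate_draws = rate_draws)
  total_l <- sum(out$mean_annual_landings_t)
  summary_tbl <- out %>%
    group_by(.data$tier) %>%
    summarise(n_fisheries = n(),
              landings_t = sum(.data$mean_annual_landings_t),
              .groups = "drop") %>%
    mutate(catch_share = .data$landings_t / total_l)
  attr(out, "tier_summary") <- summary_tbl
  out
}

#' Tier accounting of a rate assignment
#'
#' @param assignments Result of [assign_rates()].
#' @return Tibble with one row per tier: fishery count, landings, and
#'   catch share (shares sum to 1 over the allocated catch).
#' @export
tier_summary <- function(assignments) {
  s <- attr(assignments, "tier_summary")
  if (is.null(s)) {
    abort("`assignments` carries no tier summary; was it produced by assign_rates()?",
          class = "db_param_error")
  }
  s
}

#' Convert a discard rate to a discard level
#'
#' The discard rate is defined against total catch (landings + discards),
#' so with retained landings `L` and rate `r` the implied discard tonnage
#' is the unique `D` with `D / (D + L) = r`, i.e. `D = L * r / (1 - r)`.
#' Rates at or above `rate_cap` are capped with a warning to keep the
#' conversion finite.
#'
#' @param landings_t Retained landings in tonnes (>= 0). Vectorized.
#' @param rate Discard rate(s) in \[0, 1).
#' @param rate_cap Cap applied to `rate` (default 0.99).
#' @return Discard tonnage, same length as the longer input.
#' @examples
#' rate_to_discards(100, 0.5)  # 100: discards equal landings at rate 1/2
#' @export
rate_to_discards <- function(landings_t, rate, rate_cap = 0.99) {
  if (any(landings_t < 0)) {
    abort("`landings_t` must be non-negative", class = "db_param_error")
  }
  if (any(rate < 0)) {
    abort("`rate` must be non-negative", class = "db_param_error")
  }
  if (any(rate >= rate_cap)) {
    warn(paste0("rate(s) at or above the cap ", rate_cap, " were capped"))
    rate <- pmin(rate, rate_cap)
  }
  landings_t * rate / (1 - rate)
}

#' Propagate rate draws to per-fishery discard draws
#'
#' Applies the rate-to-level conversion draw by draw: for fishery `i` and
#' draw `j`, `D_ij = L_i * r_ij / (1 - r_ij)`. Deterministic tiers
#' contribute constant columns.
#'
#' @param fisheries Fishery tibble from [allocate_landings()].
#' @param assignments Result of [assign_rates()] covering all fisheries.
#' @param n_draws Expected common draw count (checked).
#' @return A long tibble with columns `fishery`, `draw`, `rate`,
#'   `discards_t`.
#' @export
propagate <- function(fisheries, assignments, n_draws = NULL) {
  assignments <- as_tibble(assignments)
  lens <- lengths(assignments$rate_draws)
  if (length(unique(lens)) != 1) {
    abort("rate draw counts differ across fisheries", class = "db_alignment_error")
  }
  if (!is.null(n_draws) && lens[1] != n_draws) {
    abort(paste0("rate draw count ", lens[1], " does not match n_draws ", n_draws),
          class = "db_alignment_error")
  }
  missing_f <- setdiff(
    fishery_id(fisheries$flag_state, fisheries$gear_type,
               fisheries$target_group, fisheries$fao_area),
    assignments$fishery
  )
  if (length(missing_f) > 0) {
    abort(paste0("assignments missing for ", length(missing_f), " fisheries"),
          class = "db_alignment_error")
  }
  nd <- lens[1]
  tibble(
    fishery = rep(assignments$fishery, each = nd),
    draw = rep(seq_len(nd), times = nrow(assignments)),
    rate = unlist(assignments$rate_draws, use.names = FALSE),
    landings_t = rep(assignments$mean_annual_landings_t, each = nd)
  ) %>%
    mutate(discards_t = .data$landings_t * .data$rate / (1 - .data$rate)) %>%
    select("fishery", "draw", "rate", "discards_t")
}

#' Aggregate discard draws to stratum estimates
#'
#' For each stratum (global, or grouped by FAO area, gear type or target
#' group) and each Monte Carlo draw, the discard level is the sum of the
#' member fisheries' discard draws, and the discard rate is
#' `level / (level + landings)` with the stratum's fixed landings. Across
#' draws the level is summarized by its mean and 95% equal-tailed CI, the
#' rate by its mean and 95% HDI — mirroring how levels and rates are
#' conventionally reported.
#'
#' @param fisheries Fishery tibble from [allocate_landings()].
#' @param discard_draws Long draw table from [propagate()].
#' @param stratum_type One of `"global"`, `"fao_area"`, `"gear_type"`,
#'   `"target_group"`.
#' @param mass Interval mass (default 0.95).
#' @return A tibble of class `stratum_estimates`, one row per stratum,
#'   with columns `stratum_type`, `stratum_label`, `mean_rate`,
#'   `rate_hdi_lo`, `rate_hdi_hi`, `mean_level_t`, `level_ci_lo`,
#'   `level_ci_hi`, `n_fisheries`, `total_landings_t`.
#' @export
aggregate_discards <- function(fisheries, discard_draws,
                               stratum_type = c("global", "fao_area",
                                                "gear_type", "target_group"),
                               mass = 0.95) {
  stratum_type <- match.arg(stratum_type)
  fisheries <- as_tibble(fisheries) %>%
    mutate(fishery = fishery_id(.data$flag_state, .data$gear_type,
                                .data$target_group, .data$fao_area))
  fisheries$stratum_label <- if (stratum_type == "global") {
    "global"
  } else {
    fisheries[[stratum_type]]
  }
  strata_landings <- fisheries %>%
    group_by(.data$stratum_label) %>%
    summarise(total_landings_t = sum(.data$mean_annual_landings_t),
              n_fisheries = n(), .groups = "drop")

  draws <- discard_draws %>%
    left_join(fisheries[, c("fishery", "stratum_label")], by = "fishery") %>%
    group_by(.data$stratum_label, .data$draw) %>%
    summarise(level = sum(.data$discards_t), .groups = "drop") %>%
    left_join(strata_landings, by = "stratum_label") %>%
    mutate(rate = .data$level / (.data$level + .data$total_landings_t))

  est <- draws %>%
    group_by(.data$stratum_label) %>%
    summarise(
      mean_rate = mean(.data$rate),
      rate_hdi_lo = hdi(.data$rate, mass)$lo,
      rate_hdi_hi = hdi(.data$rate, mass)$hi,
      mean_level_t = mean(.data$level),
      level_ci_lo = equal_tailed(.data$level, mass)$lo,
      level_ci_hi = equal_tailed(.data$level, mass)$hi,
      .groups = "drop"
    ) %>%
    left_join(strata_landings, by = "stratum_label") %>%
    mutate(stratum_type = stratum_type) %>%
    select(all_of(stratum_cols)) %>%
    arrange(.data$stratum_type, .data$stratum_label)
  class(est) <- c("stratum_estimates", class(est))
  est
}
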