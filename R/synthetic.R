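# Synthetic-world generator: produces landings, allocation keys,
# discard-rate observations and policy tables with the statistical
# structure the estimation pipeline assumes, plus embedded ground truth
# for recovery studies.

default_gear_params <- function(gears) {
  # plausible gear-level regimes: trawls discard much, lines little,
  # seines are strongly zero-inflated
  presets <- list(
    "bottom otter trawl"  = zib_params(0.05, 0.35, 8),
    "beam trawl"          = zib_params(0.05, 0.40, 8),
    "shrimp trawl"        = zib_params(0.02, 0.55, 10),
    "midwater trawl"      = zib_params(0.15, 0.15, 8),
    "purse seine"         = zib_params(0.30, 0.08, 10),
    "gillnet"             = zib_params(0.20, 0.15, 7),
    "pelagic longline"    = zib_params(0.10, 0.20, 8),
    "demersal longline"   = zib_params(0.15, 0.18, 8),
    "handline"            = zib_params(0.40, 0.08, 6),
    "pot and trap"        = zib_params(0.25, 0.12, 6),
    "dredge"              = zib_params(0.05, 0.30, 8),
    "pole and line"       = zib_params(0.45, 0.06, 6)
  )
  out <- lapply(setNames(gears, gears), function(g) {
    presets[[g]] %||% zib_params(0.2, 0.2, 8)
  })
  out
}

#' Configuration for the synthetic fishing world
#'
#' Defines the world the generator emulates: the fishery classification
#' (subsets of the gear/area/target vocabularies and a set of flag
#' states), per-gear true zero-inflated Beta discard-rate distributions,
#' a log-normal distribution of fishery landings magnitudes, the target
#' split of retained catch across the three rate-assignment tiers
#' (defaults 20% observed / 45% policy / 35% gear-model), and the
#' observation-noise level.
#'
#' @param n_fisheries Number of fisheries to generate (default 150).
#' @param n_flag_states Number of flag states.
#' @param n_species_items Number of species items used in landings cells.
#' @param gears,areas,target_groups Vocabulary subsets (defaults: 8
#'   gears, 10 areas, 6 target groups from the shipped vocabulary).
#' @param gear_params Named list of [zib_params()] giving each gear's
#'   true discard-rate distribution.
#' @param landings_meanlog,landings_sdlog Log-normal parameters of mean
#'   annual fishery landings in tonnes.
#' @param tier_shares Named numeric, target share of retained catch per
#'   tier; must sum to 1.
#' @param obs_noise_sd SD of logit-scale observation noise (default
#'   0.15); zeros are preserved as zeros.
#' @param obs_per_fishery Range (length 2) of observation records per
#'   observed fishery.
#' @param period Years covered by the landings tables.
#' @param rate_cap Cap on true rates.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_fisheries = 150L,
                         n_flag_states = 12L,
                         n_species_items = 15L,
                         gears = default_vocab()$gear_types[c(1, 3, 7, 11, 14, 16, 20, 6)],
                         areas = default_vocab()$fao_areas[1:10],
                         target_groups = default_vocab()$target_groups[1:6],
                         gear_params = default_gear_params(gears),
                         landings_meanlog = log(5000), landings_sdlog = 1.5,
                         tier_shares = c(observed = 0.20, policy = 0.45,
                                         gear_model = 0.35),
                         obs_noise_sd = 0.15,
                         obs_per_fishery = c(1L, 3L),
                         period = default_vocab()$period,
                         rate_cap = 0.99) {
  if (abs(sum(tier_shares) - 1) > 1e-9) {
    abort("tier shares must sum to 1", class = "db_config_error")
  }
  if (!all(c("observed", "policy", "gear_model") %in% names(tier_shares))) {
    abort("tier_shares must name observed, policy and gear_model",
          class = "db_config_error")
  }
  if (length(gears) == 0 || length(areas) == 0 || length(target_groups) == 0) {
    abort("vocabulary subsets must be non-empty", class = "db_config_error")
  }
  if (!all(gears %in% names(gear_params))) {
    abort("gear_params must cover every gear", class = "db_config_error")
  }
  for (g in gears) gear_params[[g]] <- as_zib_params(gear_params[[g]])
  structure(
    list(n_fisheries = as.integer(n_fisheries),
         n_flag_states = as.integer(n_flag_states),
         n_species_items = as.integer(n_species_items),
         gears = gears, areas = areas, target_groups = target_groups,
         gear_params = gear_params,
         landings_meanlog = landings_meanlog, landings_sdlog = landings_sdlog,
         tier_shares = tier_shares, obs_noise_sd = obs_noise_sd,
         obs_per_fishery = as.integer(obs_per_fishery),
         period = period, rate_cap = rate_cap),
    class = "world_config"
  )
}

# add logit-scale noise to a rate, preserving exact zeros
noisy_rate <- function(rate, sd) {
  out <- rate
  pos <- rate > 0
  if (any(pos)) {
    out[pos] <- plogis(qlogis(rate[pos]) + rnorm(sum(pos), 0, sd))
  }
  pmin(pmax(out, 0), 1 - 1e-6)
}

# greedy per-gear selection of observed fisheries until each gear's
# observed catch reaches `frac` of that gear's catch (at least one per gear)
select_observed <- function(fx, frac) {
  chosen <- character(0)
  for (g in sort(unique(fx$gear_type))) {
    sub <- fx[fx$gear_type == g, ]
    sub <- sub[sample.int(nrow(sub)), ]
    target <- frac * sum(sub$mean_annual_landings_t)
    got <- 0
    for (i in seq_len(nrow(sub))) {
      x <- sub$mean_annual_landings_t[i]
      # always observe at least one fishery per gear; after that, add a
      # fishery only if it brings the observed share closer to target
      if (i > 1 && abs(got + x - target) >= abs(got - target)) break
      chosen <- c(chosen, sub$fishery[i])
      got <- got + x
    }
  }
  chosen
}

#' Simulate a synthetic fishing world
#'
#' Generates the four input tables the pipeline consumes — landings,
#' allocation keys, discard-rate observations and policy rates — together
#' with the embedded ground truth. Fisheries are built by sampling
#' gear x target x area x flag combinations; each fishery's true discard
#' rate is a draw from its gear's zero-inflated Beta distribution (policy
#' countries instead carry their constant policy rate); mean annual
#' landings are log-normal and spread over the period years with mild
#' year-to-year noise. Policy flag states are chosen to approximate the
#' policy tier's catch share, and observed fisheries are selected per
#' gear to approximate the observed share while guaranteeing every gear
#' has at least one observation. Observed rates carry logit-scale noise
#' with exact zeros preserved.
#'
#' All outputs pass the package's readers' validation, and the generation
#' is fully reproducible from `seed`.
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @return A list with elements `landings`, `allocation_keys`,
#'   `observations`, `policy_rates` (tibbles in the reader schemas) and
#'   `truth` (a list: `gear_params` tibble, `fisheries` tibble with true
#'   rates/levels, and `strata`, the true stratified rates and levels).
#' @export
simulate_world <- function(config = world_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  flags <- sprintf("C%02d", seq_len(cfg$n_flag_states))
  species <- sprintf("SP%02d", seq_len(cfg$n_species_items))

  # fishery frame: sample distinct key combinations
  grid <- tidyr::expand_grid(
    flag_state = flags, gear_type = cfg$gears,
    target_group = cfg$target_groups, fao_area = cfg$areas
  )
  if (nrow(grid) < cfg$n_fisheries) {
    abort("vocabulary too small for requested number of fisheries",
          class = "db_config_error")
  }
  fx <- grid[sample.int(nrow(grid), cfg$n_fisheries), ]
  fx$mean_annual_landings_t <- rlnorm(cfg$n_fisheries, cfg$landings_meanlog,
                                      cfg$landings_sdlog)
  fx$fishery <- fishery_id(fx$flag_state, fx$gear_type, fx$target_group,
                           fx$fao_area)
  # inverse-CDF draws: uniforms first, then each gear's ZIB quantile map.
  # Keeps the RNG stream independent of the parameter values, so raising a
  # gear's true mu at fixed seed changes rates monotonically.
  u_zero <- runif(cfg$n_fisheries)
  u_beta <- runif(cfg$n_fisheries)
  fx$true_rate <- vapply(seq_len(cfg$n_fisheries), function(i) {
    p <- cfg$gear_params[[fx$gear_type[i]]]
    r <- if (u_zero[i] < p$zi) 0 else {
      stats::qbeta(u_beta[i], p$mu * p$phi, (1 - p$mu) * p$phi)
    }
    min(r, cfg$rate_cap - 1e-9)
  }, numeric(1))

  # policy flag states: add whole countries until the policy catch share
  # is reached
  total_l <- sum(fx$mean_annual_landings_t)
  flag_l <- fx %>%
    group_by(.data$flag_state) %>%
    summarise(l = sum(.data$mean_annual_landings_t), .groups = "drop")
  flag_order <- flag_l$flag_state[sample.int(nrow(flag_l))]
  policy_flags <- character(0)
  got <- 0
  target_policy <- cfg$tier_shares[["policy"]] * total_l
  for (f in flag_order) {
    # keep at least 2 non-policy countries so other tiers exist
    if (length(flag_order) - length(policy_flags) <= 2) break
    x <- flag_l$l[flag_l$flag_state == f]
    # add a whole country only if it brings the policy share closer to target
    if (abs(got + x - target_policy) >= abs(got - target_policy)) next
    policy_flags <- c(policy_flags, f)
    got <- got + x
  }
  policy_rate_of <- if (length(policy_flags) == 0) {
    setNames(numeric(0), character(0))
  } else {
    # first policy country models a discard ban; the rest expert estimates
    setNames(c(0, runif(length(policy_flags) - 1, 0.02, 0.25)), policy_flags)
  }
  is_policy <- fx$flag_state %in% policy_flags
  # policy-country fisheries discard at their (assumed accurate) policy rate
  fx$true_rate[is_policy] <- policy_rate_of[fx$flag_state[is_policy]]

  # observed fisheries among non-policy ones, per gear
  non_policy <- fx[!is_policy, ]
  obs_frac <- cfg$tier_shares[["observed"]] /
    (cfg$tier_shares[["observed"]] + cfg$tier_shares[["gear_model"]])
  observed_ids <- select_observed(non_policy, obs_frac)
  fx$observed <- fx$fishery %in% observed_ids

  # observation records
  obs <- purrr::map_dfr(which(fx$observed), function(i) {
    k <- sample(seq.int(cfg$obs_per_fishery[1], cfg$obs_per_fishery[2]), 1)
    tibble(
      flag_state = fx$flag_state[i], gear_type = fx$gear_type[i],
      target_group = fx$target_group[i], fao_area = fx$fao_area[i],
      rate = noisy_rate(rep(fx$true_rate[i], k), cfg$obs_noise_sd),
      weight = 1
    )
  })

  policy_tbl <- tibble(
    flag_state = policy_flags,
    gear_type = rep(NA_character_, length(policy_flags)),
    fao_area = rep(NA_character_, length(policy_flags)),
    rate = unname(policy_rate_of),
    label = if (length(policy_flags) == 0) character(0) else {
      c("discard ban", rep("expert estimate", length(policy_flags) - 1))
    }
  )

  # landings cells: each fishery gets a species item; fisheries sharing a
  # (flag, area, species) cell split it in proportion to their landings
  fx$species_item <- sample(species, cfg$n_fisheries, replace = TRUE)
  n_years <- length(cfg$period)
  year_factor <- matrix(exp(rnorm(cfg$n_fisheries * n_years, 0, 0.1)),
                        nrow = cfg$n_fisheries)
  year_factor <- year_factor / rowMeans(year_factor)  # keep the mean exact
  per_year <- fx$mean_annual_landings_t * year_factor

  cell_year <- purrr::map_dfr(seq_len(n_years), function(j) {
    tibble(flag_state = fx$flag_state, species_item = fx$species_item,
           fao_area = fx$fao_area, year = cfg$period[j],
           retained_tonnes = per_year[, j])
  }) %>%
    group_by(.data$flag_state, .data$species_item, .data$fao_area, .data$year) %>%
    summarise(retained_tonnes = sum(.data$retained_tonnes), .groups = "drop")

  keys <- fx %>%
    group_by(.data$flag_state, .data$species_item, .data$fao_area) %>%
    mutate(fraction = .data$mean_annual_landings_t /
             sum(.data$mean_annual_landings_t)) %>%
    ungroup() %>%
    select("flag_state", "species_item", "fao_area", "gear_type",
           "target_group", "fraction")

  landings <- cell_year %>%
    arrange(.data$flag_state, .data$species_item, .data$fao_area, .data$year)

  # ground truth: landings as the pipeline will see them (allocation is
  # exact arithmetic; landings carry no error model)
  fisheries_alloc <- allocate_landings(landings, keys, period = cfg$period)
  truth_fx <- fisheries_alloc %>%
    left_join(fx[, c("flag_state", "gear_type", "target_group", "fao_area",
                     "true_rate")],
              by = c("flag_state", "gear_type", "target_group", "fao_area")) %>%
    mutate(true_level_t = rate_to_discards(.data$mean_annual_landings_t,
                                           .data$true_rate, cfg$rate_cap))

  truth_strata <- purrr::map_dfr(
    c("global", "fao_area", "gear_type", "target_group"),
    function(st) {
      lab <- if (st == "global") rep("global", nrow(truth_fx)) else truth_fx[[st]]
      truth_fx %>%
        mutate(stratum_label = lab) %>%
        group_by(.data$stratum_label) %>%
        summarise(
          true_level_t = sum(.data$true_level_t),
          total_landings_t = sum(.data$mean_annual_landings_t),
          .groups = "drop"
        ) %>%
        mutate(true_rate = .data$true_level_t /
                 (.data$true_level_t + .data$total_landings_t),
               stratum_type = st) %>%
        select("stratum_type", "stratum_label", "true_rate", "true_level_t",
               "total_landings_t")
    }
  )

  gear_truth <- purrr::map_dfr(cfg$gears, function(g) {
    p <- cfg$gear_params[[g]]
    tibble(gear_type = g, zi = p$zi, mu = p$mu, phi = p$phi,
           mean_rate = zib_mean(p))
  })

  list(
    landings = landings,
    allocation_keys = keys,
    observations = obs,
    policy_rates = policy_tbl,
    truth = list(gear_params = gear_truth,
                 fisheries = truth_fx,
                 strata = truth_strata),
    config = cfg,
    seed = seed
  )
}

#' Write a simulated world to CSV files
#'
#' @param world Result of [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(world$landings, file.path(dir, "landings.csv"))
  readr::write_csv(world$allocation_keys, file.path(dir, "allocation_keys.csv"))
  readr::write_csv(world$observations, file.path(dir, "observations.csv"))
  readr::write_csv(world$policy_rates, file.path(dir, "policy_rates.csv"))
  readr::write_csv(world$truth$strata, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Compare stratum estimates against the synthetic truth
#'
#' Joins the generator's true stratified rates and levels to a set of
#' stratum estimates and reports, per stratum and per quantity (rate with
#' its HDI, level with its CI), the truth, the estimate, the interval, a
#' coverage flag, and absolute and relative errors.
#'
#' @param truth The `truth` element of [simulate_world()].
#' @param estimates One or more stratum-estimate tibbles (rows are bound).
#' @return A recovery tibble.
#' @export
truth_report <- function(truth, estimates) {
  est <- bind_rows(estimates)
  joined <- est %>%
    left_join(truth$strata, by = c("stratum_type", "stratum_label"))
  if (any(is.na(joined$true_rate))) {
    missing_lab <- joined$stratum_label[is.na(joined$true_rate)]
    abort(paste0("no truth entry for stratum label(s): ",
                 paste(head(missing_lab, 5), collapse = ", ")),
          class = "db_alignment_error")
  }
  bind_rows(
    joined %>%
      mutate(quantity = "rate", truth = .data$true_rate,
             estimate = .data$mean_rate,
             lo = .data$rate_hdi_lo, hi = .data$rate_hdi_hi),
    joined %>%
      mutate(quantity = "level_t", truth = .data$true_level_t,
             estimate = .data$mean_level_t,
             lo = .data$level_ci_lo, hi = .data$level_ci_hi)
  ) %>%
    mutate(
      covered = .data$truth >= .data$lo & .data$truth <= .data$hi,
      abs_error = abs(.data$estimate - .data$truth),
      rel_error = ifelse(.data$truth == 0, NA_real_,
                         .data$abs_error / abs(.data$truth))
    ) %>%
    select("stratum_type", "stratum_label", "quantity", "truth", "estimate",
           "lo", "hi", "covered", "abs_error", "rel_error")
}
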