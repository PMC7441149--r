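# Synthetic-world generator: determinism, validity of generated tables,
# tier structure, noiseless identity, truth reporting.

test_that("the generator is deterministic and its tables pass the readers' validation", {
  w1 <- simulate_world(world_config(n_fisheries = 60), seed = 123)
  w2 <- simulate_world(world_config(n_fisheries = 60), seed = 123)
  expect_identical(w1$landings, w2$landings)
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$allocation_keys, w2$allocation_keys)
  expect_identical(w1$policy_rates, w2$policy_rates)

  dir <- withr::local_tempdir()
  write_world(w1, dir)
  expect_equal(nrow(read_landings(file.path(dir, "landings.csv"))),
               nrow(w1$landings))
  expect_silent(keys <- read_allocation_keys(file.path(dir, "allocation_keys.csv")))
  expect_silent(obs <- read_observations(file.path(dir, "observations.csv")))
  expect_silent(read_policy_rates(file.path(dir, "policy_rates.csv")))
  expect_true(all(obs$rate >= 0 & obs$rate < 1))
})

test_that("generated gear observations reproduce the true zero fraction", {
  cfg <- world_config(n_fisheries = 350, tier_shares = c(observed = 0.9,
                                                         policy = 0.0,
                                                         gear_model = 0.1),
                      obs_per_fishery = c(3L, 5L))
  w <- simulate_world(cfg, seed = 9)
  # the zero indicator is a per-fishery property (replicate records of one
  # fishery share it), so the binomial error uses distinct fisheries
  per_fishery <- dplyr::summarise(
    dplyr::group_by(w$observations, flag_state, gear_type, target_group, fao_area),
    zero = any(rate == 0), .groups = "drop"
  )
  for (g in unique(per_fishery$gear_type)) {
    zeros <- per_fishery$zero[per_fishery$gear_type == g]
    if (length(zeros) < 15) next
    zi_true <- cfg$gear_params[[g]]$zi
    se <- sqrt(zi_true * (1 - zi_true) / length(zeros))
    expect_lt(abs(mean(zeros) - zi_true), 4 * se + 0.02)
  }
})

test_that("with full noiseless coverage the pipeline recovers the true global rate exactly", {
  cfg <- world_config(n_fisheries = 80, obs_noise_sd = 0,
                      tier_shares = c(observed = 1 - 1e-9, policy = 0,
                                      gear_model = 1e-9),
                      obs_per_fishery = c(1L, 1L))
  w <- simulate_world(cfg, seed = 31)
  fisheries <- allocate_landings(w$landings, w$allocation_keys)
  expect_equal(nrow(w$observations), nrow(fisheries))
  asg <- assign_rates(fisheries, w$observations, w$policy_rates,
                      posteriors = list(), n_draws = 100, seed = 1)
  expect_true(all(asg$tier == "observed"))
  est <- aggregate_discards(fisheries, propagate(fisheries, asg), "global")
  truth <- w$truth$strata[w$truth$strata$stratum_type == "global", ]
  expect_equal(est$mean_rate, truth$true_rate, tolerance = 1e-9)
  expect_equal(est$mean_level_t, truth$true_level_t, tolerance = 1e-9)
})

test_that("default-config tier catch shares approximate the 20/45/35 split", {
  w <- simulate_world(world_config(), seed = 4)
  fisheries <- allocate_landings(w$landings, w$allocation_keys)
  tiers <- discardbench:::assign_tiers_only(fisheries, w$observations,
                                            w$policy_rates)
  total <- sum(tiers$mean_annual_landings_t)
  share <- sapply(c("observed", "policy", "gear_model"), function(t) {
    sum(tiers$mean_annual_landings_t[tiers$tier == t]) / total
  })
  expect_lt(abs(share[["observed"]] - 0.20), 0.10)
  expect_lt(abs(share[["policy"]] - 0.45), 0.10)
  expect_lt(abs(share[["gear_model"]] - 0.35), 0.10)
  # every tier-3 gear has at least one observation to fit on
  expect_true(all(tiers$gear_type[tiers$tier == "gear_model"] %in%
                    w$observations$gear_type))
})

test_that("truth invariants hold and truth_report flags coverage correctly", {
  w <- simulate_world(world_config(n_fisheries = 60), seed = 17)
  tf <- w$truth$fisheries
  expect_equal(tf$true_rate,
               tf$true_level_t / (tf$true_level_t + tf$mean_annual_landings_t),
               tolerance = 1e-12)

  truth_global <- w$truth$strata[w$truth$strata$stratum_type == "global", ]
  est_cover <- tibble::tibble(
    stratum_type = "global", stratum_label = "global",
    mean_rate = truth_global$true_rate,
    rate_hdi_lo = truth_global$true_rate - 0.01,
    rate_hdi_hi = truth_global$true_rate + 0.01,
    mean_level_t = truth_global$true_level_t,
    level_ci_lo = truth_global$true_level_t, # zero width at truth
    level_ci_hi = truth_global$true_level_t,
    n_fisheries = 60L, total_landings_t = truth_global$total_landings_t
  )
  rep <- truth_report(w$truth, est_cover)
  expect_true(all(rep$covered))
  expect_equal(rep$abs_error[rep$quantity == "level_t"], 0)

  est_miss <- dplyr::mutate(est_cover, stratum_label = "nowhere")
  expect_error(truth_report(w$truth, est_miss), class = "db_alignment_error")
})

test_that("increasing a gear's true mu increases that gear's true stratum level", {
  base_cfg <- world_config(n_fisheries = 80)
  hi_params <- base_cfg$gear_params
  hi_params[["gillnet"]] <- zib_params(hi_params[["gillnet"]]$zi, 0.6,
                                       hi_params[["gillnet"]]$phi)
  hi_cfg <- world_config(n_fisheries = 80, gear_params = hi_params)
  w_lo <- simulate_world(base_cfg, seed = 8)
  w_hi <- simulate_world(hi_cfg, seed = 8)
  lvl <- function(w) {
    s <- w$truth$strata
    s$true_level_t[s$stratum_type == "gear_type" & s$stratum_label == "gillnet"]
  }
  expect_gt(lvl(w_hi), lvl(w_lo))
})
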