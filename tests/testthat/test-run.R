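# End-to-end driver, manifest, and headline rendering.

local_world_cfg <- function(dir, seed_world = 7, n_draws = 300, seed = 11,
                            env = parent.frame()) {
  w <- simulate_world(world_config(n_fisheries = 80), seed = seed_world)
  write_world(w, dir)
  cfg <- run_config(
    landings = file.path(dir, "landings.csv"),
    allocation_keys = file.path(dir, "allocation_keys.csv"),
    observations = file.path(dir, "observations.csv"),
    policy_rates = file.path(dir, "policy_rates.csv"),
    output_dir = file.path(dir, "out"),
    n_draws = n_draws, seed = seed,
    mcmc = mcmc_control(chains = 2, iter = 1200, warmup = 600),
    allow_nonconverged = TRUE
  )
  list(world = w, cfg = cfg)
}

test_that("run_pipeline writes all stratum tables and a complete manifest", {
  dir <- withr::local_tempdir()
  ww <- local_world_cfg(dir)
  res <- suppressMessages(run_pipeline(ww$cfg))

  for (st in c("global", "fao_area", "gear_type", "target_group")) {
    f <- file.path(dir, "out", paste0("stratum_", st, ".csv"))
    expect_true(file.exists(f))
    expect_gt(nrow(read_stratum_table(f)), 0)
  }
  manifest <- jsonlite::read_json(file.path(dir, "out", "manifest.json"))
  expect_length(manifest$tier_counts, 3)
  expect_equal(manifest$seed, 11)
  expect_true(all(c("gear_seeds", "assign_seed", "gear_diagnostics") %in%
                    names(manifest)))
  # tier catch shares account for all allocated catch
  expect_equal(sum(unlist(manifest$tier_catch_shares)), 1, tolerance = 1e-9)
})

test_that("identical config and seed give bit-identical output tables", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  w1 <- local_world_cfg(dir1); w2 <- local_world_cfg(dir2)
  suppressMessages(run_pipeline(w1$cfg))
  suppressMessages(run_pipeline(w2$cfg))
  for (f in c("stratum_global.csv", "stratum_fao_area.csv",
              "stratum_gear_type.csv", "stratum_target_group.csv",
              "tier_accounting.csv", "gear_posteriors.csv")) {
    expect_identical(readLines(file.path(dir1, "out", f)),
                     readLines(file.path(dir2, "out", f)),
                     label = f)
  }
})

test_that("a missing input file fails validation before any output is written", {
  dir <- withr::local_tempdir()
  ww <- local_world_cfg(dir)
  expect_error(
    run_config(
      landings = file.path(dir, "landings.csv"),
      allocation_keys = file.path(dir, "allocation_keys.csv"),
      observations = file.path(dir, "does_not_exist.csv"),
      policy_rates = file.path(dir, "policy_rates.csv"),
      output_dir = file.path(dir, "out2")
    ),
    class = "db_config_error"
  )
  expect_false(dir.exists(file.path(dir, "out2")) &&
                 length(list.files(file.path(dir, "out2"))) > 0)
})

test_that("the YAML run config round-trips through read_run_config", {
  dir <- withr::local_tempdir()
  ww <- local_world_cfg(dir)
  yaml::write_yaml(list(
    landings = "landings.csv", allocation_keys = "allocation_keys.csv",
    observations = "observations.csv", policy_rates = "policy_rates.csv",
    output_dir = file.path(dir, "outy"), n_draws = 250, seed = 5,
    mcmc = list(chains = 2, iter = 400, warmup = 200),
    allow_nonconverged = TRUE
  ), file.path(dir, "run.yaml"))
  cfg <- read_run_config(file.path(dir, "run.yaml"))
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$n_draws, 250L)
  expect_equal(cfg$mcmc$chains, 2L)
  expect_true(cfg$allow_nonconverged)
})

test_that("the headline reproduces the canonical worked example and degenerate cases", {
  g <- tibble::tibble(
    stratum_type = "global", stratum_label = "global",
    mean_rate = 9.14 / (75.5 + 9.14),
    rate_hdi_lo = 0.101, rate_hdi_hi = 0.115,
    mean_level_t = 9.14e6, level_ci_lo = 9.14e6, level_ci_hi = 9.14e6,
    n_fisheries = 100L, total_landings_t = 75.5e6
  )
  line <- summarize_headline(g)
  expect_match(line, "84.6 million tonnes", fixed = TRUE)
  expect_match(line, "10.8%", fixed = TRUE)
  expect_match(line, "9.1 million tonnes", fixed = TRUE)
  # catch CI bounds are landings + level CI bounds
  expect_match(line, "95% CI: 84.6-84.6", fixed = TRUE)

  zero <- dplyr::mutate(g, mean_rate = 0, mean_level_t = 0,
                        level_ci_lo = 0, level_ci_hi = 0,
                        rate_hdi_lo = 0, rate_hdi_hi = 0)
  line0 <- summarize_headline(zero)
  expect_match(line0, "0.0%", fixed = TRUE)
  expect_match(line0, "75.5 million tonnes", fixed = TRUE)
  # identical inputs render identical text
  expect_identical(line, summarize_headline(g))
})

test_that("autoplot methods return ggplot objects", {
  set.seed(3)
  fisheries <- make_fisheries(4)
  draws <- lapply(1:4, function(i) runif(60, 0, 0.4))
  est <- aggregate_discards(fisheries,
                            propagate(fisheries, make_assignments(fisheries, draws)),
                            "gear_type")
  expect_s3_class(autoplot(est, "rate"), "ggplot")
  expect_s3_class(autoplot(est, "level"), "ggplot")
  fit <- fit_gear_model(tibble::tibble(rate = sample_zib(zib_params(0.2, 0.3, 5),
                                                         50, seed = 2)),
                        control = mcmc_control(2, 400, 200), seed = 12)
  expect_s3_class(autoplot(fit), "ggplot")
})
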