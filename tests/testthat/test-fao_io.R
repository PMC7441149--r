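# Table readers/writers: schema validation, vocabulary closure, period
# filtering, round trips.

test_that("read_landings performs an identity read and filters to the period", {
  path <- write_fixture_csv(tiny_landings(), "landings.csv")
  got <- read_landings(path)
  expect_equal(nrow(got), 3)
  expect_identical(got$fao_area, c("21", "21", "27"))
  expect_equal(got$retained_tonnes, c(100, 120, 50))

  # 10 rows over 2008-2014; exactly 6 fall in 2010-2014 (counted by hand)
  mixed <- tibble::tibble(
    flag_state = "AA", species_item = sprintf("SP%02d", 1:10),
    fao_area = "21", year = c(2008, 2008, 2009, 2009, 2010, 2011,
                              2012, 2013, 2014, 2014),
    retained_tonnes = 1:10
  )
  got <- read_landings(write_fixture_csv(mixed, "mixed.csv"), period = 2010:2014)
  expect_equal(nrow(got), 6)
  expect_true(all(got$year %in% 2010:2014))
})

test_that("read_landings raises typed errors for malformed input", {
  bad_neg <- tiny_landings()
  bad_neg$retained_tonnes[2] <- -5
  expect_error(read_landings(write_fixture_csv(bad_neg, "neg.csv")),
               "row", class = "db_validation_error")

  dup <- tiny_landings()[c(1, 1, 2), ]
  expect_error(read_landings(write_fixture_csv(dup, "dup.csv")),
               class = "db_duplicate_error")

  missing_col <- tiny_landings()[, -5]
  expect_error(read_landings(write_fixture_csv(missing_col, "mc.csv")),
               "retained_tonnes", class = "db_schema_error")

  bad_area <- tiny_landings()
  bad_area$fao_area[1] <- "99"
  expect_error(read_landings(write_fixture_csv(bad_area, "area.csv")),
               class = "db_vocab_error")
})

test_that("read_observations validates rates and vocabularies and defaults weights", {
  obs <- tibble::tibble(
    flag_state = "AA", gear_type = "gillnet",
    target_group = "demersal fishes", fao_area = "27", rate = 0.55
  )
  got <- read_observations(write_fixture_csv(obs, "obs.csv"))
  expect_equal(got$rate, 0.55)
  expect_equal(got$weight, 1)

  obs$rate <- 1.2
  expect_error(read_observations(write_fixture_csv(obs, "bad.csv")),
               class = "db_validation_error")

  obs$rate <- 0.5
  obs$gear_type <- "laser net"
  expect_error(read_observations(write_fixture_csv(obs, "voc.csv")),
               "allowed values", class = "db_vocab_error")

  # duplicate fishery records are retained; combining happens downstream
  five <- tibble::tibble(
    flag_state = "AA", gear_type = "gillnet",
    target_group = "demersal fishes",
    fao_area = c("27", "27", "21", "34", "37"),
    rate = c(0.1, 0.3, 0.2, 0.4, 0.5)
  )
  expect_equal(nrow(read_observations(write_fixture_csv(five, "five.csv"))), 5)
})

test_that("allocation keys enforce fraction sums and policy rates accept partial scopes", {
  keys <- tiny_keys()
  got <- read_allocation_keys(write_fixture_csv(keys, "keys.csv"))
  expect_equal(nrow(got), 3)

  keys$fraction[1] <- 0.5  # cell now sums to 0.9
  expect_error(read_allocation_keys(write_fixture_csv(keys, "badkeys.csv")),
               class = "db_key_error")

  pol <- tibble::tibble(
    flag_state = c("IS", "CN"), gear_type = c(NA, "gillnet"),
    fao_area = c(NA, "61"), rate = c(0, 0.1),
    label = c("discard ban", "expert estimate")
  )
  got <- read_policy_rates(write_fixture_csv(pol, "pol.csv"))
  expect_identical(got$gear_type, c(NA, "gillnet"))
  expect_equal(got$rate, c(0, 0.1))
})

test_that("stratum tables round-trip exactly and sort stably", {
  set.seed(42)
  n <- 30
  est <- tibble::tibble(
    stratum_type = rep(c("fao_area", "gear_type", "target_group"), each = 10),
    stratum_label = sample(sprintf("lab%02d", 1:n)),
    mean_rate = runif(n, 0, 0.6),
    rate_hdi_lo = runif(n, 0, 0.1), rate_hdi_hi = runif(n, 0.6, 0.9),
    mean_level_t = rlnorm(n, 10, 1),
    level_ci_lo = rlnorm(n, 9, 1), level_ci_hi = rlnorm(n, 11, 1),
    n_fisheries = sample.int(50, n), total_landings_t = rlnorm(n, 12, 1)
  )
  path <- file.path(withr::local_tempdir(), "strata.csv")
  write_stratum_table(est, path)
  back <- read_stratum_table(path)
  expect_equal(nrow(back), n)
  # sorted by (stratum_type, stratum_label), values preserved exactly
  expected <- dplyr::arrange(est, stratum_type, stratum_label)
  expect_identical(back$stratum_label, expected$stratum_label)
  expect_equal(back$mean_level_t, expected$mean_level_t, tolerance = 1e-10)
  expect_equal(back$mean_rate, expected$mean_rate, tolerance = 1e-10)

  expect_error(write_stratum_table(est[0, ], path), class = "db_param_error")
  expect_error(write_stratum_table(est, file.path(tempdir(), "no/such/dir/x.csv")),
               class = "db_io_error")
})
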