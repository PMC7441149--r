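# Shared fixture builders. All fixtures are constructed in code; CSVs are
# written to tempfiles on demand.

write_fixture_csv <- function(df, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(df, path, na = "")
  path
}

# a tiny three-fishery landings/keys fixture with known arithmetic
tiny_landings <- function() {
  tibble::tibble(
    flag_state = c("AA", "AA", "BB"),
    species_item = c("SP01", "SP01", "SP02"),
    fao_area = c("21", "21", "27"),
    year = c(2010L, 2011L, 2010L),
    retained_tonnes = c(100, 120, 50)
  )
}

tiny_keys <- function() {
  tibble::tibble(
    flag_state = c("AA", "AA", "BB"),
    species_item = c("SP01", "SP01", "SP02"),
    fao_area = c("21", "21", "27"),
    gear_type = c("bottom otter trawl", "gillnet", "handline"),
    target_group = c("demersal fishes", "demersal fishes", "tuna and billfishes"),
    fraction = c(0.6, 0.4, 1.0)
  )
}

# deterministic fishery table (no allocation step needed)
make_fisheries <- function(n = 3, landings = 10^(seq_len(n) + 1)) {
  vocab <- default_vocab()
  tibble::tibble(
    flag_state = sprintf("C%02d", seq_len(n)),
    gear_type = vocab$gear_types[seq_len(n)],
    target_group = vocab$target_groups[(seq_len(n) - 1) %% 8 + 1],
    fao_area = vocab$fao_areas[(seq_len(n) - 1) %% 19 + 1],
    mean_annual_landings_t = landings
  )
}

# an assignment table with externally supplied draw vectors
make_assignments <- function(fisheries, rate_draws, tier = "observed") {
  fisheries$fishery <- with(fisheries, paste(flag_state, gear_type,
                                             target_group, fao_area, sep = "|"))
  fisheries$tier <- tier
  fisheries$rate_draws <- rate_draws
  total <- sum(fisheries$mean_annual_landings_t)
  attr(fisheries, "tier_summary") <- dplyr::summarise(
    dplyr::group_by(fisheries, tier),
    n_fisheries = dplyr::n(),
    landings_t = sum(mean_annual_landings_t), .groups = "drop"
  ) |> dplyr::mutate(catch_share = landings_t / total)
  fisheries
}

empty_observations <- function() {
  tibble::tibble(flag_state = character(0), gear_type = character(0),
                 target_group = character(0), fao_area = character(0),
                 rate = numeric(0), weight = numeric(0))
}

empty_policy <- function() {
  tibble::tibble(flag_state = character(0), gear_type = character(0),
                 fao_area = character(0), rate = numeric(0),
                 label = character(0))
}

fishery_id_vec <- function(fisheries) {
  paste(fisheries$flag_state, fisheries$gear_type, fisheries$target_group,
        fisheries$fao_area, sep = "|")
}

# discrete symmetric-tail interval: order-statistic endpoints, guaranteed
# to contain at least ceiling(mass * n) draws
et_discrete <- function(draws, mass) {
  x <- sort(draws)
  n <- length(x)
  a <- 1 - mass
  c(x[max(ceiling(n * a / 2), 1)], x[ceiling(n * (1 - a / 2))])
}

# brute-force HDI oracle: scan every contiguous window of the sorted draws
hdi_bruteforce <- function(draws, mass) {
  x <- sort(draws)
  n <- length(x)
  w <- ceiling(mass * n)
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - w + 1)) {
    width <- x[i + w - 1] - x[i]
    if (width < best[1]) best <- c(width, x[i], x[i + w - 1])
  }
  best[2:3]
}
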