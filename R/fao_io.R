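# Readers and writers for the four input table schemas and the stratum
# output table. One strict CSV dialect throughout: UTF-8, comma-separated,
# mandatory header, "." decimal separator. FAO area codes are always
# character, never integer.

read_strict_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "db_io_error")
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", "),
                 " in ", path),
          class = "db_schema_error")
  }
  tbl[, intersect(c(required, optional), names(tbl)), drop = FALSE]
}

parse_num_col <- function(tbl, col, path, lower = NULL, upper = NULL) {
  x <- suppressWarnings(as.numeric(tbl[[col]]))
  bad <- which(is.na(x) & !is.na(tbl[[col]]))
  bad <- union(bad, which(is.na(tbl[[col]])))
  if (length(bad) > 0) {
    abort(paste0("non-numeric or missing '", col, "' at row(s) ",
                 paste(head(bad, 5), collapse = ", "), " of ", path),
          class = "db_validation_error")
  }
  if (!is.null(lower)) {
    bad <- which(x < lower)
    if (length(bad) > 0) {
      abort(paste0("'", col, "' below ", lower, " at row(s) ",
                   paste(head(bad, 5), collapse = ", "), " of ", path),
            class = "db_validation_error")
    }
  }
  if (!is.null(upper)) {
    bad <- which(x > upper)
    if (length(bad) > 0) {
      abort(paste0("'", col, "' above ", upper, " at row(s) ",
                   paste(head(bad, 5), collapse = ", "), " of ", path),
            class = "db_validation_error")
    }
  }
  x
}

#' Read a landings table
#'
#' Reads FAO-style retained-catch records: one row per flag state x
#' species item x FAO area x year, with the retained weight in tonnes.
#' Rows outside `period` are dropped; duplicate keys within the period are
#' an error, as are negative or non-numeric tonnages.
#'
#' @param path CSV file with columns `flag_state`, `species_item`,
#'   `fao_area`, `year`, `retained_tonnes`.
#' @param period Integer vector of years to retain (default: the
#'   vocabulary period, 2010--2014).
#' @param vocab A vocabulary from [default_vocab()] / [read_vocab()].
#' @return A tibble of validated landings records.
#' @export
read_landings <- function(path, period = default_vocab()$period,
                          vocab = default_vocab()) {
  tbl <- read_strict_csv(path, c("flag_state", "species_item", "fao_area",
                                 "year", "retained_tonnes"))
  tbl$year <- {
    y <- suppressWarnings(as.integer(tbl$year))
    bad <- which(is.na(y))
    if (length(bad) > 0) {
      abort(paste0("non-integer 'year' at row(s) ",
                   paste(head(bad, 5), collapse = ", "), " of ", path),
            class = "db_validation_error")
    }
    y
  }
  tbl$retained_tonnes <- parse_num_col(tbl, "retained_tonnes", path, lower = 0)
  check_vocab(tbl$fao_area, vocab$fao_areas, "fao_area")
  tbl <- dplyr::filter(tbl, .data$year %in% period)
  dup <- tbl %>%
    dplyr::count(.data$flag_state, .data$species_item, .data$fao_area, .data$year) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate landings key(s), e.g. ",
                 paste(dup$flag_state[1], dup$species_item[1], dup$fao_area[1],
                       dup$year[1], sep = "/")),
          class = "db_duplicate_error")
  }
  as_tibble(tbl)
}

#' Read a discard-rate observation table
#'
#' One row per observed discard-rate record for a fishery (flag state x
#' gear x target group x area). Rates are tonnes of discards per tonnes of
#' total catch, in \[0, 1\]. A missing `weight` column defaults to 1.
#' Multiple records for the same fishery are retained as-is; any combining
#' happens downstream in [assign_rates()].
#'
#' @param path CSV with columns `flag_state`, `gear_type`, `target_group`,
#'   `fao_area`, `rate` and optionally `weight`.
#' @inheritParams read_landings
#' @return A tibble of validated observations.
#' @export
read_observations <- function(path, vocab = default_vocab()) {
  tbl <- read_strict_csv(path, c("flag_state", "gear_type", "target_group",
                                 "fao_area", "rate"), optional = "weight")
  tbl$rate <- parse_num_col(tbl, "rate", path, lower = 0, upper = 1)
  if ("weight" %in% names(tbl)) {
    tbl$weight <- parse_num_col(tbl, "weight", path)
    if (any(tbl$weight <= 0)) {
      abort("observation weights must be positive", class = "db_validation_error")
    }
  } else {
    tbl$weight <- 1
  }
  check_vocab(tbl$gear_type, vocab$gear_types, "gear_type")
  check_vocab(tbl$fao_area, vocab$fao_areas, "fao_area")
  check_vocab(tbl$target_group, vocab$target_groups, "target_group")
  as_tibble(tbl)
}

#' Read an allocation-key table
#'
#' Allocation keys map a landings cell (flag state x species item x FAO
#' area) to one or more fisheries of the same flag state and area, with
#' fractions that sum to 1 per cell (tolerance 1e-9).
#'
#' @param path CSV with columns `flag_state`, `species_item`, `fao_area`,
#'   `gear_type`, `target_group`, `fraction`.
#' @inheritParams read_landings
#' @return A tibble of validated allocation keys.
#' @export
read_allocation_keys <- function(path, vocab = default_vocab()) {
  tbl <- read_strict_csv(path, c("flag_state", "species_item", "fao_area",
                                 "gear_type", "target_group", "fraction"))
  tbl$fraction <- parse_num_col(tbl, "fraction", path)
  if (any(tbl$fraction <= 0 | tbl$fraction > 1)) {
    abort("allocation fractions must lie in (0, 1]", class = "db_validation_error")
  }
  check_vocab(tbl$gear_type, vocab$gear_types, "gear_type")
  check_vocab(tbl$fao_area, vocab$fao_areas, "fao_area")
  check_vocab(tbl$target_group, vocab$target_groups, "target_group")
  sums <- tbl %>%
    group_by(.data$flag_state, .data$species_item, .data$fao_area) %>%
    summarise(total = sum(.data$fraction), .groups = "drop")
  bad <- dplyr::filter(sums, abs(.data$total - 1) > 1e-9)
  if (nrow(bad) > 0) {
    abort(paste0("allocation fractions do not sum to 1 for cell(s), e.g. ",
                 paste(bad$flag_state[1], bad$species_item[1], bad$fao_area[1],
                       sep = "/"),
                 " (sum = ", format(bad$total[1], digits = 12), ")"),
          class = "db_key_error")
  }
  as_tibble(tbl)
}

#' Read a policy-rate table
#'
#' Policy rates are constant discard rates applied to whole flag states
#' (optionally restricted to a gear type and/or area), used for countries
#' whose rates come from expert estimates or discard bans rather than
#' fishery-specific observations.
#'
#' @param path CSV with columns `flag_state`, `rate`, `label` and optional
#'   `gear_type`, `fao_area` (empty entries mean "any").
#' @inheritParams read_landings
#' @return A tibble of validated policy rules.
#' @export
read_policy_rates <- function(path, vocab = default_vocab()) {
  tbl <- read_strict_csv(path, c("flag_state", "rate", "label"),
                         optional = c("gear_type", "fao_area"))
  tbl$rate <- parse_num_col(tbl, "rate", path, lower = 0, upper = 1)
  if (!"gear_type" %in% names(tbl)) tbl$gear_type <- NA_character_
  if (!"fao_area" %in% names(tbl)) tbl$fao_area <- NA_character_
  tbl$gear_type[tbl$gear_type %in% ""] <- NA_character_
  tbl$fao_area[tbl$fao_area %in% ""] <- NA_character_
  check_vocab(tbl$gear_type[!is.na(tbl$gear_type)], vocab$gear_types, "gear_type")
  check_vocab(tbl$fao_area[!is.na(tbl$fao_area)], vocab$fao_areas, "fao_area")
  as_tibble(tbl[, c("flag_state", "gear_type", "fao_area", "rate", "label")])
}

stratum_cols <- c("stratum_type", "stratum_label", "mean_rate", "rate_hdi_lo",
                  "rate_hdi_hi", "mean_level_t", "level_ci_lo", "level_ci_hi",
                  "n_fisheries", "total_landings_t")

#' Write / read a stratum-estimate table
#'
#' Tabular output of stratified discard estimates: one row per stratum
#' with the mean discard rate and its 95% HDI, the mean discard level in
#' tonnes and its 95% equal-tailed CI, the number of fisheries and the
#' total landings. Rows are sorted by `(stratum_type, stratum_label)` and
#' numbers are written with enough digits that a write-read round trip
#' reproduces them.
#'
#' @param estimates A stratum-estimate tibble (from
#'   [aggregate_discards()]).
#' @param path Output CSV path.
#' @return `write_stratum_table()` returns `path` invisibly;
#'   `read_stratum_table()` the estimates tibble.
#' @export
write_stratum_table <- function(estimates, path) {
  estimates <- as_tibble(estimates)
  if (nrow(estimates) == 0) {
    abort("`estimates` must be non-empty", class = "db_param_error")
  }
  missing_cols <- setdiff(stratum_cols, names(estimates))
  if (length(missing_cols) > 0) {
    abort(paste0("estimates table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "db_schema_error")
  }
  out <- estimates[, stratum_cols] %>%
    arrange(.data$stratum_type, .data$stratum_label)
  ok <- tryCatch({
    readr::write_csv(out, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write to ", path), class = "db_io_error")
  invisible(path)
}

#' @rdname write_stratum_table
#' @export
read_stratum_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "db_io_error")
  }
  readr::read_csv(path, col_types = readr::cols(
    stratum_type = readr::col_character(),
    stratum_label = readr::col_character(),
    mean_rate = readr::col_double(),
    rate_hdi_lo = readr::col_double(),
    rate_hdi_hi = readr::col_double(),
    mean_level_t = readr::col_double(),
    level_ci_lo = readr::col_double(),
    level_ci_hi = readr::col_double(),
    n_fisheries = readr::col_integer(),
    total_landings_t = readr::col_double()
  ))
}
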