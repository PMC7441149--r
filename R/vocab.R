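# Controlled vocabularies: gear types, FAO Major Fishing Areas, target
# species groups, and the assessment period. Shipped as a versioned YAML
# config so analyses can pin or extend the classification.

the <- new.env(parent = emptyenv())

#' Controlled vocabularies for fishery classification
#'
#' Fisheries are classified by flag state, gear type, target species group
#' and FAO Major Fishing Area. Gear, area and target labels are drawn from
#' closed vocabularies; every reader in the package validates against them.
#' The default vocabulary ships with the package (25 gear types, 19 FAO
#' areas stored as character codes, 8 target groups) together with the
#' default assessment period 2010--2014.
#'
#' @param path Path to a vocabulary YAML file. Defaults to the file shipped
#'   with the package.
#' @return A list of class `db_vocab` with elements `gear_types`,
#'   `fao_areas`, `target_groups` (character vectors), `period` (integer
#'   vector of years) and `version`.
#' @examples
#' v <- default_vocab()
#' length(v$gear_types)
#' @export
read_vocab <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("gear_types", "fao_areas", "target_groups", "period")) {
    if (is.null(raw[[f]])) {
      abort(paste0("vocabulary file is missing field '", f, "'"),
            class = "db_schema_error")
    }
  }
  vocab <- list(
    version       = raw$version %||% 0L,
    gear_types    = as.character(raw$gear_types),
    fao_areas     = as.character(raw$fao_areas),
    target_groups = as.character(raw$target_groups),
    period        = seq.int(raw$period$start, raw$period$end)
  )
  structure(vocab, class = "db_vocab")
}

#' @rdname read_vocab
#' @export
default_vocab <- function() {
  if (is.null(the$vocab)) {
    path <- system.file("extdata", "vocabularies.yaml",
                        package = "discardbench", mustWork = TRUE)
    the$vocab <- read_vocab(path)
  }
  the$vocab
}

# Check that labels belong to a vocabulary; typed error listing the
# allowed values otherwise.
check_vocab <- function(values, allowed, what) {
  bad <- setdiff(unique(values), allowed)
  if (length(bad) > 0) {
    abort(
      paste0(
        "unknown ", what, " label(s): ", paste(bad, collapse = ", "),
        "\nallowed values: ", paste(allowed, collapse = ", ")
      ),
      class = "db_vocab_error"
    )
  }
  invisible(values)
}

# Canonical single-string fishery identifier used for joins and draw tables.
fishery_id <- function(flag_state, gear_type, target_group, fao_area) {
  paste(flag_state, gear_type, target_group, fao_area, sep = "|")
}
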