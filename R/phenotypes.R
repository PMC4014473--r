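#' Trial design of a multi-environment evaluation
#'
#' An environment is one (location, year) combination; lines are evaluated in
#' every environment with `replicates` complete blocks.
#'
#' @param environments Tibble with columns `location` and `year` (one row per
#'   environment), or a character vector of ready-made `"location:year"`
#'   labels.
#' @param replicates Replications per environment (complete blocks).
#' @return A `trial_design` object: tibble `environments` (with `env` label
#'   column) plus `replicates`.
#' @export
trial_design <- function(environments, replicates = 1L) {
  if (is.character(environments)) {
    environments <- dplyr::bind_cols(tibble(env = environments),
                                     split_env_label(environments))
  } else {
    environments <- as_tibble(environments)
    stopifnot(all(c("location", "year") %in% names(environments)))
    environments$year <- as.character(environments$year)
    environments$env <- env_label(environments$location, environments$year)
    environments <- select(environments, "env", "location", "year")
  }
  if (nrow(environments) < 1L) abort("at least one environment is required")
  if (anyDuplicated(environments$env)) abort("duplicate environments in trial design")
  if (replicates < 1L) abort("`replicates` must be >= 1")
  structure(list(environments = environments, replicates = as.integer(replicates)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design> %d environments (%d locations x %d years), %d replicate(s)\n",
              nrow(x$environments), dplyr::n_distinct(x$environments$location),
              dplyr::n_distinct(x$environments$year), x$replicates))
  invisible(x)
}

validate_phenotypes <- function(phen) {
  phen <- as_tibble(phen)
  need <- c("line_id", "location", "year", "replicate", "trait", "value")
  missing_cols <- setdiff(need, names(phen))
  if (length(missing_cols)) {
    abort(sprintf("phenotype table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  phen$year <- as.character(phen$year)
  if (!is.numeric(phen$value) || any(!is.finite(phen$value))) {
    abort("phenotype values must be finite numbers")
  }
  dup <- phen %>%
    count(.data$line_id, .data$location, .data$year, .data$replicate, .data$trait) %>%
    filter(n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate phenotype record(s), first: line '%s', %s:%s rep %s trait '%s'",
                  dup$line_id[1], dup$location[1], dup$year[1], dup$replicate[1], dup$trait[1]))
  }
  phen
}

#' Read a long-format phenotype table
#'
#' Expects a tab-separated file with columns `line_id`, `location`, `year`,
#' `replicate`, `trait`, `value`. The trial design (distinct location x year
#' environments) is inferred from the records.
#'
#' @param path Path to a phenotype TSV.
#' @return A list with `phenotypes` (validated tibble) and `design`
#'   (inferred [trial_design]).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("phenotype file not found: %s", path))
  phen <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), location = readr::col_character(),
    year = readr::col_character(), replicate = readr::col_integer(),
    trait = readr::col_character(), value = readr::col_character()
  ), progress = FALSE)
  vals <- suppressWarnings(as.numeric(phen$value))
  bad <- which(is.na(vals))
  if (length(bad)) {
    abort(sprintf("unparseable phenotype value '%s' at row %d", phen$value[bad[1]], bad[1]))
  }
  phen$value <- vals
  phen <- validate_phenotypes(phen)
  envs <- distinct(phen, .data$location, .data$year) %>%
    arrange(.data$location, .data$year)
  design <- trial_design(envs, replicates = max(phen$replicate))
  list(phenotypes = phen, design = design)
}

#' Write a long-format phenotype table
#'
#' @param phen Phenotype tibble (see [read_phenotypes()] for columns).
#' @param path Output path (tab-separated, UTF-8).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  phen <- validate_phenotypes(phen)
  readr::write_tsv(phen, path, progress = FALSE)
  invisible(path)
}

# Average replicate observations to one genotype-in-environment value per
# line x environment x trait; this is the modelling scale.
aggregate_replicates <- function(phen, trait) {
  phen <- validate_phenotypes(phen)
  if (!trait %in% phen$trait) abort(sprintf("trait '%s' not present in phenotypes", trait))
  phen %>%
    filter(.data$trait == !!trait) %>%
    mutate(env = env_label(.data$location, .data$year)) %>%
    group_by(.data$line_id, .data$env, .data$location, .data$year) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    arrange(.data$env, .data$line_id)
}
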