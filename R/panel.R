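#' Marker panel of inbred lines at presence/absence loci
#'
#' A `marker_panel` holds the genotypes of an inbred panel at biallelic
#' presence/absence marker loci (each SSR allele is treated as its own
#' biallelic locus, named `primer-allelesize`, e.g. `"NAU3011-197"`). The raw
#' `calls` are 1 (allele present), 0 (absent) or `NA` (missing); after
#' [encode_genotypes()] the numeric `coded` matrix holds +1/-1 values with
#' missing cells mean-imputed, ready for model design matrices.
#'
#' @param calls Integer matrix (lines x loci) with values in `{0, 1, NA}`,
#'   dimnames giving line and locus ids.
#' @param coded Optional numeric matrix of encoded genotypes (see
#'   [encode_genotypes()]).
#' @param dropped Tibble logging loci removed during encoding.
#'
#' @return An object of class `marker_panel` with fields `line_ids`,
#'   `locus_ids`, `calls`, `coded`, `dropped`.
#' @export
marker_panel <- function(calls, coded = NULL, dropped = NULL) {
  if (!is.matrix(calls)) abort("`calls` must be a matrix.")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` must carry line ids as rownames and locus ids as colnames.")
  }
  line_ids <- rownames(calls)
  locus_ids <- colnames(calls)
  if (anyDuplicated(line_ids)) {
    abort(sprintf("duplicate line id(s): %s",
                  paste(unique(line_ids[duplicated(line_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(locus_ids)) {
    abort(sprintf("duplicate locus id(s): %s",
                  paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", ")))
  }
  bad <- !(calls %in% c(0L, 1L, NA))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(calls)), arr.ind = TRUE)[1, ]
    abort(sprintf("genotype calls must be 0, 1 or NA; offending cell at line '%s', locus '%s'",
                  line_ids[idx[1]], locus_ids[idx[2]]))
  }
  structure(
    list(line_ids = line_ids, locus_ids = locus_ids,
         calls = calls, coded = coded,
         dropped = dropped %||% tibble(locus = character(), reason = character())),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d lines x %d loci (%s)\n",
              length(x$line_ids), length(x$locus_ids),
              if (is.null(x$coded)) "raw calls" else "encoded"))
  if (nrow(x$dropped)) cat(sprintf("  %d loci dropped during encoding\n", nrow(x$dropped)))
  invisible(x)
}

#' @export
dim.marker_panel <- function(x) c(length(x$line_ids), length(x$locus_ids))

#' Tidy a marker panel into long format
#'
#' @param x A [marker_panel].
#' @param ... Unused.
#' @return A tibble with one row per (line, locus) cell: `line_id`,
#'   `locus_id`, `call` and, when encoded, `coded`.
#' @export
tidy.marker_panel <- function(x, ...) {
  out <- as_tibble(as.table(x$calls), .name_repair = "minimal")
  names(out) <- c("line_id", "locus_id", "call")
  out <- as_tibble(out)
  if (!is.null(x$coded)) {
    cod <- as_tibble(as.table(x$coded), .name_repair = "minimal")
    names(cod) <- c("line_id", "locus_id", "coded")
    out <- left_join(out, cod, by = c("line_id", "locus_id"))
  }
  arrange(out, .data$line_id, .data$locus_id)
}

#' Read a genotype table
#'
#' Reads a tab-separated genotype table: header `line_id` followed by one
#' column per locus, one row per line, cells `0`/`1`/`NA`.
#'
#' @param path Path to a genotype TSV.
#' @return A [marker_panel] with `calls` populated and `coded` empty.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("genotype file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "line_id") {
    abort("genotype file must have a header starting with 'line_id' and at least one locus column")
  }
  loci <- header[-1]
  if (anyDuplicated(loci)) {
    abort(sprintf("duplicate locus id(s) in header: %s",
                  paste(unique(loci[duplicated(loci)]), collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), .default = readr::col_character()
  ), na = c("NA", ""), progress = FALSE, name_repair = "minimal")
  m <- as.matrix(raw[, -1, drop = FALSE])
  bad <- !(m %in% c("0", "1", NA))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    abort(sprintf("non-{0,1,NA} genotype cell at row %d (line '%s'), column '%s': '%s'",
                  idx[1], raw$line_id[idx[1]], loci[idx[2]], m[idx[1], idx[2]]))
  }
  calls <- matrix(as.integer(m), nrow = nrow(m),
                  dimnames = list(raw$line_id, loci))
  marker_panel(calls)
}

#' Write a genotype table
#'
#' @param panel A [marker_panel]; raw `calls` are written.
#' @param path Output path (tab-separated, UTF-8).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  df <- as_tibble(panel$calls, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(line_id = panel$line_ids), df)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Encode genotype calls for modelling
#'
#' Encodes presence/absence calls to +1 (allele present, genotype `QQ`) and
#' -1 (absent, `qq`), the coding under which a pair's epistasis coefficient
#' is the product of the two locus codes. Loci whose minor-state frequency
#' (among non-missing calls) falls below `maf_min`, or whose missing rate
#' exceeds `missing_max`, are dropped and logged; monomorphic loci are always
#' dropped. Remaining missing cells are imputed to the locus mean of the
#' coded values, keeping the design dense and main-effect unbiased.
#'
#' @param panel A [marker_panel] with `calls` populated.
#' @param maf_min Minimum minor-state frequency (fraction in `[0, 0.5]`).
#' @param missing_max Maximum tolerated missing rate per locus.
#' @return The panel with `coded` populated and `dropped` logging removals.
#' @export
encode_genotypes <- function(panel, maf_min = 0.05, missing_max = 0.2) {
  stopifnot(inherits(panel, "marker_panel"))
  assert_scalar_number(maf_min, "maf_min", min = 0)
  assert_scalar_number(missing_max, "missing_max", min = 0)
  calls <- panel$calls
  miss_rate <- colMeans(is.na(calls))
  p_present <- colMeans(calls == 1L, na.rm = TRUE)
  minor <- pmin(p_present, 1 - p_present)
  minor[is.nan(minor)] <- 0

  reason <- rep(NA_character_, ncol(calls))
  reason[miss_rate > missing_max] <- "missing_rate"
  mono <- minor == 0
  reason[is.na(reason) & mono] <- "monomorphic"
  reason[is.na(reason) & minor < maf_min] <- "low_maf"

  keep <- is.na(reason)
  if (!any(keep)) abort("all loci were filtered out during encoding")
  dropped <- tibble(locus = colnames(calls)[!keep], reason = reason[!keep])

  kept <- calls[, keep, drop = FALSE]
  coded <- matrix(NA_real_, nrow(kept), ncol(kept), dimnames = dimnames(kept))
  coded[kept == 1L] <- 1
  coded[kept == 0L] <- -1
  locus_mean <- colMeans(coded, na.rm = TRUE)
  na_idx <- which(is.na(coded), arr.ind = TRUE)
  if (nrow(na_idx)) coded[na_idx] <- locus_mean[na_idx[, 2]]

  marker_panel(kept, coded = coded, dropped = dropped)
}
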