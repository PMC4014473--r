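# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Environment labels are "<location>:<year>"; kept as plain strings so they
# survive TSV round trips. Locations must not contain ":".
env_label <- function(location, year) paste(location, year, sep = ":")

split_env_label <- function(env) {
  parts <- stringr::str_split_fixed(env, ":", 2)
  tibble(location = parts[, 1], year = parts[, 2])
}

# Pair ids use the multiplication sign, as in field reporting conventions.
pair_sep <- "×"

pair_label <- function(locus_i, locus_j) paste(locus_i, locus_j, sep = pair_sep)

split_pair_label <- function(id) {
  parts <- stringr::str_split_fixed(id, stringr::fixed(pair_sep), 2)
  tibble(locus_i = parts[, 1], locus_j = parts[, 2])
}

# Deterministic sub-seed derivation, kept well below .Machine$integer.max.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 104729L * as.integer(k)) %% 2000000011L
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, format(min)))
  }
  invisible(x)
}

colvar <- function(m) {
  # population-style column variance (denominator n), used for per-column
  # contributions to phenotypic variance
  n <- nrow(m)
  mu <- colMeans(m)
  colMeans(m^2) - mu^2
}
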