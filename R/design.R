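#' Canonical ordering of a locus pair
#'
#' Pairs are unordered; the canonical form puts the lexicographically smaller
#' locus id first so every pair has one stable id.
#'
#' @param locus_i,locus_j Character vectors of locus ids (recycled).
#' @return A tibble with columns `locus_i`, `locus_j`, `pair` (the canonical
#'   `"i×j"` label).
#' @export
canonical_pair <- function(locus_i, locus_j) {
  if (any(locus_i == locus_j)) abort("a locus cannot be paired with itself")
  swap <- locus_j < locus_i
  a <- ifelse(swap, locus_j, locus_i)
  b <- ifelse(swap, locus_i, locus_j)
  tibble(locus_i = a, locus_j = b, pair = pair_label(a, b))
}

#' Assemble the model term set
#'
#' A `model_terms` object lists the candidate terms of the final mixed model
#' by random-effect group: `A` (additive loci), `AA` (epistatic pairs), `AE`
#' (locus-by-environment) and `AAE` (pair-by-environment). AE/AAE terms are
#' expanded over the environments they act in; pairs are stored canonically.
#'
#' @param additive Character vector of locus ids.
#' @param epistasis Tibble `(locus_i, locus_j)` of pairs.
#' @param add_by_env Tibble `(locus, env)`.
#' @param epi_by_env Tibble `(locus_i, locus_j, env)`.
#' @return A `model_terms` object.
#' @export
model_terms <- function(additive = character(), epistasis = NULL,
                        add_by_env = NULL, epi_by_env = NULL) {
  epi <- if (is.null(epistasis) || !nrow(epistasis)) {
    tibble(locus_i = character(), locus_j = character(), pair = character())
  } else canonical_pair(epistasis$locus_i, epistasis$locus_j) %>% distinct()
  ae <- if (is.null(add_by_env) || !nrow(add_by_env)) {
    tibble(locus = character(), env = character())
  } else distinct(as_tibble(add_by_env)[c("locus", "env")])
  aae <- if (is.null(epi_by_env) || !nrow(epi_by_env)) {
    tibble(locus_i = character(), locus_j = character(), pair = character(),
           env = character())
  } else {
    x <- as_tibble(epi_by_env)
    dplyr::bind_cols(canonical_pair(x$locus_i, x$locus_j), x["env"]) %>% distinct()
  }
  additive <- unique(as.character(additive))
  structure(list(additive = additive, epistasis = epi,
                 add_by_env = ae, epi_by_env = aae),
            class = "model_terms")
}

#' @export
print.model_terms <- function(x, ...) {
  cat(sprintf("<model_terms> A: %d loci, AA: %d pairs, AE: %d locus-env terms, AAE: %d pair-env terms\n",
              length(x$additive), nrow(x$epistasis), nrow(x$add_by_env),
              nrow(x$epi_by_env)))
  invisible(x)
}

n_terms <- function(terms) {
  length(terms$additive) + nrow(terms$epistasis) +
    nrow(terms$add_by_env) + nrow(terms$epi_by_env)
}

#' Build the fixed and random design matrices of the mixed model
#'
#' Assembles, for one trait, the observation vector `y` (replicates within a
#' line-by-environment cell averaged), the fixed incidence matrix `X`
#' (intercept plus environment factor in sum-to-zero contrasts, so the
#' intercept is the grand mean), and one random-coefficient matrix per group:
#' `A` columns are coded locus values, `AA` columns elementwise products of
#' the two loci, and `AE`/`AAE` columns the corresponding `A`/`AA` column
#' masked to the rows of their environment and zero elsewhere.
#'
#' @param panel Encoded [marker_panel].
#' @param design [trial_design].
#' @param phen Phenotype tibble.
#' @param terms [model_terms].
#' @param trait Trait name.
#' @return An `assembled_design`: `y`, `X`, `U` (named list of matrices),
#'   `obs_index` tibble, `col_info` tibble (`group`, `term`, `env`, `column`,
#'   `variance`), `envs`.
#' @export
build_design <- function(panel, design, phen, terms, trait) {
  stopifnot(inherits(panel, "marker_panel"), inherits(design, "trial_design"),
            inherits(terms, "model_terms"))
  if (is.null(panel$coded)) abort("panel must be encoded (see encode_genotypes())")
  coded <- panel$coded
  used <- unique(c(terms$additive, terms$epistasis$locus_i, terms$epistasis$locus_j,
                   terms$add_by_env$locus, terms$epi_by_env$locus_i,
                   terms$epi_by_env$locus_j))
  missing_loci <- setdiff(used, colnames(coded))
  if (length(missing_loci)) {
    abort(sprintf("term references unknown locus/loci: %s",
                  paste(missing_loci, collapse = ", ")))
  }
  envs <- design$environments$env
  bad_env <- setdiff(c(terms$add_by_env$env, terms$epi_by_env$env), envs)
  if (length(bad_env)) {
    abort(sprintf("term references unknown environment(s): %s",
                  paste(bad_env, collapse = ", ")))
  }

  agg <- aggregate_replicates(phen, trait)
  unknown_lines <- setdiff(agg$line_id, panel$line_ids)
  if (length(unknown_lines)) {
    abort(sprintf("phenotyped line(s) absent from panel: %s",
                  paste(head(unknown_lines, 5), collapse = ", ")))
  }
  unknown_envs <- setdiff(agg$env, envs)
  if (length(unknown_envs)) {
    abort(sprintf("phenotype environment(s) absent from trial design: %s",
                  paste(unknown_envs, collapse = ", ")))
  }
  y <- agg$value
  n <- length(y)
  li <- match(agg$line_id, panel$line_ids)
  env_fac <- factor(agg$env, levels = envs)

  X <- if (length(envs) > 1L) {
    stats::model.matrix(~ env_fac, contrasts.arg = list(env_fac = "contr.sum"))
  } else {
    matrix(1, n, 1)
  }
  colnames(X) <- c("mu", if (length(envs) > 1L) paste0("env_", envs[-length(envs)]))
  rownames(X) <- NULL

  mask <- function(col, env) col * (env_fac == env)

  U <- list(); info <- list()
  if (length(terms$additive)) {
    A <- coded[li, terms$additive, drop = FALSE]
    colnames(A) <- terms$additive
    U$A <- A
    info$A <- tibble(group = "A", term = terms$additive, env = NA_character_,
                     column = terms$additive)
  }
  if (nrow(terms$epistasis)) {
    AA <- vapply(seq_len(nrow(terms$epistasis)), function(r) {
      coded[li, terms$epistasis$locus_i[r]] * coded[li, terms$epistasis$locus_j[r]]
    }, numeric(n))
    AA <- matrix(AA, nrow = n, dimnames = list(NULL, terms$epistasis$pair))
    U$AA <- AA
    info$AA <- tibble(group = "AA", term = terms$epistasis$pair,
                      env = NA_character_, column = terms$epistasis$pair)
  }
  if (nrow(terms$add_by_env)) {
    AE <- vapply(seq_len(nrow(terms$add_by_env)), function(r) {
      mask(coded[li, terms$add_by_env$locus[r]], terms$add_by_env$env[r])
    }, numeric(n))
    cols <- paste0(terms$add_by_env$locus, "@", terms$add_by_env$env)
    AE <- matrix(AE, nrow = n, dimnames = list(NULL, cols))
    U$AE <- AE
    info$AE <- tibble(group = "AE", term = terms$add_by_env$locus,
                      env = terms$add_by_env$env, column = cols)
  }
  if (nrow(terms$epi_by_env)) {
    AAE <- vapply(seq_len(nrow(terms$epi_by_env)), function(r) {
      mask(coded[li, terms$epi_by_env$locus_i[r]] * coded[li, terms$epi_by_env$locus_j[r]],
           terms$epi_by_env$env[r])
    }, numeric(n))
    cols <- paste0(terms$epi_by_env$pair, "@", terms$epi_by_env$env)
    AAE <- matrix(AAE, nrow = n, dimnames = list(NULL, cols))
    U$AAE <- AAE
    info$AAE <- tibble(group = "AAE", term = terms$epi_by_env$pair,
                       env = terms$epi_by_env$env, column = cols)
  }
  col_info <- bind_rows(info)
  if (nrow(col_info)) {
    col_info$variance <- unlist(lapply(U, colvar), use.names = FALSE)
  } else {
    col_info <- tibble(group = character(), term = character(),
                       env = character(), column = character(),
                       variance = numeric())
  }
  structure(list(y = y, X = X, U = U,
                 obs_index = select(agg, "line_id", "env", "location", "year"),
                 col_info = col_info, envs = envs, terms = terms, trait = trait),
            class = "assembled_design")
}

#' @export
print.assembled_design <- function(x, ...) {
  cat(sprintf("<assembled_design> trait '%s': %d observations, %d fixed columns, random columns: %s\n",
              x$trait, length(x$y), ncol(x$X),
              if (length(x$U)) paste(sprintf("%s=%d", names(x$U), vapply(x$U, ncol, 1L)),
                                     collapse = ", ") else "none"))
  invisible(x)
}
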