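#' Partition heritability into effect categories and individual terms
#'
#' Category heritability is the category's phenotypic variance contribution
#' as a percentage of `V_P`. The category percentage is then allocated
#' across its member terms proportionally to each term's squared predicted
#' effect times the empirical variance of its coefficient column (summed
#' over environments for interaction terms), so per-term values add up to
#' the category value exactly.
#'
#' @param fit A `qts_fit` from [fit_mixed_model()].
#' @return A `qts_herit` object: `categories` (named percentages `h2_A`,
#'   `h2_AA`, `h2_AE`, `h2_AAE`, plus `h2_T`, `h2_G = h2_A + h2_AA`,
#'   `h2_GE = h2_AE + h2_AAE`) and `per_term` tibble (`group`, `term`,
#'   `h2_pct`).
#' @export
partition_heritability <- function(fit) {
  stopifnot(inherits(fit, "qts_fit"))
  vc <- fit$vc
  if (vc[["V_P"]] <= 0) abort("V_P is zero; heritability is undefined")
  cats <- c(h2_A = 100 * vc[["V_A"]] / vc[["V_P"]],
            h2_AA = 100 * vc[["V_AA"]] / vc[["V_P"]],
            h2_AE = 100 * vc[["V_AE"]] / vc[["V_P"]],
            h2_AAE = 100 * vc[["V_AAE"]] / vc[["V_P"]])
  cats <- c(cats, h2_T = sum(cats), h2_G = unname(cats["h2_A"] + cats["h2_AA"]),
            h2_GE = unname(cats["h2_AE"] + cats["h2_AAE"]))

  eff <- fit$effects
  per_term <- if (nrow(eff)) {
    eff %>%
      left_join(select(fit$col_info, "group", "column", "variance"),
                by = c("group", "column")) %>%
      group_by(.data$group, .data$term) %>%
      summarise(weight = sum(.data$effect^2 * .data$variance), .groups = "drop") %>%
      group_by(.data$group) %>%
      mutate(h2_pct = {
        cat_h2 <- unname(cats[paste0("h2_", .data$group[1])])
        if (sum(.data$weight) > 0) cat_h2 * .data$weight / sum(.data$weight)
        else rep(0, dplyr::n())
      }) %>%
      ungroup() %>%
      select("group", "term", "h2_pct") %>%
      arrange(.data$group, .data$term)
  } else {
    tibble(group = character(), term = character(), h2_pct = numeric())
  }
  structure(list(categories = cats, per_term = per_term, vc = vc,
                 trait = fit$trait),
            class = "qts_herit")
}

#' @export
print.qts_herit <- function(x, ...) {
  c2 <- round(x$categories, 2)
  cat(sprintf("<qts_herit> trait '%s': h2_A=%.2f h2_AA=%.2f h2_AE=%.2f h2_AAE=%.2f | h2_T=%.2f\n",
              x$trait, c2["h2_A"], c2["h2_AA"], c2["h2_AE"], c2["h2_AAE"], c2["h2_T"]))
  invisible(x)
}

#' @describeIn partition_heritability Tidy the per-term heritabilities.
#' @param x A `qts_herit`.
#' @param ... Unused.
#' @export
tidy.qts_herit <- function(x, ...) x$per_term

#' @describeIn partition_heritability One-row category summary (percent,
#'   rounded to report precision).
#' @export
glance.qts_herit <- function(x, ...) {
  as_tibble(as.list(round(x$categories, 2)))
}

#' Aggregate heritability percentages
#'
#' Sums category (or per-term) heritability percentages into the reported
#' aggregates: `"total"` is the sum of the four category values,
#' `"genotype"` the stable genetic part (additive + epistasis), `"gxe"` the
#' environment-interaction part, and `"terms"` an unconstrained sum of
#' per-term percentages (e.g. a selection-gain projection). Results are
#' rounded to 2 decimals, the reporting precision.
#'
#' @param parts Numeric vector of non-negative percentages: 4 values for
#'   `"total"`, 2 for `"genotype"`/`"gxe"`, any number for `"terms"`.
#' @param which Aggregation flavour.
#' @return A single percentage, rounded to 2 decimals.
#' @export
aggregate_heritability <- function(parts, which = c("total", "genotype", "gxe", "terms")) {
  which <- match.arg(which)
  parts <- as.numeric(parts)
  if (any(!is.finite(parts)) || any(parts < 0)) {
    abort("heritability percentages must be finite and non-negative")
  }
  expected <- switch(which, total = 4L, genotype = 2L, gxe = 2L, terms = NA_integer_)
  if (!is.na(expected) && length(parts) != expected) {
    abort(sprintf("`which = \"%s\"` expects %d category values, got %d",
                  which, expected, length(parts)))
  }
  round(sum(parts), 2)
}

#' Classify loci by cross-environment stability
#'
#' Partitions reported terms into the three reliability classes:
#' *constitutive* loci carry a significant main (additive or epistasis)
#' effect and are usable across environments; *environment-specific* loci
#' have only environment-interaction effects, all confined to one location
#' but significant there in at least two years; everything else is
#' *environment-sensitive*.
#'
#' @param effects Predicted-effects tibble (from [fit_mixed_model()]), with
#'   `group`, `term`, `env`, `neg_log10_p`.
#' @param design [trial_design] (for the location/year structure).
#' @param score_min Significance threshold on the -log10 p score, normally
#'   the experiment-wise threshold from the scan.
#' @return Tibble `term`, `class`, `evidence`.
#' @export
classify_locus <- function(effects, design, score_min) {
  stopifnot(inherits(design, "trial_design"))
  assert_scalar_number(score_min, "score_min", min = 0)
  if (!nrow(effects)) return(tibble(term = character(), class = character(),
                                    evidence = character()))
  eff <- effects %>%
    mutate(significant = .data$neg_log10_p >= score_min)
  purrr::map_dfr(unique(eff$term), function(tm) {
    rows <- eff[eff$term == tm, ]
    sig <- rows[rows$significant, ]
    main_sig <- sig[sig$group %in% c("A", "AA"), ]
    int_sig <- sig[sig$group %in% c("AE", "AAE"), ]
    if (nrow(main_sig)) {
      cls <- "constitutive"
      ev <- sprintf("significant %s effect", paste(unique(main_sig$group), collapse = "+"))
    } else if (nrow(int_sig)) {
      loc_year <- split_env_label(int_sig$env)
      locs <- unique(loc_year$location)
      yrs <- unique(loc_year$year)
      if (length(locs) == 1L && length(yrs) >= 2L) {
        cls <- "environment_specific"
        ev <- sprintf("%s effects at %s in %d years (%s)",
                      paste(unique(int_sig$group), collapse = "+"), locs,
                      length(yrs), paste(sort(yrs), collapse = ", "))
      } else {
        cls <- "environment_sensitive"
        ev <- sprintf("interaction effects in %s", paste(unique(int_sig$env), collapse = ", "))
      }
    } else {
      cls <- "environment_sensitive"
      ev <- "no effect passes the significance threshold"
    }
    tibble(term = tm, class = cls, evidence = ev)
  })
}

#' Screen for elite loci
#'
#' Keeps the highly significant, high-heritability terms: individual-locus
#' terms (`A`, `AE`) with score at least `score_min` and per-term
#' heritability at least `h2_min_individual` percent; pair terms
#' (`AA`, `AAE`) with score at least `score_min` and heritability at least
#' `h2_min_epistasis` percent.
#'
#' @param effects Predicted-effects tibble.
#' @param partition A `qts_herit` from [partition_heritability()].
#' @param score_min Minimum -log10 p.
#' @param h2_min_individual Minimum per-term heritability (percent) for
#'   individual loci.
#' @param h2_min_epistasis Minimum per-term heritability for pairs.
#' @return The qualifying effect rows, with `h2_pct` attached.
#' @export
elite_screen <- function(effects, partition, score_min = 8,
                         h2_min_individual = 1, h2_min_epistasis = 0.5) {
  stopifnot(inherits(partition, "qts_herit"))
  assert_scalar_number(score_min, "score_min", min = 0)
  assert_scalar_number(h2_min_individual, "h2_min_individual", min = 0)
  assert_scalar_number(h2_min_epistasis, "h2_min_epistasis", min = 0)
  if (!nrow(effects)) return(mutate(effects, h2_pct = numeric(0)))
  eff <- effects %>%
    left_join(partition$per_term, by = c("group", "term")) %>%
    mutate(h2_pct = dplyr::coalesce(.data$h2_pct, 0))
  keep <- eff %>%
    group_by(.data$group, .data$term) %>%
    summarise(top_score = max(.data$neg_log10_p), h2_pct = .data$h2_pct[1],
              .groups = "drop") %>%
    mutate(h2_min = ifelse(.data$group %in% c("A", "AE"),
                           h2_min_individual, h2_min_epistasis)) %>%
    filter(.data$top_score >= score_min, .data$h2_pct >= .data$h2_min)
  eff %>%
    dplyr::semi_join(keep, by = c("group", "term")) %>%
    arrange(.data$group, dplyr::desc(.data$neg_log10_p))
}

#' Summarise loci shared across traits
#'
#' @param per_trait_effects Named list mapping trait name to its
#'   predicted-effects tibble; pair terms contribute both member loci.
#' @return Tibble `locus`, `n_traits`, `traits` (comma-separated, sorted),
#'   ordered by locus id; the attribute `"k_counts"` tabulates how many loci
#'   are shared by exactly k traits.
#' @export
shared_locus_summary <- function(per_trait_effects) {
  if (length(per_trait_effects) < 2L) abort("at least two traits are required")
  if (is.null(names(per_trait_effects)) || any(names(per_trait_effects) == "")) {
    abort("`per_trait_effects` must be a named list (names = traits)")
  }
  loci_of <- function(eff) {
    if (!nrow(eff)) return(character())
    singles <- eff$term[eff$group %in% c("A", "AE")]
    pairs <- eff$term[eff$group %in% c("AA", "AAE")]
    members <- if (length(pairs)) unlist(split_pair_label(pairs), use.names = FALSE) else character()
    unique(c(singles, members))
  }
  long <- purrr::imap_dfr(per_trait_effects,
                          function(eff, tr) tibble(trait = tr, locus = loci_of(eff)))
  out <- long %>%
    distinct(.data$trait, .data$locus) %>%
    group_by(.data$locus) %>%
    summarise(n_traits = dplyr::n(),
              traits = paste(sort(.data$trait), collapse = ","),
              .groups = "drop") %>%
    arrange(.data$locus)
  attr(out, "k_counts") <- count(out, .data$n_traits, name = "n_loci")
  out
}

#' Export the locus-effect network
#'
#' Builds node and edge tables of the locus network: nodes are loci,
#' classed `additive` (main effect only), `interaction_only`
#' (additive-by-environment only), `both`, or `epistasis_only` (appearing
#' only as a pair member); edges are distinct pairs, classed `aa`
#' (epistasis) or `aae` (environment-specific epistasis). Pass pre-filtered
#' effects (e.g. from [elite_screen()]) to network only the reported terms.
#'
#' @param effects Predicted-effects tibble.
#' @param path Optional path prefix; writes `<path>_nodes.tsv` and
#'   `<path>_edges.tsv`.
#' @return List of tibbles `nodes` (`locus`, `class`) and `edges`
#'   (`locus_i`, `locus_j`, `class`).
#' @export
export_network <- function(effects, path = NULL) {
  singles_a <- unique(effects$term[effects$group == "A"])
  singles_ae <- unique(effects$term[effects$group == "AE"])
  pair_terms <- unique(effects$term[effects$group %in% c("AA", "AAE")])
  pair_members <- if (length(pair_terms)) {
    unique(unlist(split_pair_label(pair_terms), use.names = FALSE))
  } else character()
  all_loci <- sort(unique(c(singles_a, singles_ae, pair_members)))
  classify <- function(l) {
    has_a <- l %in% singles_a
    has_ae <- l %in% singles_ae
    if (has_a && has_ae) "both"
    else if (has_a) "additive"
    else if (has_ae) "interaction_only"
    else "epistasis_only"
  }
  nodes <- tibble(locus = all_loci,
                  class = vapply(all_loci, classify, character(1),
                                 USE.NAMES = FALSE))
  edges <- effects %>%
    filter(.data$group %in% c("AA", "AAE")) %>%
    distinct(.data$term, .data$group) %>%
    mutate(class = ifelse(.data$group == "AA", "aa", "aae")) %>%
    distinct(.data$term, .data$class)
  edges <- if (nrow(edges)) {
    dplyr::bind_cols(split_pair_label(edges$term), class = edges$class) %>%
      arrange(.data$locus_i, .data$locus_j, .data$class)
  } else {
    tibble(locus_i = character(), locus_j = character(), class = character())
  }
  if (!is.null(path)) {
    readr::write_tsv(nodes, paste0(path, "_nodes.tsv"), progress = FALSE)
    readr::write_tsv(edges, paste0(path, "_edges.tsv"), progress = FALSE)
  }
  list(nodes = nodes, edges = edges)
}
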