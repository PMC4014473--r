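#' Specify the genetic architecture of a simulated study
#'
#' Collects the effect lists of the phenotype model
#' \deqn{y_{hk} = \mu + e_h + \sum_i x_{ik} a_i + \sum_{i<j} x_{ik}x_{jk} aa_{ij}
#'   + \sum_i x_{ik} ae_{ih} + \sum_{i<j} x_{ik}x_{jk} aae_{ijh} + \epsilon_{hk}}
#' where \eqn{x \in \{+1,-1\}} are locus codes. Environment-interaction
#' effects (`ae`, `aae`) are centered across all declared environments at
#' simulation time so that main and interaction effects are identifiable.
#'
#' @param additive Tibble/data frame `(locus, a)` of additive effects.
#' @param epistasis Tibble `(locus_i, locus_j, aa)` of pairwise
#'   additive-by-additive effects.
#' @param add_by_env Tibble `(locus, env, ae)`; environments not listed for a
#'   locus contribute 0 before centering.
#' @param epi_by_env Tibble `(locus_i, locus_j, env, aae)`.
#' @param env_means Named numeric vector of fixed environment effects
#'   \eqn{e_h} (names = `"location:year"` labels); missing environments get 0.
#' @param grand_mean Population mean \eqn{\mu} (trait units).
#' @param resid_var Residual variance \eqn{\sigma^2_\epsilon} per replicate
#'   observation (squared trait units).
#' @return An `effect_config` list.
#' @export
effect_config <- function(additive = NULL, epistasis = NULL,
                          add_by_env = NULL, epi_by_env = NULL,
                          env_means = NULL, grand_mean = 0, resid_var = 1) {
  assert_scalar_number(grand_mean, "grand_mean")
  assert_scalar_number(resid_var, "resid_var", min = 0)
  as_tbl <- function(x, cols) {
    if (is.null(x)) return(tibble::as_tibble(setNames(
      c(rep(list(character()), length(cols) - 1L), list(numeric())), cols)))
    x <- as_tibble(x)
    stopifnot(all(cols %in% names(x)))
    x[cols]
  }
  structure(list(
    additive = as_tbl(additive, c("locus", "a")),
    epistasis = as_tbl(epistasis, c("locus_i", "locus_j", "aa")),
    add_by_env = as_tbl(add_by_env, c("locus", "env", "ae")),
    epi_by_env = as_tbl(epi_by_env, c("locus_i", "locus_j", "env", "aae")),
    env_means = env_means, grand_mean = grand_mean, resid_var = resid_var
  ), class = "effect_config")
}

#' Simulate a biallelic marker panel
#'
#' Draws independent presence/absence loci for an inbred panel: each locus's
#' presence frequency is drawn from `maf_dist`, and line calls are
#' independent Bernoulli draws. Loci that come out monomorphic are redrawn so
#' every locus is polymorphic. The returned panel is already encoded
#' (+1 present / -1 absent, no missing cells).
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param n_loci Number of loci (>= 1).
#' @param maf_dist Presence-frequency distribution: a single value in (0, 1),
#'   a `c(min, max)` uniform range within (0, 1), or a `function(n)` drawing
#'   `n` frequencies.
#' @param seed RNG seed for reproducibility.
#' @return An encoded [marker_panel].
#' @export
simulate_panel <- function(n_lines, n_loci, maf_dist = c(0.1, 0.5), seed = NULL) {
  if (n_lines < 2L) abort("`n_lines` must be >= 2")
  if (n_loci < 1L) abort("`n_loci` must be >= 1")
  draw <- if (is.function(maf_dist)) {
    maf_dist
  } else if (is.numeric(maf_dist) && length(maf_dist) %in% 1:2) {
    lo <- min(maf_dist); hi <- max(maf_dist)
    if (lo <= 0 || hi >= 1) {
      abort("degenerate `maf_dist`: frequencies must lie strictly inside (0, 1)")
    }
    function(n) runif(n, lo, hi)
  } else {
    abort("`maf_dist` must be a value, a c(min, max) range, or a function(n)")
  }
  with_seed(seed, {
    p <- draw(n_loci)
    if (any(p <= 0 | p >= 1)) {
      abort("degenerate `maf_dist`: frequencies must lie strictly inside (0, 1)")
    }
    calls <- matrix(rbinom(n_lines * n_loci, 1L, rep(p, each = n_lines)),
                    nrow = n_lines)
    for (j in seq_len(n_loci)) {
      tries <- 0L
      while (length(unique(calls[, j])) < 2L) {
        tries <- tries + 1L
        if (tries > 1000L) abort("could not draw a polymorphic locus; maf_dist too extreme for n_lines")
        calls[, j] <- rbinom(n_lines, 1L, p[j])
      }
    }
    sizes <- sample(100:400, n_loci, replace = TRUE)
    dimnames(calls) <- list(sprintf("L%04d", seq_len(n_lines)),
                            sprintf("SYN%04d-%d", seq_len(n_loci), sizes))
    coded <- matrix(ifelse(calls == 1L, 1, -1), nrow = n_lines,
                    dimnames = dimnames(calls))
    marker_panel(calls, coded = coded)
  })
}

# Expand interaction effect lists to a dense term x environment matrix,
# centered across all environments (identifiability of main vs interaction).
center_interaction <- function(tbl, id_cols, val_col, envs) {
  if (!nrow(tbl)) {
    return(list(table = tbl, matrix = matrix(0, 0, length(envs),
                                             dimnames = list(NULL, envs))))
  }
  tbl$.id <- do.call(paste, c(tbl[id_cols], sep = pair_sep))
  ids <- unique(tbl$.id)
  m <- matrix(0, length(ids), length(envs), dimnames = list(ids, envs))
  bad <- setdiff(tbl$env, envs)
  if (length(bad)) abort(sprintf("interaction effect references unknown environment(s): %s",
                                 paste(bad, collapse = ", ")))
  m[cbind(match(tbl$.id, ids), match(tbl$env, envs))] <- tbl[[val_col]]
  m <- m - rowMeans(m)
  long <- as_tibble(as.table(m), .name_repair = "minimal")
  names(long) <- c(".id", "env", val_col)
  keys <- unique(tbl[c(id_cols, ".id")])
  long <- left_join(as_tibble(long), keys, by = ".id")
  long <- long[c(id_cols, "env", val_col)]
  list(table = long, matrix = m, ids = keys)
}

#' Simulate phenotypes from a marker panel under a known architecture
#'
#' Forward-simulates trait values for every line in every environment and
#' replicate of the trial design under the mixed phenotype model (see
#' [effect_config()]), with i.i.d. Gaussian residuals. Alongside the
#' phenotype table it returns a truth record with the centered effects
#' actually applied and the realized variance contribution of each effect
#' category on the replicate-averaged (analysis) scale.
#'
#' @param panel Encoded [marker_panel].
#' @param design [trial_design].
#' @param cfg [effect_config].
#' @param trait Trait name to write into the phenotype records.
#' @param seed RNG seed for the residual draws.
#' @return A list `phenotypes` (long tibble) and `truth` (list: centered
#'   `effects`, realized `v_a`, `v_aa`, `v_ae`, `v_aae`, `v_e`, `v_p`,
#'   `h2` percentages, and `v_p_empirical`).
#' @export
simulate_phenotypes <- function(panel, design, cfg, trait = "trait1", seed = NULL) {
  stopifnot(inherits(panel, "marker_panel"), inherits(design, "trial_design"),
            inherits(cfg, "effect_config"))
  if (is.null(panel$coded)) abort("panel must be encoded before simulation")
  coded <- panel$coded
  envs <- design$environments$env
  check_loci <- unique(c(cfg$additive$locus, cfg$epistasis$locus_i,
                         cfg$epistasis$locus_j, cfg$add_by_env$locus,
                         cfg$epi_by_env$locus_i, cfg$epi_by_env$locus_j))
  missing_loci <- setdiff(check_loci, colnames(coded))
  if (length(missing_loci)) {
    abort(sprintf("effect config references unknown locus/loci: %s",
                  paste(missing_loci, collapse = ", ")))
  }

  n_lines <- nrow(coded)
  n_env <- length(envs)

  # per-line genetic contributions
  g_a <- if (nrow(cfg$additive)) {
    as.vector(coded[, cfg$additive$locus, drop = FALSE] %*% cfg$additive$a)
  } else rep(0, n_lines)
  prod_cols <- function(i, j) coded[, i] * coded[, j]
  g_aa <- rep(0, n_lines)
  if (nrow(cfg$epistasis)) {
    for (r in seq_len(nrow(cfg$epistasis))) {
      g_aa <- g_aa + prod_cols(cfg$epistasis$locus_i[r], cfg$epistasis$locus_j[r]) *
        cfg$epistasis$aa[r]
    }
  }

  ae <- center_interaction(cfg$add_by_env, "locus", "ae", envs)
  aae <- center_interaction(cfg$epi_by_env, c("locus_i", "locus_j"), "aae", envs)

  g_ae <- matrix(0, n_lines, n_env)   # lines x envs
  if (nrow(ae$matrix)) {
    loci <- ae$ids$locus[match(rownames(ae$matrix), ae$ids$.id)]
    g_ae <- coded[, loci, drop = FALSE] %*% ae$matrix
  }
  g_aae <- matrix(0, n_lines, n_env)
  if (nrow(aae$matrix)) {
    for (r in seq_len(nrow(aae$matrix))) {
      key <- rownames(aae$matrix)[r]
      ij <- aae$ids[match(key, aae$ids$.id), ]
      g_aae <- g_aae + outer(prod_cols(ij$locus_i, ij$locus_j), aae$matrix[r, ])
    }
  }

  e_h <- setNames(rep(0, n_env), envs)
  if (!is.null(cfg$env_means)) {
    bad <- setdiff(names(cfg$env_means), envs)
    if (length(bad)) abort(sprintf("env_means references unknown environment(s): %s",
                                   paste(bad, collapse = ", ")))
    e_h[names(cfg$env_means)] <- cfg$env_means
  }

  reps <- design$replicates
  grid <- tidyr::expand_grid(env = envs, line_id = panel$line_ids,
                             replicate = seq_len(reps))
  li <- match(grid$line_id, panel$line_ids)
  ei <- match(grid$env, envs)
  mean_part <- cfg$grand_mean + e_h[ei] + g_a[li] + g_aa[li] +
    g_ae[cbind(li, ei)] + g_aae[cbind(li, ei)]
  eps <- with_seed(seed, rnorm(nrow(grid), 0, sqrt(cfg$resid_var)))
  loc_year <- split_env_label(grid$env)
  phen <- tibble(line_id = grid$line_id, location = loc_year$location,
                 year = loc_year$year, replicate = grid$replicate,
                 trait = trait, value = as.numeric(mean_part + eps))

  # realized variances on the replicate-averaged analysis scale
  obs <- tidyr::expand_grid(env = envs, line_id = panel$line_ids)
  oli <- match(obs$line_id, panel$line_ids)
  oei <- match(obs$env, envs)
  popvar <- function(v) mean(v^2) - mean(v)^2
  eps_agg <- tapply(eps, list(factor(grid$env, envs), factor(grid$line_id, panel$line_ids)),
                    mean)
  eps_vec <- eps_agg[cbind(oei, oli)]
  v <- c(v_a = popvar(g_a[oli]), v_aa = popvar(g_aa[oli]),
         v_ae = popvar(g_ae[cbind(oli, oei)]), v_aae = popvar(g_aae[cbind(oli, oei)]),
         v_e = popvar(eps_vec))
  y_agg <- cfg$grand_mean + e_h[oei] + g_a[oli] + g_aa[oli] +
    g_ae[cbind(oli, oei)] + g_aae[cbind(oli, oei)] + eps_vec
  v_p <- sum(v)
  truth <- list(
    effects = list(additive = cfg$additive, epistasis = cfg$epistasis,
                   add_by_env = ae$table, epi_by_env = aae$table),
    env_means = e_h, grand_mean = cfg$grand_mean, resid_var = cfg$resid_var,
    v_a = unname(v["v_a"]), v_aa = unname(v["v_aa"]), v_ae = unname(v["v_ae"]),
    v_aae = unname(v["v_aae"]), v_e = unname(v["v_e"]), v_p = v_p,
    v_p_empirical = popvar(y_agg - e_h[oei]),
    h2 = setNames(100 * v[c("v_a", "v_aa", "v_ae", "v_aae")] / v_p,
                  c("h2_a", "h2_aa", "h2_ae", "h2_aae"))
  )
  list(phenotypes = phen, truth = truth)
}

#' Generate a complete fixture study
#'
#' Bundles panel, trial design, phenotypes and truth for one of three study
#' presets:
#' \describe{
#'   \item{`tiny`}{50 lines x 20 loci x 2 environments, one replicate;
#'     planted architecture with category heritabilities
#'     (additive, epistasis, add x env, epi x env) = (20, 20, 5, 20) percent
#'     and 35 percent residual.}
#'   \item{`null`}{200 lines x 50 loci x 4 environments (2 locations x
#'     2 years), no genetic effects, unit residual variance.}
#'   \item{`paper_shape`}{323 lines x 651 loci x 9 environments (3 locations
#'     x 3 years), 3 replicates; a moderate planted architecture.}
#' }
#'
#' @param preset One of `"tiny"`, `"null"`, `"paper_shape"`.
#' @param seed RNG seed; the same seed regenerates the identical study.
#' @return A list `panel`, `design`, `phenotypes`, `truth`.
#' @export
make_fixture_study <- function(preset = c("tiny", "null", "paper_shape"), seed = 1L) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    tiny = list(n_lines = 50L, n_loci = 20L, maf = 0.5,
                locations = c("LocA", "LocB"), years = "2007", reps = 1L),
    null = list(n_lines = 200L, n_loci = 50L, maf = c(0.2, 0.5),
                locations = c("LocA", "LocB"), years = c("2007", "2008"), reps = 1L),
    paper_shape = list(n_lines = 323L, n_loci = 651L, maf = c(0.1, 0.5),
                       locations = c("Anyang", "Kuche", "Nanjing"),
                       years = c("2007", "2008", "2009"), reps = 3L)
  )
  panel <- simulate_panel(spec$n_lines, spec$n_loci, maf_dist = spec$maf,
                          seed = derive_seed(seed, 1L))
  design <- trial_design(tidyr::expand_grid(location = spec$locations,
                                            year = spec$years),
                         replicates = spec$reps)
  envs <- design$environments$env
  loci <- panel$locus_ids
  cfg <- switch(preset,
    tiny = {
      # category variances 0.20 / 0.20 / 0.05 / 0.20, residual 0.35 (V_P ~ 1)
      effect_config(
        additive = tibble(locus = loci[c(1, 2)], a = rep(sqrt(0.1), 2)),
        epistasis = tibble(locus_i = loci[5], locus_j = loci[6], aa = sqrt(0.2)),
        add_by_env = tibble(locus = loci[9], env = envs,
                            ae = c(sqrt(0.05), -sqrt(0.05))),
        epi_by_env = tibble(locus_i = loci[13], locus_j = loci[14], env = envs,
                            aae = c(sqrt(0.2), -sqrt(0.2))),
        env_means = setNames(c(0.5, -0.5), envs),
        grand_mean = 10, resid_var = 0.35
      )
    },
    null = effect_config(env_means = setNames(seq(-0.3, 0.3, length.out = length(envs)), envs),
                         grand_mean = 10, resid_var = 1),
    paper_shape = {
      nanjing <- grep("^Nanjing", envs, value = TRUE)
      effect_config(
        additive = tibble(locus = loci[c(10, 20, 30)], a = c(0.25, 0.2, -0.2)),
        epistasis = tibble(locus_i = loci[c(40, 60)], locus_j = loci[c(50, 70)],
                           aa = c(0.25, -0.2)),
        add_by_env = tibble(locus = loci[600], env = nanjing, ae = 0.4),
        epi_by_env = tibble(locus_i = loci[100], locus_j = loci[200],
                            env = nanjing[c(1, 3)], aae = c(0.45, 0.45)),
        env_means = setNames(seq(-1, 1, length.out = length(envs)), envs),
        grand_mean = 25, resid_var = 1
      )
    }
  )
  sim <- simulate_phenotypes(panel, design, cfg, seed = derive_seed(seed, 2L))
  list(panel = panel, design = design, phenotypes = sim$phenotypes, truth = sim$truth)
}

#' Write the truth record of a simulated study as JSON
#'
#' @param truth Truth record from [simulate_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  truth$h2 <- as.list(truth$h2)          # keep category names in the JSON
  truth$env_means <- as.list(truth$env_means)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
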