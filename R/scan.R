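new_qts_scan <- function(records, threshold, alpha_ew, n_perm, seed, perm_max,
                         stage) {
  records <- arrange(records, dplyr::desc(.data$score), .data$term)
  structure(list(records = records, threshold = threshold, alpha_ew = alpha_ew,
                 n_perm = n_perm, seed = seed, perm_max = perm_max,
                 stage = stage),
            class = "qts_scan")
}

#' @export
print.qts_scan <- function(x, ...) {
  cat(sprintf("<qts_scan> stage %s: %d terms tested, %d pass the experiment-wise threshold %.3f (alpha = %.3g, %d permutations)\n",
              x$stage, nrow(x$records), sum(x$records$passes),
              x$threshold, x$alpha_ew, x$n_perm))
  invisible(x)
}

#' @describeIn scan_main Tidy the per-term scan records.
#' @param x A `qts_scan` object.
#' @param ... Unused.
#' @export
tidy.qts_scan <- function(x, ...) x$records

#' @describeIn scan_main One-row scan summary (threshold, counts, settings).
#' @export
glance.qts_scan <- function(x, ...) {
  tibble(stage = x$stage, n_tested = nrow(x$records),
         n_passing = sum(x$records$passes), threshold = x$threshold,
         alpha_ew = x$alpha_ew, n_perm = x$n_perm,
         seed = x$seed %||% NA_integer_)
}

# experiment-wise critical value: k-th order statistic of the B permutation
# maxima with k = ceiling((1 - alpha) * (B + 1)); under exchangeability the
# family-wise error of "observed max >= threshold" is (B + 1 - k)/(B + 1).
perm_threshold <- function(perm_max, alpha_ew) {
  B <- length(perm_max)
  k <- min(B, ceiling((1 - alpha_ew) * (B + 1)))
  sort(perm_max)[k]
}

# center a vector or matrix within environment blocks
center_within <- function(m, env_fac) {
  m <- as.matrix(m)
  for (lev in levels(env_fac)) {
    idx <- which(env_fac == lev)
    m[idx, ] <- sweep(m[idx, , drop = FALSE], 2, colMeans(m[idx, , drop = FALSE]))
  }
  m
}

# n x B matrix of within-environment permutations of the (centered) vector yc
perm_matrix <- function(yc, env_fac, n_perm) {
  Yp <- matrix(0, length(yc), n_perm)
  for (lev in levels(env_fac)) {
    idx <- which(env_fac == lev)
    nh <- length(idx)
    Yp[idx, ] <- vapply(seq_len(n_perm), function(b) yc[idx][sample.int(nh)],
                        numeric(nh))
  }
  Yp
}

# prepare the shared scan workspace: aggregated y, env factor, coded
# observation matrix, within-env centered copies
scan_workspace <- function(panel, design, phen, trait) {
  if (is.null(panel$coded)) abort("panel must be encoded (see encode_genotypes())")
  agg <- aggregate_replicates(phen, trait)
  envs <- design$environments$env
  unknown <- setdiff(agg$env, envs)
  if (length(unknown)) abort(sprintf("phenotype environment(s) absent from trial design: %s",
                                     paste(unknown, collapse = ", ")))
  li <- match(agg$line_id, panel$line_ids)
  if (anyNA(li)) abort("phenotyped line(s) absent from panel")
  env_fac <- factor(agg$env, levels = envs)
  Xobs <- panel$coded[li, , drop = FALSE]
  poly <- colvar(Xobs) > 0
  if (any(!poly)) {
    warn(sprintf("skipping %d locus/loci with constant coded values: %s",
                 sum(!poly), paste(head(colnames(Xobs)[!poly], 5), collapse = ", ")))
  }
  list(y = agg$value, env_fac = env_fac, Xobs = Xobs, poly = poly,
       li = li, envs = envs, n = nrow(agg))
}

# block F statistics for every locus: the (a, ae-over-environments) block of
# locus i added to the environment-only baseline. Because the a column plus
# its environment-masked copies span the per-environment masked columns, the
# block sum of squares decomposes per environment after within-environment
# centering. Returns -log10 p scores for the observed y and each column of Yp.
main_block_scores <- function(Xc, yc, Yp, env_fac, d_by_env) {
  m <- ncol(Xc)
  H <- nlevels(env_fac)
  n <- length(yc)
  B <- if (is.null(Yp)) 0L else ncol(Yp)
  SSR <- numeric(m)
  SSRp <- if (B) matrix(0, m, B) else NULL
  for (h in seq_len(H)) {
    idx <- which(env_fac == levels(env_fac)[h])
    d <- d_by_env[h, ]
    ok <- d > 0
    cy <- drop(crossprod(Xc[idx, , drop = FALSE], yc[idx]))
    SSR[ok] <- SSR[ok] + cy[ok]^2 / d[ok]
    if (B) {
      cp <- crossprod(Xc[idx, , drop = FALSE], Yp[idx, , drop = FALSE])
      SSRp[ok, ] <- SSRp[ok, ] + cp[ok, , drop = FALSE]^2 / d[ok]
    }
  }
  df1 <- colSums(d_by_env > 0)
  df2 <- n - H - df1
  SST <- sum(yc^2)
  score_of <- function(ssr) {
    Fstat <- (ssr / df1) / pmax(SST - ssr, .Machine$double.eps) * df2
    -pf(Fstat, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  perm_scores <- NULL
  if (B) {
    # SST is permutation-invariant: permuting within environments preserves
    # the within-environment centered sum of squares
    perm_scores <- matrix(0, m, B)
    Fp <- (SSRp / df1) / pmax(SST - SSRp, .Machine$double.eps) * df2
    perm_scores <- -pf(Fp, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  list(score = score_of(SSR), df1 = df1, df2 = df2, perm_scores = perm_scores)
}

#' Scan individual loci for additive and environment-interaction effects
#'
#' For every polymorphic locus, tests the joint (additive,
#' additive-by-environment) block against the environment-only baseline with
#' an F test, reported as a -log10 p score. The experiment-wise critical
#' score is the (1 - `alpha_ew`) quantile of the per-permutation maximum
#' score under permutation of trait values within environment (which
#' preserves environment means under the null). With a single environment
#' the block reduces to the additive term alone.
#'
#' @param panel Encoded [marker_panel].
#' @param design [trial_design].
#' @param phen Phenotype tibble.
#' @param trait Trait name.
#' @param alpha_ew Experiment-wise type-I error level.
#' @param n_perm Number of within-environment permutations.
#' @param seed RNG seed for the permutations.
#' @return A `qts_scan` with per-locus records (`term`, `kind = "A"`,
#'   `score`, `passes`), the permutation threshold and settings.
#' @export
scan_main <- function(panel, design, phen, trait, alpha_ew = 0.05,
                      n_perm = 1000, seed = NULL) {
  ws <- scan_workspace(panel, design, phen, trait)
  keep <- which(ws$poly)
  if (!length(keep)) abort("no polymorphic loci to scan")
  Xc <- center_within(ws$Xobs[, keep, drop = FALSE], ws$env_fac)
  yc <- drop(center_within(ws$y, ws$env_fac))
  d_by_env <- t(vapply(levels(ws$env_fac), function(lev) {
    colSums(Xc[ws$env_fac == lev, , drop = FALSE]^2)
  }, numeric(length(keep))))
  d_by_env <- matrix(d_by_env, nrow = nlevels(ws$env_fac))
  Yp <- with_seed(seed, perm_matrix(yc, ws$env_fac, n_perm))
  res <- main_block_scores(Xc, yc, Yp, ws$env_fac, d_by_env)
  perm_max <- apply(res$perm_scores, 2, max)
  threshold <- perm_threshold(perm_max, alpha_ew)
  records <- tibble(term = colnames(Xc), kind = "A", score = res$score,
                    passes = res$score >= threshold)
  new_qts_scan(records, threshold, alpha_ew, n_perm, seed, perm_max, "main")
}

#' Enumerate canonical locus pairs
#'
#' @param locus_ids Character vector of locus ids.
#' @return Tibble of all `m(m-1)/2` canonical pairs (`locus_i`, `locus_j`,
#'   `pair`).
#' @export
enumerate_pairs <- function(locus_ids) {
  locus_ids <- unique(locus_ids)
  m <- length(locus_ids)
  if (m < 2L) return(tibble(locus_i = character(), locus_j = character(),
                            pair = character()))
  idx <- combn(m, 2L)
  canonical_pair(locus_ids[idx[1, ]], locus_ids[idx[2, ]])
}

#' Scan locus pairs for epistasis and environment-interaction effects
#'
#' For each candidate pair, tests the (epistasis,
#' epistasis-by-environment) block conditional on both loci's main-effect
#' blocks, with the same within-environment permutation-max threshold
#' machinery as [scan_main()]. Under `pair_policy = "filtered"` the
#' candidates are pairs with at least one member whose stage-1 score passes
#' a relaxed experiment-wise threshold (level `relax_alpha`); `"all"` tests
#' every canonical pair.
#'
#' @inheritParams scan_main
#' @param stage1 The stage-1 `qts_scan` (required for `"filtered"`).
#' @param pair_policy `"filtered"` or `"all"`.
#' @param relax_alpha Relaxed experiment-wise level used to pick stage-1
#'   members under the filtered policy.
#' @return A `qts_scan` with per-pair records (`kind = "AA"`).
#' @export
scan_pairs <- function(panel, design, phen, trait, stage1 = NULL,
                       pair_policy = c("filtered", "all"), alpha_ew = 0.05,
                       n_perm = 1000, relax_alpha = 0.2, seed = NULL) {
  pair_policy <- match.arg(pair_policy)
  ws <- scan_workspace(panel, design, phen, trait)
  keep <- colnames(ws$Xobs)[ws$poly]
  cand <- if (pair_policy == "all") {
    enumerate_pairs(keep)
  } else {
    if (is.null(stage1)) abort("`stage1` scan is required for pair_policy = 'filtered'")
    thr_relax <- perm_threshold(stage1$perm_max, relax_alpha)
    members <- stage1$records$term[stage1$records$score >= thr_relax]
    members <- intersect(members, keep)
    if (!length(members)) {
      return(new_qts_scan(tibble(term = character(), kind = character(),
                                 score = numeric(), passes = logical()),
                          Inf, alpha_ew, n_perm, seed, numeric(), "pairs"))
    }
    enumerate_pairs(keep) %>%
      filter(.data$locus_i %in% members | .data$locus_j %in% members)
  }
  if (!nrow(cand)) {
    return(new_qts_scan(tibble(term = character(), kind = character(),
                               score = numeric(), passes = logical()),
                        Inf, alpha_ew, n_perm, seed, numeric(), "pairs"))
  }

  env_fac <- ws$env_fac
  H <- nlevels(env_fac)
  n <- ws$n
  Xc <- center_within(ws$Xobs[, keep, drop = FALSE], env_fac)
  yc <- drop(center_within(ws$y, env_fac))
  SST <- sum(yc^2)
  Yp <- with_seed(seed, perm_matrix(yc, env_fac, n_perm))
  env_rows <- lapply(levels(env_fac), function(lev) which(env_fac == lev))

  score_pair <- function(i, j) {
    p_obs <- ws$Xobs[, i] * ws$Xobs[, j]
    if (colvar(matrix(p_obs)) == 0) return(NULL)
    pc <- drop(center_within(p_obs, env_fac))
    ssr_main <- 0; ssr_main_p <- numeric(ncol(Yp))
    num <- 0; num_p <- numeric(ncol(Yp))
    df1 <- 0L; df_main <- 0L
    for (idx in env_rows) {
      Z <- cbind(Xc[idx, i], Xc[idx, j])
      qz <- qr(Z)
      df_main <- df_main + qz$rank
      fit_y <- qr.fitted(qz, yc[idx])
      ssr_main <- ssr_main + sum(fit_y^2)
      fit_p <- qr.fitted(qz, Yp[idx, , drop = FALSE])
      ssr_main_p <- ssr_main_p + colSums(fit_p^2)
      rp <- pc[idx] - qr.fitted(qz, pc[idx])
      ss <- sum(rp^2)
      if (ss > 1e-10 * length(idx)) {
        df1 <- df1 + 1L
        num <- num + sum(rp * yc[idx])^2 / ss
        num_p <- num_p + drop(crossprod(rp, Yp[idx, , drop = FALSE]))^2 / ss
      }
    }
    if (df1 == 0L) return(NULL)
    ssr_add <- num; ssr_add_p <- num_p
    df2 <- n - H - df_main - df1
    if (df2 < 1L) abort("too few observations for the pair-scan F test")
    Fobs <- (ssr_add / df1) / pmax(SST - ssr_main - ssr_add, .Machine$double.eps) * df2
    Fp <- (ssr_add_p / df1) / pmax(SST - ssr_main_p - ssr_add_p, .Machine$double.eps) * df2
    list(score = -pf(Fobs, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10),
         perm = -pf(Fp, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10))
  }

  scores <- rep(NA_real_, nrow(cand))
  perm_scores <- matrix(-Inf, nrow(cand), n_perm)
  skipped <- character()
  for (r in seq_len(nrow(cand))) {
    sp <- score_pair(cand$locus_i[r], cand$locus_j[r])
    if (is.null(sp)) { skipped <- c(skipped, cand$pair[r]); next }
    scores[r] <- sp$score
    perm_scores[r, ] <- sp$perm
  }
  if (length(skipped)) {
    warn(sprintf("skipping %d pair(s) with constant interaction column: %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  ok <- !is.na(scores)
  perm_max <- apply(perm_scores[ok, , drop = FALSE], 2, max)
  threshold <- perm_threshold(perm_max, alpha_ew)
  records <- tibble(term = cand$pair[ok], kind = "AA", score = scores[ok],
                    passes = scores[ok] >= threshold)
  new_qts_scan(records, threshold, alpha_ew, n_perm, seed, perm_max, "pairs")
}

#' Select the final model term set from the scans
#'
#' Keeps every locus and pair passing its experiment-wise threshold,
#' truncated to the `max_terms` highest-scoring ones (ties broken
#' lexicographically by term id), and attaches their environment-interaction
#' companions over all declared environments (when there is more than one).
#'
#' @param scan1 Stage-1 `qts_scan` (loci).
#' @param scan2 Optional stage-2 `qts_scan` (pairs).
#' @param design [trial_design] supplying the environment list.
#' @param max_terms Cap on the number of selected A/AA terms.
#' @return A [model_terms] object (environment-only when nothing passes).
#' @export
select_terms <- function(scan1, scan2 = NULL, design, max_terms = Inf) {
  recs <- scan1$records
  if (!is.null(scan2)) recs <- bind_rows(recs, scan2$records)
  recs <- recs %>% filter(.data$passes) %>%
    arrange(dplyr::desc(.data$score), .data$term)
  if (nrow(recs) > max_terms) recs <- recs[seq_len(max_terms), ]
  envs <- design$environments$env
  add <- recs$term[recs$kind == "A"]
  pairs <- if (any(recs$kind == "AA")) split_pair_label(recs$term[recs$kind == "AA"]) else NULL
  ae <- aae <- NULL
  if (length(envs) > 1L) {
    if (length(add)) ae <- tidyr::expand_grid(locus = add, env = envs)
    if (!is.null(pairs) && nrow(pairs)) {
      aae <- tidyr::expand_grid(dplyr::bind_cols(pairs), env = envs)
    }
  }
  model_terms(additive = add, epistasis = pairs, add_by_env = ae,
              epi_by_env = aae)
}
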