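# shared fixtures and independent oracles

# model terms matching the planted architecture of a fixture study's truth
truth_terms <- function(truth) {
  tr <- truth$effects
  model_terms(
    additive = tr$additive$locus,
    epistasis = tr$epistasis,
    add_by_env = if (nrow(tr$add_by_env)) tr$add_by_env[c("locus", "env")],
    epi_by_env = if (nrow(tr$epi_by_env)) tr$epi_by_env[c("locus_i", "locus_j", "env")]
  )
}

# Henderson mixed-model equations solved by explicit inversion: the
# independent oracle for BLUP predictions at fixed variance components.
mme_solve <- function(y, X, Ulist, sigma2) {
  Z <- do.call(cbind, Ulist)
  lambda <- unlist(lapply(names(Ulist), function(g) {
    # a component estimated at the zero boundary means (numerically) no
    # shrinkage target: a huge ridge drives its BLUPs to zero
    lam <- if (sigma2[[g]] > 0) sigma2[["resid"]] / sigma2[[g]] else 1e12
    rep(lam, ncol(Ulist[[g]]))
  }))
  p <- ncol(X); q <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, q)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C) %*% rhs
  list(b = sol[seq_len(p)], u = sol[p + seq_len(q)])
}

# brute-force -log10 p for the (a, ae) block of one locus via lm/anova
oracle_locus_score <- function(panel, phen, trait, locus) {
  keep <- phen$trait == trait
  env <- paste(phen$location[keep], phen$year[keep], sep = ":")
  agg <- stats::aggregate(value ~ line_id + env,
                          data = data.frame(line_id = phen$line_id[keep],
                                            env = env, value = phen$value[keep]),
                          FUN = mean)
  d <- data.frame(value = agg$value, env = factor(agg$env),
                  x = panel$coded[match(agg$line_id, panel$line_ids), locus])
  f0 <- stats::lm(value ~ env, data = d)
  f1 <- stats::lm(value ~ env + env:x, data = d)
  a <- stats::anova(f0, f1)
  -log10(a[["Pr(>F)"]][2])
}

small_genotype_file <- function(path, lines, loci, cells) {
  header <- paste(c("line_id", loci), collapse = "\t")
  rows <- vapply(seq_along(lines), function(i) {
    paste(c(lines[i], cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}
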