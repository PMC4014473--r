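test_that("in the noiseless limit the planted additive effect is recovered exactly", {
  panel <- simulate_panel(40, 6, maf_dist = 0.5, seed = 201)
  design <- trial_design(tibble::tibble(location = c("A", "B"), year = "2007"))
  cfg <- effect_config(additive = tibble::tibble(locus = panel$locus_ids[1], a = 0.7),
                       grand_mean = 3, resid_var = 0)
  sim <- simulate_phenotypes(panel, design, cfg, seed = 202)
  terms <- model_terms(additive = panel$locus_ids[1])
  asm <- build_design(panel, design, sim$phenotypes, terms, "trait1")
  fit <- fit_mixed_model(asm)
  expect_equal(fit$effects$effect, 0.7, tolerance = 1e-6)
  expect_equal(fit$fixed$estimate[fit$fixed$parameter == "mu"], 3, tolerance = 1e-6)
  expect_lt(fit$vc[["V_e"]], 1e-6)
})

test_that("BLUPs equal the direct mixed-model-equation solution on a 12-observation instance", {
  panel <- simulate_panel(6, 4, maf_dist = 0.5, seed = 203)
  design <- trial_design(tibble::tibble(location = c("A", "B"), year = "2007"))
  loci <- panel$locus_ids
  cfg <- effect_config(additive = tibble::tibble(locus = loci[1:2], a = c(0.8, -0.6)),
                       epistasis = tibble::tibble(locus_i = loci[3], locus_j = loci[4],
                                                  aa = 0.5),
                       grand_mean = 1, resid_var = 0.2)
  sim <- simulate_phenotypes(panel, design, cfg, seed = 204)
  terms <- truth_terms(sim$truth)
  asm <- build_design(panel, design, sim$phenotypes, terms, "trait1")
  expect_length(asm$y, 12L)
  fit <- fit_mixed_model(asm)

  sigma2 <- as.list(fit$sigma2)
  oracle <- mme_solve(asm$y, asm$X, asm$U, sigma2)
  expect_equal(fit$effects$effect, unname(oracle$u), tolerance = 1e-6)
  expect_equal(unname(fit$fixed$estimate[1:ncol(asm$X)])[1], oracle$b[1],
               tolerance = 1e-6)

  # MINQUE(1) BLUPs must satisfy the same identity at its own components
  fitm <- fit_mixed_model(asm, method = "minque1")
  or2 <- mme_solve(asm$y, asm$X, asm$U, as.list(fitm$sigma2))
  expect_equal(fitm$effects$effect, unname(or2$u), tolerance = 1e-6)
})

test_that("null data drive the genetic components to zero and V_e to the residual variance", {
  st <- make_fixture_study("null", seed = 205)
  loci <- st$panel$locus_ids
  terms <- model_terms(
    additive = loci[1:3],
    epistasis = tibble::tibble(locus_i = loci[5], locus_j = loci[8]),
    add_by_env = tidyr::expand_grid(locus = loci[1:3], env = st$design$environments$env),
    epi_by_env = tidyr::expand_grid(locus_i = loci[5], locus_j = loci[8],
                                    env = st$design$environments$env))
  asm <- build_design(st$panel, st$design, st$phenotypes, terms, "trait1")
  fit <- fit_mixed_model(asm)
  genetic <- fit$vc[c("V_A", "V_AA", "V_AE", "V_AAE")]
  expect_true(all(genetic < 0.05 * fit$vc[["V_P"]]))
  expect_equal(fit$vc[["V_e"]], 1, tolerance = 0.1)
  # variance partition conservation is exact
  expect_equal(fit$vc[["V_P"]],
               sum(fit$vc[c("V_A", "V_AA", "V_AE", "V_AAE", "V_e")]))
})

test_that("BLUP predictions are shrunk relative to least squares", {
  panel <- simulate_panel(50, 4, maf_dist = 0.5, seed = 206)
  design <- trial_design(tibble::tibble(location = "A", year = "2007"))
  cfg <- effect_config(additive = tibble::tibble(locus = panel$locus_ids[1], a = 0.5),
                       grand_mean = 0, resid_var = 0.5)
  sim <- simulate_phenotypes(panel, design, cfg, seed = 207)
  terms <- model_terms(additive = panel$locus_ids[1])
  asm <- build_design(panel, design, sim$phenotypes, terms, "trait1")
  fit <- fit_mixed_model(asm)
  ols <- stats::lsfit(cbind(asm$X[, -1, drop = FALSE], asm$U$A), asm$y)$coefficients
  expect_lte(abs(fit$effects$effect), abs(ols[length(ols)]))
})

test_that("REML matches the one-way ANOVA method of moments on balanced data", {
  g <- 8; r <- 5; n <- g * r
  set.seed(208)
  grp <- factor(rep(seq_len(g), each = r))
  u <- rnorm(g, 0, sqrt(2))
  y <- 10 + u[grp] + rnorm(n, 0, 1)
  Z <- stats::model.matrix(~ grp - 1)
  col_info <- tibble::tibble(group = "A", term = colnames(Z), env = NA_character_,
                             column = colnames(Z), variance = apply(Z, 2, stats::var))
  asm <- structure(list(y = y, X = matrix(1, n, 1, dimnames = list(NULL, "mu")),
                        U = list(A = Z), obs_index = NULL, col_info = col_info,
                        envs = "E:1", terms = NULL, trait = "t"),
                   class = "assembled_design")
  fit <- fit_mixed_model(asm, tol = 1e-10)
  msb <- stats::anova(stats::lm(y ~ grp))["grp", "Mean Sq"]
  msw <- stats::anova(stats::lm(y ~ grp))["Residuals", "Mean Sq"]
  expect_equal(unname(fit$sigma2["A"]), (msb - msw) / r, tolerance = 1e-4)
  expect_equal(unname(fit$sigma2["resid"]), msw, tolerance = 1e-4)
})

test_that("reduced models drop the right groups and lose heritability when epistasis is real", {
  panel <- simulate_panel(150, 20, maf_dist = 0.5, seed = 209)
  design <- trial_design(tibble::tibble(location = c("A", "B"), year = "2007"))
  envs <- design$environments$env
  loci <- panel$locus_ids
  cfg <- effect_config(
    additive = tibble::tibble(locus = loci[1], a = 0.3),
    epistasis = tibble::tibble(locus_i = loci[3], locus_j = loci[5], aa = 0.7),
    epi_by_env = tibble::tibble(locus_i = loci[7], locus_j = loci[9], env = envs,
                                aae = c(0.6, -0.6)),
    grand_mean = 10, resid_var = 0.5)
  sim <- simulate_phenotypes(panel, design, cfg, seed = 210)
  terms <- truth_terms(sim$truth)
  terms$add_by_env <- tidyr::expand_grid(locus = terms$additive, env = envs)
  asm <- build_design(panel, design, sim$phenotypes, terms, "trait1")

  full <- fit_mixed_model(asm)
  add_only <- refit_reduced(asm, "additive_only")
  add_ae <- refit_reduced(asm, "additive_plus_ae")

  expect_setequal(unique(add_only$effects$group), "A")
  expect_setequal(unique(add_ae$effects$group), c("A", "AE"))

  h2_T <- function(f) 100 * (f$vc[["V_P"]] - f$vc[["V_e"]]) / f$vc[["V_P"]]
  expect_lt(h2_T(add_only), h2_T(full))
  # the additive effect survives model reduction; epistasis variance is lost
  expect_lt(abs(add_ae$effects$effect[add_ae$effects$group == "A"] - 0.3), 0.25)
  expect_equal(add_ae$vc[["V_AA"]], 0)

  # with no interaction terms selected, full refit equals the additive fit
  terms2 <- model_terms(additive = loci[1])
  asm2 <- build_design(panel, design, sim$phenotypes, terms2, "trait1")
  f_full <- refit_reduced(asm2, "full")
  f_add <- refit_reduced(asm2, "additive_only")
  expect_equal(f_full$sigma2, f_add$sigma2)
  expect_equal(f_full$effects$effect, f_add$effects$effect)
})

test_that("an environment-only design errors with more fixed columns than observations", {
  asm <- structure(list(y = c(1, 2), X = diag(3)[1:2, ],
                        U = list(), col_info = NULL, envs = "a", trait = "t"),
                   class = "assembled_design")
  expect_error(fit_mixed_model(asm), "observations")
})
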