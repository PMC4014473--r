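fake_fit <- function(vc, effects = NULL, col_info = NULL) {
  empty <- tibble::tibble(group = character(), term = character(),
                          env = character(), column = character(),
                          effect = numeric(), std_error = numeric(),
                          neg_log10_p = numeric())
  structure(list(vc = c(vc, V_P = sum(vc)), effects = effects %||% empty,
                 col_info = col_info %||% tibble::tibble(
                   group = character(), term = character(), env = character(),
                   column = character(), variance = numeric()),
                 trait = "t"),
            class = "qts_fit")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("category heritabilities are variance shares on the percent scale", {
  # equal components split the phenotypic variance five ways: 20% each
  f <- fake_fit(c(V_A = 1, V_AA = 1, V_AE = 1, V_AAE = 1, V_e = 1))
  p <- partition_heritability(f)
  expect_equal(unname(p$categories[c("h2_A", "h2_AA", "h2_AE", "h2_AAE")]),
               rep(20, 4))
  expect_equal(unname(p$categories["h2_T"]), 80)
  expect_equal(unname(p$categories["h2_G"]), 40)
  expect_equal(unname(p$categories["h2_GE"]), 40)

  # no genetic variance -> all zero
  p0 <- partition_heritability(fake_fit(c(V_A = 0, V_AA = 0, V_AE = 0,
                                          V_AAE = 0, V_e = 2)))
  expect_equal(unname(p0$categories["h2_T"]), 0)

  expect_error(partition_heritability(fake_fit(c(V_A = 0, V_AA = 0, V_AE = 0,
                                                 V_AAE = 0, V_e = 0))), "V_P")
})

test_that("per-term heritabilities sum to their category value on a fitted study", {
  st <- make_fixture_study("tiny", seed = 301)
  terms <- truth_terms(st$truth)
  asm <- build_design(st$panel, st$design, st$phenotypes, terms, "trait1")
  fit <- fit_mixed_model(asm)
  p <- partition_heritability(fit)
  sums <- tapply(p$per_term$h2_pct, p$per_term$group, sum)
  for (g in names(sums)) {
    expect_equal(unname(sums[g]), unname(p$categories[paste0("h2_", g)]),
                 tolerance = 1e-10)
  }
  # Eq-style additivity of the reported (rounded) partition
  r <- round(p$categories, 2)
  expect_lt(abs(r[["h2_T"]] - (r[["h2_A"]] + r[["h2_AA"]] + r[["h2_AE"]] +
                                 r[["h2_AAE"]])), 0.011 * 4)
})

test_that("the per-term share of a lone planted locus matches its variance share", {
  # a single-coefficient variance component is noisy in any one realization,
  # so compare the mean over replicates with the mean planted share
  design <- trial_design(tibble::tibble(location = "A", year = "2007"))
  res <- vapply(1:30, function(i) {
    panel <- simulate_panel(400, 5, maf_dist = 0.5, seed = 302 + i)
    cfg <- effect_config(additive = tibble::tibble(locus = panel$locus_ids[1],
                                                   a = 0.5),
                         grand_mean = 0, resid_var = 0.75)
    sim <- simulate_phenotypes(panel, design, cfg, seed = 1302 + i)
    asm <- build_design(panel, design, sim$phenotypes,
                        model_terms(additive = panel$locus_ids[1]), "trait1")
    p <- partition_heritability(fit_mixed_model(asm))
    c(est = p$per_term$h2_pct[1], planted = 100 * sim$truth$v_a / sim$truth$v_p)
  }, numeric(2))
  expect_lt(abs(mean(res["est", ]) - mean(res["planted", ])), 2)
})

test_that("heritability aggregation sums and rounds to report precision", {
  expect_equal(aggregate_heritability(c(0, 0, 0, 0), "total"), 0)
  expect_equal(aggregate_heritability(c(10.5, 20.25, 5, 1.125), "total"), 36.88)
  expect_equal(aggregate_heritability(c(4.5, 1.25), "gxe"), 5.75)
  expect_equal(aggregate_heritability(c(1.11, 2.22, 3.33), "terms"), 6.66)
  expect_error(aggregate_heritability(c(-1, 2), "gxe"), "non-negative")
  expect_error(aggregate_heritability(c(1, 2, 3), "total"), "expects 4")
})

test_that("locus classification partitions terms into the three stability classes", {
  effects <- tibble::tibble(
    group = c("A",
              "AAE", "AAE",
              "AE",
              "AE"),
    term = c("CONST-1",
             "P1-1×P2-1", "P1-1×P2-1",
             "SENS-1",
             "WEAK-1"),
    env = c(NA, "Kuche:2007", "Kuche:2008", "Nanjing:2007", "Anyang:2007"),
    column = c("CONST-1", "P1-1×P2-1@Kuche:2007", "P1-1×P2-1@Kuche:2008",
               "SENS-1@Nanjing:2007", "WEAK-1@Anyang:2007"),
    effect = c(0.3, -0.08, -0.07, 0.2, 0.01),
    std_error = 0.01,
    neg_log10_p = c(40, 12, 8.8, 9, 0.5))
  design <- trial_design(tidyr::expand_grid(location = c("Anyang", "Kuche", "Nanjing"),
                                            year = c("2007", "2008")))
  cls <- classify_locus(effects, design, score_min = 3)
  got <- setNames(cls$class, cls$term)
  # a significant main effect -> constitutive
  expect_equal(unname(got["CONST-1"]), "constitutive")
  # interaction effects at one location in two years -> environment-specific
  expect_equal(unname(got["P1-1×P2-1"]), "environment_specific")
  # a single environment-year -> environment-sensitive
  expect_equal(unname(got["SENS-1"]), "environment_sensitive")
  # nothing significant -> environment-sensitive
  expect_equal(unname(got["WEAK-1"]), "environment_sensitive")
  # the classification is a partition: one class per reported term
  expect_equal(sort(unique(effects$term)), sort(cls$term))
  expect_equal(anyDuplicated(cls$term), 0L)
})

test_that("the elite screen applies score and heritability thresholds per kind", {
  part <- structure(list(categories = c(h2_A = 10, h2_AA = 10, h2_AE = 5,
                                        h2_AAE = 5, h2_T = 30, h2_G = 20, h2_GE = 10),
                         per_term = tibble::tibble(
                           group = c("A", "A", "AA", "AAE"),
                           term = c("L1-1", "L2-1", "L3-1×L4-1", "L5-1×L6-1"),
                           h2_pct = c(2.0, 0.9, 0.6, 0.4))),
                    class = "qts_herit")
  effects <- tibble::tibble(
    group = c("A", "A", "AA", "AAE"),
    term = c("L1-1", "L2-1", "L3-1×L4-1", "L5-1×L6-1"),
    env = c(NA, NA, NA, "A:2007"),
    column = c("L1-1", "L2-1", "L3-1×L4-1", "L5-1×L6-1@A:2007"),
    effect = c(0.5, 0.4, 0.3, 0.2), std_error = 0.01,
    neg_log10_p = c(12, 9, 8.5, 7.9))

  kept <- elite_screen(effects, part)
  # L1: A with score>=8, h2>=1 -> kept; L2: h2 0.9 < 1 -> out
  # L3 pair: score 8.5, h2 0.6 >= 0.5 -> kept; L5 pair: score 7.9 < 8 -> out
  expect_setequal(kept$term, c("L1-1", "L3-1×L4-1"))

  # boundary: scores and heritabilities at exactly the threshold qualify
  effects$neg_log10_p[4] <- 8.0
  part$per_term$h2_pct[4] <- 0.5
  kept2 <- elite_screen(effects, part)
  expect_true("L5-1×L6-1" %in% kept2$term)

  # brute-force set equality on a random synthetic table
  set.seed(304)
  n <- 60
  rand <- tibble::tibble(
    group = sample(c("A", "AE", "AA", "AAE"), n, replace = TRUE),
    term = sprintf("T%02d-1", seq_len(n)), env = NA_character_,
    column = sprintf("T%02d-1", seq_len(n)),
    effect = rnorm(n), std_error = 0.1,
    neg_log10_p = runif(n, 0, 16))
  randp <- structure(list(per_term = tibble::tibble(
    group = rand$group, term = rand$term, h2_pct = runif(n, 0, 2)),
    categories = c(h2_A = 1, h2_AA = 1, h2_AE = 1, h2_AAE = 1)),
    class = "qts_herit")
  kept3 <- elite_screen(rand, randp, score_min = 8,
                        h2_min_individual = 1, h2_min_epistasis = 0.5)
  brute <- merge(rand, randp$per_term)
  brute <- brute[brute$neg_log10_p >= 8 &
                   brute$h2_pct >= ifelse(brute$group %in% c("A", "AE"), 1, 0.5), ]
  expect_setequal(kept3$term, brute$term)

  expect_equal(nrow(elite_screen(effects[0, ], part)), 0L)
})

test_that("shared-locus summaries count trait associations per locus", {
  eff <- function(a = character(), pairs = character()) {
    tibble::tibble(group = c(rep("A", length(a)), rep("AA", length(pairs))),
                   term = c(a, pairs))
  }
  # disjoint loci -> every count is 1
  res <- shared_locus_summary(list(t1 = eff(a = "L1-1"), t2 = eff(a = "L2-1")))
  expect_true(all(res$n_traits == 1))

  # one locus planted in all four traits (also via pair membership)
  res4 <- shared_locus_summary(list(
    ly = eff(a = "HUB-1"), bn = eff(a = c("HUB-1", "X1-1")),
    bw = eff(pairs = "HUB-1×Z1-1"), lp = eff(a = "HUB-1")))
  expect_equal(res4$n_traits[res4$locus == "HUB-1"], 4L)
  k <- attr(res4, "k_counts")
  expect_equal(k$n_loci[k$n_traits == 4], 1L)
  # deterministic lexicographic order
  expect_equal(res4$locus, sort(res4$locus))

  expect_error(shared_locus_summary(list(t1 = eff())), "two traits")
})

test_that("network export classes nodes and edges like the reporting legend", {
  one <- tibble::tibble(group = "A", term = "L1-1", env = NA_character_,
                        column = "L1-1", effect = 1, std_error = 0.1,
                        neg_log10_p = 10)
  net1 <- export_network(one)
  expect_equal(net1$nodes, tibble::tibble(locus = "L1-1", class = "additive"))
  expect_equal(nrow(net1$edges), 0L)

  # an epistatic pair with no individual effects: two epistasis-only nodes
  pair <- tibble::tibble(group = "AA", term = "L2-1×L3-1", env = NA_character_,
                         column = "L2-1×L3-1", effect = 0.5, std_error = 0.1,
                         neg_log10_p = 9)
  net2 <- export_network(pair)
  expect_equal(net2$nodes$class, c("epistasis_only", "epistasis_only"))
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$class, "aa")

  # edge count equals the number of distinct selected pairs
  eff <- dplyr::bind_rows(
    one, pair,
    tibble::tibble(group = "AAE", term = "L2-1×L3-1", env = "A:2007",
                   column = "L2-1×L3-1@A:2007", effect = 0.2, std_error = 0.1,
                   neg_log10_p = 8.5),
    tibble::tibble(group = "AAE", term = "L4-1×L5-1", env = "A:2007",
                   column = "L4-1×L5-1@A:2007", effect = 0.2, std_error = 0.1,
                   neg_log10_p = 8.5),
    tibble::tibble(group = "AE", term = "L1-1", env = "A:2007",
                   column = "L1-1@A:2007", effect = 0.2, std_error = 0.1,
                   neg_log10_p = 8.5))
  net3 <- export_network(eff)
  distinct_pairs <- length(unique(eff$term[eff$group %in% c("AA", "AAE")]))
  expect_equal(length(unique(paste(net3$edges$locus_i, net3$edges$locus_j))),
               distinct_pairs)
  # L1 has both additive and environment-interaction effects
  expect_equal(net3$nodes$class[net3$nodes$locus == "L1-1"], "both")

  tmp <- withr::local_tempdir()
  export_network(eff, path = file.path(tmp, "net"))
  expect_true(file.exists(file.path(tmp, "net_nodes.tsv")))
  expect_true(file.exists(file.path(tmp, "net_edges.tsv")))
})
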