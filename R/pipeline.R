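#' Build a run configuration
#'
#' Collects every pipeline setting in one validated object. `x` may be a
#' named list or the path of a YAML file with the same keys.
#'
#' @param x Named list or YAML path. Recognised keys: `genotypes`,
#'   `phenotypes`, `outdir`, `traits` (default: all traits found),
#'   `alpha_ew`, `n_perm`, `pair_policy`, `relax_alpha`, `method`,
#'   `maf_min`, `missing_max`, `max_terms`, `elite` (list `score_min`,
#'   `h2_min_individual`, `h2_min_epistasis`), `preset` (for
#'   [run_simulate()]), `seed` (required; no wall-clock seeding).
#' @return A `qts_config` list.
#' @export
qts_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  cfg <- list(
    genotypes = x$genotypes %||% NULL,
    phenotypes = x$phenotypes %||% NULL,
    outdir = x$outdir %||% ".",
    traits = x$traits %||% NULL,
    alpha_ew = x$alpha_ew %||% 0.05,
    n_perm = x$n_perm %||% 1000L,
    pair_policy = x$pair_policy %||% "filtered",
    relax_alpha = x$relax_alpha %||% 0.2,
    method = x$method %||% "reml",
    maf_min = x$maf_min %||% 0.05,
    missing_max = x$missing_max %||% 0.2,
    max_terms = x$max_terms %||% Inf,
    elite = list(
      score_min = x$elite$score_min %||% 8,
      h2_min_individual = x$elite$h2_min_individual %||% 1,
      h2_min_epistasis = x$elite$h2_min_epistasis %||% 0.5
    ),
    preset = x$preset %||% "tiny",
    seed = x$seed
  )
  if (is.null(cfg$seed)) abort("`seed` is required in the run configuration")
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("alpha_ew", "n_perm", "relax_alpha", "maf_min", "missing_max")) {
    assert_scalar_number(cfg[[f]], f, min = 0)
  }
  for (f in names(cfg$elite)) assert_scalar_number(cfg$elite[[f]], f, min = 0)
  cfg$pair_policy <- match.arg(cfg$pair_policy, c("filtered", "all"))
  cfg$method <- match.arg(cfg$method, c("reml", "minque1"))
  structure(cfg, class = "qts_config")
}

write_sidecar <- function(cfg, path, extra = list()) {
  settings <- unclass(cfg)
  settings[c("genotypes", "phenotypes", "outdir")] <- NULL  # hash settings, not paths
  side <- c(list(seed = cfg$seed,
                 config_hash = rlang::hash(settings),
                 package = "qtsmap",
                 version = as.character(utils::packageVersion("qtsmap"))),
            extra)
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a study to files
#'
#' Generates the preset fixture study named in the configuration and writes
#' `genotypes.tsv`, `phenotypes.tsv`, `truth.json` and a provenance sidecar
#' into `outdir`. The same seed reproduces identical files.
#'
#' @param cfg A [qts_config()].
#' @return Invisibly, the named vector of file paths written.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "qts_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  study <- make_fixture_study(cfg$preset, seed = cfg$seed)
  paths <- c(genotypes = file.path(cfg$outdir, "genotypes.tsv"),
             phenotypes = file.path(cfg$outdir, "phenotypes.tsv"),
             truth = file.path(cfg$outdir, "truth.json"),
             sidecar = file.path(cfg$outdir, "simulate_sidecar.json"))
  write_genotypes(study$panel, paths["genotypes"])
  write_phenotypes(study$phenotypes, paths["phenotypes"])
  write_truth(study$truth, paths["truth"])
  write_sidecar(cfg, paths["sidecar"], list(stage = "simulate", preset = cfg$preset))
  invisible(paths)
}

#' Run the association-mapping pipeline
#'
#' Per trait: encodes the genotypes, runs the single-locus and pair scans
#' with permutation thresholds, selects the passing terms, fits the final
#' mixed model, partitions heritability, classifies loci, screens elite
#' terms and exports the network. All artifacts are written under
#' `outdir/<trait>/`.
#'
#' @param cfg A [qts_config()] with `genotypes` and `phenotypes` paths set.
#' @return Invisibly, a named list (per trait) with the scan, fit,
#'   partition, classes and elite objects.
#' @export
run_map <- function(cfg) {
  stopifnot(inherits(cfg, "qts_config"))
  if (is.null(cfg$genotypes) || is.null(cfg$phenotypes)) {
    abort("`genotypes` and `phenotypes` paths are required for run_map()")
  }
  panel <- read_genotypes(cfg$genotypes) %>%
    encode_genotypes(maf_min = cfg$maf_min, missing_max = cfg$missing_max)
  pio <- read_phenotypes(cfg$phenotypes)
  phen <- pio$phenotypes
  design <- pio$design
  traits <- cfg$traits %||% sort(unique(phen$trait))

  results <- list()
  for (ti in seq_along(traits)) {
    trait <- traits[ti]
    message(sprintf("[qtsmap] mapping trait '%s'", trait))
    tdir <- file.path(cfg$outdir, trait)
    dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
    s1 <- scan_main(panel, design, phen, trait, alpha_ew = cfg$alpha_ew,
                    n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 10L + ti))
    s2 <- scan_pairs(panel, design, phen, trait, stage1 = s1,
                     pair_policy = cfg$pair_policy, alpha_ew = cfg$alpha_ew,
                     n_perm = cfg$n_perm, relax_alpha = cfg$relax_alpha,
                     seed = derive_seed(cfg$seed, 20L + ti))
    terms <- select_terms(s1, s2, design, max_terms = cfg$max_terms)
    asm <- build_design(panel, design, phen, terms, trait)
    fit <- fit_mixed_model(asm, method = cfg$method)
    part <- partition_heritability(fit)
    score_min <- min(c(s1$threshold, if (is.finite(s2$threshold)) s2$threshold))
    classes <- classify_locus(fit$effects, design, score_min = score_min)
    elite <- elite_screen(fit$effects, part, score_min = cfg$elite$score_min,
                          h2_min_individual = cfg$elite$h2_min_individual,
                          h2_min_epistasis = cfg$elite$h2_min_epistasis)
    net <- export_network(elite, path = file.path(tdir, "network"))

    readr::write_tsv(tidy(s1), file.path(tdir, "scan_loci.tsv"), progress = FALSE)
    readr::write_tsv(tidy(s2), file.path(tdir, "scan_pairs.tsv"), progress = FALSE)
    eff_out <- fit$effects %>%
      left_join(part$per_term, by = c("group", "term")) %>%
      mutate(effect_type = ifelse(is.na(.data$env),
                                  ifelse(.data$group == "A", "a", "aa"),
                                  paste0(tolower(.data$group), "@", .data$env))) %>%
      select(locus = "term", "effect_type", predict = "effect",
             "std_error", "neg_log10_p", "h2_pct")
    readr::write_tsv(eff_out, file.path(tdir, "effects.tsv"), progress = FALSE)
    jsonlite::write_json(as.list(fit$vc), file.path(tdir, "components.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    herit <- list(categories = as.list(round(part$categories, 2)),
                  per_term = part$per_term)
    jsonlite::write_json(herit, file.path(tdir, "heritability.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_tsv(classes, file.path(tdir, "classes.tsv"), progress = FALSE)
    readr::write_tsv(elite, file.path(tdir, "elite.tsv"), progress = FALSE)
    write_sidecar(cfg, file.path(tdir, "map_sidecar.json"),
                  list(stage = "map", trait = trait,
                       threshold_loci = s1$threshold,
                       threshold_pairs = if (is.finite(s2$threshold)) s2$threshold else NA,
                       n_selected_terms = n_terms(terms)))
    results[[trait]] <- list(scan_loci = s1, scan_pairs = s2, terms = terms,
                             fit = fit, partition = part, classes = classes,
                             elite = elite, network = net)
  }
  invisible(results)
}

#' Regenerate aggregate report tables from stored artifacts
#'
#' Reads the per-trait artifacts written by [run_map()] (without refitting)
#' and writes `heritability_summary.tsv` (one row per trait with the four
#' category percentages and the total) plus a combined `effects_report.tsv`.
#'
#' @param cfg A [qts_config()] whose `outdir` holds [run_map()] artifacts.
#' @return Invisibly, the heritability summary tibble.
#' @export
run_report <- function(cfg) {
  stopifnot(inherits(cfg, "qts_config"))
  traits <- cfg$traits %||% {
    dirs <- list.dirs(cfg$outdir, recursive = FALSE, full.names = FALSE)
    sort(dirs[file.exists(file.path(cfg$outdir, dirs, "heritability.json"))])
  }
  if (!length(traits)) abort("no map artifacts found under `outdir`")
  summ <- purrr::map_dfr(traits, function(trait) {
    hfile <- file.path(cfg$outdir, trait, "heritability.json")
    if (!file.exists(hfile)) abort(sprintf("missing artifact: %s", hfile))
    h <- jsonlite::read_json(hfile, simplifyVector = TRUE)
    tibble(trait = trait, h2_A = h$categories$h2_A, h2_AA = h$categories$h2_AA,
           h2_AE = h$categories$h2_AE, h2_AAE = h$categories$h2_AAE,
           h2_T = h$categories$h2_T)
  })
  effects <- purrr::map_dfr(traits, function(trait) {
    efile <- file.path(cfg$outdir, trait, "effects.tsv")
    if (!file.exists(efile)) abort(sprintf("missing artifact: %s", efile))
    eff <- readr::read_tsv(efile, col_types = readr::cols(), progress = FALSE)
    dplyr::bind_cols(tibble(trait = trait), eff)
  })
  readr::write_tsv(summ, file.path(cfg$outdir, "heritability_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(effects, file.path(cfg$outdir, "effects_report.tsv"),
                   progress = FALSE)
  invisible(summ)
}
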