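---
title: "Methods: mixed-model association mapping with epistasis and environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model association mapping with epistasis and environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtsmap)
```

## The model

`qtsmap` maps quantitative trait loci in inbred panels genotyped at
biallelic presence/absence markers (each SSR allele is treated as its own
locus) and phenotyped in multi-environment trials, where an environment is
one location × year combination. The phenotype of line $k$ in environment
$h$ is

$$
y_{hk} = \mu + e_h + \sum_i x_{ik} a_i + \sum_{i<j} x_{ik}x_{jk}\,aa_{ij}
 + \sum_i x_{ik}\,ae_{ih} + \sum_{i<j} x_{ik}x_{jk}\,aae_{ijh} + \varepsilon_{hk},
$$

with locus codes $x \in \{+1,-1\}$ for the two homozygous genotypes
($QQ$/$qq$; the panel is inbred, so there is no heterozygote and no
dominance term). Environments are fixed effects; the four genetic groups —
additive ($a$), additive×additive epistasis ($aa$), additive×environment
($ae$) and epistasis×environment ($aae$) — are random, each group with a
single variance component. In matrix form
$y = Xb + \sum_v U_v e_v + \varepsilon$, where $X$ carries the intercept
and the environment factor and each $U_v$ is the coefficient matrix of a
random group: additive columns are the codes, epistasis columns the
elementwise products of two code columns, and interaction columns the
corresponding main column masked to the rows of one environment and zero
elsewhere. The phenotypic variance is partitioned as
$V_P = V_A + V_{AA} + V_{AE} + V_{AAE} + V_e$ and heritability on the
percent scale as $h^2_T = h^2_A + h^2_{AA} + h^2_{AE} + h^2_{AAE}$.

Model assumptions worth stating explicitly: loci enter as fixed known
codes (missing calls are mean-imputed); residuals are i.i.d. Gaussian;
there is no correction for population structure or kinship — the model
this package implements does not include one, and the simulator therefore
does not generate structured panels by default. On structured real panels
the scan's error control is nominal only with respect to the permutation
null, which preserves within-environment exchangeability but not family
relatedness.

### Coding and contrast choices

The $\pm 1$ coding makes every epistasis coefficient the plain product of
the two locus codes and gives effect signs the usual
"major-allele genotype" reading. The environment factor uses sum-to-zero
contrasts so the intercept estimates the population mean $\mu$ rather than
a reference environment's mean. Replicates within a line × environment
cell are averaged before modelling — the model describes
genotype-in-environment values, and whether the original field replicates
should instead enter as residual-level observations is not decidable from
the reported material; averaging is the default and the residual component
is then the variance of a replicate mean.

### Identifiability of interaction effects

In the simulator, every $ae$ and $aae$ effect vector is centered across
all declared environments at generation time (environments not listed for
a term contribute zero before centering). Without this constraint a
locus's main effect and the mean of its environment interactions are
confounded; centering is the standard G×E decomposition and makes the
planted $a$ versus $ae$ split well defined, which the recovery tests rely
on.

## The two-stage scan

The final model's terms must be selected before fitting; the package uses
a deliberately simple, auditable two-stage screen rather than attempting
to reproduce any particular software's unpublished search heuristics.

**Stage 1 (loci).** For each polymorphic locus, an F test of the joint
$(a, ae_1, \dots, ae_H)$ block against the environment-only baseline.
Because the additive column plus its masked copies span the per-environment
masked columns, the block decomposes per environment after
within-environment centering, which is what makes the scan (and its
permutation replicates) a handful of matrix products.

**Stage 2 (pairs).** For each candidate pair, an F test of the
$(aa, aae_1, \dots, aae_H)$ block conditional on both loci's main-effect
blocks. Under the default `filtered` policy, candidates are pairs with at
least one member passing a relaxed stage-1 threshold (experiment-wise
level 0.2); `all` tests every canonical pair and is the right choice when
pairs with no individually detectable members matter — such pairs are a
prominent feature of real epistatic architectures, and the filtered policy
will structurally miss them. Degenerate candidates (constant product
columns) are skipped with a warning.

**Error control.** Experiment-wise significance uses the permutation-max
method: trait values are permuted within environment (preserving
environment means under the null), the maximum score over all tested terms
is recorded per permutation, and the critical value is the
$\lceil (1-\alpha)(B+1) \rceil$-th order statistic of the $B$ maxima. A
term passes when its observed score is at least the critical value; under
exchangeability the family-wise error of this rule is
$(B + 1 - k)/(B + 1) \approx \alpha$, which the acceptance suite verifies
empirically (500 null studies of 200 lines × 50 loci × 4 environments,
$B = 200$, measured rate 0.056 at $\alpha = 0.05$). Defaults:
`alpha_ew = 0.05`, `n_perm = 1000`.

Selected loci and pairs enter the final model together with their
interaction companions in **all** environments (the fit decides which are
nonzero); selection is truncated to `max_terms` by score with
lexicographic tie-breaks so reruns are deterministic.

## Variance components, BLUP and significance

`fit_mixed_model()` estimates one variance component per group plus the
residual. The default method is REML by average information: after three
expectation–maximisation warm-up steps, Newton steps on the AI matrix with
step-halving against the REML log-likelihood, falling back to the
(guaranteed-ascent) EM update when the AI step fails. Convergence is
declared when the largest component change falls below `tol` (relative to
the phenotypic variance, default 1e-6); components that converge onto the
lower boundary are truncated to exactly zero and the model is refit
without them, keeping the variance partition interpretable. MINQUE(1) —
the one-shot quadratic unbiased estimator with all prior values 1 — is
provided as `method = "minque1"`; the estimation method behind the
published analyses of this model family is not documented, so both
standard choices are available and agree closely on the simulated studies.

Random effects are predicted as BLUPs at the estimated components,
$\hat e_v = \hat\sigma^2_v U_v' P y$, with standard errors from the
predictor's own covariance $\hat\sigma^4_v U_v' P U_v$ and two-sided
Wald tests converted to $-\log_{10} P$. A jackknife over lines would be a
more robust significance option and is a known omission. A dedicated test
confirms the BLUPs equal the explicit solution of Henderson's mixed-model
equations on a small instance to machine precision, and that shrinkage
never inflates an estimate past its least-squares counterpart.

Phenotypic variance contributions convert per-coefficient components to
the observation scale: $V_v = \hat\sigma^2_v \sum_c s^2_c$, summing the
empirical variances $s^2_c$ of the group's coefficient columns. This makes
$V_P$ the exact sum of the five components by construction and, because
the simulator's realized category variances are computed from the same
empirical columns, puts truth and estimate on the same scale.

## Heritability accounting and reporting

Category heritability is $100\,V_v / V_P$. Per-term heritability allocates
the category percentage across member terms proportionally to
$\hat u_t^2 s^2_t$ (squared predicted effect × empirical column variance,
summed over a term's environment columns). A plain
$100\,\hat u_t^2 s^2_t / V_P$ would not sum to the category value —
BLUP shrinkage makes $\sum_t \hat u_t^2 < q_v \hat\sigma^2_v$ — so the
normalised allocation is used; it preserves the ranking and relative
magnitudes and guarantees the additivity that the per-term tables assume.
Reported percentages are rounded to 2 decimals, matching the usual print
precision of such tables; `aggregate_heritability()` reproduces the
published aggregation identities (category totals, G×E and stable-genetic
sums, per-term selection-gain projections) exactly from printed
components.

Locus classification uses a single significance currency — the
experiment-wise scan threshold applied to the Wald scores: *constitutive*
terms have a significant main ($a$/$aa$) effect; *environment-specific*
terms have only interaction effects, all at one location and significant
there in at least two years; everything else (including terms with nothing
significant) is *environment-sensitive*. The elite screen keeps individual
terms with score ≥ 8 and per-term $h^2 \ge 1\%$ and pair terms with
score ≥ 8 and $h^2 \ge 0.5\%$ (all thresholds configurable; the boundary
is inclusive). The network export classes nodes as additive-only,
interaction-only, both, or epistasis-only (loci appearing only as pair
members) and edges as `aa` or `aae`.

## The synthetic-data generator

`make_fixture_study()` bundles three presets, chosen once as the package's
study conditions:

* **`tiny`** — 50 lines × 20 loci × 2 environments, one replicate,
  presence frequency fixed at 0.5; planted architecture: 2 additive loci,
  1 epistasis pair, 1 locus × environment term, 1 pair × environment term,
  with magnitudes set to category heritabilities (20, 20, 5, 20)% over a
  35% residual. This is the workhorse for recovery tests: large enough for
  stable fits, small enough for hundreds of replicates.
* **`null`** — 200 lines × 50 loci × 4 environments, no genetic effects,
  unit residual; the calibration fixture.
* **`paper_shape`** — 323 lines × 651 loci × 9 environments (3 locations ×
  3 years) with 3 replicates, a panel of the published study's dimensions
  carrying a moderate planted architecture (total genetic heritability
  around 50%), for shape/scale testing of the full pipeline.

The generator simulates unlinked loci with independent Bernoulli calls —
real SSR panels have linkage disequilibrium, population structure and
correlated environments, none of which are emulated. Passing tests
therefore demonstrate the machinery's correctness under its own model, not
robustness to structured real data. Residuals are Gaussian i.i.d. (their
real distribution is unreported in this model family's literature);
monomorphic draws are rejected and redrawn so every simulated locus is
polymorphic.

## Numerical choices and degenerate inputs

* Genotype encoding drops monomorphic loci always, and loci failing
  `maf_min` (default 0.05) or `missing_max` (default 0.2); dropping every
  locus is a hard error. Imputation is the locus mean of coded values.
* Constant coded columns in the scan are skipped with a warning, not an
  error; a completely constant panel is an error.
* The scan's F statistics guard zero denominators with machine epsilon;
  per-locus degrees of freedom count only environments where the masked
  column varies.
* Variance components are bounded below at $10^{-10}\,\mathrm{var}(y)$
  during iteration; the truncate-and-refit boundary is ten times that.
* Ties in term selection break lexicographically by term id; pair ids are
  canonical (lexicographically smaller locus first), so all outputs are
  permutation-invariant and byte-reproducible under a fixed seed.
* The pipeline refuses wall-clock seeding: `seed` is a required config
  field and every artifact directory carries a sidecar with the seed and a
  hash of the scientific settings (paths excluded, so reruns in different
  directories compare equal).

## Problem sizes used by the test and acceptance suites

Calibration uses 500 null studies with 200 permutations each; recovery
uses 100 tiny-fixture replicates; the BLUP oracle uses a 12-observation
instance; the reduced-model comparison uses 200 lines × 2 environments.
These sizes give the stochastic checks comfortable margins (binomial
bands, replicate-mean tolerances) while keeping a full run around a
minute.

## Known limitations

* No population-structure or kinship correction, and no simulator support
  for generating it.
* No interactions beyond two loci.
* Wald-type significance only (no jackknife/resampling of predictions).
* The filtered pair policy misses pairs with two individually invisible
  members; use `pair_policy = "all"` where that matters and the panel size
  allows.
* Per-effect magnitudes from different software implementing this model
  family are not expected to match term-for-term: predictor scaling
  conventions (plain BLUP versus adjusted predictors) differ and are
  rarely documented; this package's conventions are stated above.
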