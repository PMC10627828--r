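---
title: "Methods: from amplicon counts to co-abundance modules and covariate associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from amplicon counts to co-abundance modules and covariate associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagmod)
```

vagmod implements the analysis chain used for large vaginal 16S
cohorts: quality control, (sub)genus profiling, compositional
correlation networks with module discovery, eigentaxon scores and a
five-level covariate-adjusted association framework. This vignette
explains the models and the choices behind them; nothing here asserts
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## Quality control

The QC statistic is the *normalized read concentration* (NRC): a
sample's library size divided by the volume (µl) of that sample pooled
into its sequencing run, then divided by the median of this read
concentration over all samples of the same run. Negative controls are
included in the run median, since the definition names no exclusions;
the report records this choice
(`attr(report, "run_median_includes_controls")`). Samples are retained
when NRC > 0.05 **and** library size > 2,000 reads — both strict
inequalities, read literally from "higher than" and "greater than".
Taxon QC removes non-bacterial ASVs and ASVs longer than 260 bases
(strict). The 10 % prevalence filter ("present in at least 10 % of all
samples") is deliberately a separate operation
(`filter_prevalence`): it applies only where the statistics need it
(network inference, per-taxon testing) and is recomputed on the
post-sample-QC table, so sample QC and taxon prevalence do not
interact silently. QC is idempotent apart from that recomputation.

## Profiling choices

* **Logarithms.** Natural log everywhere (CLR, Shannon); no base is
  canonical in the field and the choice only rescales.
* **CLR zeros.** Default pseudocount 0.5 added to counts before
  closure — the common amplicon convention (half the detection limit).
  The strategy is a plain argument and recorded as an attribute of the
  output, so correlation-sensitive analyses can vary it.
* **Dominance.** A sample is dominated by its most abundant (sub)genus
  when that taxon reaches **at least** 30 % ("at least" in the source
  definition, so `>=`); two taxa at ≥ 30 % each mark dual dominance.
  Exact ties are broken lexicographically and flagged — with continuous
  abundances they are essentially impossible, so the rule only matters
  for constructed data.
* **CST assignment.** Nearest centroid under the Yue–Clayton
  θ = Σxy / (Σx² + Σy² − Σxy), the similarity used by the external
  VALENCIA classifier; cosine similarity is available as an
  alternative. Centroid and table vocabularies are matched by name and
  unmatched taxa are dropped and reported — the mapping, not the
  classifier, is where real-data effort lives. Reference centroids are
  user-supplied; tests use synthetic centroids.
* **Embeddings.** PCoA is deterministic; t-SNE (via Rtsne, exact
  gradient, no PCA preprocessing) requires a seed, with perplexity 30
  by default, lowered automatically for small cohorts.

## SparCC

Correlations between relative abundances are distorted by closure;
SparCC estimates correlations between the *latent absolute* abundances
instead. Per Dirichlet draw (fractions ~ Dirichlet(counts + 1) per
sample) the algorithm forms the log-ratio variation matrix
$t_{ij} = \mathrm{Var}_s\,\log(x_{is}/x_{js})$, solves
$(\mathrm{diag}(d) + A)\,\omega = (T \circ A)\mathbf{1}$ for the basis
variances (the linear system implied by
$t_{ij}=\omega_i+\omega_j-2\rho_{ij}\sqrt{\omega_i\omega_j}$ under the
sparsity approximation $\sum_j \rho_{ij}\approx 0$), recovers
$\rho_{ij}$, clamps to $[-1,1]$, and iteratively removes the
strongest-correlated pair above the exclusion threshold from the
system before re-solving. The reported matrix is the element-wise
median over draws. Defaults follow the original algorithm: threshold
0.1, 10 exclusion iterations, 20 Dirichlet draws; all recorded in the
result's `params`.

Numerical safeguards, needed for small taxon sets: no taxon may drop
below three included pairs during exclusion (keeping the system
nonsingular), a degenerate solve aborts the exclusion loop and keeps
the last solution, and a non-positive basis variance — a symptom of
the sparsity approximation failing for that taxon — falls back to the
taxon's observed log-fraction variance rather than an arbitrary floor
(which would clamp whole rows of correlations to ±1).

With `n_dirichlet_draws = 0` the observed count fractions are used in
a single closed-form solve. This mode is exactly invariant to
per-sample count rescaling and equals the dense-algebra oracle used in
the tests; with resampling, invariance is only approximate because the
Dirichlet posterior concentrates with absolute depth — that is a
property of the estimator, not an implementation artifact.

Permutation significance shuffles every taxon's counts independently
across samples (destroying all between-taxon association, keeping
marginals), recomputes ρ, and uses the add-one estimator
$p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(1 + n_{perm})$, so
p = 0 is impossible. 1,000 permutations is the cohort-scale default.

## MCL and modules

Markov clustering runs on an adjacency derived from the network. The
source analyses do not state how the correlation matrix became a
graph; the default rule here keeps $|\rho|$ for pairs with permutation
p < 0.05 and zeroes the rest. The magnitude (not the signed value) is
used because negative between-module correlations appear in this kind
of data and should not act as attraction; alternatives
(`positive`, `abs_threshold`) are one argument away. MCL itself is the
standard algorithm — self-loops, column normalisation, alternating
expansion (power 2) and inflation (power 2) to convergence at 1e-6 or
100 iterations — and clusters are the connected components of the
converged matrix's non-zero pattern, which is exact for idempotent
limits. Modules are clusters with ≥ 3 members, named after the member
with the highest mean relative abundance.

## Eigentaxa

The eigentaxon of a module is the first principal component of the
module taxa's CLR columns, computed on per-taxon *centred, unscaled*
values (the definition speaks of the component of the taxa, with no
mention of scaling; correlation-PCA is available via `scale_pca`).
The score is multiplied by the sign of its correlation with the CLR
abundance of the module's most abundant taxon, so higher always means
"more of the module"; an exactly zero anchor correlation gets sign +1
and a flag. Scores are z-standardised by default because the
downstream linear models use standardised responses. Constant-CLR taxa
are dropped from the PCA with a warning; a module reduced below two
usable taxa is an error. All samples that passed QC enter the PCA.

## The association framework

Every level fits the same model,
`response ~ effect + age + antibiotic + intercourse + technical`,
with categorical covariates dummy-coded against their most frequent
level and listwise deletion per test (`n_used` is reported).

* **Beta diversity.** Marginal (type-III-like) PERMANOVA:
  $SS_{\mathrm{eff}} = \mathrm{tr}(H_{\mathrm{full}} G) -
  \mathrm{tr}(H_{\mathrm{red}} G)$ on the Gower-centred distance
  matrix; $R^2 = SS_{\mathrm{eff}}/\mathrm{tr}(G)$. Significance
  permutes *only the effect's values* across samples, holding
  adjusters fixed — the computational shortcut that makes hundreds of
  questionnaire factors tractable. Freedman–Lane-style residual
  permutation would be the conservative alternative; the simple scheme
  is used because it is what the restricted-permutation description
  implies, and its type-I calibration is verified by simulation in the
  acceptance suite. The adaptive schedule runs 1,000 permutations and
  escalates to 10,000 (fresh draws from a derived seed) when
  p ≤ 0.001. The observed statistic is cross-checked against
  `vegan::adonis2(by = "margin")` in the tests.
* **Alpha diversity and eigentaxa.** OLS on the z-standardised
  response; the effect is the standardised coefficient with 95 % CI.
* **CSTs.** One-versus-all logistic regression for CSTs with ≥ 120
  samples (smaller ones are skipped and logged); perfect separation is
  flagged rather than reported as a huge log-odds.
* **Consensus differential abundance.** Three built-in
  covariate-adjusted methods — OLS on CLR abundances, an ALDEx2-style
  Dirichlet–Monte-Carlo CLR OLS (128 instances by default; p averaged,
  effect median over instances), and OLS on within-taxon ranks — stand
  in for the six external pipelines of cohort practice; the consensus
  rule (≥ 3 methods at BH q < 0.05) and the correction families are
  implemented exactly, and external tools plug in as adapter
  functions. Parity with the external tools is not claimed.
  Distributional assumptions of the methods are not formally tested.
* **BH families.** `bh_adjust` corrects within a family — all
  modules/CSTs × factors in one family, all taxa × factors in another,
  never across methods — via `p.adjust`, verified against the
  brute-force step-up definition on random vectors.
* **Cumulative variance.** `variance_explained` reports sequential
  (order-dependent) sums of squares of one joint fit; collinear
  factors are dropped with a warning.

## The synthetic cohort generator

`simulate_cohort` realises the data-generating process the analysis
assumes: per-sample log abundance = per-taxon baseline + archetype
dominance boost + Σ module loading × latent factor + planted covariate
effects + run × taxon batch effect + Gaussian taxon noise; library
sizes are log-normal; counts are multinomial on the softmax — the
log-normal-to-composition model matching SparCC's assumptions. The
dominance boost is solved from the softmax so the planted dominant
taxon's expected share equals the archetype's target fraction.
Negative controls draw their depths as a small fraction of the depth
model. Cycle phase is derived by labelling the final 14 days of the
reported cycle luteal (standard physiology), days beyond the reported
length indeterminate — the upstream description does not state its
rule, and hormone-level prediction is replaced by categorical
contraceptive-class metadata since no formula is given. One root seed
fans out to per-stage streams, so every stage replays bit-identically.

Default scales: median depth 10⁴ reads (log-sd 0.3), run batch sd 0.3,
latent factor sd 1, residual taxon noise sd 0.5. The noise scale is
the one free parameter the recovery conditions constrain: with unit
loadings and unit latent variance, a four-taxon module's PC1 carries
residual variance σ²/4, so taxon noise sd 0.5 leaves the
eigentaxon–latent correlation ≈ 0.97 — a realistic residual dispersion
for genus-level log abundances that keeps planted structure
recoverable, which is what the generator exists to provide.

What the generator does **not** emulate: the real cohort's marginal
taxon frequencies, zero inflation beyond what the multinomial induces,
taxonomic misclassification, chimeras, or sequence-level error. Tests
passing on synthetic data therefore demonstrate algorithmic
correctness and statistical calibration under the assumed model, not
robustness to real-data pathologies.

## Problem sizes and determinism

The test and acceptance suites run at desk scale, chosen to make each
check statistically meaningful: planted-module recovery uses 600
samples × 46 taxa at depth 2×10⁴ with 200 network permutations;
null calibration uses 200 PERMANOVA replicates (199 permutations each)
and 50 differential-abundance seeds (16 Monte-Carlo instances);
SparCC's null behaviour uses 500 samples × 20 taxa. Every permutation
test reports the permutations actually used, and every seeded stage is
bit-reproducible.

## Known limitations

* The MCL edge rule and the SparCC parameterisation are assumptions
  where the cohort methods are silent; both are configurable and
  recorded in output metadata.
* Consensus DA's built-in trio is internally correlated (all three are
  linear models on transformed abundances); agreement among them is
  weaker evidence than agreement among six independent external tools.
* The association framework is cross-sectional: no mixed-effects or
  longitudinal structure.
* `count_ratio_pct` rounds half away from zero to one decimal, the
  convention of printed cohort tables; a source table rounding
  differently can disagree by one unit in the last digit.
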