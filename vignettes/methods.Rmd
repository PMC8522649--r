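---
title: "Morphometric similarity networks and imaging transcriptomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks and imaging transcriptomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`mstx` implements a case-control imaging-transcriptomics pipeline for
morphometric similarity (MS) networks. The chain is:

1. **Harmonization.** Per-subject regional MRI features (7 per region:
   FA, MD, gray-matter volume, surface area, cortical thickness,
   intrinsic/Gaussian curvature, mean curvature) are adjusted for
   site/scanner batch effects by parametric empirical-Bayes location/scale
   harmonization (`harmonize_features()`).
2. **MS estimation.** Features are z-scored within subject across regions
   (`zscore_features()`); the MS matrix is the Pearson correlation, over the
   7 features, between every pair of regions (`ms_matrix()`); regional MS is
   the off-diagonal row mean — the weighted degree of each cortical node
   under signed, weighted edges (`regional_ms()`).
3. **Case-control statistics.** Per region, OLS of regional MS on the group
   indicator with age, sex and education as covariates; Benjamini-Hochberg
   FDR across regions (`ms_tmap()`, `fdr_bh()`). Partial correlations link
   mean MS over the significant region sets to a memory composite
   (`mean_ms_subset()`, `partial_correlation()`).
4. **Transcription-imaging association.** First-component PLS of the
   left-hemisphere T map on a regions x genes expression matrix. With a
   univariate response the PLS1 weight vector has the closed form
   `w = X'y / ||X'y||` after column standardization; gene Z scores are the
   ratio of `w` to its bootstrap standard error over region resamples, and
   the signed gene sets are `|Z|` beyond a Bonferroni-derived threshold
   (`pls1_fit()`, `pls_bootstrap_z()`, `threshold_gene_sets()`).
5. **Enrichment.** The signed gene sets are screened against: moderated-t
   differential expression (`moderated_de()`), cell-type-specific genes from
   a permutation-calibrated specificity index (`psi_compute()`), and
   arbitrary gene-set collections (`ora_collection()`), all through one
   hypergeometric/Fisher overlap primitive (`fisher_overlap()`).

Every stage is driven by `run_pipeline()` and exercisable end-to-end on
synthetic data with planted ground truth.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `covariates` | age, sex, education | nuisance terms of the regional model and partial correlations |
| `fdr_thresh` | 0.05 | BH threshold defining the decreased/increased region sets |
| `B` | 1000 | bootstrap resamples of regions for gene Z scores |
| `z_crit` | derived | smallest two-decimal z with two-sided normal tail ≤ α/n genes; 4.72 at 20,737 genes |
| `p_thresh`, `fc_thresh` | 0.01, 1 | DE screen: unadjusted p and \|log2 FC\| cut-offs |
| `psi_thresh` | 0.05 | specificity-index threshold for cell-type gene lists |
| `B_perm` | 1000 | permutation draws for the specificity-index null |
| `fisher_alternative` | greater | overlap-test sidedness; both sides are always reported |

# Design choices where the design was open

**Z-scoring axis.** Features are standardized within subject, across
regions. This makes MS a within-individual similarity (two regions are
similar because their multimodal profiles co-vary inside that brain) and
removes per-feature units. A pooled axis (`zscore_axis = "pooled"`) is kept
as a sensitivity switch; it preserves between-subject level differences and
changes the question being asked, so it is not the default.

**Weighted degree over 307 neighbours.** The self-correlation is
identically 1 and carries no information; the regional summary averages the
off-diagonal row only. Signed edges are kept — no absolute value, no
thresholding — so anticorrelated regions lower a node's degree.

**Harmonize before z-scoring.** Batch effects act on raw feature scales;
within-subject standardization would partially mask location shifts while
leaving scale effects to contaminate correlations. The shipped order is
harmonize → z-score → correlate, and an integration test asserts the order
matters.

**Covariate preservation in harmonization.** The batch model retains group,
age, sex and education, so harmonization cannot absorb the case-control
signal; `combat_preserve_group = FALSE` switches this off for sensitivity
analyses. Empirical-Bayes hyperpriors are estimated within each feature
rather than pooled across all features: features differ in units and batch
susceptibility, and pooling would shrink a feature-specific batch shift
toward an irrelevant grand mean (a planted +2 shift on one feature is then
only partially removed; the within-feature prior removes it essentially
completely).

**Group coding.** Case = 1, control = 0: negative T means lower MS in
cases, so signs match the convention of reporting decreased-similarity
regions with negative statistics.

**Pooled-variance t for demographics.** The printed group-comparison
statistics of the motivating design are reproduced by the pooled (not
Welch) formula, so `group_compare()` uses pooled variance; the chi-squared
test is Pearson's without continuity correction.

**Gene-column standardization in PLS.** Compiled expression matrices mix
per-gene scales; unit-variance columns make the weight vector scale-free.
The unscaled variant remains available (`scale_genes = FALSE`).

**Bootstrap sign alignment.** Each resampled weight vector is flipped to
positive inner product with the point estimate before the per-gene standard
deviation is taken; without this, sign switching inflates the standard
errors and deflates every Z score.

**Overlap-test sidedness.** The one-sided hypergeometric upper tail is the
default (over-representation is a directional question), but the printed
corrected p-value of the motivating analysis is only reproduced by the
two-sided Fisher test, so both are computed and reported on every overlap
(`p_greater`, `p_two_sided`).

**Specificity-index null.** The observed index is a mean of fold-change
ranks that share their numerator across comparisons. A null that assigns
ranks independently per comparison ignores that dependence and flags ~14%
of exchangeable-noise genes at a nominal 5%. The shipped null permutes gene
labels instead — the target column once per draw (preserving the shared
numerator), each comparison column independently — and is calibrated
(~5% under exchangeable noise). This is the one place the implementation
departs from a stated design suggestion, in favour of the stated
calibration requirement.

**Moderated t.** The variance prior is moment-matched on log variances
(trigamma matching with a Newton inverse), the total df is capped at the
pooled residual df, and `prior_df` can be forced to `0` (per-gene t) or
`Inf` (common variance) for diagnostics; agreement with the standard
empirical-Bayes implementation is asserted in the tests against `limma` on
a fixture.

# The synthetic world

The generator (`simulation_config()`, `generate_cohort()`,
`generate_expression()`, `generate_de_dataset()`,
`generate_celltype_profiles()`) emulates the four input kinds with known
planted structure. Defaults state the emulated world: 308 regions (151
left), 7 features, 50 subjects per group, 10 planted decreased-MS and 9
increased-MS regions (the reference design's Table-2 counts), 2,000 genes
with 5% positively and 5% negatively coupled spatial profiles at coupling
0.8, 10% planted down- and 7.5% up-regulated genes at |log2 FC| = 2, and
100 markers per cell type.

Because MS is a correlation, group effects are planted on correlation
structure, not means: each subject's regional profile mixes two latent
feature patterns (region loadings shared across subjects; a minority of
regions load negatively so that within-subject centering leaves the effect
regions with clearly positive weighted degree) plus independent noise. In
cases, decreased-MS regions swap a fraction `w = 0.5 * effect_size` of
latent-signal variance for noise; increased-MS regions do the reverse;
per-feature variances are held fixed, so the effect is invisible to
mass-univariate feature tests. The swap coefficient was calibrated once so
that the stated design point (effect 1.5, n = 50/group, seed 7) recovers at
least 80% of planted regions at FDR < 0.05 with the correct sign, and was
not revisited.

The memory composite is a linear function of each subject's mean MS over
the planted decreased regions (computed from the clean, pre-batch features)
plus noise, with a group-level offset; batch effects are per-feature
location shifts and alternating scale factors applied last, so
harmonization faces exactly what the generator planted. All randomness
flows from one master seed through a documented FNV-1a splitting scheme
(`child_seed()`), so any stage can be regenerated independently and
bit-identically.

What the generator does **not** emulate: spatial autocorrelation of
cortical maps, donor structure of expression atlases, probe-level
microarray noise, realistic effect-size distributions of a clinical cohort,
or site-by-covariate confounding. A green recovery test therefore
establishes that the estimators recover the planted structure of this
stated world at the stated rates — not that the pipeline's operating
characteristics on real cohort data match them. One known leakage is
documented: planting effects in a subset of regions slightly shifts the
within-subject standardization of case subjects, making non-effect regions
weakly non-null; sensitivity and sign recovery, not false-positive counts,
are the tested claims at non-zero effect size.

# Numerical conventions

- Pearson correlations over the 7 features use the sample sd (n − 1);
  with so few paired observations individual edges are noisy by design and
  stabilize in the 307-neighbour average.
- Degenerate regions (zero feature variance) are masked — row and column
  `NA`, excluded from other regions' degrees — never imputed; downstream
  statistics propagate `NA` with a warning.
- Bootstrap resamples that are degenerate (constant response or fewer than
  three distinct regions) are redrawn and counted.
- The Bonferroni Z threshold is the two-decimal ceiling of the normal
  quantile, with a guard against floating-point representation at the
  boundary; thresholding uses strict inequalities.
- `fdr_bh()` is the exact step-up adjustment (reverse cumulative minimum),
  dual-checked in the tests against an independent rank-loop oracle and
  `p.adjust`.
- The specificity index regularizes fold-change ratios with ε = 1e-9
  before ranking, making an all-zero denominator profile well defined.

# Limitations

- Only the first PLS component is computed; multi-component extensions and
  spatial-autocorrelation-preserving null maps (spin tests) are out of
  scope.
- The over-representation module treats gene sets as flat lists: no
  ontology DAG, ancestry propagation, or annotation retrieval.
- Harmonization assumes at least two subjects per batch and no
  batch-unique zero-variance series; such inputs error rather than being
  silently repaired.
- Printed result values of the motivating analysis that depend on its
  proprietary cohort and atlas inputs (regional T values, spatial
  correlation coefficients, gene-set counts) are not desk-reproducible and
  are treated as context; the acceptance machinery reproduces the
  quantities derivable from published inputs and the synthetic recovery
  rates.
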