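# mstx — morphometric similarity networks and imaging transcriptomics

`mstx` is an R package for asking, end to end, how case-control changes in
cortical **morphometric similarity (MS) networks** relate to spatial gene
expression, and what the associated genes do. It is aimed at neuroimaging
groups with multimodal regional MRI features (T1- and DTI-derived) and a
regions-by-genes expression matrix, and at methodologists who want every
stage of such a pipeline testable against planted ground truth.

## The model

For subject *s* with z-scored feature matrix `X_s` (regions × 7 features),
the MS network has edges

    MS_s(i, j) = cor(X_s[i, ], X_s[j, ])        (Pearson, signed)

and each region's **weighted degree** is its mean similarity to all other
regions. Regional group differences are tested with per-region OLS

    degree ~ group + age + sex + education

giving a T map with Benjamini-Hochberg FDR across regions. The
left-hemisphere T map is then regressed on expression by one-component
partial least squares; with a univariate response the PLS1 gene weights are
the normalized gene–response covariances,

    w = X'y / ||X'y||,   Z_g = w_g / se_boot(w_g)

with the standard error from `B = 1000` bootstrap resamples of regions.
Genes beyond the Bonferroni-derived threshold (|Z| > 4.72 at 20,737 genes)
form signed PLS1+/PLS1− sets, which are screened by hypergeometric/Fisher
overlap against differentially expressed genes (moderated t, p < 0.01 and
|log2 FC| > 1), cell-type-specific genes (specificity index, pSI < 0.05),
and arbitrary gene-set collections. Batch effects are removed beforehand by
parametric empirical-Bayes (ComBat-style) harmonization with biological
covariates preserved.

A synthetic-data module generates all four input kinds with planted,
labelled structure (affected regions, coupled genes, DEGs, cell-type
markers) so the whole chain is testable without access to cohort data.

## Worked example

```r
library(mstx)

cfg     <- simulation_config(seed = 7)           # stated synthetic world
cohort  <- zscore_features(harmonize_features(generate_cohort(cfg)))
regional <- regional_ms_table(cohort)            # subjects x regions degree
tmap    <- ms_tmap(regional, cohort$meta)        # covariate-adjusted T map

sig <- subset(tmap, q < 0.05)
mm  <- mean_ms_subset(regional, sig$region_id[sig$T < 0])
pc  <- partial_correlation(mm, cohort$meta$memory_score,
                           cohort$meta[c("age", "sex", "education")])

ex   <- generate_expression(tmap, cfg)
y    <- setNames(tmap$T, tmap$region_id)[rownames(ex$expr)]
fit  <- pls_bootstrap_z(pls1_fit(ex$expr, y), ex$expr, y,
                        B = 1000, seed = child_seed(7, "bootstrap"))
sets <- threshold_gene_sets(fit)

de  <- generate_de_dataset(cfg, coupling = ex$truth$coupling)
der <- moderated_de(de$expr, de$group)
bg  <- names(fit$w)
ov  <- fisher_overlap(intersect(sets$neg, bg),
                      intersect(der$gene[der$label == "down"], bg), bg, m = 2)
```

This prints (seed 7, shipped defaults):

```
significant regions: 30  ( 8 decreased / 22 increased )
memory partial r = 0.67 (p = 1.3e-13, n = 96)
PLS1 varexp_y = 1.00; z_crit = 4.22; 100 PLS1+ / 100 PLS1- genes
PLS1- x down-DEG overlap: k = 71, Pc = 7.99e-53
```

Reading the numbers: of the 19 planted effect regions, 16 are recovered
with the correct sign (the extra "increased" regions are the documented
standardization leakage of the simulator — see the methods vignette); mean
MS over the decreased regions tracks the memory composite positively after
covariate control; the 100 + 100 genes selected at the derived threshold
(4.22 for 2,000 genes) are almost exactly the planted coupled genes; and
the planted PLS1−/down-DEG overlap is decisively enriched after Bonferroni
correction over the two DEG directions.

The full pipeline with TSV outputs and a run manifest:

```r
run_pipeline(pipeline_config(seed = 7, out_dir = "run7"))
```

or from the shell: `exec/mstx run --seed 7 --out run7`, then
`exec/mstx report --out run7`.

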