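# immfocus

Bulk tumor RNA-seq measures a mixture: malignant cells plus however much
immune tissue the biopsy happened to capture. For immune genes, most of the
apparent between-patient expression variability is therefore *immune
sampling noise* — variation in the immune fraction φ<sub>s</sub> of each
biopsy — which both inflates variance and confounds survival associations.
`immfocus` is for researchers analysing tumor cohorts (expression matrix +
clinical follow-up) who want immune-gene expression on a *per-immune-cell*
scale without running a deconvolution model.

## The method

1. **INGS derivation.** An *immune-normalizing gene set* is derived from the
   cohort itself: all genes with Pearson r² > 0.5 (and r > 0) against an
   anchor gene — by default *PTPRC* (CD45), the pan-leukocyte marker — form
   a provisional set, which is refined by dropping genes whose
   coefficient-of-variation ratio under leave-one-out normalization exceeds
   0.8.
2. **Normalization.** The per-sample factor f<sub>s</sub> is the mean INGS
   expression in sample *s* (∝ immune fraction); every gene is divided by
   f<sub>s</sub>, INGS members by their leave-one-out factor
   f<sub>s</sub><sup>(i)</sup> so no gene normalizes itself.
3. **Screens.** Per-gene CVR = CV(normalized)/CV(raw) ranks
   normalization-responsive genes (groups `cvr_low` / `cvr_high` /
   `cvr_random`); a tertile-stratified Kaplan–Meier / log-rank scan on raw
   vs normalized data, summarised by LOD = ln(p<sub>norm</sub> /
   p<sub>raw</sub>), quantifies gains in prognostic power (LOD ≤ −2 is a
   > e² ≈ 7-fold gain); χ²/t tests check stage, gender and age association
   of the hits; a k×2 χ² tests annotation enrichment of the groups.

A seeded tumor/immune mixture simulator (`simulate_cohort()`) generates
cohorts with known immune fractions, latent immune activity and
activity-linked hazard, so every stage is testable against ground truth.
See the methods vignette (`vignettes/immune-normalization.Rmd`) for the
model, parameter defaults and design rationale.

## Worked example

```r
library(immfocus)

sim <- simulate_cohort(sim_config(seed = 42))   # 2000 genes x 480 patients
fit <- immfocus(sim$expr)
fit
#> Immune normalization fit
#>   cohort: 2000 genes x 480 samples
#>   anchor: PTPRC; provisional set: 151 genes; final INGS: 151 genes
#>   per-sample factor f: median 320.8 (range 8.139-1234)

cor(coef(fit), sim$truth$phi)                   # factor vs true immune fraction
#> [1] 0.9983845

norm <- predict(fit)                            # normalized matrix
tab  <- compute_cvr_table(sim$expr, norm)
cmp  <- compare_group_cvr(select_cvr_groups(tab, group_size = 150, seed = 42), tab)
cmp$stats
#>        group   n       mean          sd
#> 1    cvr_low 150  0.2520363 0.009371256
#> 2   cvr_high 150 12.4053967 0.460574922
#> 3 cvr_random 150  9.5123374 3.530230856

cls  <- sim$truth$gene_class
scan <- gene_survival_scan(sim$expr, norm, sim$clinical,
                           genes = names(cls)[cls == "prognostic_immune"])
head(scan[, c("gene", "p_raw", "p_norm", "lod")], 3)
#>      gene        p_raw       p_norm       lod
#> 1 PRG0001 1.421201e-04 6.972860e-13 -19.13274
#> 2 PRG0002 5.668995e-05 2.299707e-16 -26.23067
#> 3 PRG0003 8.148868e-06 6.443782e-11 -11.74769
```

The fit recovers the true 151-gene immune block exactly; the most
normalization-responsive genes (mean CVR 0.25) are the immune block, while
tumor-intrinsic genes gain variance (CVR ≫ 1) because they are divided by a
factor unrelated to them; and for genes whose per-cell expression carries
the hazard-linked activity signal, normalization strengthens the survival
association by 12–27 natural-log units of p-value (negative LOD).

Real cohorts enter through `read_expression_matrix()` (merged TSV or
per-sample RSEM files), `read_clinical_table()` and `align_cohort()`;
`run_pipeline()` executes the whole analysis into a directory of TSV
artifacts with a JSON manifest, and `inst/cli/immfocus.R` is a thin
command-line wrapper over the same functions.

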