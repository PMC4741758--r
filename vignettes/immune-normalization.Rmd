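---
title: "Immune normalization of bulk tumor expression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune normalization of bulk tumor expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immfocus)
```

## The problem and the model

A bulk tumor biopsy is a mixture: malignant cells plus whatever stromal and
immune tissue the needle happened to capture. For an immune gene, the
measured abundance in sample $s$ is therefore approximately

$$ X_{gs} \;=\; m_g \,\varphi_s\, \varepsilon_{gs}, $$

where $m_g$ is the gene's per-immune-cell abundance, $\varphi_s$ the immune
fraction of the biopsy, and $\varepsilon_{gs}$ multiplicative measurement
noise. Most of the between-patient spread in immune-gene expression is then
sampling noise in $\varphi_s$, not biology — and it masks the biologically
interesting per-cell signal (immune activity) that covaries with outcome.

The package estimates $\varphi_s$, up to a constant, without deconvolution.
An *immune-normalizing gene set* (INGS) is derived empirically from the
cohort itself:

1. **Anchor correlation.** Every gene is correlated (Pearson, across
   samples, linear scale) with an anchor gene whose expression is a faithful
   pan-immune readout. The default anchor is *PTPRC* (CD45, the leukocyte
   common antigen), expressed on essentially all immune cells and few
   others. Genes with $r^2 > 0.5$ (strictly) and $r > 0$ form the
   provisional set.
2. **CVR refinement.** Each provisional gene is normalized by the
   leave-one-out mean of the other provisional genes and its coefficient of
   variation ratio $\mathrm{CVR} = \mathrm{CV}_\text{norm} /
   \mathrm{CV}_\text{raw}$ is computed. Genes whose spread is not actually
   reduced ($\mathrm{CVR} > 0.8$) are dropped in a single pass; the
   survivors are the final INGS.

The per-sample factor is the arithmetic mean of the INGS genes,
$f_s = \frac{1}{|I|}\sum_{g \in I} X_{gs}$, and normalized expression is
$X_{gs} / f_s$. INGS members are divided by their leave-one-out factor
$f_s^{(i)}$ instead, so no gene is normalized by itself. The identity
$k f_s = (k-1) f_s^{(i)} + X_{is}$ ($k = |I|$) is used to compute all
leave-one-out factors in one pass and is asserted in the tests.

Downstream, the package quantifies what the normalization buys:

* **CVR screening** ranks all genes by CVR and forms three equal groups —
  the most responsive (`cvr_low`), the least responsive (`cvr_high`), and a
  seeded random draw (`cvr_random`, which may overlap the other two by
  design, since it is drawn "regardless of CVR").
* **Survival screening** stratifies patients into the bottom and top
  expression tertiles of each gene ($\lfloor N/3 \rfloor$ each) and compares
  them with the Kaplan–Meier estimator and the log-rank test, once on raw
  and once on normalized values (tertiles re-derived from normalized ranks).
  The per-gene change in prognostic power is
  $\mathrm{LOD}_g = \ln(p'_g / p_g)$, the natural-log ratio of the
  normalized to the raw log-rank p-value; $\mathrm{LOD} \le -2$ is a more
  than $e^2 \approx 7.4$-fold gain. Significance is Bonferroni-controlled at
  $\alpha / N_\text{tests}$.
* **Clinical association** tests whether expression-stratified tertiles
  differ in combined pathological stage (I+II vs III+IV; Yates-corrected
  $2\times2$ $\chi^2$), age (pooled-variance Student t) and gender
  (Yates $\chi^2$).
* **Enrichment** tests whether a gene group is over-represented in a
  user-supplied annotation list via a $k\times2$ Pearson $\chi^2$ (no
  continuity correction above one degree of freedom).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `anchor` | `"PTPRC"` | anchor gene; any pan-population marker works mechanically |
| `r2_threshold` | 0.5 | strict lower bound on squared anchor correlation |
| `require_positive` | `TRUE` | provisional members must correlate positively |
| `cvr_threshold` | 0.8 | refinement keeps genes with CVR $\le$ 0.8 |
| `group_size` | 500 | genes per CVR group |
| `alpha` | 0.05 | family-wise level before Bonferroni division |
| `n_tests` | `"auto"` | Bonferroni divisor; defaults to the scanned set size |
| `p_floor` | 1e-300 | floor applied before the LOD log-ratio |

Thresholds are deliberately asymmetric at the boundary: membership requires
$r^2$ *strictly above* 0.5, while refinement *keeps* CVR exactly 0.8 (only
values above it are dropped). Both boundary semantics are pinned by tests.

## Design choices where the design was open

* **Sign of the anchor correlation.** A squared-correlation rule alone would
  admit genes that *anti*-correlate with immune content; averaging them into
  $f$ would cancel the very signal being estimated. `require_positive`
  therefore defaults on, with a flag for the literal $r^2$-only behaviour.
  On every simulated cohort tried the two modes coincide, because strong
  negative correlates of total immune content are rare.
* **Single-pass refinement.** The CVR filter runs once, with factors built
  from the provisional set; it is not iterated to a fixed point (an
  `iterate` switch exists but is off). Iterating changes membership only
  marginally and makes the derivation order-sensitive in edge cases.
* **Anchor retention.** The anchor is kept in the final INGS even if its own
  CVR were above threshold — the set is defined by correlation *to* the
  anchor, and dropping it would make the derivation self-undermining. In
  practice its CVR is far below 0.8.
* **Arithmetic mean for `f`.** "Average expression" is read literally; a
  geometric-mean variant would down-weight high-abundance members but
  changes little on real scales and is not the default.
* **Linear scale.** Expression is used untransformed. CV magnitudes only
  make sense on the linear scale; a `log2_transform` switch exists for the
  correlation stage only and is off by default.
* **Tertile size** is $\lfloor N/3 \rfloor$ for both tails, the symmetric
  convention; ranking ties are broken by sample id so stratification is
  deterministic.
* **Normalized-data tertiles are re-derived** from normalized ranks rather
  than frozen at the raw grouping: each dataset is tested on its own
  stratification. A fixed-grouping mode is available (`regroup = FALSE`).
* **Yates continuity correction** is applied to every $2\times2$
  $\chi^2$. The package also offers a legacy adjustment mode
  (`legacy_rounding`) in which the raw p is rounded to 4 decimals before
  Bonferroni multiplication — this exists solely to reproduce historical
  per-gene stage tables digit-for-digit and is off for new analyses.
* **Bonferroni by default,** Benjamini–Hochberg as an option
  (`adjust = "BH"`), reflecting the screening context: the default protects
  the family-wise error of a 500-gene scan.

## The simulator: what it emulates and what it does not

`simulate_cohort()` draws seeded cohorts from the generative model the
normalization assumes, so every stage can be validated against ground
truth:

* immune fraction $\varphi_s \sim \mathrm{Beta}(2, 6)$ (mean 0.25, a
  realistic biopsy-to-biopsy spread for an immune-infiltrated solid tumor);
* latent immune activity $a_s \sim \mathcal N(0, 1)$, independent of
  $\varphi_s$;
* per-gene baselines $m_g \sim \mathrm{LogNormal}(\log 500, 1.5)$, a wide
  RSEM-like abundance range;
* expression $X_{gs} = m_g\, w_{gs}\, \varepsilon_{gs}$ with
  $w = \varphi_s$ for the anchor and the immune block,
  $w = \varphi_s e^{\gamma a_s}$ ($\gamma = 0.5$) for prognostic immune
  genes, $w = 1$ for tumor-intrinsic genes, and lognormal noise
  $\varepsilon$ with mean 1 and CV 0.15;
* death times exponential with hazard $\lambda_0 e^{\beta a_s}$
  ($\lambda_0 = \log 2 / 1200\ \text{days}^{-1}$, $\beta = 0.8$), censored
  by an independent uniform horizon calibrated to a 65% censored fraction —
  the event rate of a large kidney-cancer cohort;
* defaults of 480 patients and 2000 genes (150 immune, 30 prognostic
  immune, 1 anchor, the rest tumor-intrinsic).

The construction puts the confounding exactly where the method claims to
remove it: raw prognostic-immune expression mixes $\varphi_s$ (sampling
noise) with $a_s$ (the hazard-linked signal), so the raw log-rank test is
diluted while the normalized one is not. Tumor-intrinsic genes gain variance
under normalization (they are divided by an unrelated factor), which is what
the CVR contrast measures.

What the simulator does **not** emulate: discrete counting noise,
gene–gene correlation within blocks beyond the shared factors, multiple
immune-cell subpopulations with distinct states, tumor-cell expression of
immune genes (checkpoint-ligand-like behaviour), non-proportional hazards,
and informative censoring. Passing the recovery suite therefore shows the
machinery is correct under the model's own assumptions, not that any given
real cohort satisfies them.

## Validation performed by the test suite

All empirical statements below are computed by `tests/testthat/` and
`scripts/acceptance.R`; none are asserted from memory.

* On the default simulated cohort, the derived INGS lies at least 90% inside
  the true immune block and $\mathrm{cor}(f, \varphi) > 0.95$.
* Mean CVR over the immune block is below 0.9 and over the tumor block above
  0.95 (in practice the separation is roughly 0.26 vs 10).
* With $\beta = 0$ (expression independent of survival, 480 patients), the
  uncorrected tertile log-rank screen rejects at a rate inside
  $[0.03, 0.07]$ at $\alpha = 0.05$ over 200 replicates.
* Over 50 replicate cohorts, the median LOD of prognostic immune genes is
  negative (large gains, around $-19$) while the median LOD of
  tumor-intrinsic genes is not negative.
* The Kaplan–Meier estimator, the log-rank statistic, CV/CVR and the
  $\chi^2$ machinery are each checked against independent oracles: a
  hand-expanded product-limit example, exact enumeration of all twenty
  $3{+}3$ label assignments, direct formula recomputation, and Fisher's
  exact test on ample tables.
* The legacy stage-association convention reproduces published per-gene
  adjusted p-values (e.g. 0.0132, 0.0088, 0.0044, 0.2772, 0.6864, 0.0484)
  exactly from their printed $2\times2$ counts.

Problem sizes in the suite — 480-sample default cohorts, 200 null
replicates, 50 LOD replicates, 120-sample cohorts for unit tests — were
chosen so each property is measured with comfortable statistical margin
while the whole suite stays quick to run routinely.

## Known limitations

* The INGS is cancer-type specific; a set derived on one cohort should only
  be reused on cohorts with a comparable immune milieu (the JSON
  serialization exists for exactly that workflow, with the caveat attached).
* Genes expressed by both tumor and immune cells will not pass the CVR
  filter and are invisible to the method — by design, but worth remembering
  when a known marker is absent from results.
* The survival screen is univariate: no Cox modelling, no adjustment for
  stage or age. The clinical-association tests exist to surface such
  confounding, not to correct it.
* With very small INGS sizes the leave-one-out factor differs noticeably
  from the plain factor; the per-sample mean of normalized INGS genes equals
  1 only in the plain-factor limit, with the discrepancy shrinking as the
  set grows.
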