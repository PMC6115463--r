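# phosksea

Kinase-set enrichment and prognostic stratification for phosphoproteomics.

Relapse in triple-negative breast cancer (TNBC) is hard to predict from
classical clinicopathology, and most phosphosites detected by mass
spectrometry have no annotated function. One productive route is to project
phosphoprofiles onto their *driver kinases*: rank phosphosites by how
differentially phosphorylated they are between relapsed and non-relapsed
tumors, map each site's flanking sequence to kinase/phosphatase/SH2 linear
motifs, test each kinase's putative substrate set for enrichment at one end
of the ranked list (kinase-set enrichment analysis, KSEA), and carry the
enriched kinases to immunohistochemistry, where a simple per-patient binary
signature stratifies outcome. phosksea implements that pipeline as a tested,
reusable R package for analysts working with phosphosite quantification
tables, motif libraries, clinical tables and xenograft growth data — plus a
synthetic-data module that generates every input with planted ground truth so
each stage has a recoverable answer.

## The statistics at the core

* **Differential phosphorylation.** Per site, a two-group linear model on
  log2 intensities with empirical-Bayes variance shrinkage (limma); BH
  adjustment; sites with *q* < 0.15 selected. Sites need ≥ 2 observations per
  group; no imputation.
* **KSEA.** For a kinase set *S* of size *K* in a ranked list of *N* sites,
  walk the list: hits add `|m_i|^p / Σ_{S} |m_j|^p`, misses subtract
  `1/(N−K)`; the enrichment score ES is the signed supremum of the running
  sum. A permutation null (phenotype relabeling at ≥ 7 samples/group, random
  same-size sets otherwise) gives NES = ES / mean |null ES of matching
  sign|, nominal *p*, and FDR *q* over the pooled signed-NES null;
  significance at *q* < 0.05 with a relaxed *q* < 0.25 boundary for carrying
  candidates into validation.
* **K-high.** Per kinase, H-score = `(%area_high·3 + %area_med·2 +
  %area_low·1)/100 ∈ [0,3]`; patients strictly above the cohort 75th
  percentile are coded 1; K-high is the OR over the six signature kinases
  (PRKCE, c-Kit, p-ERK, p-P70S6K, p-PNKP, CDK6), and the 6-bit statuses form
  a pattern taxonomy with 2⁶ = 64 possible patterns.
* **Survival.** Kaplan–Meier + log-rank (univariate); Cox proportional
  hazards (Efron ties) adjusted for T, N, grade, age, Bonferroni across
  kinase variables.
* **Preclinical.** Tumor volume `V = D·d²/2`;
  `TGI = (1 − (T_F/T_0)_A / (T_F/T_0)_V) × 100`; Welch t for arm contrasts.

## Worked example

```r
library(phosksea)

cfg <- sim_config(seed = 1, active_kinases = "KIN_001")  # plant one active kinase
dat <- simulate_cohort(cfg)          # motifs, proteome, intensities, clinical, growth
lg  <- log2_transform(dat$sites)

diff <- phospho_diff(lg, dat$groups)           # limma moderated t, BH, q < 0.15
sum(diff$selected)
#> [1] 36

ks <- ksea(lg, dat$groups, dat$motifs, n_perm = 400, mode = "set", seed = 8)
head(tidy(ks)[, 1:7], 3)
#>   kinase  category  size    es   nes       p      q
#> 1 KIN_001 kinase      36 0.991  2.24 0.00304 0
#> 2 KIN_201 kinase     101 0.767  1.89 0.00257 0
#> 3 KIN_084 kinase      11 0.888  1.75 0.00405 0.0140
```

The planted kinase (36 matched substrates, 30 of them planted) tops the list
with ES ≈ 0.99 — nearly all its substrates sit at the head of the ranking —
and an FDR *q* below the 0.05 boundary. Sets like `KIN_201` overlap the
planted substrates, a normal feature of overlapping linear motifs.

```r
st <- binarize_quartile(dat$clinical)          # 75th-percentile encoding
enumerate_patterns(st, relapse = dat$clinical$event)
#> Kinase activation patterns: 36 observed out of 64 possible
#> # A tibble: 36 x 4  (pattern, n, n_relapse, exclusive_to_relapsed)

kinase_screen(dat$clinical, dplyr::mutate(st, `K-high` = unname(k_high(st))))[, c(1, 4, 6, 7)]
#>   variable       hr        cox_p p_bonferroni
#> 6     CDK6 3.266468 5.138205e-05 0.0003596744
#> 7   K-high 7.288944 8.554496e-04 0.0059881473
```

In this 113-patient synthetic cohort (planted K-high hazard ratio 9.22),
K-high carries a Cox HR of 7.3 after adjustment for T/N/grade/age and
survives Bonferroni correction. `run_pipeline(pipeline_config(...), out_dir)`
chains all stages and writes every table, a config snapshot and a log with
input checksums; `autoplot()` methods cover KSEA tables, KM curves and
pattern tables, and `plot_enrichment(ks, "KIN_001")` draws the running-sum
chart for one kinase.

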