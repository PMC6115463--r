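---
title: "Kinase-set enrichment and K-high stratification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase-set enrichment and K-high stratification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosksea)
```

phosksea implements an end-to-end phosphoproteomics analysis for relapse in
triple-negative breast cancer (TNBC): differential phosphosite selection,
motif-based kinase-substrate mapping, kinase-set enrichment analysis (KSEA),
immunohistochemistry-based prognostic stratification (K-high), survival
modeling, and preclinical tumor-growth-inhibition scoring. This vignette is
the package's account of the underlying models, the tunable parameters, and
the design decisions taken where the methodology left genuine choices open.

## The analysis model, stage by stage

### Differential phosphorylation

Phosphosite intensities (label-free MS quantities) are log2-transformed;
zeros and blanks are treated as *missing*, never as measured zeros, because a
missing phosphopeptide usually means "below detection". Per site, a two-group
linear model (relapsed vs non-relapsed) is fitted with limma's empirical-Bayes
variance shrinkage; two-sided moderated-t p-values are Benjamini–Hochberg
adjusted and sites with q < 0.15 are flagged as differentially phosphorylated.
Missing values are handled by *omission*: a site needs at least two observed
values per group to be tested, and no imputation is performed — imputing
low-abundance dropouts would manufacture exactly the intensity-dependent
signal the test is looking for. The pooled-variance (not Welch) form mirrors
the standard linear-model framework; `shrink = FALSE` gives the ordinary
pooled t (prior degrees of freedom zero), which the tests use as an oracle
anchor.

### Motif mapping

Each phosphosite carries a 15-residue flanking window (±7 around the
phospho-S/T/Y, `_`-padded at protein termini). A linear motif is a vector of
15 position constraints — each slot either `X` (any residue) or a set of
allowed residues, with the center constrained to S/T/Y. Padding satisfies
only `X`: a terminal site cannot positively match a constraint outside the
protein. This position-set dialect (HPRD-style) is deliberately simpler than
regular expressions: it covers kinase, phosphatase and SH2 linear motifs and
is exactly testable. Substrate sets outside 5–500 members are excluded,
following gene-set-analysis conventions; phosphatase and SH2 sets are scored
identically to kinase sets and keep their category label, since enrichment of
a phosphatase's substrate set is informative even though the tool cannot
decide whether the phosphatase is active.

### KSEA

Sites are ranked by a signed contrast metric — the moderated t by default
(`metric = "signed_t"`), log2 fold change as an alternative, since ranking
"by intensity" is ambiguous between abundance and regulation; the choice is a
parameter rather than an assertion. Walking the ranked list, members of a
kinase's substrate set increment a running sum by their `|metric|^p` share of
the set total (p = 1 by default, the classic weighted Kolmogorov–Smirnov
form; p = 0 gives the unweighted statistic), and non-members decrement it by
`1/(N − K)`. The enrichment score (ES) is the signed supremum; exact ties
between the positive and negative extremum (these occur as exact rationals)
resolve to the positive one. A set spanning the whole list leaves the miss
decrement undefined; it is reported as ES 0 with a `degenerate` flag.

The null distribution comes from permutations. *Phenotype* permutation
relabels samples and recomputes the metric — the more faithful null, but it
needs at least 7 samples per group (below that the label space is too small
and the mode falls back to *set* permutation with a warning). *Set*
permutation scores random same-size site sets against the fixed observed
ranking. NES divides ES by the mean |null ES| of matching sign for that set;
FDR q follows the standard pooled signed-NES procedure, and with a single set
q equals the nominal p. Significance is flagged at q < 0.05, plus a relaxed
boundary (default q < 0.25) used when carrying candidates forward to
antibody-based validation, where losing a true kinase is costlier than
carrying a false one. No Bonferroni correction is applied at this stage; the
study design reserves Bonferroni for the clinical kinase tests.

Two behaviors of the NES statistic are worth knowing. First, NES saturates
around 2–3 once every substrate separates cleanly, because the permutation
null inflates in parallel with the planted signal; NES is monotone in effect
size only below saturation (the raw ES stays monotone throughout), and the
test suite probes it there. Second, with strongly regulated substrates a
motif whose matches form a *superset* of a truly active kinase's substrates
can attain a slightly higher NES than the active kinase itself — larger sets
have tighter nulls, so size normalization can outweigh a small raw-ES
deficit. Ranked lists should therefore be read with set overlap in mind
(the `leading_edge` column makes this easy).

### K-high stratification and the pattern taxonomy

Immunohistochemistry staining is summarized by the H-score,
`(high·3 + med·2 + low·1)/100 ∈ [0, 3]` over the percentages of tissue area
with high / medium / low staining. (Published renderings of this formula
sometimes garble the third term typographically; the 3/2/1 weighting over
high/medium/low areas is the only coherent reading, and it is what
`h_score()` computes.) Per kinase, patients strictly above the cohort's 75th
percentile (linear-interpolation quantile, type 7; ties at the threshold
count as 0) are encoded 1. K-high is the logical OR over the six signature
kinases — PRKCE, c-Kit, p-ERK, p-P70S6K, p-PNKP, CDK6, in that fixed order —
so K-high = 0 demands all six below threshold. The same order renders each
patient's statuses as a 6-bit pattern; with six kinases the pattern space has
2⁶ = 64 members, and `enumerate_patterns()` tabulates the observed ones with
relapse counts and relapsed-exclusivity flags. K-test variables (ORs over
subsets of 2–5 kinases) are configuration — the particular nine combinations
used historically are not recorded anywhere recoverable, so
`k_test_variables()` takes the subsets as input. Whether quartiles should be
pooled across validation cohorts is likewise unstated; the package computes
them per cohort.

### Survival and preclinical scoring

Kaplan–Meier curves use the product-limit estimator (events precede
censorings at tied times); the median is the earliest time with S ≤ 0.5,
reported as `NA` ("not reached") otherwise. Log-rank tests and Cox
proportional-hazards fits go through the survival package with the Efron tie
approximation (less biased than Breslow under moderate ties); each kinase
indicator is adjusted for T, N, grade and age, entered as numeric ordinal
scores (configurable to factors), and Cox p-values are Bonferroni-corrected
across the kinase variables tested. For a single binary covariate the Cox
score test equals the log-rank statistic — the tests assert this identity
numerically.

Tumor volumes use the caliper approximation `V = D·d²/2` (largest × shortest
diameter squared, halved). Tumor growth inhibition is
`TGI = (1 − (T_F/T_0)_treated / (T_F/T_0)_vehicle) · 100`, with the final
time point defaulting to the last day both arms were measured. The arm growth
ratio is the ratio of arm *means* by default (`ratio = "of_means"`); the
mean-of-per-animal-ratios variant is available, as the published formula does
not disambiguate. Arm comparisons at a time point use Welch's t-test.

## The synthetic-data generators

Every input the pipeline consumes can be generated with planted ground truth,
so each stage has a recoverable answer:

* **Motif library** — 327 motifs by default (224 kinase, 23 phosphatase, 80
  SH2, matching the motif resource the analysis emulates), each constraining
  the center (S/T/Y; SH2 motifs center on Y) plus 1–3 flanking positions to
  1–3 residues. Real linear-motif libraries overlap heavily; so do these,
  which is why incidental and superset matches occur by design.
* **Proteome and sites** — random 120-residue proteins with phosphosites at
  interior, non-overlapping positions; substrates of each active kinase have
  their windows rewritten to satisfy that kinase's motif, so the membership
  truth table is exact by construction (re-matching recovers it).
* **Intensity matrix** — log2 intensities ~ Normal(site baseline, `noise_sd`)
  with the planted `effect_log2fc` added in the relapsed group; dropout is
  logistic in the true log2 intensity (an "MNAR-lite" model reflecting that
  faint phosphopeptides are detected less often), calibrated so the overall
  missing fraction equals `missing_rate_base`. Intensities are emitted on the
  raw scale. Defaults — 10+10 samples, 1000 sites, log2FC 2, noise SD 0.3,
  10% missingness — are the conditions the recovery and calibration suites
  run under.
* **Clinical cohort** — six continuous H-scores per patient (scaled Beta
  draws, so ~25% exceed each 75th percentile), ordinal T/N/G and age, and
  exponential relapse times whose hazard is multiplied by planted hazard
  ratios attached to kinase statuses or to the derived K-high indicator
  (default: HR 9.22 on K-high, the effect size the pipeline is expected to
  recover at large n). Censoring is independent Uniform(0, c_max) with c_max
  solved numerically so the expected censored fraction equals `censor_rate`
  (default 0.5). Cohort size defaults to 113.
* **Growth curves** — `V(t) = V0·exp(r·m_arm·t)` with lognormal measurement
  noise; `r` defaults to 0.1/day and arm multipliers are configuration.

What the generators deliberately do **not** emulate: peptide-to-site
ambiguity and localization probabilities, correlated site co-regulation
within pathways, batch effects, cohort heterogeneity in censoring, or
informative censoring. Tests passing on this synthetic world demonstrate
that the statistics recover what was planted under their own model
assumptions — they do not certify performance on real cohorts, where those
unmodeled features dominate the error budget.

## Numerical choices and degenerate inputs

* Ranking ties break lexicographically on `site_id`, making every ordering
  deterministic and permutation-invariant.
* ES extremum ties (positive vs negative, exact rationals) resolve positive,
  with a 1e-12 guard so floating-point noise cannot flip the sign.
* In phenotype permutations, a site left with fewer than two observations in
  a group under some relabeling gets metric 0 (mid-rank) for that
  permutation, keeping the ranked universe fixed.
* A substrate set whose observed metrics are all exactly zero falls back to
  equal hit weights.
* Nominal permutation p-values use the (1 + b)/(1 + B) form, so p = 0 never
  occurs.
* BH uses π₀ = 1 (plain step-up, conservative); no π₀ estimation.
* Consensus clustering (hierarchical, average linkage, 1 − Pearson distance,
  default 1000 resampling iterations at 80% sample subsampling) excludes
  zero-variance samples with a warning; pairs never co-sampled get a missing
  consensus entry, treated as 0.5 when cutting the final tree.
* `cox_fit()` warns when events are fewer than covariates; `coxph`'s own
  convergence machinery (damped Newton) handles monotone likelihoods and its
  iteration count is surfaced in `converged`.

## Problem sizes in the test and acceptance suites

The heavier suites use 20 replicate cohorts of 1000 sites × 20 samples with
400 permutations per KSEA run — enough Monte-Carlo resolution (1/400 per
sign) to judge a 0.05 FDR boundary while keeping a full run of the suite on
one CPU in a few minutes. Parameter-recovery checks for the Cox stage use
cohorts of n = 2000 and average the estimate over three cohorts, since a
single cohort's sampling error (≈0.07 on the log-HR) is of the same order as
the recovery band being verified. The Wald-coverage property uses 200
replicates at n = 500 so the binomial granularity of the coverage estimate is
finer than the band it must fall in.

## Known limitations

* The moderated test assumes roughly Gaussian log-intensities and a common
  two-group design; paired or multi-factor designs, batch correction and
  imputation are out of scope.
* KSEA inherits GSEA's size-normalization quirks described above; with very
  strong planted effects the top NES can belong to a superset of the truly
  active kinase's substrates even when the active kinase's raw ES is higher.
* The pattern taxonomy and mutation overlay are pure tabulation — no
  inference is attached to pattern/mutation co-occurrence.
* TGI compares arm-level growth ratios; it does not model per-animal
  longitudinal correlation, and no combination-index (synergy) statistic is
  computed.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(seed = 1, active_kinases = "KIN_001"),
  n_perm = 400)
res <- run_pipeline(cfg, out_dir = tempfile("phosksea_run_"))
head(tidy(res$ksea))
res$screen
autoplot(res$km)
```
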