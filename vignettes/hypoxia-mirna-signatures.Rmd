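---
title: "Deriving and validating hypoxia-associated miRNA signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating hypoxia-associated miRNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypomir)
```

## The problem

Tumour hypoxia confers radioresistance and a poor prognosis, and
hypoxia-modifying treatments (such as carbogen–nicotinamide given with
radiotherapy) appear to help mainly the patients whose tumours are
actually hypoxic. Expression signatures that classify tumours as
hypoxic or normoxic are therefore candidate predictive biomarkers.
miRNAs are attractive signature material because they survive FFPE
storage far better than mRNA. `hypomir` implements, end to end, the
standard derivation and validation chain for such a signature, together
with a synthetic-data generator so every stage can be tested against a
known ground truth.

The chain has four stages.

1. **Seed discovery (qPCR).** Cell lines are profiled on qPCR array
   cards under normoxia and hypoxia. Expression is quantified by the
   ΔΔCt method: per sample, ΔCt(feature) = Ct(feature) − reference
   (endogenous controls); per feature, ΔΔCt = mean ΔCt under hypoxia −
   mean ΔCt under normoxia, and fold change = 2^(−ΔΔCt). A feature is
   *induced* when the Welch-test p-value is below 0.05 and the fold
   change exceeds 1.0 (both strict; no multiple-testing correction —
   the screen convention for triplicate array cards, where an FDR
   cut-off costs too much power against high intra-group variation).
   Features with Ct ≥ 30, or undetermined, in every replicate of both
   conditions are excluded as undetected. miRNAs induced at the severe
   hypoxia condition in at least two cell lines become *seeds*.

2. **Supervised selection against an mRNA anchor.** A development
   cohort with matched mRNA and miRNA profiles is labelled
   hypoxic/normoxic by a published mRNA hypoxia signature (the
   *anchor*), scored as the mean log2 expression of its genes and
   dichotomised at the cohort median. The Boruta all-relevant algorithm
   then selects the seed miRNAs that predict this label, and a Spearman
   filter (Benjamini–Hochberg FDR < 0.05 against the continuous anchor
   score) assigns each survivor a sign.

3. **Signed scoring and stratification.** The signature score of a
   sample is mean(log2 expression of positively correlated miRNAs) −
   mean(negatively correlated miRNAs). Scores are dichotomised at a
   quantile cut-off (median or upper quartile; linear-interpolation
   quantiles; ties go to normoxic). A cut-off learned in one cohort can
   be transferred to another as a stored numeric threshold.

4. **Survival validation.** Cox proportional-hazards models (Efron
   ties, 5-year administrative censoring) quantify prognosis, the
   within-stratum benefit of the experimental arm, and the
   treatment-by-hypoxia interaction. The univariable p-value is the
   score (log-rank) test; multivariable models admit covariates with
   univariable p < 0.1 and report Wald p-values. Continuous IHC-like
   hypoxia markers are compared between strata with the Mann–Whitney U
   test (exact enumeration up to 10 per group, tie-corrected normal
   approximation otherwise).

## A worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(simulation_config(seed = 1))
res <- run_pipeline(cfg)
res$derivation$signature
res$validation$OS$benefit_hypoxic
attr(res$validation$LRFS$interaction, "interaction_p")
```

`run_derivation()` performs stages 1–2, `run_validation()` stages 3–4
on a two-arm trial; every intermediate result (differential calls,
Boruta history, correlation table, manifests) is attached to the return
values and, given `out_dir`, written as plain TSV/JSON plus a Boruta
importance plot.

## What the generator emulates

`simulation_config()` mirrors the design of a typical derivation
study, and its defaults are the package's fixed reference conditions:

* **qPCR plates** — 4 bladder cancer cell lines (one non-muscle-invasive
  line profiled only at the severe condition), 384 target miRNAs, 3
  endogenous controls, biological triplicates at 21%, 1% and 0.2% O2.
  30 planted miRNAs drop by 1.5 Ct under hypoxia in the 2–4 lines where
  they are induced. Target replicate noise is 0.25 Ct; endogenous
  controls get 0.1 Ct — controls are selected as reference genes
  precisely because they are stable, and qPCR technical variance
  shrinks at high abundance — so the replicate ΔCt standard deviation
  is ≈ 0.26 and the Welch test at n = 3 detects a 1.5 Ct shift with
  ≈ 95% probability. A per-sample global Ct offset (sd 0.5) is shared
  by targets and controls, so control normalisation is genuinely
  needed. 5% of features sit above the Ct 30 detection limit to
  exercise the exclusion rule.
* **Development cohort** — 400 patients; a latent binary hypoxia state
  (prevalence 0.5) shifts 99 anchor mRNAs up by 1 log2 unit and the 14
  planted signature miRNAs (7 up, 7 down) by ±1 log2 unit against noise
  of sd 1; two planted seeds are unexpressed in the cohort to exercise
  the expression filter. Overall and progression-free survival are
  exponential with baseline hazard 0.02/month, hypoxia log-HR log 1.7,
  administrative censoring at 60 months and exponential dropout at
  0.005/month.
* **Two-arm trial** — 95 patients per arm, forced 1:1; hypoxia
  prevalence 0.25; the experimental arm reduces the hazard only in the
  hypoxic stratum (HR 0.45 by default). Continuous CAIX/GLUT1/HIF-1α
  marker values shift with the latent state.

Where the emulated study design fixes a value (cell-line and replicate
counts, array size, O2 conditions, arm sizes, 5-year censoring) the
default is that value. Effect sizes, noise levels and hazards are not
reported by derivation studies; the defaults above were chosen once as
values a practitioner would call realistic for these platforms —
2–3-fold inductions, log2 expression noise of 1, ~70% five-year event
fraction — and give the planted effects enough power to make recovery
failures informative.

Exponential survival (not Weibull) is deliberate: it is the simplest
model satisfying the proportional-hazards assumption the Cox analyses
make. Expression is simulated directly on the log2(x+1) scale; raw
counts, batch effects and platform chemistry are out of scope. Hypoxia
is a binary latent class (the analysis chain dichotomises), with a
continuous severity score recorded for rank-based checks. Because the
generator plants clean additive shifts with independent Gaussian
noise, passing tests demonstrate that the chain recovers the structure
it assumes — not that it is robust to correlated features, platform
batch effects or non-proportional hazards in real cohorts.

## Numerical and design choices

* **Control normalisation.** The reference is the geometric mean of
  the control *abundances* (2^−Ct), i.e. the arithmetic mean of
  control Ct values — the geNorm convention. This makes ΔCt exactly
  invariant to a constant Ct shift of a whole sample, which is the
  property normalisation exists to provide. The variant that takes the
  geometric mean of the Ct values themselves, as array-card protocols
  sometimes word it, is available as `control_mean = "geomean_ct"`;
  it is only approximately shift-invariant (a ±2 Ct sample offset
  perturbs ΔCt by ~2×10⁻³ for controls spread over 15–17 Ct).
* **Control selection.** Every non-empty subset of candidate controls
  is scored by the standard deviation, across samples, of its
  per-sample reference value; the most stable subset wins, with ties
  going to the larger subset, then lexicographic order. Selection can
  be scoped per experiment (default) or per cell line.
* **Welch degenerate cases.** Both groups constant with equal means
  gives p = 1; constant with unequal means gives p = 0 (the limit of
  the statistic); fewer than two determined replicates in either
  condition flags the feature not-evaluable rather than producing a
  number.
* **Boruta.** Importance is the Z-scored out-of-bag permutation
  importance (mean accuracy decrease over its standard error), the
  measure of the classic Boruta implementation. In-bag impurity
  importance is unsuitable for the hit test: the strongest
  chance-correlated noise feature in a 50-feature screen beats a
  re-drawn shadow maximum persistently and ends up confirmed far above
  the nominal rate. For the same reason one shuffled shadow is drawn
  per *original* feature each iteration — rejected features leave the
  forest, but the shadowMax bar keeps the original p-way selection
  burden rather than collapsing as features are rejected. Hits are
  tested after every iteration against Binomial(iterations, ½),
  two-sided with Bonferroni correction over the currently undecided
  features (α = 0.05); decisions are final, survivors at `max_iter`
  are tentative, and tentative features are passed to the Spearman
  filter by default (`include_tentative = FALSE` restricts to
  confirmed). Forests use 500 trees and balanced class weights.
  Gini ranking (`rank_gini()`) retains impurity importance, as that is
  what a "Gini importance ranking" means.
* **Splits.** The stratified 70:30 split fixes the total training size
  at `round(0.7 n)` and allocates it to label strata by largest
  remainder, so every stratum is within one sample of proportionality
  — e.g. 405 patients always split 284/121 regardless of how an odd
  median split sizes the strata.
* **Quantile cut-offs** use linear interpolation (R type 7), fixed so
  thresholds are reproducible across platforms; classification is
  strict (score > cut-off), so ties and degenerate all-equal scores
  fall to normoxic — conservative hypoxia calls.
* **Interaction test.** The p-value is a likelihood-ratio test of the
  interaction term; at realistic within-stratum event counts (a few
  dozen) the LRT is better calibrated than the Wald test, which is
  also reported. Degenerate designs (constant arm or label, zero
  events) return flagged fits rather than numbers.
* **Determinism.** All randomness flows through one seed: generators
  and forests derive fixed sub-seeds from it, and reruns with the same
  configuration are byte-identical.

## Problem sizes used in the checks

The test suite validates the chain at the generator's default sizes
(384 features, 400-patient cohorts, 190–400-patient trials), with
replication chosen to keep each property estimable: 1,000 random
instances for the Welch and Spearman oracle comparisons, 100 random
tables for normalisation invariance, 20 null screens for calibration,
5 seeds for Boruta recovery and end-to-end signature recovery, 200
replicates for hazard-ratio recovery and CI coverage, 1,000 null
trials for interaction type-I error, and 100 trials for the planted
treatment-benefit power analysis.

## Limitations

The anchor signature is a configuration input: choosing *which*
published mRNA signature anchors the labels (a model-selection step
over external cohorts in real studies) is out of scope. NanoString or
sequencing platform normalisation is accepted as already done —
matrices enter as log2 values. The qPCR module does not model
amplification efficiency or standard curves. Survival modelling covers
proportional hazards only: no competing risks, time-varying effects or
diagnostics beyond convergence flags. And synthetic recovery, however
clean, says nothing about the biological validity of any particular
signature in real tumours — that requires external cohorts.
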