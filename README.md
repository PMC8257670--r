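# hypomir

Derivation and validation of hypoxia-associated miRNA expression
signatures for tumour classification, aimed at translational
radiobiology groups building predictive biomarkers for
hypoxia-modifying therapy.

Tumour hypoxia causes radioresistance; hypoxia-modifying treatment
(e.g. carbogen–nicotinamide with radiotherapy) mainly benefits patients
whose tumours are actually hypoxic. `hypomir` implements the full
derivation chain for a miRNA signature that makes that call, and the
survival analyses that test whether it predicts treatment benefit:

1. **Seed discovery** — ΔΔCt analysis of qPCR array-card data from cell
   lines cultured in normoxia and hypoxia: per sample,
   ΔCt = Ct(feature) − reference(endogenous controls); per feature,
   ΔΔCt = mean ΔCt(hypoxia) − mean ΔCt(normoxia) and
   FC = 2^(−ΔΔCt). Features with Welch p < 0.05 and FC > 1.0 are
   *induced*; miRNAs induced in ≥ 2 cell lines at severe hypoxia become
   seeds. Detection-limit exclusion (Ct ≥ 30 in all replicates) and
   stability-based endogenous-control selection included.
2. **Supervised selection** — a development cohort is labelled
   hypoxic/normoxic by an mRNA anchor signature (mean log2 expression,
   median cut-off); the Boruta shadow-feature algorithm selects the
   seed miRNAs predicting that label; a Spearman/FDR filter against the
   continuous anchor score assigns signs.
3. **Signed scoring** — score = mean(positive miRNAs) − mean(negative
   miRNAs) on log2 expression, dichotomised at a median or
   upper-quartile cut-off (transferable between cohorts as a stored
   threshold).
4. **Validation** — Cox proportional-hazards prognosis, within-stratum
   treatment benefit (HR of the experimental arm among
   signature-hypoxic patients) and a treatment-by-hypoxia interaction
   test (likelihood ratio), plus Kaplan–Meier curves and Mann–Whitney
   marker-association tests.

A synthetic-data module generates every input with recorded ground
truth — qPCR plates with planted hypoxia-induced miRNAs, a cohort whose
latent hypoxia state drives anchor mRNAs, signature miRNAs and
survival, and a two-arm trial with a planted treatment-by-hypoxia
interaction — so the whole chain is testable without any external
download. The published 14-miRNA bladder cancer hypoxia signature
(7 up, 7 down) ships as a built-in fixture
(`published_mirna_signature()`).

## Worked example

```r
library(hypomir)

cfg <- run_config(simulation_config(seed = 1))
res <- run_pipeline(cfg)

res$derivation$signature
#> Gene signature 'mirna-hypoxia' (derived)
#>   positive (up):  7 features
#>   negative (down): 7 features

attr(res$derivation$signature, "boruta")
#> Boruta run: 17 iterations
#>   confirmed: 14  tentative: 0  rejected: 14
```

The simulated screen finds 30 seed miRNAs induced in ≥ 2 cell lines;
Boruta confirms 14 of them against the anchor labels and rejects the
16 that are induced in vitro but carry no signal in tumours; the
Spearman filter signs all 14 — exactly the planted 7 up / 7 down
signature. Validation in the simulated 190-patient trial then asks the
clinical question: does the experimental arm help the patients the
signature calls hypoxic?

```r
res$validation$OS$benefit_hypoxic
#> Cox proportional-hazards fit (n = 48, events = 32)
#>       term   coef    hr ci_low ci_high      p  test wald_p
#>  armRT+CON -0.736 0.479  0.232   0.989 0.0421 score 0.0465

attr(res$validation$OS$interaction, "interaction_p")
#> [1] 0.09856558
```

Within the hypoxic stratum the experimental arm halves the hazard
(HR 0.48, 95% CI 0.23–0.99, log-rank p = 0.042) — recovering the
planted benefit (true HR 0.45) — while the normoxic stratum shows
none; at this trial size the interaction test is borderline
(p = 0.099), the expected behaviour for ~190 patients with a quarter
of them hypoxic.

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R` (`simulate` and `run-all` subcommands
over a YAML config). See the vignette
(`vignettes/hypoxia-mirna-signatures.Rmd`) for the model, parameter
meanings and numerical conventions.

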