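# SomaticSexBias

Three-stage detection of sex-biased somatic genomic features in cancer
cohorts, with a synthetic-cohort generator for calibration and power
studies.

## The problem

Pan-cancer cohorts mix tumour subtypes with wildly different mutation
rates, unequal sample sizes and unequal sex ratios. Asking "is this
genomic feature different between male- and female-derived tumours?"
naively produces artifacts: a subtype that is both over-represented and
male-enriched will imprint its molecular profile on any marginal
male-female comparison. `SomaticSexBias` implements a vetting funnel for
sex-bias claims across driver mutation frequencies, SNV density
(mutations/Mbp, overall/coding/non-coding), chromosome and genome
instability (percent gained/lost/altered), gene-level copy number
aberrations, tumour clonality and mutation timing (truncal variant
fractions), and mutational-signature presence and activity (SBS/DBS/ID
classes), on the autosomes only.

## The method

For each feature and scope (pan-cancer, and each tumour subtype with
n ≥ 15):

1. **Univariate screen.** Continuity-corrected proportion test (binary
   features) or Mann–Whitney U test with the Hodges–Lehmann shift
   Δ = median{ xᵢᴹ − xⱼᶠ } (continuous features), with
   Benjamini–Hochberg adjustment inside analysis-specific FDR families;
   candidates at *q* < 0.1. Signature activity additionally requires a
   Kolmogorov–Smirnov *p* < 0.1.
2. **Covariate-adjusted model.** Logistic regression for binary
   candidates; linear regression on Yeo–Johnson-transformed values for
   continuous candidates, with λ chosen by profile likelihood on a grid
   over [−2, 2]. Covariates (age, ancestry, subtype for pan-cancer,
   SNV density for signature models) pass availability (<15% missing),
   variability (≥2 levels) and collinearity (|r| ≤ 0.9) screens; sex is
   coded female → male. Sex-term Wald *p*-values are BH-adjusted;
   significance at *q* < 0.1.
3. **Down-sampling robustness.** Pan-cancer findings: every subtype is
   repeatedly drawn to the median subtype size with replacement.
   Sex-imbalanced scopes (>60% one sex): the larger sex is repeatedly
   drawn down to the smaller sex's count. A finding is rejected when the
   95% percentile interval of the resampled male−female difference
   overlaps 0, or when the median resampled *p* exceeds 0.05. Findings
   are then refit in extended models including tumour stage and grade.

A finding that survives all three stages is **confirmed**; an extended
model *q* in [0.1, 0.2) leaves it **trending**.

Because the consortium data the method is designed for are controlled
access, the package ships a synthetic-cohort generator
(`simulateDataset`) that emulates the shape of those inputs with
configurable *planted* sex effects, recorded in a truth table so that
recovery, error control and confound rejection are all testable offline.

## Worked example

```r
library(SomaticSexBias)

cfg <- pipelineConfig(demoSimulationConfig(nPerSubtype = 60),
                      reps = 100, chromLevel = FALSE)
rep <- runPipeline(cfg, seed = 11)
rep
```

```
SexBiasReport
  stage 1: 5148 comparisons, 64 candidates (q < 0.1)
  stage 2: 64 fits, 60 significant
  stage 3: 60 down-sampling verdicts (58 pass)
  findings: confirmed=40, rejected=17, trending=7
```

The demonstration configuration is a 10-subtype cohort with planted
pan-cancer effects at the magnitudes reported for real whole-genome
cohorts: a driver mutated in 13% of female vs ~31% of male donors
(log-OR = log 3), a 1.5× male mutation-load multiplier, polyclonality of
26% (male) vs 80% (female), an SBS1-like signature present in 88% vs
97%, and a male excess of chromosome-7 gains. `findingsTable(rep)` lists
each finding with its stage-1 effect and *q*, stage-2 sex coefficient
(positive = male-dominated) and *q*, down-sampling verdicts and final
status; `truthComparison(rep)` scores the run against the planted truth.
At this reduced example scale the mutation-load and chromosome-7 effects
do not always survive the funnel (power returns at the default
2,000-donor scale):

```r
subset(findingsTable(rep), scope == "pan-cancer")
```

```
         feature_id      scope    status       q1       q2 sex_coefficient
1       driver_DRV1 pan-cancer confirmed 3.61e-06 3.37e-06          1.0043
11       polyclonal pan-cancer confirmed 1.08e-31 2.31e-25         -2.1015
44       truncal_SV pan-cancer confirmed 9.50e-59 4.94e-47          0.2713
55 sig_SBS1_present pan-cancer confirmed 8.83e-05 2.72e-05         -1.3631
```

(The polyclonality and SBS1 coefficients are negative: those planted
effects favour female donors.)

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/sexbias-pipeline.R`:

```sh
Rscript inst/scripts/sexbias-pipeline.R --stage run-all \
    --config my-config.yaml --seed 1 --outdir out/
```

writing the simulated dataset (TSV; segments BED-like, 0-based
half-open), all stage tables and a run manifest. See
`vignettes/methods.Rmd` for the statistical model, the generator's
assumptions and its limitations.
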