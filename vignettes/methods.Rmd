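---
title: "Detecting sex-biased somatic genomic features: models and methods"
author: "SomaticSexBias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-biased somatic genomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SomaticSexBias)
```

## The problem

Male- and female-derived tumours differ in incidence, aggressiveness and
outcome, and part of that difference is molecular: driver genes mutated at
different frequencies, different somatic mutation loads, different copy
number aberration (CNA) burdens, different subclonal architectures and
different mutational-signature activity. Detecting such sex-biases in a
pan-cancer cohort is statistically delicate. Tumour subtypes differ by
orders of magnitude in mutation rate and are unevenly represented; sexes
can be badly imbalanced within a subtype; and clinical covariates (age,
ancestry, stage, grade) are partially missing and partially confounded
with sex. A naive comparison finds "sex effects" that are really subtype
composition effects.

`SomaticSexBias` implements a three-stage statistical framework for this
problem, restricted throughout to the 22 autosomes (sex chromosomes are
excluded by design, as their copy number and variant calls are not
comparable between the sexes) and to non-sex-specific tumour subtypes.

## The three stages

**Stage 0 — feature derivation.** Raw-style inputs (binary driver event
calls, coding/non-coding SNV counts, ploidy-adjusted gain/loss segments,
subclonal cluster counts, truncal/subclonal variant counts per class,
per-signature attributed mutation counts) are reduced to per-donor
features: mutation densities in mutations/Mbp (overall, coding,
non-coding, with non-coding size defined as autosome minus coding so the
two contexts partition the genome); percent chromosome/genome gained,
lost and altered (aberrant basepairs over chromosome or autosome size;
gain and loss intervals are disjoint by construction so altered = gained
+ lost); gene-level gain/neutral/loss calls (majority-overlap rule by
default: a gene is called when more than half its length is covered, an
exact 50/50 tie is neutral — whether consortium pipelines used
any-overlap or majority-overlap is not documented, so the rule is
configurable); a polyclonality indicator (more than one subclonal
cluster); truncal variant fractions per class (donors with zero variants
of a class are excluded — 0/0 carries no timing information); and per
signature a "signature-positive" indicator (any attributed mutations)
plus, among positive donors, the fraction of the donor's class total
attributed to the signature. Donors whose class total is zero are
excluded from that class's signature features.

**Stage 1 — univariate screening.** Every feature is tested for a sex
difference in every eligible scope: pan-cancer and each tumour subtype
with at least 15 donors contributing values. Binary features use the
two-sample proportion test with Yates continuity correction (identical
to the continuity-corrected chi-squared test on the 2x2 table; signature
presence is reported under the chi-squared label, the convention for
that analysis). Continuous features use the Mann-Whitney U test — exact
for small tie-free samples, tie-corrected normal approximation otherwise
— accompanied by the Hodges-Lehmann location shift (the median of all
male-minus-female pairwise differences) and its rank-inversion 95%
confidence interval. Signature activity additionally gets a two-sample
Kolmogorov-Smirnov comparison; because "significant or trending" has no
printed threshold, activity candidates are retained only when the KS p
is below a configurable 0.1. p-values are Benjamini-Hochberg adjusted
within analysis-specific FDR families (drivers per scope; clonality in
one family across scopes; densities per mutation context with pan-cancer
and subtype p-values pooled; instability per scope over gained, lost and
altered together; gene CNAs per scope and direction; signature presence
and activity per scope). Candidates are flagged at q < 0.1.

**Stage 2 — covariate-adjusted modelling.** Each candidate is refit with
covariates: logistic regression for binary features, linear regression
for continuous features after a Yeo-Johnson transform

$$y^{(\lambda)} = \begin{cases}
((y+1)^\lambda - 1)/\lambda & \lambda \ne 0,\ y \ge 0\\
\log(y+1) & \lambda = 0,\ y \ge 0\\
-((-y+1)^{2-\lambda} - 1)/(2-\lambda) & \lambda \ne 2,\ y < 0\\
-\log(-y+1) & \lambda = 2,\ y < 0
\end{cases}$$

whose power $\lambda$ is selected by maximising the Gaussian profile
log-likelihood (including the Jacobian term) over a fixed grid
$[-2, 2]$ in steps of 0.01. The grid makes selection deterministic; the
bounds cover standard use of the power family. $\lambda$ is selected
once per model on the pooled outcome (both sexes together), so the
transform cannot itself encode a sex effect, and it is recorded in the
fit result. Numerically the positive branch is evaluated as
`expm1(lambda * log1p(y)) / lambda`, which is algebraically identical to
the printed form but continuous to machine precision as
$\lambda \to 0$ (and likewise at 2).

Covariates are screened per model: dropped when 15% or more of values
are missing in scope, when fewer than two levels remain after
complete-case filtering, or when their design columns correlate above
0.9 in absolute value with an earlier covariate's. Sex is mandatory and
coded female → male, so a positive coefficient always means
male-dominated bias. Categorical covariates are treatment-coded against
their most frequent level. Tumour subtype enters only pan-cancer models;
overall SNV density enters every mutational-signature model, absorbing
the tendency to attribute more signatures in SNV-dense samples. The sex
term's two-sided Wald p-values are BH-adjusted within the stage-1
family; significance is q < 0.1. A perfectly (or quasi-) separated sex
contrast is flagged as non-converged (an astronomical sex coefficient or
standard error; separation confined to a nuisance covariate level is
tolerated) and excluded from adjustment rather than pushed through
penalised likelihood, keeping inference comparable across features.

**Stage 3 — down-sampling robustness and extended models.** Two
resampling probes attack the covariate imbalances that most often
manufacture spurious pan-cancer sex effects.

* *Subtype balance* (pan-cancer findings): each repetition draws every
  subtype down (or up) to the median subtype sample size with
  replacement — the lower median for an even subtype count, so the
  target is an attainable size — irrespective of sex, preserving each
  subtype's internal sex composition while equalising subtype weights.
* *Sex balance* (any finding whose scope has one sex above 60%): each
  repetition resamples the larger sex with replacement down to the
  smaller sex's count. The smaller sex is kept whole by default; the
  printed rule ("down-sample to the smaller number of samples with
  replacement") is ambiguous about whether the smaller sex is also
  resampled, so a `both` mode is available.

Per repetition the male-female difference (in proportion for binary
features, in median otherwise) and the univariate p-value are recorded;
10,000 repetitions is the publication-grade default. A finding is
rejected when the empirical 2.5-97.5 percentile interval of the
difference distribution overlaps 0 (closed containment: a bound exactly
at 0 rejects, the conservative reading) or, failing that, when the
median down-sampled p exceeds 0.05. Resampling with replacement
necessarily creates ties, so the per-repetition Mann-Whitney p is the
tie-corrected normal approximation — the branch the exact test would
defer to anyway. Findings with no applicable probe pass by default.

Each vetted finding is also refit as an *extended model* with tumour
stage and grade added. These covariates are exempt from the missingness
screen — including them despite heavy missingness is the point — at the
documented cost of up to ~50% data loss under complete-case filtering.
A finding is confirmed when its extended q stays below 0.1, demoted to
"trending" for q in [0.1, 0.2), and rejected beyond that; findings whose
extended model is not estimable fall back to the core-model verdict.

## The synthetic-cohort generator

No public generative model exists for consortium-style somatic data, so
every distributional choice in the generator is an explicit stand-in,
chosen for shape realism and parameter interpretability rather than
biological fidelity:

* Subtype sample sizes are honoured exactly; sex, age (normal, truncated
  positive), ancestry, stage and grade are sampled per donor, with
  completely-at-random missingness — the "<15% missing" inclusion rule
  concerns availability, not mechanism, so MCAR suffices.
* Driver events are Bernoulli with planted effects on the log-odds
  scale; SNV totals are negative binomial (over-dispersion is typical
  of mutation burden) with a multiplicative planted effect; coding
  counts are binomial within the total at the genome's coding fraction.
* Segments: per donor and chromosome at most one gain and one loss,
  Beta-distributed length fractions, losses placed in the gap left by
  the gain so calls never overlap. Planted effects shift event
  probabilities additively.
* Clonality is Bernoulli per donor with log-odds planted effects;
  polyclonal donors get 2 + Poisson clusters. Timing totals are
  negative binomial; truncal fractions are Beta around the class
  parameter, forced to 1 for monoclonal donors (a tumour with a single
  clone has nothing subclonal).
* Signatures: negative-binomial class totals, Bernoulli presence,
  Dirichlet-multinomial attribution over the present signatures, so
  class totals are conserved exactly. A donor with no present signature
  in a class gets a zero class total (a decomposition always attributes
  to something, so "mutations with no signature" cannot occur).

Planted magnitudes live on the scale the stage-2 models estimate (log
odds for binary features, log multipliers for counts — so zero always
encodes a null — absolute shifts for fractions), which makes recovery
tests direct. One master seed expands into per-component child seeds
through a fixed affine splitting rule (`childSeed`), so each component
is reproducible independently of which others are enabled.

The demonstration configuration plants magnitudes at the scale of
reported pan-cancer sex-biases: a driver mutated in 13% of female vs
~31% of male donors (log-OR = log 3); a 1.5x male mutation-load
multiplier; polyclonality 26% (male) vs 80% (female); an SBS1-like
signature present in 88% vs 97%; an ID5-like +0.03 activity shift; a
chromosome-7 gain frequency of 0.51 (female) vs 0.70 (male), which
reproduces median percent-chromosome-7-altered values of ~0.4% vs ~5%;
and a +0.18 truncal-SV fraction shift. Everything else is null.

What the generator does *not* emulate: sequence-level context (no reads,
no trinucleotide spectra — attribution counts are drawn directly),
correlated missingness, subtype-specific covariate structure, within-
donor correlation between data types beyond what the planted effects
induce, and batch or quality artefacts. Passing tests therefore
demonstrate that the *statistics* behave as designed under a controlled
generative model, not that any particular biological claim about real
tumours is reproduced.

## Numerical and design choices

* Coordinates are 0-based half-open on disk (BED convention) and 1-based
  closed in memory (the GRanges convention); conversion happens only at
  the I/O boundary.
* The screening and down-sampling engines use direct implementations of
  the tie-corrected normal-approximation Mann-Whitney p and the Yates
  chi-squared p that agree with `wilcox.test` / `prop.test` to 1e-12
  (asserted in the test suite); the per-call overhead of the formula
  interfaces dominates large replicate studies otherwise.
* The Hodges-Lehmann shift is computed literally as the median of all
  pairwise differences whenever the pair count allows; the root-finding
  estimate some implementations use deviates in the far decimals.
* Lambda grid ties are broken towards the smaller lambda (first grid
  point); constant outcomes are an error, not a silent lambda = 1.
* Down-sampled medians of zero-inflated features (a per-chromosome
  percent-altered where fewer than half of donors carry any aberration)
  are degenerate at 0 and can never exclude 0: such features are only
  detectable through this framework when the aberration is common
  enough for both sex medians to be positive, which is also the regime
  the published per-chromosome findings occupy.
* `medianSubtypeSize` uses the lower median for an even number of
  subtypes; a configurable fixed target is available.

## Problem sizes used by the test suite

The suite exercises the framework at desk scale, chosen once: error
control on 1,000 replicate all-null cohorts of 20 subtypes x 50 donors
(~250 stage-1 comparisons each, 200 down-sampling repetitions);
planted-effect recovery on 100 replicate 2,000-donor cohorts; confound
rejection on 20 replicates of a 780-donor adversarial design; and
down-sampling mechanics at 500-10,000 repetitions. Statistical oracles
(exact-test enumeration, brute-force step-up BH, per-basepair interval
accumulation) run on small inputs where exhaustive computation is exact.

## Known limitations

Rank-based screening plus a Gaussian working model after a power
transform is robust but not optimal for heavy-tailed or zero-inflated
features; robust regression would be a natural extension. Extended
models lose up to half the data to complete-case filtering and
correspondingly lose power. The down-sampling probes target subtype and
sex imbalance specifically; other confounders (ancestry structure,
batch) are handled only through the regression covariates. Pan-cancer
conclusions always depend on the subtype mix of the cohort at hand.
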