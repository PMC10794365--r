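---
title: "Viewing reaction time diagnostics: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viewing reaction time diagnostics: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrtdx)
```

## The measurement problem

Viewing reaction time (VRT) is an indirect, latency-based measure of sexual
interest: people look longer at sexually salient stimuli, even when
instructed only to rate attractiveness as quickly as possible. In the
paradigm this package scores, computer-generated nude images of males and
females in Tanner developmental stages 1-5 (10 categories, 8 trials each)
are rated on a 1-4 attractiveness scale; the latency between stimulus onset
and the rating is recorded, and trials without a response within 5000 ms
are recorded as missing. The target population is help-seeking men outside
the judicial system (the "Dunkelfeld"), where a valid indirect measure of
pedohebephilic interest would be clinically useful and no offense-record
criterion is available.

## From latencies to the VRT index

Raw latencies confound sexual salience with general response speed, which
differs markedly between individuals (and, in the population this pipeline
targets, between diagnostic groups). `ipsatize()` therefore standardizes
each participant's latencies against their own distribution:

$$z_{it} = \frac{\mathrm{RT}_{it} - \bar{\mathrm{RT}}_{i}}{s_i},$$

with mean and SD (n-1 denominator) over all of participant $i$'s valid
trials pooled across categories. Ipsatization as within-person
*z*-standardization (rather than mean-centering only) is a design choice:
it puts every participant's index on a "within-person SD" scale, which is
what makes the interaction regression's intercept interpretable as "the
undiagnosed, non-offending group sits about one within-person SD below
zero". Mean-centering is available via `center_only = TRUE`.

The index itself (`vrt_index()`) is the *maximum* mean (ipsatized) latency
over the six pre-/peripubertal categories (Tanner 1-3, either sex) minus
the maximum over the four postpubertal categories (Tanner 4-5). Maxima,
not averages, because averaging across stimulus sexes would dilute the
signal with the non-preferred sex: a heterosexual teleiophile is slow only
on adult-female stimuli, and pooling adult males in would pull the adult
aggregate toward the overall mean. Positive index: relatively longer
viewing of child stimuli. Ties between category means are broken
deterministically (males before females, ascending Tanner stage) and the
winning categories are recorded; ties have measure zero on continuous data
but occur after mean-imputation.

Two orders were possible for imputation and ipsatization; the package
imputes raw latencies first and ipsatizes after, because all three
imputation schemes are defined on raw reaction times within age-by-sex
category. This is stated here because the choice is consequential (the
ipsatization denominator includes imputed trials) and not self-evident.

## Eligibility screening

`apply_eligibility()` implements the data-quality filters: more than 10%
missing trials (strictly greater — a participant at exactly 8/80 is
retained; the boundary behavior is a declared convention, configurable via
`threshold`), any stimulus category with zero valid trials (the index's
maxima would be undefined), VRT testing more than 28 days from the
clinical interview (4 weeks taken as 28 days; unknown intervals are
retained by default since exclusion should rest on documented intervals),
and an unknown clinical diagnosis (which bars inference). Reasons
accumulate rather than short-circuit, matching how such screens are
reported. A configurable anticipatory-response floor (`min_latency_ms`)
is exposed but off by default; the paradigm itself imposes none.

## Missing-latency imputation and pooling

Non-responses at 5000 ms make missingness part of the paradigm.
Three schemes are implemented (`impute_individual_mean()`,
`impute_regression()`, `impute_pmm()`); the individual category mean is
the reference method, the others feed a sensitivity grid. Both predictive
schemes model a participant's category mean from their other nine category
means over the whole sample; PMM performs type-1 matching (predicted-to-
predicted distance) with `k_donors = 5` and draws one of the nearest
observed values per missing trial, `m = 5` times. `k = 5` and type-1
matching are the conventional PMM defaults; `m = 5` follows standard
multiple-imputation practice for this design. "With individuals as
separate classes" is implemented as restricting the donor pool to the
recipient's own observed trials in that category — one defensible reading
of an under-specified phrase, flagged here deliberately. Multiple
imputations are combined by Rubin's rules — `pool_rubin()` uses
$T = W + (1 + 1/m)B$ and the Barnard-Rubin small-sample degrees of
freedom — before any equivalence bound or verdict is derived, so bounds
always come from pooled quantities.

Imputation operates at trial level (every missing trial receives a value)
rather than replacing category means wholesale; this keeps per-category
trial counts meaningful downstream.

## Hypothesis 1: interaction regression with SESOI equivalence

`fit_interaction_model()` regresses the index on dummies for the clinical
diagnosis (P), prior child sexual offenses (CSO), prior CSAM use, and all
products. The scientific claim is conjoint: a positive diagnosis effect
*and* negligible modulation by offense history. The second part cannot be
established by failing to reject zero, so the package implements the
composite-null equivalence logic:

* the smallest effect size of interest is anchored on the diagnosis
  effect itself: the region of negligible interactions is
  $(-\mathrm{LL}_{95}(\beta_P),\; 0]$, i.e. an interaction is
  non-negligible if it could cancel the diagnosis effect or increase it;
* each interaction's 90% CI is compared to that region (equivalence at
  $\alpha = 0.05$): an upper violation is $\mathrm{UL}_{90} > 0$ (strict),
  a lower violation is $\mathrm{LL}_{90} \le -\mathrm{LL}_{95}(\beta_P)$
  (inclusive). The inclusive/strict asymmetry follows the rule's published
  footnote arithmetic, which resolves an ambiguity in its prose statement
  (the "negative of the lower limit" reading is the one consistent with
  the printed marks).

All CIs use t quantiles on the residual df; this reproduces published
90% intervals from printed coefficients and SEs to four decimals, which
normal quantiles do not. No multiplicity adjustment is applied across the
three interaction verdicts (none is part of the procedure). If the
diagnosis effect's 95% CI fails to exclude zero, the equivalence region is
empty and `sesoi_bounds()` warns rather than inventing a region.

## Hypothesis 2: subgroup ROC equivalence

`roc_comparison()` builds empirical ROC curves of the index against the
diagnosis separately for participants with and without any CSO/CSAM
history. AUC is the Mann-Whitney pair probability (ties one-half);
bootstrap CIs are stratified percentile intervals with 2000 replicates by
default (the resampling scheme is a package choice — stratification
guarantees both classes in every resample); the AUCs are compared with the
unpaired DeLong test using placement-value variances and
Welch-Satterthwaite fractional degrees of freedom (total n minus one per
curve, the convention of the standard ROC software for this test); and
equivalence is declared only if the 95% CI of the offense-history group
encompasses the 90% CI of the no-history group (closed-interval
convention). The Youden-optimal cutoff is reported for the overall sample,
with thresholds at midpoints between adjacent observed scores and ties
resolved toward higher specificity. Score orientation throughout: higher
index predicts the diagnosis.

## Hypotheses 3-4 and descriptive machinery

Criterion validity uses Spearman's rho on pairwise-complete observations
(instrument subsamples overlap only partially), with p-values from the t
approximation on n-2 df — chosen over exact permutation p's because the
instrument scores are heavily tied ordinal sums. `chisq_yates()` and
`welch_t()` provide the 2x2 and two-sample comparisons used in cohort
description; the Yates correction is the default because it is the variant
that reproduces the published group-comparison statistics from their
printed counts. `icc_oneway()` implements the "classical" one-way
random-effects ICC(1) with an F-based CI and returns a not-calculable
result (rather than an error or a zero) when ratings show no variance.

## The synthetic cohort generator

No clinical VRT data are publicly deposited, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
and the defaults *are* the study conditions: n = 282 (68 without / 214
with the diagnosis), per-group per-category latency and rating means/SDs
as published for that sample, censoring at 5000 ms, and offense-history
prevalences (30% CSO, 72% CSAM, 17% neither). Only marginal prevalences
are published; the joint diagnosis-by-offense cell table is derived once
from the marginals by inclusion-exclusion with the diagnosis rate applied
proportionally within offense cells.

Participant-level structure is an explicit assumption, since only marginal
summaries are published:

* a general-speed random intercept, SD 300 ms;
* a "child-shift" random effect on all Tanner 1-3 categories, SD 550 ms,
  chosen once so that the generator's raw-index spread lands in the
  neighborhood of the published index SDs (about 560-660 ms) — this is
  what gives individuals within a group different true indices, and it is
  the latent deviance that criterion scales correlate with;
* Gaussian trial noise at the published category SD, floored at 150 ms
  (a log-normal option exists because real RT distributions are
  right-skewed; the Gaussian default is the minimal model consistent with
  published means/SDs);
* 3% additional completely-at-random missingness on top of censoring
  (censoring alone produces almost no missing trials under Gaussian noise
  at these means; real non-response is mostly mechanism-free from the
  paradigm's viewpoint).

Criterion scores (`simulate_criteria()`) are generated through a Gaussian
copula on the rank of the latent deviance, with copula correlation
$2\sin(\pi\rho_s/6)$ so the *Spearman* correlation hits the requested
target, then binned uniformly into each instrument's observed integer
range. By default scores exist only for diagnosed participants with a CSO
history, mirroring the assessment design (and its n of about 50-65).

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: sequence and order effects, instruction
effects, within-person covariance across categories beyond a single
random intercept plus child shift (the published record contains no
category covariance), non-Gaussian RT shape under the default, and any
systematic relation between missingness and interest beyond censoring.
Parameter-recovery results on synthetic cohorts validate the *pipeline*,
not the clinical validity of the VRT.

## Numerical and testing choices

Problem sizes in the test suite are chosen to give stable Monte-Carlo
verdicts at interactive runtimes: 500 replicates for CI-coverage checks
(93-97% acceptance band at n = 282), 200 outer replicates with 1000 inner
resamples for bootstrap-coverage checks, 1000 replicates for
null-uniformity (Kolmogorov-Smirnov at 0.01), and a 20 000-participant
cohort to pin the generator-implied group contrast used as truth in
parameter recovery. Degenerate inputs fail loudly and early: zero latency
spread, fewer than two valid trials, one-class ROC input, empty
equivalence regions, and empty cohorts all raise informative errors
rather than propagating silently.

## Interfaces

This is an analysis package: the exported functions, `run_analysis()` with
`analysis_config()`, and `scripts/acceptance.R` are the interface; there
is deliberately no shell binary. `run_analysis()` executes the full
sensitivity grid (four imputation methods crossed with ipsatized and raw
bases, eight hypothesis-1 fits), the subgroup ROC comparison, and the
criterion correlation table, deriving every stage seed from one master
seed so reports are byte-identical across runs. It reports statistics
about cohorts; it never outputs, and must never be used as, an individual
diagnosis.

## Known limitations

The two published optimal-cutoff figures for the overall sample disagree
with each other (-0.5 with specificity 75.0%/sensitivity 86.4% in one
place, -0.3 with 82.7%/79.3% in another); neither is treated as ground
truth here, and the package simply reports its own Youden cutoff. Several
published descriptive chi-squares are not recoverable from their printed
counts (likely undocumented missingness); only the five reproducible rows
are used as fixtures. The adapted risk-instrument factor definitions
contain one internal inconsistency in the published record (a four-
component factor with a printed observed range of 0-3); the four-component
definition is implemented and the discrepancy surfaced in the scorer's
documentation.
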