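---
title: "Selection-rate-adjusted prevalence estimation for multi-phase screening studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-rate-adjusted prevalence estimation for multi-phase screening studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fasdprev)
```

## The estimation problem

Active case ascertainment studies of fetal alcohol spectrum disorder
(FASD) screen a whole school population in successive phases and give a
full diagnostic work-up only to the children who advance through every
phase.  In the design this package models, children pass through:

1. consent forms distributed to `n_invited` children, of whom
   `n_responded` families respond and `n_consented` consent;
2. a Phase I screen (growth, sentinel facial features,
   behavioural/learning history) completed by `n_phase1_assessed`
   children, of whom `n_phase2_selected` meet at least one criterion;
3. a Phase II neurodevelopmental assessment completed by
   `n_phase2_assessed` children, of whom `n_deficit2plus` show deficits
   (two standard deviations below the mean on a subtest) in at least
   two domains;
4. a biological-mother interview completed for `n_interviewed`
   children, which establishes the prenatal alcohol exposure history.

Suspected cases are confirmed only at a multidisciplinary case
conference at the very end, so the raw case counts (`n_fas`, `n_pfas`,
`n_arnd`) refer to much smaller denominators than the screened
population.  Dividing cases by the Phase I population would therefore
understate prevalence: children lost at each stage had, under the
design's assumptions, the same risk as those retained.

## The plug-in estimator

The estimator back-projects each case count through the selection
proportions of the stages its diagnosis requires.  FAS is diagnosable
from growth and facial criteria alone, without the maternal interview,
so its case rate is taken over children completing the
neurodevelopmental assessment:

$$\hat\pi_{FAS} = 1000 \cdot
  \frac{n_{sel}}{n_{P1}} \cdot \frac{k_{FAS}}{n_{P2}}$$

pFAS and ARND require a confirmed exposure history and hence the
interview:

$$\hat\pi_{cat} = 1000 \cdot
  \frac{n_{sel}}{n_{P1}} \cdot \frac{n_{def}}{n_{P2}} \cdot
  \frac{k_{cat}}{n_{int}}, \qquad cat \in \{pFAS, ARND\}$$

and total FASD is the sum of the three.  The identifying assumptions
are (i) attrition at every stage is independent of diagnostic status
(missing at random), and (ii) the Phase I criteria capture every true
case — a child screened out at Phase I is assumed not to be a case in
the main analysis.  Assumption (ii) is relaxed by the sensitivity mode
below.

```{r}
fx <- load_fixture("study_text")
estimate_all(fx$cascade, fx$dx, mode = "main")
```

The FAS and pFAS values reproduce the motivating study's printed
estimates (1.2 and 2.0 per 1000) exactly after one-decimal half-up
rendering.  The same chain yields 15.9 per 1000 for ARND and 19.2 in
total where the study prints 15.0 and 18.1; the exact variant behind
those two printed numbers (a different denominator, a simulation mean,
or a replicate median) is not recoverable from the study's main text,
so `run_full_report()` flags the discrepancy explicitly rather than
asserting either number.  The count set itself is also internally
inconsistent between the study's narrative (793 selected / 762
assessed) and its comparison table (817 / 786); the `study_text`
fixture uses the narrative values because they reproduce the printed
FAS and pFAS estimates, and the `study_table1` fixture ships the
alternative for sensitivity checking.

## Sensitivity analysis: cases among screen-negative children

The typically developing control children (TDCC) are screen-negative
children given the full assessment to provide normative data.  Finding
suspected cases among them contradicts assumption (ii), so the
sensitivity mode extrapolates the control-arm case rate over the
screen-negative fraction:

$$\hat\pi^{sens}_{cat} = \hat\pi_{cat} + 1000 \cdot
  \frac{k^{TDCC}_{cat}}{n_{TDCC}} \cdot \frac{N_{neg}}{n_{P1}}$$

The study does not state at which stage "screen-negative" is drawn, so
three bases are provided: children never selected into Phase II
(`phase1_negatives`), children never crossing the two-domain deficit
threshold (`pre_interview_negatives`, the default — these are the
children from whose ranks the TDCC were in fact drawn and the
definition whose result, 26.3 per 1000 for ARND, falls nearest the
study's printed 26.1), and children whose mothers were never
interviewed (`pre_conference_negatives`).  All three are reported side
by side by `run_full_report()`; they bracket the printed value:

```{r}
sapply(negative_bases(), function(b)
  render_per_1000(estimate_sensitivity(fx$cascade, fx$dx, "ARND", b)$per_1000))
```

The default control denominator is the 84 controls completing the
neurodevelopmental assessment; the post-exclusion 83 can be supplied
instead via `diagnosis_counts()`.

## Monte Carlo percentile confidence intervals

Analytic variance formulas for a product of three small-sample
proportions are awkward; the study instead simulated 100,000
prevalence replicates.  The resampling scheme and quantile convention
are not stated, so this package adopts the simplest construction
consistent with "simulated estimates of selection rates and
prevalence": each stage proportion $k/n$ is redrawn independently as
$X/n$ with $X \sim \mathrm{Binomial}(n, k/n)$, each case count is
redrawn the same way (or as $\mathrm{Poisson}(k)$ with
`resampling = "poisson_cases"`), the plug-in formula is re-applied,
and the interval is the nearest-rank 2.5th/97.5th percentile of the
replicates.  Draws come from a single seeded generator in a fixed
documented order (selection proportion, deficit proportion, FAS, pFAS,
ARND case counts, then control-arm counts and the screen-negative
fraction in sensitivity mode), so runs are bit-reproducible and all
categories share the same stage draws under a common seed.

```{r}
estimate_with_ci(fx$cascade, fx$dx, "FAS", "main",
                 mc_settings(n_reps = 100000, seed = 1))
```

This reproduces the qualitative behaviour of the printed intervals —
in particular the 0.0 lower bounds for FAS and pFAS, which arise
because a count with mean 3 (or 2) has a 2.5th percentile of zero.
The printed CI endpoints themselves depend on the unrecoverable exact
scheme and are deliberately never asserted; the test suite instead
checks properties: bit-reproducibility under a fixed seed, containment
of the point estimate, agreement of the replicate mean with the
closed-form product-of-means expectation, interval narrowing under
count scaling, and near-nominal coverage on synthetic cohorts.

## The synthetic cohort simulator

`generate_cohort()` draws child-level records with known true status
so the whole pipeline can be validated by parameter recovery: status
multinomial from per-1000 true prevalences; one collapsed binary
"meets any Phase I criterion" indicator (the three criterion groups
the field distinguishes — growth, facial, behavioural — affect who is
selected but not the estimator's arithmetic, which consumes only stage
totals); a two-domain deficit indicator; and independent Bernoulli
participation at every stage.  ARND-status children failing the
deficit threshold are counted as deferred and screen-negative,
matching the study design's treatment of deferred cases.

Defaults emulate the motivating study's cascade: participation 0.469
(response), 0.699 (consent), 0.949 (Phase I completion), 0.961
(Phase II completion), 0.409 (interview); true prevalences 1.2 / 2.0 /
16.0 per 1000; control-child positive rates 0.297 (Phase I) and 0.386
(deficit threshold), calibrated so that about 31% of assessed children
are selected and about 42% of Phase II completers cross the deficit
threshold.  Screening sensitivities for true cases default to 1
because that is the estimator's own identifying assumption; the study
reports no estimates of them, so these defaults are calibration
choices, not data.  What the simulator deliberately does *not* emulate
— continuous psychometric scores, facial measurements, diagnostic
disagreement at case conference, non-random consent — bounds what
passing tests show about real data: they validate the estimator under
its own assumptions, not the assumptions themselves.

```{r}
cfg <- cohort_config(n_children = 50000, seed = 42)
coh <- generate_cohort(cfg)
estimate_all(coh$cascade, coh$dx)
```

`recovery_experiment()` repeats this, reporting per-category relative
bias and CI coverage.  Under missing-at-random dropout the estimator
is consistent; making cases half as likely to be interviewed
(`interview_case_multiplier = 0.5`) forces the documented downward
bias:

```{r}
recovery_experiment(cohort_config(n_children = 50000, seed = 7), n_sim = 20)
```

## Numerical and design choices

* **Rounding.**  All internal arithmetic is unrounded; one-decimal
  half-up rounding (`round_half_up()`, with a 1e-9 nudge absorbing
  binary representation error) happens only at rendering, matching how
  the study prints percentages and per-1000 rates.  Base `round()`
  rounds half to even and does not reproduce printed tables.
* **Quantiles.**  Nearest-rank (the value at rank $\lceil qn \rceil$),
  the convention under which replicates $1..100$ give a 95% interval
  of $(3, 98)$.
* **Degenerate inputs.**  Zero denominators raise errors naming the
  stage; zero case counts propagate to exact-zero estimates and
  degenerate all-zero replicate vectors; a pooled SD of zero yields
  $t = 0$ for equal means and an explicit error otherwise; an ANOVA
  with no between- or within-group variance returns $F = 0$.
* **Group statistics.**  The case/control chi-squares use the
  uncorrected Pearson formula — the study's printed statistics match
  only without the Yates correction.  $t$, ANOVA and Tukey statistics
  are computed from summary statistics (n, mean, SD) because raw data
  are unavailable; printed $t$ values were computed on unrounded raw
  data and are therefore reproduced only approximately.
* **Problem sizes.**  The validation suite uses cohorts of up to
  100,000 children, 200 recovery replications with 2,000 Monte Carlo
  replicates per interval, and the full 100,000 replicates for the
  fixture intervals — sizes at which binomial Monte Carlo error is
  well below every tolerance asserted.

## Limitations

The estimator inherits the design's assumptions: no adjustment for
consent-stage self-selection, diagnostic misclassification at case
conference, or demographic weighting.  The ARND/total discrepancy with
the printed values, and the printed CI endpoints, remain open: they
depend on details of the original computation that the main text does
not specify.
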