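---
title: "Measuring multivariate vaccine equity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multivariate vaccine equity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxequity)
```

This vignette is the package's own account of its methods: the model
and its assumptions, the conventions that matter when comparing results
across tools, the choices made where the design was genuinely open, and
what the synthetic validation does and does not establish about real
survey data.

## Status derivation

Eleven binary outcomes are derived per child from the per-dose received
flags, the child's age in months, and an immunization schedule mapping
each antigen-dose to an eligibility age. The default schedule encodes a
Cambodia-style national program — BCG at birth, the DTP and OPV series
at 2, 3 and 4 months (the 6/10/14-week visits integerized to months),
MCV1 at 9 months. A child is *eligible* for a dose when `age_months`
is at or above the schedule age (closed lower bound: a child at exactly
the schedule age can be vaccinated).

Three rules deserve emphasis:

* **Per-antigen indicators mask underage children** (`NA`), they never
  count them as failures. This mirrors the analysis's single *fair*
  factor — being too young for a dose is an acceptable reason not to
  have it.
* **Age windows partition exhaustively**: ZERO applies below 12 months,
  FULL below 24 months, COMPLETE at 24 months and above. The boundary
  month 24 belongs to COMPLETE, making the windows non-overlapping.
* **FULL follows the literal definition** — all age-eligible,
  non-excluded doses received. MCV1 is excluded from FULL by default
  because supplemental catch-up campaigns deliver it far outside its
  schedule age; the exclusion set is configurable. A very young child
  eligible only for BCG is FULL with BCG alone.

Ingest never imputes: any missing covariate or dose flag rejects the
row with a reason (complete-case analysis, with a reported exclusion
tally). Education levels and district labels are data-driven
categories; wealth quintile stays ordinal for ranking but is
dummy-coded in every model.

## Ranking and the concentration-index family

All indices are built on weighted fractional ranks: after sorting by
the ranking variable, each child's rank is (cumulative weight before it
+ half its own weight) / total weight. Ties share their block's weight
midpoint, which keeps the weighted mean rank at exactly 0.5 and makes a
completely uninformative ranking give index 0 exactly — the tie rule is
load-bearing, not cosmetic.

The *composite* ranking orders children by the fitted probability of
the favorable outcome from a weighted logistic regression on the unfair
factors only. Logistic (rather than linear) regression respects the
binary outcome for ranking purposes; the decomposition deliberately
uses a different link (below). The fair factor is excluded from the
ranking model: the ordering is meant to reflect unfair drivers alone.

**Sign conventions are the main interoperability trap.** For adverse
outcomes (ZERO), the composite ranking uses the propensity of the
favorable complement (not being zero-dose), so the most disadvantaged
are first in every ranking, and the index itself is computed on the
complement. Algebraically this equals flipping the sign of the burden
index — the Wagstaff denominators exchange (1 − μ′ = μ) — so a
*positive* composite W always reads "burden concentrated among the
disadvantaged". Wealth-only indices keep the conventional sign
(negative = burden among the poor). This is why a near-zero, negative
wealth-only index can coexist with a large positive composite index for
zero-dose status: the two are answering differently-signed questions
about differently-built orderings. Reported prevalence `mu` is always
the outcome as recorded (the burden prevalence for ZERO).

The Wagstaff normalization W = C/(1 − μ) is used for the headline
index because it restores attainable ±1 bounds for binary outcomes and
weighs the extremes of the ranking; the Erreygers correction E = 4μC is
computed alongside (E = 4μ(1 − μ)W wherever W exists). When a stratum
has prevalence exactly 0 or 1 the Wagstaff index is undefined and
reported `NA` with a degenerate flag — never a fabricated zero — while
coverage is still reported.

### Uncertainty

The published applications of this methodology print 95% intervals
without stating the estimator, so two standard approximations are
offered. The default *convenient regression* regresses the transformed
outcome 2·var<sub>w</sub>(r)·h/μ on the rank with weights; the slope
equals C exactly, and its HC1 sandwich standard error is delta-scaled
by 1/(1 − μ) to W (treating μ as fixed). The *bootstrap* resamples
children with replacement (carrying their weights), recomputes ranks
within each resample, and takes the percentile interval; it is seeded
and reproducible. By default the bootstrap does not refit the
propensity model per resample — refitting (`refit = TRUE`) is costly
and conflates ranking-model uncertainty with index uncertainty; the
calibration study below therefore evaluates the bootstrap on the
wealth-only ranking, where the resampled statistic is complete.

### Absolute equity gap

The AEG is the difference in prevalence between the top and bottom
fifths of the ranking, in natural coverage units. Quintile boundaries
fall at cumulative weight 0.2/0.8; a child straddling a boundary is
assigned wholly to the side holding the midpoint of its weight mass —
a deterministic, weight-consistent rule. For adverse outcomes the gap
is computed on the favorable complement so it is positive when the
disadvantaged are worse off.

## Decomposition

The decomposition regression is a weighted **linear probability
model**, not a logit: the per-factor contribution formula
(β<sub>k</sub> x̄<sub>k</sub>/μ)·C<sub>k</sub> plus the residual
generalized-concentration term is exactly additive only under
linearity, and exact conservation (contributions reconstruct W to
machine precision, shares sum to 100) was judged more valuable than
link consistency with the ranking model; using different models for
ranking and decomposition is standard practice in this literature.
Dummy contributions are summed within each categorical factor; the fair
factor enters as the count of doses the child is still too young for,
grouped separately. Negative shares are reported as-is and flagged —
a factor can genuinely offset inequity — with no renormalization.

Two subtleties, established during testing and worth recording:

* Individual dummy contributions depend on the reference level; only
  the *total explained* share is invariant to reference choice, and
  that is what the test suite asserts.
* "Uninformative covariates give the residual ~100%" holds when the
  *decomposition* covariates are noise but the outcome has real
  structure along the rank. If the ranking itself is built from the
  same uninformative covariates, the finite-sample composite index is
  spuriously positive (the model ranks children by its own fitted
  noise) and that spurious inequity is attributed to the factors, not
  the residual. This upward bias of the self-ranked composite index
  under the null is real, documented, and shrinks with sample size —
  the test suite measures it at n = 2,000 versus n = 20,000. Composite
  indices from small strata should be read with this bias in mind.

## Stratified and trend analysis

District-level indices default to ranking by the *nationally* fitted
propensity, re-ranked within each district: the decomposition and model
fit are national-level constructs, and within-stratum re-ranking is the
minimal choice yielding well-defined district indices. A `refit` mode
re-estimates the model per district and flags failures as unstable —
useful at large district sizes, noisy below the default low-n floor of
25 (cells are flagged, never suppressed). District coverages aggregate
exactly (weighted by applicable weight mass) to national coverage, and
the tests assert this identity; district *indices* do not aggregate to
the national index — rank-based measures are not decomposable across
strata — and no such identity is asserted. Multi-survey analysis treats
each survey as an independent cross-section (no pooling, no
calendar-time model) and tracks coverage and the equity level 1 − W.

## The synthetic generator and what validation shows

Because the real microdata are registration-gated, validation rests on
a generator whose population truth is exactly computable. All
covariates are categorical, so the joint distribution lives on a finite
lattice (19 districts × 5 wealth quintiles × 3 education levels × sex ×
urban × insurance, with ages uniform on 0–59 months) and `ground_truth()`
enumerates it exactly: μ as the lattice-weighted outcome probability,
W and AEG from ranking lattice cells by the true propensity, with
straddling cells split fractionally (the population limit of the
finite-sample quintile rule). This enumerability is the decisive reason
the generator has no continuous covariates.

Each dose is received, when age-eligible, with probability
logistic(base + district effect + Σ factor effects − dropout·(dose − 1)).
Within a series the doses share one latent uniform draw
(`adherence = 1`), so dose sets are nested — a child with DTP3 has
DTP1–2 — while each dose's *marginal* probability stays exactly
logistic, which keeps both the series-monotonicity property and the
enumeration simple. Defaults were chosen once to emulate a 2014-era
Cambodia survey: per-dose marginals near 94% (BCG), 92/87/82% (DTP
series, base logit 2.4 with dropout 0.45), 80% (MCV1); a dominant
wealth gradient (±0.6 log-odds across quintiles) with education linked
to wealth through a transition matrix (correlation 0.5); small sex and
insurance effects; one remote district pair with a strongly negative
effect; gamma(4, 4) sampling weights. The three-survey bundle raises
base rates and relaxes gradients across "years" to exercise the trend
harness qualitatively. One scale tension in the published reference
values is worth knowing: printed composite indices near 0.06 and
quintile gaps above 20 percentage points cannot both hold under the
definitions above, so the defaults target the *gap* scale; synthetic
composite W values are correspondingly larger than the printed ones.

What the generator does *not* emulate: DHS cluster/stratum sampling
design (weights are independent of covariates, so design effects and
weight–outcome correlation are absent), dose dates and timeliness,
recall error and proxy reporting, migration, and any continuous
covariates. Passing tests therefore establish correctness of the
estimators and their calibration under independent weighted sampling —
not robustness to clustered designs or measurement error.

Validation problem sizes, chosen to make Monte-Carlo noise negligible
relative to the tolerance asserted: oracle equivalence on 1,000 random
micro-instances (n ≤ 8) to 1e-10; decomposition conservation on 100
datasets of n = 600 to 1e-8; parameter recovery at n = 50,000 within 3
standard errors of the enumeration truth with the active factor's share
above 90%; bootstrap calibration over 500 replicates of n = 2,000 with
200 resamples, asserting 95 ± 3% coverage.

## Known limitations

* Variance estimators ignore the survey's cluster/stratum design
  beyond the weights; with real DHS data, design-effect-adjusted
  intervals would be wider.
* The convenient-regression SE treats μ as fixed; the bootstrap default
  treats the composite ranking as fixed. Composite-index intervals for
  small strata inherit both approximations plus the null bias above.
* The decomposition is descriptive: contributions are associations of
  correlated factors under a linear approximation, not causal effects,
  and should not be used to target factor-specific interventions.
* The ranking model is a main-effects logistic; propensity
  misspecification (interactions among unfair factors) changes the
  ordering and hence the index, a dependence shared by all
  model-ranked concentration indices.
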