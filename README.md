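# vaxequity

Multivariate measurement of equity in childhood immunization from
child-level household-survey microdata.

Immunization programs increasingly need to know not just *how many*
children are vaccinated but *which* children are left behind. Ranking
households by wealth alone — the traditional concentration-index
approach — misses disadvantage that accumulates across maternal
education, geography, insurance and other social factors. `vaxequity`
implements a composite, multivariate equity toolkit for monitoring and
evaluation teams working with DHS-style surveys: it derives vaccination
statuses from per-dose records, ranks children by a model-based
propensity for relative disadvantage, quantifies how unequally each
outcome is distributed, and attributes that inequity to its correlates —
nationally, per district, and across survey years. It is a descriptive
and evaluative instrument, not a causal one.

## The statistics

For child *i* with binary outcome *h<sub>i</sub>*, sampling weight
*w<sub>i</sub>* and weighted fractional rank *r<sub>i</sub>* ∈ (0, 1) in
a disadvantage ordering (most disadvantaged first):

- **Concentration index**: C = 2 cov<sub>w</sub>(h, r) / μ, with μ the
  weighted mean of *h*.
- **Wagstaff normalized index** (binary outcomes): W = C / (1 − μ),
  restoring the ±1 bounds; the headline index. **Equity level** = 1 − W.
- **Erreygers corrected index**: E = 4 μ C, satisfying
  E = 4 μ (1 − μ) W.
- **Absolute equity gap (AEG)**: difference in outcome prevalence
  between the top and bottom fifths of the ranking, in coverage units.

Two rankings are supported: *wealth-only* (ascending wealth quintile)
and *composite* — ascending fitted probability of the favorable outcome
from a weighted logistic regression on the "unfair" factors (sex,
urban/rural, district, insurance, maternal education, wealth quintile).
For adverse outcomes (zero-dose status) the composite index is computed
on the favorable complement, so a positive composite W always reads
"burden concentrated among the disadvantaged"; wealth-only indices keep
the conventional sign (negative = burden among the poor). See
`?rank_sample` before comparing signs across tools.

Composite inequity is decomposed with the regression-based
(Wagstaff–van Doorslaer / Kitagawa–Blinder–Oaxaca style) method: a
weighted linear probability model h = α + Σ β<sub>k</sub> x<sub>k</sub> + ε
gives per-factor contributions (β<sub>k</sub> x̄<sub>k</sub> / μ) C<sub>k</sub>
plus a residual (unexplained) term; on the Wagstaff scale these
reconstruct W exactly and their shares sum to 100%. The sole *fair*
factor — being too young for scheduled doses — is grouped separately.

Eleven outcomes are derived from the dose records and a configurable
immunization schedule: the eight antigen-doses (BCG, DTP1–3, OPV1–3,
MCV1; underage children are masked, never counted as failures), plus
ZERO (under 12 months, no dose ever), FULL (under 24 months, all
age-eligible doses except MCV1) and COMPLETE (24+ months, all doses).

## Worked example

Real DHS microdata are registration-gated, so the package ships a
synthetic generator with the same schema and an exactly enumerable
ground truth:

```r
library(vaxequity)

children <- generate_children(synthetic_config(n_children = 8000, seed = 2024))
dat    <- with_status(children)                      # adds the 11 outcomes
ranked <- rank_sample(dat, "DTP3", source = "composite")
inequity(ranked)
#> # A tibble: 1 × 15
#>   outcome source    direction     n n_excluded    mu      C     W     E   se_W
#> 1 DTP3    composite favorable  7485        515 0.813 0.0771 0.413 0.251 0.0189
#>   ci_lo ci_hi   AEG equity_level degenerate
#> 1 0.376 0.450 0.315        0.587 FALSE
```

DTP3 coverage is 81.3% among the 7,485 age-eligible children; the
composite Wagstaff index of 0.413 (95% CI 0.376–0.450) says coverage is
concentrated among the advantaged, and the most disadvantaged fifth
trails the most advantaged fifth by 31.5 percentage points (AEG).
Attribution of that inequity:

```r
tidy(decompose_inequity(ranked))
#> # A tibble: 8 × 5
#>   outcome group              contribution     share negative
#> 1 DTP3    wealth_quintile      0.201      48.7      FALSE
#> 2 DTP3    maternal_education   0.145      35.1      FALSE
#> 3 DTP3    district             0.0695     16.8      FALSE
#> 4 DTP3    residual            -0.00715    -1.73     TRUE
#> ...
```

Wealth and maternal education dominate, as this scenario's generator
intends; shares sum to 100 exactly. `run_national()`,
`run_by_district()` and `run_trends()` orchestrate the full battery and
`write_report()` emits tidy CSVs plus a JSON run log; a thin CLI lives
in `inst/cli/vaxequity` (`run` / `simulate` subcommands). Reference
published estimates for Cambodia DHS 2014 are available via
`reference_national_2014()` for orientation.

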