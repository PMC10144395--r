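# Independent brute-force oracles. These deliberately re-derive the
# quantities from first principles (loops, geometry) rather than reusing
# any package internals.

# Weighted mid-rank of each observation, one at a time.
oracle_rank <- function(values, weights) {
  tot <- sum(weights)
  vapply(seq_along(values), function(i) {
    before <- sum(weights[values < values[i]])
    block <- sum(weights[values == values[i]])
    (before + block / 2) / tot
  }, numeric(1))
}

# Concentration index from the concentration-curve geometry: sort by the
# ranking variable, merge tied blocks, and take 1 - 2 * area under the
# curve of cumulative outcome share against cumulative weight share
# (trapezoid rule).
oracle_ci_curve <- function(h, values, weights) {
  ord <- order(values)
  h <- h[ord]; v <- values[ord]; w <- weights[ord]
  grp <- cumsum(c(TRUE, v[-1] != v[-length(v)]))
  wg <- tapply(w, grp, sum)
  hg <- tapply(h * w, grp, sum)
  p <- c(0, cumsum(wg) / sum(wg))
  L <- c(0, cumsum(hg) / sum(hg))
  area <- sum(diff(p) * (L[-1] + L[-length(L)]) / 2)
  1 - 2 * area
}

# Weighted mean via an explicit loop.
oracle_wmean <- function(x, w) {
  s <- 0; tw <- 0
  for (i in seq_along(x)) { s <- s + x[i] * w[i]; tw <- tw + w[i] }
  s / tw
}

# A tiny hand-buildable cohort; defaults give a valid record.
make_child <- function(id = "c1", age = 12, sex = "male",
                       district = "A", urban = "rural", wealth = 3,
                       edu = "primary", insured = "no", weight = 1,
                       doses = rep(1L, 8), year = 2014L) {
  row <- tibble::tibble(
    child_id = id, survey_year = year, age_months = age, sex = sex,
    district = district, urban = urban, wealth_quintile = wealth,
    maternal_education = edu, insured = insured, weight = weight)
  dn <- paste0("dose_", c("bcg", "dtp1", "dtp2", "dtp3",
                          "opv1", "opv2", "opv3", "mcv1"))
  for (k in seq_along(dn)) row[[dn[k]]] <- as.integer(doses[k])
  row
}

make_children <- function(...) {
  suppressMessages(validate_children(dplyr::bind_rows(...)))
}

# Calibration scenario: a single active wealth gradient, everything else
# flat, so ground truth concentrates on one factor.
wealth_only_scenario <- function(n, seed) {
  synthetic_config(
    n_children = n, seed = seed,
    districts = dplyr::mutate(default_districts(), effect = 0),
    coefficients = list(wealth = c(-0.8, -0.4, 0, 0.4, 0.8),
                        education = c(0, 0, 0), urban = 0, female = 0,
                        insured = 0))
}

# Uninformative scenario: all covariate effects zero.
null_scenario <- function(n, seed, ...) {
  synthetic_config(
    n_children = n, seed = seed,
    districts = dplyr::mutate(default_districts(), effect = 0),
    wealth_education_correlation = 0,
    coefficients = list(wealth = rep(0, 5), education = c(0, 0, 0),
                        urban = 0, female = 0, insured = 0),
    ...)
}
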