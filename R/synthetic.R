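#' Default district table for the synthetic generator
#'
#' Nineteen district/district-pair labels matching Cambodia's DHS
#' administrative grouping, with plausible population shares and
#' district-level log-odds effects on dose receipt: most districts sit
#' near zero, one remote district pair carries a strong negative effect
#' and the capital a positive one, emulating the observed geographic
#' coverage gradient.
#'
#' @return Tibble with `name`, `share`, `effect`.
#' @export
default_districts <- function() {
  d <- tibble::tribble(
    ~name, ~share, ~effect,
    "Banteay Meanchey",          0.050,  0.40,
    "Battambang & Pailin",       0.075,  0.30,
    "Kampong Cham",              0.115, -0.15,
    "Kampong Chhnang",           0.035,  0.25,
    "Kampong Speu",              0.055,  0.00,
    "Kampong Thom",              0.045,  0.10,
    "Kampot & Kep",              0.045, -0.40,
    "Kandal",                    0.085,  0.10,
    "Kratie",                    0.025, -0.50,
    "Mondulkiri & Ratanakiri",   0.020, -0.90,
    "Oddar Meanchey",            0.015, -0.10,
    "Phnom Penh",                0.105,  0.50,
    "Preah Sihanouk & Koh Kong", 0.025,  0.05,
    "Preah Vihear & Stung Treng",0.025, -0.20,
    "Prey Veng",                 0.070, -0.10,
    "Pursat",                    0.030, -0.20,
    "Siem Reap",                 0.065,  0.05,
    "Svay Rieng",                0.040,  0.00,
    "Takeo",                     0.075,  0.10
  )
  d$share <- d$share / sum(d$share)
  d
}

#' Configure a synthetic DHS-like survey scenario
#'
#' Defines the joint covariate distribution and the outcome model of the
#' generator. Covariates form a finite lattice — district, wealth
#' quintile (uniform), maternal education (linked to wealth through a
#' transition matrix), sex, urban/rural and insurance (independent
#' Bernoullis) — so population ground truth is exactly enumerable (see
#' [ground_truth()]). Each dose is received, when the child is age-
#' eligible, with probability
#' `plogis(base_rate + district effect + factor effects - dropout * (dose - 1))`;
#' doses within a series share a single latent draw when `adherence = 1`
#' (the default), which makes series monotone — a child with DTP3 also
#' has DTP1-2 — while keeping each dose's marginal probability exact.
#' Ages are uniform over 0-59 months and weights are either constant
#' (`"uniform"`) or gamma-distributed with mean 1 (`"gamma"`, DHS-like
#' variability).
#'
#' The defaults emulate a 2014-era Cambodia survey: per-dose coverage in
#' the 80-94% range with series dropout, a dominant wealth and maternal-
#' education gradient, and small sex/insurance effects.
#'
#' @param n_children Number of children to draw.
#' @param seed Integer seed; fully determines the draw.
#' @param survey_year Survey year stamped on the records.
#' @param districts Tibble with `name`, `share`, `effect` (log-odds).
#' @param wealth_education_correlation In `[0, 1]`: 0 makes education
#'   independent of wealth, 1 makes it deterministic in wealth.
#' @param education_levels Ordered education levels.
#' @param coefficients List of log-odds effects: `wealth` (length 5),
#'   `education` (one per level), scalars `urban`, `female`, `insured`.
#' @param base_rates Named per-dose baseline log-odds.
#' @param dropout Per-dose log-odds decrement within a series.
#' @param adherence Probability a dose uses the shared series draw
#'   (1 = perfectly nested series).
#' @param p_urban,p_insured,p_female Bernoulli parameters.
#' @param weight_model `"gamma"` or `"uniform"`.
#' @param schedule A `vx_schedule` used for eligibility gating.
#' @return A validated `vx_scenario` list.
#' @export
synthetic_config <- function(n_children = 8000, seed = 1,
                             survey_year = 2014,
                             districts = default_districts(),
                             wealth_education_correlation = 0.5,
                             education_levels = c("none", "primary",
                                                  "secondary+"),
                             coefficients = list(
                               wealth = c(-0.6, -0.3, 0, 0.3, 0.6),
                               education = c(-0.5, 0, 0.4),
                               urban = 0.15,
                               female = -0.02,
                               insured = 0.1
                             ),
                             base_rates = c(bcg = 2.75, dtp1 = 2.4,
                                            dtp2 = 2.4, dtp3 = 2.4,
                                            opv1 = 2.4, opv2 = 2.4,
                                            opv3 = 2.4, mcv1 = 1.4),
                             dropout = 0.45, adherence = 1,
                             p_urban = 0.25, p_insured = 0.1,
                             p_female = 0.5,
                             weight_model = c("gamma", "uniform"),
                             schedule = default_schedule()) {
  weight_model <- match.arg(weight_model)
  districts <- tibble::as_tibble(districts)
  assert_that(all(c("name", "share", "effect") %in% names(districts)),
              "districts needs columns name, share, effect")
  assert_that(abs(sum(districts$share) - 1) < 1e-8,
              "district population shares must sum to 1")
  assert_that(length(coefficients$wealth) == 5,
              "coefficients$wealth must have one entry per quintile")
  assert_that(length(coefficients$education) == length(education_levels),
              "coefficients$education must match education_levels")
  assert_that(wealth_education_correlation >= 0 &&
                wealth_education_correlation <= 1,
              "wealth_education_correlation must be in [0, 1]")
  assert_that(adherence >= 0 && adherence <= 1,
              "adherence must be in [0, 1]")
  assert_that(all(dose_names() %in% names(base_rates)),
              "base_rates must name every antigen-dose")
  cfg <- list(n_children = as.integer(n_children), seed = as.integer(seed),
              survey_year = as.integer(survey_year), districts = districts,
              wealth_education_correlation = wealth_education_correlation,
              education_levels = education_levels,
              coefficients = coefficients,
              base_rates = base_rates[dose_names()], dropout = dropout,
              adherence = adherence, p_urban = p_urban,
              p_insured = p_insured, p_female = p_female,
              weight_model = weight_model, schedule = schedule)
  structure(cfg, class = "vx_scenario")
}

# Row-stochastic matrix P(education level | wealth quintile): a convex
# blend of the uniform distribution and a deterministic wealth-to-level
# map, governed by the correlation parameter.
education_transition <- function(config) {
  L <- length(config$education_levels)
  rho <- config$wealth_education_correlation
  peak <- ceiling((1:5) * L / 5)
  t(vapply(1:5, function(q) {
    p <- rep((1 - rho) / L, L)
    p[peak[q]] <- p[peak[q]] + rho
    p
  }, numeric(L)))
}

# Dose position within its series (1 for single-dose antigens).
dose_position <- function() {
  c(bcg = 1, dtp1 = 1, dtp2 = 2, dtp3 = 3,
    opv1 = 1, opv2 = 2, opv3 = 3, mcv1 = 1)
}

dose_series <- function() {
  c(bcg = "bcg", dtp1 = "dtp", dtp2 = "dtp", dtp3 = "dtp",
    opv1 = "opv", opv2 = "opv", opv3 = "opv", mcv1 = "mcv")
}

# Linear predictor of the unfair factors for each row of a covariate
# frame with columns district, wealth_quintile, maternal_education (level
# index), sex_female (0/1), urban01, insured01.
unfair_eta <- function(config, district_idx, q, edu_idx, female, urban01,
                       insured01) {
  cf <- config$coefficients
  config$districts$effect[district_idx] + cf$wealth[q] +
    cf$education[edu_idx] + cf$urban * urban01 + cf$female * female +
    cf$insured * insured01
}

# Marginal receipt probability of each dose (columns) for linear
# predictors eta (rows), before eligibility gating.
dose_probs <- function(config, eta) {
  pos <- dose_position()
  sapply(dose_names(), function(d) {
    plogis(config$base_rates[[d]] + eta - config$dropout * (pos[[d]] - 1))
  })
}

#' Generate synthetic child records
#'
#' Draws a survey of children from a [synthetic_config()] scenario. The
#' draw is fully determined by `config$seed`. Dose receipt is gated by
#' age eligibility under the scenario's schedule; within a series the
#' shared latent draw (at `adherence = 1`) makes dose sets nested while
#' preserving each dose's marginal probability.
#'
#' @param config A `vx_scenario`.
#' @return A validated children tibble conforming to
#'   [children_schema()].
#' @export
generate_children <- function(config) {
  assert_that(inherits(config, "vx_scenario"),
              "generate_children expects a vx_scenario from synthetic_config()")
  n <- config$n_children
  sched_ages <- setNames(config$schedule$age_months, config$schedule$dose)
  trans <- education_transition(config)

  withr::with_seed(config$seed, {
    district_idx <- sample.int(nrow(config$districts), n, replace = TRUE,
                               prob = config$districts$share)
    q <- sample.int(5, n, replace = TRUE)
    edu_idx <- vapply(q, function(qi) {
      sample.int(ncol(trans), 1, prob = trans[qi, ])
    }, integer(1))
    female <- runif(n) < config$p_female
    urban01 <- as.integer(runif(n) < config$p_urban)
    insured01 <- as.integer(runif(n) < config$p_insured)
    age <- sample(0:59, n, replace = TRUE)
    weight <- switch(config$weight_model,
                     uniform = rep(1, n),
                     gamma = rgamma(n, shape = 4, rate = 4))

    eta <- unfair_eta(config, district_idx, q, edu_idx, as.integer(female),
                      urban01, insured01)
    probs <- dose_probs(config, eta)
    series <- dose_series()
    u_series <- matrix(runif(n * 4), n, 4,
                       dimnames = list(NULL, c("bcg", "dtp", "opv", "mcv")))
    doses <- matrix(0L, n, length(dose_names()),
                    dimnames = list(NULL, dose_names()))
    for (d in dose_names()) {
      u <- u_series[, series[[d]]]
      if (config$adherence < 1) {
        own <- runif(n)
        use_own <- runif(n) >= config$adherence
        u <- ifelse(use_own, own, u)
      }
      doses[, d] <- as.integer(u <= probs[, d] & age >= sched_ages[[d]])
    }

    out <- tibble::tibble(
      child_id = sprintf("c%06d", seq_len(n)),
      survey_year = config$survey_year,
      age_months = age,
      sex = ifelse(female, "female", "male"),
      district = config$districts$name[district_idx],
      urban = ifelse(urban01 == 1, "urban", "rural"),
      wealth_quintile = q,
      maternal_education = config$education_levels[edu_idx],
      insured = ifelse(insured01 == 1, "yes", "no"),
      weight = weight
    )
    for (d in dose_names()) out[[paste0("dose_", d)]] <- doses[, d]
    suppressMessages(
      validate_children(out, education_levels = config$education_levels)
    )
  })
}

# Probability of the outcome given the unfair linear predictor eta and an
# age in months, under adherence = 1 (nested series). Returns NA for ages
# where the outcome is not applicable. Vectorized over eta.
outcome_prob_at_age <- function(config, outcome, eta, age) {
  sched_ages <- setNames(config$schedule$age_months, config$schedule$dose)
  excl <- attr(config$schedule, "full_exclusions")
  probs <- dose_probs(config, eta)       # length(eta) x 8
  eligible <- age >= sched_ages
  outcome <- toupper(outcome)
  series <- dose_series()

  series_agg <- function(doses, fun, empty) {
    el <- doses[eligible[doses]]
    if (length(el) == 0) return(rep(empty, length(eta)))
    out <- probs[, el[1]]
    for (d in el[-1]) out <- fun(out, probs[, d])
    out
  }

  if (outcome %in% toupper(dose_names())) {
    d <- tolower(outcome)
    if (!eligible[d]) return(rep(NA_real_, length(eta)))
    return(probs[, d])
  }
  if (outcome == "ZERO") {
    if (age >= 12) return(rep(NA_real_, length(eta)))
    p_none <- rep(1, length(eta))
    for (s in unique(series)) {
      doses <- dose_names()[series == s]
      p_none <- p_none * (1 - series_agg(doses, pmax, 0))
    }
    return(p_none)
  }
  if (outcome == "FULL") {
    if (age >= 24) return(rep(NA_real_, length(eta)))
    p_all <- rep(1, length(eta))
    for (s in unique(series)) {
      doses <- setdiff(dose_names()[series == s], excl)
      p_all <- p_all * series_agg(doses, pmin, 1)
    }
    return(p_all)
  }
  if (outcome == "COMPLETE") {
    if (age < 24) return(rep(NA_real_, length(eta)))
    p_all <- rep(1, length(eta))
    for (s in unique(series)) {
      p_all <- p_all * series_agg(dose_names()[series == s], pmin, 1)
    }
    return(p_all)
  }
  rlang::abort(paste0("unknown outcome: ", outcome))
}

#' Population ground truth for a synthetic scenario
#'
#' Computes the generator-implied population values of the prevalence,
#' concentration indices and absolute equity gap for an outcome by exact
#' enumeration over the finite covariate lattice (district x wealth x
#' education x sex x urban x insurance, age-averaged over the outcome's
#' applicable window), weighting cells by their exact probabilities.
#' Cells are ranked by the true propensity of the favorable outcome form
#' (composite ranking) or by wealth quintile; quintile boundaries for the
#' AEG split straddling cells fractionally, the population limit of the
#' finite-sample midpoint rule. Requires `adherence = 1` for the
#' comprehensive statuses (ZERO/FULL/COMPLETE), whose probabilities
#' depend on the within-series coupling.
#'
#' @param config A `vx_scenario`.
#' @param outcome One of [outcome_names()].
#' @param ranking `"composite"` or `"wealth_only"`.
#' @param max_cells Enumeration cap; larger lattices error with advice to
#'   fall back to Monte-Carlo estimation.
#' @return One-row tibble: `outcome`, `ranking`, `mu` (prevalence as
#'   recorded), `C`, `W`, `E`, `AEG` (all under the same sign conventions
#'   as [inequity()]).
#' @export
ground_truth <- function(config, outcome,
                         ranking = c("composite", "wealth_only"),
                         max_cells = 2e6) {
  ranking <- match.arg(ranking)
  assert_that(inherits(config, "vx_scenario"),
              "ground_truth expects a vx_scenario")
  outcome <- toupper(outcome)
  if (outcome %in% c("ZERO", "FULL", "COMPLETE")) {
    assert_that(config$adherence == 1,
                paste0("ground truth for ", outcome, " requires adherence ",
                       "= 1; use Monte-Carlo estimation otherwise"))
  }
  L <- length(config$education_levels)
  cells <- expand.grid(district_idx = seq_len(nrow(config$districts)),
                       q = 1:5, edu_idx = seq_len(L), female = 0:1,
                       urban01 = 0:1, insured01 = 0:1)
  assert_that(nrow(cells) * 60 <= max_cells,
              paste0("covariate lattice too large to enumerate (",
                     nrow(cells) * 60, " cells); increase max_cells or ",
                     "estimate by Monte-Carlo simulation"))
  trans <- education_transition(config)
  p_cell <- config$districts$share[cells$district_idx] * (1 / 5) *
    trans[cbind(cells$q, cells$edu_idx)] *
    ifelse(cells$female == 1, config$p_female, 1 - config$p_female) *
    ifelse(cells$urban01 == 1, config$p_urban, 1 - config$p_urban) *
    ifelse(cells$insured01 == 1, config$p_insured, 1 - config$p_insured)
  eta <- unfair_eta(config, cells$district_idx, cells$q, cells$edu_idx,
                    cells$female, cells$urban01, cells$insured01)

  # Age-average the outcome probability over the applicable window.
  acc <- rep(0, nrow(cells))
  n_ages <- 0L
  for (age in 0:59) {
    p <- outcome_prob_at_age(config, outcome, eta, age)
    if (!all(is.na(p))) {
      acc <- acc + p
      n_ages <- n_ages + 1L
    }
  }
  assert_that(n_ages > 0, paste0("outcome ", outcome,
                                 " is applicable at no age under 60 months"))
  p_raw <- acc / n_ages
  mass <- p_cell * (n_ages / 60)
  mass <- mass / sum(mass)

  adverse <- is_adverse(outcome)
  h <- if (adverse && ranking == "composite") 1 - p_raw else p_raw
  rank_var <- if (ranking == "composite") {
    if (adverse) 1 - p_raw else p_raw
  } else {
    as.numeric(cells$q)
  }
  r <- fractional_rank(rank_var, mass)
  mu_idx <- wtd_mean(h, mass)
  mu_raw <- wtd_mean(p_raw, mass)
  C <- if (mu_idx > 0) 2 * wtd_cov(h, r, mass) / mu_idx else 0
  W <- as.numeric(wagstaff_index(C, mu_idx))
  E <- erreygers_index(C, mu_idx)

  # AEG: fractional quintile split in rank order (composite convention:
  # favorable form, disadvantaged first).
  h_fav <- if (adverse) 1 - p_raw else p_raw
  ord <- order(rank_var)
  m <- mass[ord]
  hv <- h_fav[ord]
  cw <- cumsum(m)
  lower <- cw - m
  bot_w <- pmax(0, pmin(cw, 0.2) - lower)
  top_w <- pmax(0, cw - pmax(lower, 0.8))
  aeg <- sum(top_w * hv) / sum(top_w) - sum(bot_w * hv) / sum(bot_w)

  tibble::tibble(outcome = outcome, ranking = ranking, mu = mu_raw,
                 C = C, W = W, E = E, AEG = aeg)
}

#' Default three-survey scenario bundle
#'
#' Three synthetic "survey years" (2004, 2010, 2014) with rising baseline
#' coverage and weakening socio-demographic gradients, for exercising the
#' multi-survey trend harness qualitatively.
#'
#' @param n_children Children per survey.
#' @param seed Base seed; each year offsets it.
#' @return Named list of `vx_scenario` objects.
#' @export
default_scenarios <- function(n_children = 8000, seed = 1) {
  base <- synthetic_config(n_children = n_children, seed = seed)
  tweak <- function(year, rate_shift, grad_scale, seed_offset) {
    synthetic_config(
      n_children = n_children, seed = seed + seed_offset,
      survey_year = year,
      coefficients = list(
        wealth = base$coefficients$wealth * grad_scale,
        education = base$coefficients$education * grad_scale,
        urban = base$coefficients$urban * grad_scale,
        female = base$coefficients$female,
        insured = base$coefficients$insured
      ),
      base_rates = base$base_rates + rate_shift,
      dropout = base$dropout
    )
  }
  list(`2004` = tweak(2004, -1.0, 1.8, 0L),
       `2010` = tweak(2010, -0.5, 1.4, 1L),
       `2014` = tweak(2014, 0, 1.0, 2L))
}
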