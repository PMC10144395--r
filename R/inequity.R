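#' Plain concentration index
#'
#' Twice the weighted covariance between the outcome and the fractional
#' disadvantage rank, divided by the weighted outcome mean:
#' `C = 2 cov_w(h, r) / mu`. Zero means no systematic concentration;
#' positive means the outcome is concentrated among the higher-ranked
#' (more advantaged) individuals. When the outcome mean is 0 or 1 the
#' index is degenerate and returned as 0 with the `degenerate` attribute
#' set, rather than an error, so that empty strata propagate cleanly.
#'
#' @param h A `vx_ranked` sample, or a 0/1 (or bounded) outcome vector.
#' @param ranks Fractional ranks (ignored when `h` is a `vx_ranked`).
#' @param weights Positive weights; default equal.
#' @return The index (numeric scalar) with attribute `degenerate`.
#' @export
concentration_index <- function(h, ranks = NULL, weights = NULL) {
  if (inherits(h, "vx_ranked")) {
    ranks <- h$rank
    weights <- h$w
    h <- h$h
  }
  n <- length(h)
  assert_that(n >= 1 && length(ranks) == n, "outcome and ranks must align")
  if (is.null(weights)) weights <- rep(1, n)
  mu <- wtd_mean(h, weights)
  if (mu == 0 || all(h == h[1])) {
    return(structure(0, degenerate = (mu %in% c(0, 1))))
  }
  C <- 2 * wtd_cov(h, ranks, weights) / mu
  structure(C, degenerate = FALSE)
}

#' Wagstaff-normalized concentration index for a binary outcome
#'
#' `W = C / (1 - mu)`, restoring the attainable bounds to +/-1 for a
#' binary outcome. This normalization weighs observations at the extremes
#' of the disadvantage ranking heavily, and is the headline index of the
#' package. Undefined (returned as `NA`) when `mu` is 0 or 1 — e.g. a
#' district stratum where nobody (or everybody) has the outcome.
#'
#' @param C Plain concentration index.
#' @param mu Weighted outcome mean in `[0, 1]` (on the scale on which `C`
#'   was computed).
#' @return `W`, or `NA_real_` when degenerate.
#' @export
wagstaff_index <- function(C, mu) {
  ifelse(mu <= 0 | mu >= 1, NA_real_, C / (1 - mu))
}

#' Erreygers-corrected concentration index
#'
#' `E = 4 * mu * C`: a correction for bounded outcomes that adjusts for
#' the mean of the dependent variable and is defined even at degenerate
#' means (E = 0 when mu = 0). Satisfies `E = 4 mu (1 - mu) W` wherever
#' `W` is defined.
#'
#' @inheritParams wagstaff_index
#' @return `E`.
#' @export
erreygers_index <- function(C, mu) 4 * mu * C

#' Equity level
#'
#' One minus the Wagstaff index: 1 is perfect equity, lower values mean
#' the outcome (or its burden, under the composite adverse-outcome
#' convention) is more concentrated among the disadvantaged. Used to
#' track equity across survey years.
#'
#' @param W Wagstaff-normalized index.
#' @return `1 - W`.
#' @export
equity_level <- function(W) 1 - W

#' Absolute equity gap
#'
#' The gap in outcome prevalence between the top (most advantaged) and
#' bottom (most disadvantaged) fifths of the ranking, in natural coverage
#' units. Quintile boundaries fall at cumulative weight 0.2 and 0.8 of
#' the rank ordering; a child straddling a boundary is assigned wholly to
#' the quintile where the midpoint of its weight mass falls. For adverse
#' outcomes the gap is computed on the favorable complement, so a
#' positive AEG always reads "the disadvantaged quintile is worse off by
#' this many coverage points".
#'
#' @param sample A `vx_ranked` sample.
#' @return The gap (numeric scalar in `[-1, 1]`).
#' @export
absolute_equity_gap <- function(sample) {
  assert_that(inherits(sample, "vx_ranked"),
              "absolute_equity_gap expects a vx_ranked sample")
  n <- nrow(sample)
  assert_that(n >= 5, "absolute_equity_gap needs at least 5 observations")
  h_fav <- if (attr(sample, "direction") == "adverse") {
    1 - sample$h_raw
  } else {
    sample$h_raw
  }
  ord <- order(sample$rank)
  w <- sample$w[ord]
  h <- h_fav[ord]
  cw <- cumsum(w)
  tot <- cw[n]
  mid <- cw - w / 2
  bottom <- mid <= 0.2 * tot
  top <- mid >= 0.8 * tot
  assert_that(any(bottom) && any(top),
              "a ranking quintile has zero total weight")
  wtd_mean(h[top], w[top]) - wtd_mean(h[bottom], w[bottom])
}

#' Uncertainty for the Wagstaff index
#'
#' Two estimators are offered; the printed intervals of published
#' applications rarely state their estimator, so both are documented as
#' approximations.
#' \describe{
#'   \item{convenient_regression}{weighted least squares of the
#'     transformed outcome `2 var_w(r) h_i / mu` on the fractional rank
#'     `r_i`; the slope equals the plain index `C` exactly, and its
#'     heteroskedasticity-robust (sandwich, HC1) standard error is
#'     delta-scaled by `1/(1 - mu)` to the Wagstaff index. Fast and
#'     deterministic; treats `mu` as fixed.}
#'   \item{bootstrap}{children are resampled with replacement carrying
#'     their weights; ranks are recomputed from the stored ranking
#'     variable within each resample (set `refit = TRUE` to also refit
#'     the composite propensity model, at substantial cost) and the
#'     percentile interval of the resampled `W` values is returned.
#'     Seeded and reproducible.}
#' }
#'
#' @param sample A `vx_ranked` sample.
#' @param method `"convenient_regression"` (default) or `"bootstrap"`.
#' @param reps Bootstrap replicates (>= 100).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param refit Refit the propensity model in each bootstrap resample?
#' @return List with `se`, `ci` (length-2), and `method`. Degenerate
#'   samples return `NA`s.
#' @export
index_uncertainty <- function(sample,
                              method = c("convenient_regression", "bootstrap"),
                              reps = 1000, seed = NULL, conf = 0.95,
                              refit = FALSE) {
  method <- match.arg(method)
  assert_that(inherits(sample, "vx_ranked"),
              "index_uncertainty expects a vx_ranked sample")
  h <- sample$h
  w <- sample$w
  r <- sample$rank
  mu <- wtd_mean(h, w)
  if (mu == 0 || mu == 1) {
    return(list(se = NA_real_, ci = c(NA_real_, NA_real_), method = method))
  }
  z <- qnorm(1 - (1 - conf) / 2)

  if (method == "convenient_regression") {
    if (nrow(sample) < 10) {
      rlang::warn(paste0("convenient-regression standard error computed on ",
                         "only ", nrow(sample),
                         " observations; interpret with caution"))
    }
    y <- 2 * wtd_var(r, w) * h / mu
    fit <- lm(y ~ r, weights = w)
    se_C <- sqrt(sandwich::vcovHC(fit, type = "HC1")["r", "r"])
    se_W <- se_C / (1 - mu)
    W <- as.numeric(wagstaff_index(concentration_index(sample), mu))
    return(list(se = se_W, ci = c(W - z * se_W, W + z * se_W),
                method = method))
  }

  assert_that(reps >= 100, "bootstrap needs at least 100 replicates")
  boot_one <- function() {
    idx <- sample.int(length(h), replace = TRUE)
    hb <- h[idx]
    wb <- w[idx]
    mub <- wtd_mean(hb, wb)
    if (mub == 0 || mub == 1) return(NA_real_)
    if (refit && !is.null(attr(sample, "model"))) {
      db <- attr(sample, "data")[idx, , drop = FALSE]
      db$.hfav <- hb
      mod <- tryCatch(
        suppressWarnings(fit_propensity(db, ".hfav",
                                        unfair = attr(sample, "unfair"),
                                        weights = attr(sample, "weights_col"))),
        error = function(e) NULL
      )
      if (is.null(mod)) return(NA_real_)
      rv <- mod$propensity
    } else {
      rv <- sample$rank_var[idx]
    }
    rb <- fractional_rank(rv, wb)
    (2 * wtd_cov(hb, rb, wb) / mub) / (1 - mub)
  }
  run <- function() vapply(seq_len(reps), function(i) boot_one(), numeric(1))
  stats <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  stats <- stats[!is.na(stats)]
  alpha <- (1 - conf) / 2
  list(se = sd(stats),
       ci = as.numeric(quantile(stats, c(alpha, 1 - alpha), names = FALSE)),
       method = method)
}

#' Full inequity summary for a ranked sample
#'
#' Computes the complete metric battery for one outcome under one ranking
#' criterion: weighted prevalence, plain / Wagstaff / Erreygers indices,
#' uncertainty, absolute equity gap and equity level. `mu` is always the
#' prevalence of the outcome as recorded (the burden prevalence for
#' ZERO), while the composite indices for adverse outcomes are computed
#' on the favorable complement so that positive values read "burden
#' concentrated among the disadvantaged" (see [rank_sample()]).
#'
#' @param sample A `vx_ranked` sample.
#' @param uncertainty `"convenient_regression"`, `"bootstrap"` or
#'   `"none"`.
#' @param reps,seed,conf Passed to [index_uncertainty()].
#' @return One-row tibble: `outcome`, `source`, `direction`, `n`,
#'   `n_excluded`, `mu`, `C`, `W`, `E`, `se_W`, `ci_lo`, `ci_hi`, `AEG`,
#'   `equity_level`, `degenerate`.
#' @export
inequity <- function(sample,
                     uncertainty = c("convenient_regression", "bootstrap",
                                     "none"),
                     reps = 1000, seed = NULL, conf = 0.95) {
  uncertainty <- match.arg(uncertainty)
  assert_that(inherits(sample, "vx_ranked"),
              "inequity expects a vx_ranked sample")
  h <- sample$h
  w <- sample$w
  mu_idx <- wtd_mean(h, w)
  mu_raw <- wtd_mean(sample$h_raw, w)
  C <- concentration_index(sample)
  degenerate <- mu_idx == 0 || mu_idx == 1
  W <- as.numeric(wagstaff_index(as.numeric(C), mu_idx))
  E <- erreygers_index(as.numeric(C), mu_idx)
  aeg <- if (nrow(sample) >= 5 && !degenerate) {
    absolute_equity_gap(sample)
  } else {
    NA_real_
  }
  unc <- if (uncertainty == "none" || degenerate) {
    list(se = NA_real_, ci = c(NA_real_, NA_real_))
  } else {
    index_uncertainty(sample, method = uncertainty, reps = reps, seed = seed,
                      conf = conf)
  }
  tibble::tibble(
    outcome = attr(sample, "outcome"),
    source = attr(sample, "source"),
    direction = attr(sample, "direction"),
    n = nrow(sample),
    n_excluded = attr(sample, "n_excluded") %||% 0L,
    mu = mu_raw,
    C = as.numeric(C),
    W = W,
    E = E,
    se_W = unc$se,
    ci_lo = unc$ci[1],
    ci_hi = unc$ci[2],
    AEG = aeg,
    equity_level = equity_level(W),
    degenerate = degenerate
  )
}
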