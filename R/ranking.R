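#' Weighted fractional ranks
#'
#' Weighted mid-ranks in (0, 1): after sorting ascending by `values`, each
#' observation's rank is (cumulative weight before it + half its own
#' weight) / total weight. Observations tied on `values` share the
#' weighted mean rank of their tied block — the block's weight midpoint —
#' so the weighted mean of the ranks is exactly 0.5 and an uninformative
#' ranking variable yields rank 0.5 for everyone. These ranks underlie all
#' concentration indices in the package.
#'
#' @param values Finite numeric ranking variable (ascending = most
#'   disadvantaged first, by this package's conventions).
#' @param weights Positive sampling weights; default equal.
#' @return Numeric vector of ranks in (0, 1), in input order.
#' @export
fractional_rank <- function(values, weights = NULL) {
  n <- length(values)
  assert_that(n > 0, "fractional_rank: empty input")
  if (is.null(weights)) weights <- rep(1, n)
  assert_that(length(weights) == n && all(weights > 0),
              "fractional_rank: weights must be positive and match values")
  assert_that(all(is.finite(values)), "fractional_rank: values must be finite")
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord]
  cw <- cumsum(w)
  tot <- cw[n]
  new_block <- c(TRUE, v[-1] != v[-n])
  blk <- cumsum(new_block)
  last <- which(c(new_block[-1], TRUE))      # last index of each block
  block_end <- cw[last]
  block_start <- c(0, block_end[-length(block_end)])
  r_block <- (block_start + block_end) / (2 * tot)
  out <- numeric(n)
  out[ord] <- r_block[blk]
  out
}

#' Fit the composite disadvantage-propensity model
#'
#' Weighted logistic regression of a binary outcome on the unfair factors
#' only (sex, urban/rural, district, insurance, maternal education and
#' wealth-quintile dummies). The fitted probabilities are the composite
#' "propensity for relative advantage" in the outcome; ranking children by
#' them ascending puts the most disadvantaged — those least likely to
#' attain the favorable outcome — first. The fair factor (age
#' eligibility) is deliberately excluded: the ranking reflects unfair
#' drivers alone.
#'
#' @param data Data frame holding the outcome and unfair-factor columns.
#' @param outcome Name of the 0/1 outcome column.
#' @param unfair Character vector of unfair-factor columns; default
#'   [unfair_factors()]. Categorical columns are dummy-coded with the
#'   first level as reference; `wealth_quintile` is dummy-coded too.
#' @param weights Name of the sampling-weight column (default
#'   `"weight"`).
#' @return A `vx_propensity`: list with the `glm` fit, fitted
#'   probabilities `propensity`, `converged`, `separation` flags and `n`.
#' @export
fit_propensity <- function(data, outcome, unfair = unfair_factors(),
                           weights = "weight", label = outcome) {
  df <- model_frame(data, outcome, unfair, weights)
  h <- df$.h
  assert_that(length(unique(h)) == 2,
              paste0("outcome '", label,
                     "' needs at least one event and one non-event to fit ",
                     "a propensity model"))
  # factors left with a single level (e.g. within a small stratum, or a
  # deliberately constant covariate) carry no information; drop them so
  # the design stays full-rank. With none left the model is
  # intercept-only and every propensity equals the weighted mean.
  informative <- vapply(unfair, function(v) {
    x <- df[[v]]
    if (is.factor(x)) nlevels(x) >= 2 else length(unique(x)) >= 2
  }, logical(1))
  rhs <- if (any(informative)) {
    paste(vapply(unfair[informative], model_term, character(1)),
          collapse = " + ")
  } else {
    "1"
  }
  fml <- as.formula(paste(".h ~", rhs))
  fit <- suppressWarnings(
    glm(fml, family = quasibinomial(), data = df, weights = df$.w)
  )
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    rlang::abort(paste0("propensity model is singular; collinear term(s): ",
                        paste(bad, collapse = ", ")))
  }
  p <- fitted(fit)
  separation <- mean(p < 1e-8 | p > 1 - 1e-8) > 0.05
  if (!fit$converged || separation) {
    rlang::warn(paste0("propensity model for '", label,
                       "' did not converge cleanly (possible separation); ",
                       "fitted probabilities are near 0/1"))
  }
  structure(list(fit = fit, propensity = as.numeric(p),
                 coefficients = coef(fit), converged = fit$converged,
                 separation = separation, outcome = label,
                 unfair = unfair, n = nrow(df)),
            class = "vx_propensity")
}

#' @method tidy vx_propensity
#' @export
tidy.vx_propensity <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' @method glance vx_propensity
#' @export
glance.vx_propensity <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n, converged = x$converged,
                 separation = x$separation)
}

# Extract outcome/weights/covariates into an analysis frame: applicable
# rows only (outcome not NA), complete cases on the covariates, factors
# with unused levels dropped so model matrices stay full-rank in strata.
model_frame <- function(data, outcome, covars, weights) {
  assert_that(outcome %in% names(data),
              paste0("outcome column '", outcome, "' not found"))
  missing_cov <- setdiff(covars, names(data))
  assert_that(length(missing_cov) == 0,
              paste0("covariate column(s) not found: ",
                     paste(missing_cov, collapse = ", ")))
  df <- data[, unique(c(outcome, covars, weights)), drop = FALSE]
  names(df)[match(c(outcome, weights), names(df))] <- c(".h", ".w")
  keep <- !is.na(df$.h) & complete.cases(df[, covars, drop = FALSE])
  df <- df[keep, , drop = FALSE]
  df <- droplevels(df)
  attr(df, "n_excluded") <- sum(!keep)
  attr(df, "keep") <- keep
  df
}

#' Rank a sample by wealth or by composite disadvantage
#'
#' Builds the ranked sample on which all inequity metrics operate. Two
#' ranking criteria are supported:
#' \describe{
#'   \item{wealth_only}{children are ranked ascending in household wealth
#'     quintile (poorest first), the traditional socioeconomic ranking.
#'     The concentration index is computed on the outcome exactly as
#'     recorded, so for an adverse outcome such as ZERO a \emph{negative}
#'     index reads "burden concentrated among the poor".}
#'   \item{composite}{children are ranked ascending in the model-predicted
#'     propensity of the \emph{favorable} form of the outcome (for ZERO,
#'     the propensity of not being zero-dose), so the most disadvantaged
#'     always come first; and for adverse outcomes the index is computed
#'     on the favorable complement. A \emph{positive} composite index
#'     therefore always reads "burden concentrated among the
#'     disadvantaged", which is why a near-zero wealth-only index can
#'     coexist with a large positive composite index for zero-dose
#'     status. This sign convention is the main interoperability trap
#'     when comparing against wealth-ranked indices.}
#' }
#' Rows where the outcome is not applicable (mask `NA`) or any covariate
#' is missing are excluded and tallied.
#'
#' @param data Children tibble with derived status columns (see
#'   [with_status()]).
#' @param outcome Outcome column name (one of [outcome_names()], or any
#'   0/1 column).
#' @param source `"composite"` or `"wealth_only"`.
#' @param direction `"favorable"`, `"adverse"`, or `"auto"` (adverse for
#'   ZERO, favorable otherwise).
#' @param unfair Unfair-factor columns for the composite model.
#' @param weights Sampling-weight column name.
#' @param propensity Optional pre-fitted `vx_propensity` (or numeric
#'   vector aligned with `data` rows) to rank by, e.g. a national model
#'   applied within a district; if `NULL` and `source = "composite"`, a
#'   model is fitted on `data`.
#' @return A `vx_ranked` tibble with columns `h` (index outcome: the
#'   favorable form under composite ranking), `h_raw` (outcome as
#'   recorded), `w`, `rank_var`, `rank`, plus attributes `outcome`,
#'   `source`, `direction`, `model`, `data` (the analysis rows) and
#'   `n_excluded`.
#' @export
rank_sample <- function(data, outcome,
                        source = c("composite", "wealth_only"),
                        direction = c("auto", "favorable", "adverse"),
                        unfair = unfair_factors(), weights = "weight",
                        propensity = NULL) {
  source <- match.arg(source)
  direction <- match.arg(direction)
  if (direction == "auto") {
    direction <- if (is_adverse(outcome)) "adverse" else "favorable"
  }
  covars <- if (source == "wealth_only") "wealth_quintile" else unfair
  df <- model_frame(data, outcome, covars, weights)
  assert_that(nrow(df) > 0,
              paste0("no applicable complete-case rows for outcome '",
                     outcome, "'"))
  h_raw <- as.numeric(df$.h)
  w <- as.numeric(df$.w)
  model <- NULL

  if (source == "wealth_only") {
    h <- h_raw
    rank_var <- as.numeric(df$wealth_quintile)
  } else {
    h_fav <- if (direction == "adverse") 1 - h_raw else h_raw
    if (is.null(propensity)) {
      df_fav <- df
      df_fav$.h <- h_fav
      model <- fit_propensity(df_fav, ".h", unfair = unfair, weights = ".w",
                              label = outcome)
      p <- model$propensity
    } else if (inherits(propensity, "vx_propensity")) {
      model <- propensity
      p <- as.numeric(predict(propensity$fit, newdata = df,
                              type = "response"))
    } else {
      p <- as.numeric(propensity)
      assert_that(length(p) == nrow(df),
                  "propensity vector must match the applicable rows")
    }
    h <- h_fav
    rank_var <- p
  }

  full <- droplevels(tibble::as_tibble(data)[attr(df, "keep"), , drop = FALSE])
  out <- tibble::tibble(h = h, h_raw = h_raw, w = w, rank_var = rank_var,
                        rank = fractional_rank(rank_var, w))
  structure(out, outcome = outcome, source = source, direction = direction,
            model = model, data = full, weights_col = weights,
            unfair = unfair, n_excluded = attr(df, "n_excluded"),
            class = c("vx_ranked", class(out)))
}
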