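# Map model terms onto reporting factor groups.
factor_group <- function(term_label, fair) {
  base <- gsub("factor\\(|\\)", "", term_label)
  if (base %in% fair) return("underage")
  switch(base,
    wealth_quintile = "wealth_quintile",
    maternal_education = "maternal_education",
    district = "district",
    urban = "urban_rural",
    sex = "sex_of_child",
    insured = "insurance",
    base
  )
}

model_term <- function(col) {
  if (col == "wealth_quintile") "factor(wealth_quintile)" else col
}

#' Decompose composite inequity into factor contributions
#'
#' Regression-based decomposition of the concentration index: a weighted
#' linear probability model `h_i = alpha + sum_k beta_k x_ik + eps_i` is
#' fitted to the index outcome, and each covariate's contribution to the
#' plain index is `(beta_k * xbar_k / mu) * C_k`, where `C_k` is the
#' concentration index of the covariate against the composite rank. The
#' residual ("unexplained") contribution is the generalized concentration
#' index of the residuals over `mu`. All contributions are rescaled by
#' `1/(1 - mu)` onto the Wagstaff scale, on which they reconstruct `W`
#' exactly; percentage shares are `100 * contribution / W` and sum to
#' 100. Dummy contributions are aggregated within each categorical
#' factor. The linear probability model is used deliberately — the
#' contribution formula is exactly additive only under linearity — even
#' though the ranking itself comes from a logistic propensity model.
#'
#' The fair factor (the count of scheduled doses the child is still too
#' young for) enters the regression alongside the unfair factors but is
#' grouped separately in the report. Negative shares are meaningful (a
#' factor can offset inequity) and are reported as-is, flagged rather
#' than truncated.
#'
#' @param sample A `vx_ranked` sample, normally composite-ranked; its
#'   stored analysis rows must carry the covariates.
#' @param unfair Unfair-factor columns; defaults to the ranking model's.
#' @param fair Fair-factor column(s); default `"underage_count"`. Use
#'   `character(0)` to decompose on unfair factors only.
#' @return A `vx_decomposition`: list with `contributions` (tibble:
#'   `group`, `contribution`, `share`, `negative`), per-term details
#'   (`terms`), `W`, `C`, `mu`, `n`, `r.squared`, `explained_share`,
#'   `residual_share`, `fair_share`, `degenerate`.
#' @export
decompose_inequity <- function(sample, unfair = NULL,
                               fair = "underage_count") {
  assert_that(inherits(sample, "vx_ranked"),
              "decompose_inequity expects a vx_ranked sample")
  data <- attr(sample, "data")
  unfair <- unfair %||% attr(sample, "model")$unfair %||% unfair_factors()
  fair <- intersect(fair, names(data))
  covars <- c(unfair, fair)
  missing_cov <- setdiff(covars, names(data))
  assert_that(length(missing_cov) == 0,
              paste0("decomposition covariate(s) not in ranked sample: ",
                     paste(missing_cov, collapse = ", ")))

  h <- sample$h
  w <- sample$w
  r <- sample$rank
  mu <- wtd_mean(h, w)
  outcome <- attr(sample, "outcome")
  if (mu == 0 || mu == 1) {
    return(structure(list(
      contributions = tibble::tibble(group = character(0),
                                     contribution = numeric(0),
                                     share = numeric(0),
                                     negative = logical(0)),
      terms = tibble::tibble(), W = NA_real_, C = 0, mu = mu,
      n = nrow(sample), r.squared = NA_real_,
      explained_share = NA_real_, residual_share = NA_real_,
      fair_share = NA_real_, outcome = outcome, degenerate = TRUE
    ), class = "vx_decomposition"))
  }

  # constant columns (single-level factors, zero-variance counts) cannot
  # enter the regression; they contribute exactly zero anyway
  varying <- vapply(covars, function(v) {
    x <- data[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) >= 2 else length(unique(x)) >= 2
  }, logical(1))
  covars <- covars[varying]
  assert_that(length(covars) > 0,
              "no varying covariates to decompose on")
  fml <- as.formula(paste("~", paste(vapply(covars, model_term, character(1)),
                                     collapse = " + ")))
  X <- model.matrix(fml, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(paste0("decomposition design matrix is rank-deficient; ",
                        "collinear term(s): ",
                        paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm.wfit(X, h, w)
  beta <- fit$coefficients
  eps <- h - as.numeric(X %*% beta)

  assign <- attr(X, "assign")
  labels <- attr(terms(fml), "term.labels")
  keep <- assign > 0
  contrib_C <- vapply(which(keep), function(j) {
    2 * beta[j] * wtd_cov(X[, j], r, w) / mu
  }, numeric(1))
  group <- unname(vapply(labels[assign[keep]], factor_group, character(1),
                         fair = fair))
  resid_C <- 2 * wtd_cov(eps, r, w) / mu

  W <- as.numeric(wagstaff_index(as.numeric(concentration_index(sample)), mu))
  scale <- 1 / (1 - mu)
  term_tbl <- tibble::tibble(
    term = colnames(X)[keep],
    group = group,
    beta = beta[keep],
    x_mean = vapply(which(keep), function(j) wtd_mean(X[, j], w), numeric(1)),
    cov_rank = vapply(which(keep), function(j) wtd_cov(X[, j], r, w),
                      numeric(1)),
    contribution = contrib_C * scale
  )
  groups <- term_tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(contribution = sum(.data$contribution),
                     .groups = "drop")
  groups <- dplyr::bind_rows(
    groups,
    tibble::tibble(group = "residual", contribution = resid_C * scale)
  )
  groups$share <- 100 * groups$contribution / W
  groups$negative <- groups$share < 0

  res_share <- groups$share[groups$group == "residual"]
  fair_share <- sum(groups$share[groups$group == "underage"])
  ss_tot <- wtd_var(h, w)
  structure(list(
    contributions = groups,
    terms = term_tbl,
    W = W, C = as.numeric(concentration_index(sample)), mu = mu,
    n = nrow(sample),
    r.squared = if (ss_tot > 0) 1 - wtd_var(eps, w) / ss_tot else NA_real_,
    explained_share = 100 - res_share,
    residual_share = res_share,
    fair_share = fair_share,
    outcome = outcome,
    degenerate = FALSE
  ), class = "vx_decomposition")
}

#' Tidy share table for a decomposition
#'
#' One row per factor group (plus the residual), ordered by absolute
#' share, with negative shares flagged.
#'
#' @param result A `vx_decomposition`.
#' @return Tibble with `outcome`, `group`, `contribution`, `share`,
#'   `negative`.
#' @export
decomposition_report <- function(result) {
  assert_that(inherits(result, "vx_decomposition"),
              "decomposition_report expects a vx_decomposition")
  result$contributions |>
    dplyr::mutate(outcome = result$outcome, .before = 1) |>
    dplyr::arrange(dplyr::desc(abs(.data$share)))
}

#' @method tidy vx_decomposition
#' @export
tidy.vx_decomposition <- function(x, ...) decomposition_report(x)

#' @method glance vx_decomposition
#' @export
glance.vx_decomposition <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n, mu = x$mu, C = x$C, W = x$W,
                 r.squared = x$r.squared,
                 explained_share = x$explained_share,
                 residual_share = x$residual_share,
                 fair_share = x$fair_share,
                 degenerate = x$degenerate)
}

#' @export
print.vx_decomposition <- function(x, ...) {
  cat("Concentration-index decomposition for", x$outcome %||% "outcome",
      sprintf("(W = %.3f, mu = %.3f, n = %d)\n", x$W, x$mu, x$n))
  print(decomposition_report(x))
  invisible(x)
}

#' Stacked-bar chart of decomposition shares
#'
#' @param object A `vx_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vx_decomposition
#' @export
autoplot.vx_decomposition <- function(object, ...) {
  df <- decomposition_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$share,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "share of inequity (%)", fill = "factor") +
    ggplot2::theme_minimal()
}
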