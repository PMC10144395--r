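default_config <- function(config = list()) {
  utils::modifyList(list(
    uncertainty = "convenient_regression",
    reps = 1000L,
    seed = NULL,
    low_n = 25L,
    unfair = unfair_factors(),
    decompose = TRUE
  ), config)
}

# Metrics for one outcome under one ranking source, robust to degenerate
# strata: outcomes that are inapplicable everywhere, or have a single
# class (no events or no non-events), yield flagged rows with NA indices
# rather than errors.
safe_metrics <- function(dat, outcome, source, config, propensity = NULL) {
  blank <- tibble::tibble(
    outcome = outcome, source = source,
    direction = ifelse(is_adverse(outcome), "adverse", "favorable"),
    n = 0L, n_excluded = 0L, mu = NA_real_, C = NA_real_, W = NA_real_,
    E = NA_real_, se_W = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    AEG = NA_real_, equity_level = NA_real_, degenerate = TRUE
  )
  h <- dat[[outcome]]
  ok <- !is.na(h)
  if (!any(ok)) return(blank)
  single_class <- length(unique(h[ok])) < 2
  if (single_class && source == "composite" && is.null(propensity)) {
    # No model can be fitted; report prevalence and degenerate indices.
    wv <- dat$weight[ok]
    blank$n <- sum(ok)
    blank$mu <- wtd_mean(h[ok], wv)
    blank$C <- 0
    blank$E <- 0
    return(blank)
  }
  ranked <- tryCatch(
    suppressWarnings(rank_sample(dat, outcome, source = source,
                                 unfair = config$unfair,
                                 propensity = propensity)),
    error = function(e) NULL
  )
  if (is.null(ranked)) return(blank)
  inequity(ranked, uncertainty = config$uncertainty, reps = config$reps,
           seed = config$seed)
}

#' National vaccine-equity report
#'
#' Runs the full metric battery at the national level: for each of the
#' eleven outcomes, weighted coverage/prevalence, the wealth-only and
#' composite Wagstaff indices, the Erreygers index, uncertainty, the
#' absolute equity gap, and (for composite ranking) the factor
#' decomposition. Outcomes with fewer than two classes are flagged
#' degenerate and carried as NA rows; the run always completes.
#' Deterministic given `config$seed`.
#'
#' @param children Validated children tibble.
#' @param schedule A `vx_schedule`.
#' @param config List overriding defaults: `uncertainty`
#'   (`"convenient_regression"`, `"bootstrap"`, `"none"`), `reps`,
#'   `seed`, `low_n` (flagging floor, default 25), `unfair`,
#'   `decompose`.
#' @param outcomes Outcomes to analyse; default all eleven.
#' @return A `vx_report`: list with `metrics` (tidy tibble, one row per
#'   outcome x ranking source), `decomposition` (named list of
#'   `vx_decomposition`), `decomposition_shares` (long tibble),
#'   `exclusions`, `settings`.
#' @export
run_national <- function(children, schedule = default_schedule(),
                         config = list(), outcomes = outcome_names()) {
  config <- default_config(config)
  dat <- with_status(children, schedule)
  rows <- list()
  decomps <- list()
  for (oc in outcomes) {
    for (src in c("wealth_only", "composite")) {
      rows[[paste(oc, src)]] <- safe_metrics(dat, oc, src, config)
    }
    if (isTRUE(config$decompose)) {
      ranked <- tryCatch(
        suppressWarnings(rank_sample(dat, oc, source = "composite",
                                     unfair = config$unfair)),
        error = function(e) NULL
      )
      if (!is.null(ranked)) {
        dec <- tryCatch(decompose_inequity(ranked), error = function(e) NULL)
        if (!is.null(dec) && !dec$degenerate) decomps[[oc]] <- dec
      }
    }
  }
  metrics <- dplyr::bind_rows(rows) |>
    dplyr::mutate(low_n = .data$n < config$low_n)
  shares <- if (length(decomps)) {
    dplyr::bind_rows(lapply(decomps, decomposition_report))
  } else {
    tibble::tibble(outcome = character(0), group = character(0),
                   contribution = numeric(0), share = numeric(0),
                   negative = logical(0))
  }
  structure(list(
    metrics = metrics,
    decomposition = decomps,
    decomposition_shares = shares,
    exclusions = dplyr::distinct(metrics[, c("outcome", "source",
                                             "n_excluded")]),
    settings = config
  ), class = "vx_report")
}

#' @method tidy vx_report
#' @export
tidy.vx_report <- function(x, ...) x$metrics

#' @method glance vx_report
#' @export
glance.vx_report <- function(x, ...) {
  tibble::tibble(n_outcomes = length(unique(x$metrics$outcome)),
                 n_degenerate = sum(x$metrics$degenerate),
                 uncertainty = x$settings$uncertainty)
}

#' @export
print.vx_report <- function(x, ...) {
  cat("National vaccine-equity report\n")
  print(x$metrics)
  invisible(x)
}

#' Per-district vaccine-equity report
#'
#' Computes coverage and the composite Wagstaff index within each
#' district. By default (`mode = "national_model"`) the composite
#' propensity is fitted once nationally and children are re-ranked
#' within each district, the minimal choice that yields well-defined
#' district indices when per-district models would be unstable;
#' `mode = "refit"` re-estimates the propensity within each district and
#' flags districts where the fit fails as `unstable`. District cells
#' with zero applicable children are NA; cells with prevalence 0 or 1
#' carry coverage and NA indices (never fabricated zeros); cells below
#' the `low_n` floor are flagged, not suppressed.
#'
#' @inheritParams run_national
#' @param mode `"national_model"` or `"refit"`.
#' @return A `vx_district_report`: list with `by_district` (tidy tibble:
#'   `district`, `outcome`, `n`, `coverage`, `W`, `E`, `degenerate`,
#'   `low_n`, `unstable`), `national` (the same outcomes nationally),
#'   `settings`.
#' @export
run_by_district <- function(children, schedule = default_schedule(),
                            config = list(),
                            mode = c("national_model", "refit"),
                            outcomes = outcome_names()) {
  mode <- match.arg(mode)
  config <- default_config(config)
  dat <- with_status(children, schedule)
  districts <- levels(dat$district)
  rows <- list()
  for (oc in outcomes) {
    nat_model <- NULL
    if (mode == "national_model") {
      nat_ranked <- tryCatch(
        suppressWarnings(rank_sample(dat, oc, source = "composite",
                                     unfair = config$unfair)),
        error = function(e) NULL
      )
      nat_model <- if (!is.null(nat_ranked)) attr(nat_ranked, "model")
    }
    for (d in districts) {
      sub <- dat[!is.na(dat$district) & dat$district == d, , drop = FALSE]
      sub$district <- factor(as.character(sub$district), levels = districts)
      applicable <- sum(!is.na(sub[[oc]]))
      if (applicable == 0) {
        rows[[paste(oc, d)]] <- tibble::tibble(
          district = d, outcome = oc, n = 0L, coverage = NA_real_,
          W = NA_real_, E = NA_real_, degenerate = TRUE, low_n = TRUE,
          unstable = FALSE)
        next
      }
      unstable <- FALSE
      prop <- nat_model
      if (mode == "refit") {
        prop <- NULL
      }
      res <- safe_metrics(sub, oc, "composite", config, propensity = prop)
      if (mode == "refit" && res$degenerate && applicable > 0) {
        unstable <- TRUE
      }
      rows[[paste(oc, d)]] <- tibble::tibble(
        district = d, outcome = oc, n = res$n,
        coverage = res$mu, W = res$W, E = res$E,
        degenerate = res$degenerate,
        low_n = res$n < config$low_n, unstable = unstable)
    }
  }
  national <- run_national(children, schedule,
                           config = utils::modifyList(config,
                                                      list(decompose = FALSE)),
                           outcomes = outcomes)
  structure(list(by_district = dplyr::bind_rows(rows),
                 national = national, mode = mode, settings = config),
            class = "vx_district_report")
}

#' @method tidy vx_district_report
#' @export
tidy.vx_district_report <- function(x, ...) x$by_district

#' Wide district tables (coverage and composite index)
#'
#' @param report A `vx_district_report`.
#' @return A list of two wide tibbles, `coverage` and `ci`, one row per
#'   district and one column per outcome.
#' @export
district_tables <- function(report) {
  assert_that(inherits(report, "vx_district_report"),
              "district_tables expects a vx_district_report")
  long <- report$by_district
  list(
    coverage = tidyr::pivot_wider(long[, c("district", "outcome", "coverage")],
                                  names_from = "outcome",
                                  values_from = "coverage"),
    ci = tidyr::pivot_wider(long[, c("district", "outcome", "W")],
                            names_from = "outcome", values_from = "W")
  )
}

#' Multi-survey trend report
#'
#' Analyses each survey year as an independent cross-section and tracks
#' coverage and the equity level (1 - composite Wagstaff index) across
#' years. No pooling or calendar-time model is applied.
#'
#' @param surveys Either a named list of children tibbles (names are
#'   survey years) or a single children tibble with a `survey_year`
#'   column; at least two years.
#' @inheritParams run_national
#' @return A `vx_trends`: list with `by_year` (named list of
#'   `vx_report`) and `trends` (tidy tibble: `survey_year`, `outcome`,
#'   `coverage`, `W`, `equity_level`, `n`).
#' @export
run_trends <- function(surveys, schedule = default_schedule(),
                       config = list(), outcomes = outcome_names()) {
  if (is.data.frame(surveys)) {
    assert_that("survey_year" %in% names(surveys) &&
                  !all(is.na(surveys$survey_year)),
                "a single surveys table needs a survey_year column")
    surveys <- split(surveys, surveys$survey_year)
  }
  assert_that(length(surveys) >= 2,
              "run_trends needs at least two survey years")
  years <- names(surveys) %||% as.character(seq_along(surveys))
  by_year <- lapply(surveys, function(ch) {
    run_national(ch, schedule, config, outcomes = outcomes)
  })
  names(by_year) <- years
  trends <- purrr::imap(by_year, function(rep, yr) {
    rep$metrics |>
      dplyr::filter(.data$source == "composite") |>
      dplyr::transmute(survey_year = as.integer(yr),
                       outcome = .data$outcome, coverage = .data$mu,
                       W = .data$W,
                       equity_level = .data$equity_level, n = .data$n)
  }) |>
    dplyr::bind_rows()
  structure(list(by_year = by_year, trends = trends), class = "vx_trends")
}

#' @method tidy vx_trends
#' @export
tidy.vx_trends <- function(x, ...) x$trends

#' Coverage and equity trend chart
#'
#' @param object A `vx_trends`.
#' @param outcomes Outcomes to display (default ZERO, FULL, MCV1, DTP3).
#' @param ... Unused.
#' @return A ggplot object: coverage and equity level against survey
#'   year, faceted by outcome.
#' @method autoplot vx_trends
#' @export
autoplot.vx_trends <- function(object,
                               outcomes = c("ZERO", "FULL", "MCV1", "DTP3"),
                               ...) {
  df <- object$trends |>
    dplyr::filter(.data$outcome %in% outcomes) |>
    tidyr::pivot_longer(c("coverage", "equity_level"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$survey_year, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "survey year", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write report artifacts to a directory
#'
#' Writes tidy CSV outputs (`national.csv`, `decomposition.csv`,
#' `district_coverage.csv`, `district_ci.csv`, `trends.csv`, as
#' applicable) and a `run_log.json` with settings and exclusion tallies.
#'
#' @param x A `vx_report`, `vx_district_report` or `vx_trends`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(written = character(0))
  if (inherits(x, "vx_report")) {
    readr::write_csv(x$metrics, file.path(dir, "national.csv"))
    readr::write_csv(x$decomposition_shares,
                     file.path(dir, "decomposition.csv"))
    log$written <- c("national.csv", "decomposition.csv")
    log$settings <- x$settings[c("uncertainty", "reps", "low_n")]
    log$seed <- x$settings$seed
    log$exclusions <- x$exclusions
  } else if (inherits(x, "vx_district_report")) {
    tabs <- district_tables(x)
    readr::write_csv(tabs$coverage, file.path(dir, "district_coverage.csv"))
    readr::write_csv(tabs$ci, file.path(dir, "district_ci.csv"))
    readr::write_csv(x$national$metrics, file.path(dir, "national.csv"))
    log$written <- c("district_coverage.csv", "district_ci.csv",
                     "national.csv")
    log$mode <- x$mode
    log$settings <- x$settings[c("uncertainty", "reps", "low_n")]
    log$seed <- x$settings$seed
  } else if (inherits(x, "vx_trends")) {
    readr::write_csv(x$trends, file.path(dir, "trends.csv"))
    log$written <- "trends.csv"
  } else {
    rlang::abort("write_report does not know this object type")
  }
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
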