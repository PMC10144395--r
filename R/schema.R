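#' Canonical antigen-dose names
#'
#' The eight antigen-doses tracked by the package, in schedule order:
#' BCG at birth, the DTP and OPV three-dose series, and the first
#' measles-containing vaccine dose (MCV1).
#'
#' @return Character vector of dose names.
#' @export
dose_names <- function() {
  c("bcg", "dtp1", "dtp2", "dtp3", "opv1", "opv2", "opv3", "mcv1")
}

dose_cols <- function() paste0("dose_", dose_names())

#' Names of the unfair-factor covariates
#'
#' The socio-demographic covariates treated as unacceptable ("unfair")
#' influences on vaccination status: sex of the child, urban/rural
#' residence, district, health-insurance status, maternal education, and
#' household wealth quintile. The sole fair factor — being underage for
#' scheduled doses — is derived from age and the schedule, not listed here.
#'
#' @return Character vector of column names.
#' @export
unfair_factors <- function() {
  c("sex", "urban", "district", "insured", "maternal_education",
    "wealth_quintile")
}

#' The canonical child-record schema
#'
#' One row per surveyed child. Required columns:
#' \describe{
#'   \item{child_id}{opaque identifier (character)}
#'   \item{age_months}{integer age in months, 0--59}
#'   \item{sex}{`"male"` or `"female"`}
#'   \item{district}{district (or district-pair) label; levels are
#'     data-driven}
#'   \item{urban}{`"urban"` or `"rural"`}
#'   \item{wealth_quintile}{integer 1--5, 1 = poorest}
#'   \item{maternal_education}{education level of the mother; default
#'     levels `"none" < "primary" < "secondary+"`, configurable}
#'   \item{insured}{household health-insurance status, `"yes"`/`"no"`}
#'   \item{weight}{positive survey sampling weight}
#'   \item{dose_bcg, dose_dtp1..3, dose_opv1..3, dose_mcv1}{0/1 received
#'     flags; a missing flag is an ingest error, never a silent zero}
#'   \item{survey_year}{optional integer survey year}
#' }
#'
#' @return A tibble describing each column.
#' @export
children_schema <- function() {
  tibble::tribble(
    ~column, ~type, ~required, ~description,
    "child_id", "character", TRUE, "opaque child identifier",
    "age_months", "integer", TRUE, "age in completed months (0-59)",
    "sex", "category", TRUE, "male / female",
    "district", "category", TRUE, "district of residence (data-driven levels)",
    "urban", "category", TRUE, "urban / rural",
    "wealth_quintile", "integer", TRUE, "household wealth quintile 1 (poorest) - 5",
    "maternal_education", "category", TRUE, "maternal education level (configurable levels)",
    "insured", "category", TRUE, "household health insurance: yes / no",
    "weight", "numeric", TRUE, "positive survey sampling weight",
    "survey_year", "integer", FALSE, "survey year"
  ) |>
    dplyr::bind_rows(tibble::tibble(
      column = dose_cols(), type = "integer", required = TRUE,
      description = paste0("received flag (0/1) for ", toupper(dose_names()))
    ))
}

#' Construct an immunization schedule
#'
#' A schedule maps each antigen-dose to the age in months at which a child
#' becomes eligible for it. Multi-dose series must have strictly increasing
#' eligibility ages. `full_exclusions` names the doses excluded from the
#' fully-immunized-for-age (FULL) definition; by default MCV1 is excluded
#' because it is commonly delivered through supplemental catch-up campaigns
#' and therefore reaches ages well outside its schedule age.
#'
#' @param entries Named integer vector or list: dose name -> eligibility age
#'   in months. Must cover all of [dose_names()].
#' @param full_exclusions Character vector of doses excluded from FULL.
#' @return A `vx_schedule`: a tibble with columns `dose`, `age_months` and
#'   a `full_exclusions` attribute.
#' @export
schedule <- function(entries, full_exclusions = "mcv1") {
  entries <- unlist(entries)
  missing <- setdiff(dose_names(), names(entries))
  assert_that(length(missing) == 0,
              paste0("schedule is missing doses: ",
                     paste(missing, collapse = ", ")))
  ages <- as.integer(entries[dose_names()])
  assert_that(all(!is.na(ages)) && all(ages >= 0),
              "schedule eligibility ages must be integers >= 0")
  for (series in list(c("dtp1", "dtp2", "dtp3"), c("opv1", "opv2", "opv3"))) {
    a <- ages[match(series, dose_names())]
    assert_that(all(diff(a) > 0),
                paste0("eligibility ages must strictly increase along the ",
                       toupper(sub("[0-9]$", "", series[1])),
                       " series (got ", paste(a, collapse = " >= "), ")"))
  }
  full_exclusions <- intersect(tolower(full_exclusions), dose_names())
  out <- tibble::tibble(dose = dose_names(), age_months = ages)
  structure(out, full_exclusions = full_exclusions,
            class = c("vx_schedule", class(out)))
}

#' Default national immunization schedule
#'
#' Encodes a Cambodia-style NIP schedule: BCG at birth, DTP and OPV at
#' (approximately) 6, 10 and 14 weeks — integerized to 2, 3 and 4 months —
#' and MCV1 at 9 months. MCV1 is excluded from FULL by default.
#'
#' @return A `vx_schedule`.
#' @export
default_schedule <- function() {
  schedule(c(bcg = 0L, dtp1 = 2L, dtp2 = 3L, dtp3 = 4L,
             opv1 = 2L, opv2 = 3L, opv3 = 4L, mcv1 = 9L))
}

#' Load an immunization schedule from a YAML file
#'
#' The file has an `entries` map (dose name -> eligibility age in months)
#' and an optional `full_exclusions` list. Doses omitted from `entries`
#' fall back to the default schedule; with `path = NULL` the default
#' schedule is returned unchanged.
#'
#' @param path Path to a YAML schedule file, or `NULL` for the default.
#' @return A `vx_schedule`.
#' @export
load_schedule <- function(path = NULL) {
  def <- default_schedule()
  if (is.null(path)) return(def)
  assert_that(file.exists(path), paste0("schedule file not found: ", path))
  cfg <- yaml::read_yaml(path)
  entries <- setNames(def$age_months, def$dose)
  for (nm in names(cfg$entries %||% list())) {
    key <- tolower(nm)
    assert_that(key %in% dose_names(),
                paste0("unknown dose in schedule file: ", nm))
    entries[[key]] <- cfg$entries[[nm]]
  }
  excl <- cfg$full_exclusions %||% attr(def, "full_exclusions")
  schedule(entries, full_exclusions = unlist(excl))
}

new_children <- function(df, education_levels, district_levels) {
  df$child_id <- as.character(df$child_id)
  df$age_months <- as.integer(df$age_months)
  df$wealth_quintile <- as.integer(df$wealth_quintile)
  df$weight <- as.numeric(df$weight)
  df$sex <- factor(as.character(df$sex), levels = c("male", "female"))
  df$urban <- factor(as.character(df$urban), levels = c("urban", "rural"))
  df$insured <- factor(as.character(df$insured), levels = c("no", "yes"))
  df$maternal_education <- factor(as.character(df$maternal_education),
                                  levels = education_levels)
  df$district <- factor(as.character(df$district), levels = district_levels)
  if (!"survey_year" %in% names(df)) df$survey_year <- NA_integer_
  df$survey_year <- as.integer(df$survey_year)
  for (dc in dose_cols()) df[[dc]] <- as.integer(df[[dc]])
  dplyr::select(df, dplyr::all_of(c(
    "child_id", "survey_year", "age_months", "sex", "district", "urban",
    "wealth_quintile", "maternal_education", "insured", "weight",
    dose_cols()
  )))
}

#' Validate a table of child records
#'
#' Checks each row against the canonical schema invariants: age in 0--59,
#' positive weight, wealth quintile in 1..5, recognised category levels,
#' and a 0/1 flag for every antigen-dose. Rows failing any check are
#' rejected with a reason — ingest never imputes a default category or a
#' silent zero dose. Category levels for `district` (and, unless
#' `education_levels` is supplied, `maternal_education`) are data-driven.
#'
#' @param df Data frame with the columns of [children_schema()].
#' @param education_levels Ordered character vector of education levels;
#'   `NULL` uses the default three levels extended by any extra labels
#'   present in the data.
#' @return A tibble of accepted, typed records. The rejected rows, with a
#'   `reason` column, are attached as attribute `"rejected"` (see
#'   [rejected_rows()]); the number rejected is attribute
#'   `"n_excluded"`.
#' @export
validate_children <- function(df, education_levels = NULL) {
  df <- tibble::as_tibble(df)
  required <- setdiff(children_schema()$column[children_schema()$required],
                      "survey_year")
  missing_cols <- setdiff(required, names(df))
  assert_that(length(missing_cols) == 0,
              paste0("missing required column(s): ",
                     paste(missing_cols, collapse = ", ")))

  edu_seen <- unique(as.character(df$maternal_education))
  edu_seen <- edu_seen[!is.na(edu_seen) & edu_seen != ""]
  if (is.null(education_levels)) {
    default_edu <- c("none", "primary", "secondary+")
    education_levels <- c(intersect(default_edu, c(default_edu, edu_seen)),
                          sort(setdiff(edu_seen, default_edu)))
  }
  district_levels <- sort(unique(as.character(df$district)))
  district_levels <- district_levels[district_levels != ""]

  num_ok <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  blank <- function(x) is.na(x) | as.character(x) == ""
  reasons <- vector("list", nrow(df))
  add <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }

  add(blank(df$child_id), "missing child_id")
  add(!num_ok(df$age_months), "non-numeric age_months")
  age <- suppressWarnings(as.numeric(df$age_months))
  add(num_ok(df$age_months) & (age < 0 | age > 59 | age != floor(age)),
      "age_months outside 0-59")
  add(!num_ok(df$weight), "non-numeric weight")
  wt <- suppressWarnings(as.numeric(df$weight))
  add(num_ok(df$weight) & wt <= 0, "nonpositive weight")
  add(!num_ok(df$wealth_quintile) |
        !(suppressWarnings(as.numeric(df$wealth_quintile)) %in% 1:5),
      "wealth_quintile not in 1..5")
  add(!(as.character(df$sex) %in% c("male", "female")), "invalid sex")
  add(!(as.character(df$urban) %in% c("urban", "rural")), "invalid urban")
  add(!(tolower(as.character(df$insured)) %in% c("yes", "no")),
      "invalid insured")
  add(blank(df$district), "missing district")
  add(!(as.character(df$maternal_education) %in% education_levels),
      "missing or unrecognised maternal_education")
  for (dc in dose_cols()) {
    v <- suppressWarnings(as.numeric(df[[dc]]))
    add(is.na(v) | !(v %in% c(0, 1)), paste0("missing or non-binary ", dc))
  }

  bad <- vapply(reasons, function(r) length(r) > 0, logical(1))
  rejected <- df[bad, , drop = FALSE]
  rejected$reason <- vapply(reasons[bad], paste, character(1), collapse = "; ")
  accepted <- df[!bad, , drop = FALSE]
  accepted$insured <- tolower(as.character(accepted$insured))
  out <- new_children(accepted, education_levels, district_levels)
  attr(out, "rejected") <- tibble::as_tibble(rejected)
  attr(out, "n_excluded") <- sum(bad)
  if (any(bad)) {
    rlang::inform(paste0(sum(bad), " of ", nrow(df),
                         " rows rejected during validation; see rejected_rows()"))
  }
  out
}

#' Rows rejected during ingest validation
#'
#' @param children A validated children tibble from [read_children()] or
#'   [validate_children()].
#' @return A tibble of rejected input rows with a `reason` column.
#' @export
rejected_rows <- function(children) {
  attr(children, "rejected") %||%
    tibble::tibble(reason = character(0))
}

#' Read child-level immunization records
#'
#' Reads a flat CSV (UTF-8, header row), one row per child, in the
#' documented schema (see [children_schema()]). `format = "dhs_flat"`
#' accepts a pre-flattened survey export whose columns are renamed through
#' a column-mapping configuration (`col_map`): either a named character
#' vector or a YAML file of `canonical_name: source_name` pairs. Raw DHS
#' recode files (.dta/.sav with variable codebooks) are out of scope and
#' must be flattened upstream.
#'
#' @param path CSV file path.
#' @param format `"csv"` (canonical column names) or `"dhs_flat"`
#'   (renamed through `col_map`).
#' @param col_map Optional column mapping, named vector or YAML path.
#' @param education_levels Passed to [validate_children()].
#' @return A validated children tibble; rejected rows are available via
#'   [rejected_rows()].
#' @export
read_children <- function(path, format = c("csv", "dhs_flat"),
                          col_map = NULL, education_levels = NULL) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("input file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (format == "dhs_flat" && is.null(col_map)) {
    rlang::abort("format 'dhs_flat' requires a col_map configuration")
  }
  if (!is.null(col_map)) {
    if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
      col_map <- unlist(yaml::read_yaml(col_map))
    }
    present <- col_map[col_map %in% names(df)]
    df <- dplyr::rename(df, !!!setNames(as.list(unname(present)),
                                        names(present)))
  }
  validate_children(df, education_levels = education_levels)
}

#' Write child records to the canonical CSV
#'
#' Inverse of [read_children()]: writing then re-reading reproduces all
#' fields exactly.
#'
#' @param children Validated children tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_children <- function(children, path) {
  out <- dplyr::mutate(children, dplyr::across(dplyr::where(is.factor),
                                               as.character))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
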