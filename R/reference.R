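#' Reference national estimates, Cambodia DHS 2014
#'
#' National coverage/prevalence, wealth-only and composite Wagstaff
#' concentration indices, and composite-ranking absolute equity gaps for
#' the eleven vaccination outcomes, as published for Cambodia's 2014
#' Demographic and Health Survey in the multivariate vaccine-equity
#' literature. The underlying microdata are registration-gated, so these
#' values cannot be recomputed at desk scale; they are shipped for
#' arithmetic cross-checks (equity-level and percentage-point identities)
#' and for orienting synthetic scenarios, not as test oracles for the
#' estimators.
#'
#' @return Tibble with `outcome`, `coverage_pct` (percent),
#'   `W_wealth_only`, `W_composite`, `AEG` (proportion scale).
#' @export
reference_national_2014 <- function() {
  path <- system.file("extdata", "cambodia_dhs2014_national.csv",
                      package = "vaxequity", mustWork = TRUE)
  readr::read_csv(path, col_types = "cdddd", progress = FALSE)
}
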