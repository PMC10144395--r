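# A 20-child hand-built cohort spanning two districts with a visible
# wealth gradient in COMPLETE status.
fixture_cohort <- function() {
  make_children(dplyr::bind_rows(lapply(1:20, function(i) {
    wealth <- ((i - 1) %% 5) + 1
    covered <- wealth >= 3 || i %in% c(1, 7)
    make_child(paste0("c", i), age = 30 + i,
               district = ifelse(i <= 10, "East", "West"),
               wealth = wealth, weight = 0.5 + 0.1 * i,
               doses = rep(as.integer(covered), 8))
  })))
}

test_that("national metrics equal an independently scripted recomputation", {
  ch <- fixture_cohort()
  rep <- run_national(ch, config = list(uncertainty = "none",
                                        decompose = FALSE),
                      outcomes = "COMPLETE")
  row <- rep$metrics[rep$metrics$source == "wealth_only", ]
  # brute-force recomputation from raw pieces
  h <- as.integer(vapply(1:20, function(i) {
    (((i - 1) %% 5) + 1) >= 3 || i %in% c(1, 7)
  }, logical(1)))
  w <- 0.5 + 0.1 * (1:20)
  wealth <- ((1:20 - 1) %% 5) + 1
  mu <- oracle_wmean(h, w)
  r <- oracle_rank(wealth, w)
  rbar <- oracle_wmean(r, w)
  covw <- oracle_wmean((h - mu) * (r - rbar), w)
  C <- 2 * covw / mu
  expect_equal(row$mu, mu, tolerance = 1e-12)
  expect_equal(row$C, C, tolerance = 1e-12)
  expect_equal(row$W, C / (1 - mu), tolerance = 1e-12)
  expect_equal(row$E, 4 * mu * C, tolerance = 1e-12)
  expect_equal(row$equity_level, 1 - C / (1 - mu), tolerance = 1e-12)
})

test_that("reports are deterministic under a fixed seed", {
  cfg <- synthetic_config(n_children = 900, seed = 17)
  ch <- generate_children(cfg)
  cfgl <- list(uncertainty = "bootstrap", reps = 120, seed = 5)
  r1 <- run_national(ch, config = cfgl, outcomes = c("DTP3", "ZERO"))
  r2 <- run_national(ch, config = cfgl, outcomes = c("DTP3", "ZERO"))
  expect_identical(r1$metrics, r2$metrics)
})

test_that("a one-district dataset gives district metrics equal to national", {
  cfg <- synthetic_config(
    n_children = 1200, seed = 23,
    districts = tibble::tibble(name = "Only", share = 1, effect = 0))
  ch <- generate_children(cfg)
  conf <- list(uncertainty = "none", decompose = FALSE)
  nat <- run_national(ch, config = conf, outcomes = "DTP3")
  dist <- run_by_district(ch, config = conf, outcomes = "DTP3")
  drow <- dist$by_district
  nrow_ <- nat$metrics[nat$metrics$source == "composite", ]
  expect_equal(drow$coverage, nrow_$mu, tolerance = 1e-12)
  expect_equal(drow$W, nrow_$W, tolerance = 1e-12)
})

test_that("a district with zero prevalence reports 0% coverage and NA index", {
  # East has zero-dose infants; West has none at all
  ch <- make_children(dplyr::bind_rows(lapply(1:40, function(i) {
    district <- ifelse(i <= 20, "East", "West")
    zero_dose <- district == "East" && (i %% 4 == 0)
    make_child(paste0("c", i), age = 4 + (i %% 8),
               district = district, wealth = ((i - 1) %% 5) + 1,
               doses = rep(as.integer(!zero_dose), 8))
  })))
  rep <- run_by_district(ch, config = list(uncertainty = "none"),
                         outcomes = "ZERO")
  west <- rep$by_district[rep$by_district$district == "West", ]
  expect_equal(west$coverage, 0)
  expect_true(is.na(west$W))
  expect_true(west$degenerate)
  east <- rep$by_district[rep$by_district$district == "East", ]
  expect_equal(east$coverage, 0.25, tolerance = 1e-12)
})

test_that("district coverages aggregate exactly to national coverage", {
  cfg <- synthetic_config(n_children = 3000, seed = 29)
  ch <- generate_children(cfg)
  conf <- list(uncertainty = "none", decompose = FALSE)
  nat <- run_national(ch, config = conf, outcomes = "DTP3")
  dist <- run_by_district(ch, config = conf, outcomes = "DTP3")
  st <- with_status(ch)
  ok <- !is.na(st$DTP3)
  mass <- tapply(st$weight[ok], as.character(st$district[ok]), sum)
  long <- dist$by_district
  covs <- setNames(long$coverage, long$district)[names(mass)]
  expect_equal(sum(mass * covs) / sum(mass),
               nat$metrics$mu[nat$metrics$source == "composite"],
               tolerance = 1e-10)
})

test_that("refit mode recovers district-specific gradients at large n", {
  districts <- tibble::tibble(name = c("Flat", "Steep"),
                              share = c(0.5, 0.5), effect = c(0, 0))
  # Steep district: strong wealth gradient; Flat: none. Build by
  # generating two one-district surveys and binding them.
  flat <- generate_children(synthetic_config(
    n_children = 15000, seed = 41,
    districts = districts[1, ] |> dplyr::mutate(share = 1),
    coefficients = list(wealth = rep(0, 5), education = c(0, 0, 0),
                        urban = 0, female = 0, insured = 0)))
  steep <- generate_children(synthetic_config(
    n_children = 15000, seed = 42,
    districts = districts[2, ] |> dplyr::mutate(share = 1),
    coefficients = list(wealth = c(-1, -0.5, 0, 0.5, 1),
                        education = c(0, 0, 0), urban = 0, female = 0,
                        insured = 0)))
  steep$child_id <- paste0("s", steep$child_id)
  ch <- suppressMessages(validate_children(dplyr::bind_rows(flat, steep)))
  rep <- run_by_district(ch, config = list(uncertainty = "none"),
                         mode = "refit", outcomes = "DTP3")
  long <- rep$by_district
  W_flat <- long$W[long$district == "Flat"]
  W_steep <- long$W[long$district == "Steep"]
  truth_steep <- ground_truth(synthetic_config(
    n_children = 1, seed = 1,
    districts = districts[2, ] |> dplyr::mutate(share = 1),
    coefficients = list(wealth = c(-1, -0.5, 0, 0.5, 1),
                        education = c(0, 0, 0), urban = 0, female = 0,
                        insured = 0)), "DTP3")$W
  expect_lt(abs(W_flat), 0.06)
  expect_gt(W_steep, 0.5 * truth_steep)
  expect_lt(abs(W_steep - truth_steep), 0.12)
})

test_that("two identical surveys produce identical trend metrics", {
  cfg <- synthetic_config(n_children = 800, seed = 31, survey_year = 2004)
  a <- generate_children(cfg)
  b <- dplyr::mutate(a, survey_year = 2010L)
  tr <- run_trends(list(`2004` = a, `2010` = b),
                   config = list(uncertainty = "none", decompose = FALSE),
                   outcomes = c("DTP3", "ZERO"))
  td <- tr$trends
  for (oc in c("DTP3", "ZERO")) {
    sub <- td[td$outcome == oc, ]
    expect_equal(sub$coverage[1], sub$coverage[2], tolerance = 1e-12)
    expect_equal(sub$W[1], sub$W[2], tolerance = 1e-12)
  }
  expect_equal(td$equity_level, 1 - td$W)
})

test_that("rising-coverage scenarios yield monotone coverage trends", {
  scen <- default_scenarios(n_children = 4000, seed = 3)
  surveys <- lapply(scen, generate_children)
  tr <- run_trends(surveys, config = list(uncertainty = "none",
                                          decompose = FALSE),
                   outcomes = c("DTP3", "MCV1"))
  for (oc in c("DTP3", "MCV1")) {
    cov <- tr$trends$coverage[tr$trends$outcome == oc]
    expect_true(all(diff(cov) > 0))
  }
})

test_that("report artifacts are written as CSV plus a run log", {
  cfg <- synthetic_config(n_children = 700, seed = 57)
  ch <- generate_children(cfg)
  rep <- run_national(ch, config = list(uncertainty = "none"),
                      outcomes = c("DTP3", "ZERO"))
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "national.csv")))
  expect_true(file.exists(file.path(dir, "decomposition.csv")))
  log <- jsonlite::read_json(file.path(dir, "run_log.json"))
  expect_equal(log$settings$uncertainty, "none")
  back <- readr::read_csv(file.path(dir, "national.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep$metrics))
})
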