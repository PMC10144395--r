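test_that("the seed fully determines the generated survey", {
  cfg <- synthetic_config(n_children = 500, seed = 123)
  a <- generate_children(cfg)
  b <- generate_children(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_children(synthetic_config(n_children = 500, seed = 124))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("with all effects zero every antigen's coverage matches its base rate", {
  p <- 0.8
  cfg <- null_scenario(100000, 71, base_rates = setNames(
    rep(qlogis(p), 8), dose_names()), dropout = 0)
  ch <- generate_children(cfg)
  st <- status_table(ch)
  for (oc in toupper(dose_names())) {
    ok <- !is.na(st[[oc]])
    expect_equal(weighted.mean(st[[oc]][ok], ch$weight[ok]), p,
                 tolerance = 0.005 / p)  # within 0.5 pp of 80%
  }
})

test_that("positive dropout makes series coverage strictly decreasing", {
  cfg <- synthetic_config(n_children = 30000, seed = 73)
  ch <- generate_children(cfg)
  st <- status_table(ch)
  cov <- vapply(c("DTP1", "DTP2", "DTP3"), function(oc) {
    ok <- !is.na(st[[oc]])
    weighted.mean(st[[oc]][ok], ch$weight[ok])
  }, numeric(1))
  expect_true(all(diff(cov) < 0))
  # nested series: a child with DTP3 also has DTP1 and DTP2
  expect_true(all(ch$dose_dtp1[ch$dose_dtp3 == 1] == 1))
  expect_true(all(ch$dose_dtp2[ch$dose_dtp3 == 1] == 1))
})

test_that("generated data conform to the ingest schema", {
  cfg <- synthetic_config(n_children = 400, seed = 5)
  ch <- generate_children(cfg)
  revalidated <- suppressMessages(validate_children(
    dplyr::mutate(ch, dplyr::across(dplyr::where(is.factor), as.character))))
  expect_equal(nrow(revalidated), 400)
  expect_equal(nrow(rejected_rows(revalidated)), 0)
})

test_that("ground truth is exact for a single binary factor", {
  # one 50/50 district split, outcome probability 0.9 vs 0.7
  cfg <- synthetic_config(
    n_children = 1, seed = 1,
    districts = tibble::tibble(name = c("lo", "hi"), share = c(0.5, 0.5),
                               effect = c(qlogis(0.7), qlogis(0.9))),
    wealth_education_correlation = 0,
    coefficients = list(wealth = rep(0, 5), education = rep(0, 3),
                        urban = 0, female = 0, insured = 0),
    base_rates = setNames(rep(0, 8), dose_names()), dropout = 0)
  gt <- ground_truth(cfg, "BCG")
  expect_equal(gt$mu, 0.8, tolerance = 1e-12)
  expect_equal(gt$AEG, 0.2, tolerance = 1e-12)
  # enumeration oracle cross-checked by direct arithmetic: two tied
  # blocks of mass 1/2 at mid-ranks 1/4 and 3/4
  cov_true <- 0.5 * 0.7 * (0.25 - 0.5) + 0.5 * 0.9 * (0.75 - 0.5)
  C_true <- 2 * cov_true / 0.8
  expect_equal(gt$C, C_true, tolerance = 1e-12)
  expect_equal(gt$W, C_true / 0.2, tolerance = 1e-12)
  # and by brute-force simulation
  big <- generate_children(synthetic_config(
    n_children = 200000, seed = 2,
    districts = cfg$districts, wealth_education_correlation = 0,
    coefficients = cfg$coefficients, base_rates = cfg$base_rates,
    dropout = 0, weight_model = "uniform"))
  stb <- status_table(big)
  ok <- !is.na(stb$BCG)
  expect_equal(mean(stb$BCG[ok]), 0.8, tolerance = 0.005)
})

test_that("all-null effects give zero ground-truth inequity", {
  cfg <- null_scenario(1, 1)
  gt <- ground_truth(cfg, "DTP3")
  expect_equal(gt$W, 0, tolerance = 1e-12)
  expect_equal(gt$AEG, 0, tolerance = 1e-12)
})

test_that("estimated composite W converges to enumeration truth with n", {
  truth <- ground_truth(wealth_only_scenario(1, 1), "DTP3")$W
  err <- vapply(c(5000, 50000), function(n) {
    ch <- with_status(generate_children(wealth_only_scenario(n, 83)))
    r <- rank_sample(ch, "DTP3")
    iq <- inequity(r, uncertainty = "none")
    abs(iq$W - truth)
  }, numeric(1))
  expect_lt(err[2], 0.03)
  expect_lt(err[2], err[1] + 0.02)  # no blow-up; typically shrinking
})

test_that("composite W under the null is biased up but shrinks with n", {
  # ranking an outcome on its own fitted noise inflates W in finite
  # samples; the bias must shrink as n grows
  what <- function(n, seed) {
    ch <- with_status(generate_children(null_scenario(n, seed)))
    r <- suppressWarnings(rank_sample(ch, "DTP3"))
    inequity(r, uncertainty = "none")$W
  }
  w_small <- vapply(1:8, function(i) what(2000, 300 + i), numeric(1))
  w_large <- vapply(1:8, function(i) what(20000, 400 + i), numeric(1))
  expect_gt(mean(w_small), 0)          # documented upward bias
  expect_lt(mean(w_large), mean(w_small))
})

test_that("oversized lattices are refused with advice", {
  cfg <- synthetic_config(n_children = 10, seed = 1)
  expect_error(ground_truth(cfg, "DTP3", max_cells = 100),
               "Monte-Carlo|lattice")
})
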