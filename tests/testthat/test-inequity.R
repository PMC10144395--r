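test_that("concentration index matches hand-computed and degenerate cases", {
  r4 <- fractional_rank(1:4)
  expect_equal(as.numeric(concentration_index(c(0, 0, 1, 1), r4)), 0.5)
  expect_equal(as.numeric(concentration_index(rep(1, 4), r4)), 0)
  C0 <- concentration_index(rep(0, 4), r4)
  expect_equal(as.numeric(C0), 0)
  expect_true(attr(C0, "degenerate"))
})

test_that("covariance formula equals the concentration-curve geometry", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 200
    v <- runif(n)
    w <- runif(n, 0.2, 4)
    h <- as.integer(runif(n) < plogis(2 * v - 0.5))
    r <- fractional_rank(v, w)
    expect_equal(as.numeric(concentration_index(h, r, w)),
                 oracle_ci_curve(h, v, w), tolerance = 1e-10)
  }
})

test_that("index is scale-invariant in weights and antisymmetric in rank", {
  set.seed(31)
  v <- runif(60)
  w <- runif(60, 0.5, 2)
  h <- rbinom(60, 1, 0.6)
  C <- as.numeric(concentration_index(h, fractional_rank(v, w), w))
  expect_equal(as.numeric(concentration_index(h, fractional_rank(v, w * 3), w * 3)),
               C, tolerance = 1e-12)
  expect_equal(as.numeric(concentration_index(h, fractional_rank(-v, w), w)),
               -C, tolerance = 1e-12)
})

test_that("Wagstaff and Erreygers transforms satisfy bounds and identity", {
  expect_equal(wagstaff_index(0.5, 0.5), 1)
  expect_equal(wagstaff_index(0, 0.3), 0)
  expect_true(is.na(wagstaff_index(0, 0)))
  expect_true(is.na(wagstaff_index(0.1, 1)))
  expect_equal(erreygers_index(0.5, 0.5), 1)
  expect_equal(erreygers_index(0.2, 0), 0)
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    h <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(h)) < 2) next
    w <- runif(n, 0.1, 3)
    r <- fractional_rank(runif(n), w)
    mu <- weighted.mean(h, w)
    C <- as.numeric(concentration_index(h, r, w))
    expect_equal(erreygers_index(C, mu),
                 4 * mu * (1 - mu) * wagstaff_index(C, mu),
                 tolerance = 1e-10)
  }
})

test_that("full concentration among the top-ranked attains W = 1 exactly", {
  for (mu in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
    # two-point sample with weights aligned to mu: the bottom mass has
    # none of the outcome, the top mass all of it
    h <- c(0, 1)
    w <- c(1 - mu, mu)
    r <- fractional_rank(c(1, 2), w)
    C <- as.numeric(concentration_index(h, r, w))
    expect_equal(wagstaff_index(C, mu), 1, tolerance = 1e-12)
  }
})

test_that("equity level is one minus the Wagstaff index", {
  expect_equal(equity_level(0), 1)
  expect_equal(equity_level(1), 0)
  expect_equal(equity_level(-0.2), 1.2)
})

test_that("absolute equity gap matches a brute-force two-child quintile", {
  # 10 equal-weight children ranked by wealth: quintiles of 2 children
  doses <- lapply(1:10, function(i) rep(as.integer(i %in% c(1, 4, 6, 8, 9, 10)), 8))
  ch <- make_children(dplyr::bind_rows(lapply(1:10, function(i) {
    make_child(paste0("c", i), age = 30, wealth = ceiling(i / 2),
               doses = doses[[i]])
  })))
  chs <- with_status(ch)
  r <- rank_sample(chs, "COMPLETE", source = "wealth_only")
  got <- absolute_equity_gap(r)
  h <- vapply(doses, function(d) d[1], integer(1))
  expect_equal(got, mean(h[9:10]) - mean(h[1:2]))
})

test_that("absolute equity gap attains the bounds and the null", {
  # full split: top quintile covered, bottom not
  ch <- with_status(make_children(dplyr::bind_rows(lapply(1:10, function(i) {
    make_child(paste0("c", i), age = 30, wealth = ceiling(i / 2),
               doses = rep(as.integer(i > 8), 8))
  }))))
  r <- rank_sample(ch, "COMPLETE", source = "wealth_only")
  expect_equal(absolute_equity_gap(r), 1)
  # outcome independent of rank at large n: gap near zero
  cfg <- null_scenario(20000, 77)
  big <- with_status(generate_children(cfg))
  rb <- rank_sample(big, "DTP3", source = "wealth_only")
  expect_lt(abs(absolute_equity_gap(rb)), 0.03)
})

test_that("degenerate strata yield NA Wagstaff and zero Erreygers", {
  ch <- with_status(make_children(dplyr::bind_rows(lapply(1:30, function(i) {
    make_child(paste0("c", i), age = 6, wealth = sample(1:5, 1),
               doses = c(1, rep(0L, 7)))
  }))))
  # nobody is zero-dose: burden prevalence 0
  r <- rank_sample(ch, "ZERO", source = "wealth_only")
  iq <- inequity(r, uncertainty = "none")
  expect_equal(iq$mu, 0)
  expect_true(is.na(iq$W))
  expect_true(iq$degenerate)
  expect_equal(iq$C, 0)
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  cfg <- wealth_only_scenario(800, 19)
  ch <- with_status(generate_children(cfg))
  r <- rank_sample(ch, "DTP3", source = "wealth_only")
  u1 <- index_uncertainty(r, "bootstrap", reps = 150, seed = 99)
  u2 <- index_uncertainty(r, "bootstrap", reps = 150, seed = 99)
  expect_identical(u1, u2)
  u3 <- index_uncertainty(r, "bootstrap", reps = 150, seed = 100)
  expect_false(identical(u1$ci, u3$ci))
})

test_that("convenient regression warns on very small samples", {
  ch <- with_status(make_children(dplyr::bind_rows(lapply(1:5, function(i) {
    make_child(paste0("c", i), age = 30, wealth = i,
               doses = rep(as.integer(i > 2), 8))
  }))))
  r <- rank_sample(ch, "COMPLETE", source = "wealth_only")
  expect_warning(index_uncertainty(r, "convenient_regression"), "caution")
})

test_that("convenient-regression slope reproduces the index estimate", {
  cfg <- wealth_only_scenario(3000, 23)
  ch <- with_status(generate_children(cfg))
  r <- rank_sample(ch, "DTP3", source = "composite")
  iq <- inequity(r, uncertainty = "convenient_regression")
  expect_gt(iq$se_W, 0)
  expect_equal(unname(iq$ci_hi - iq$W), unname(iq$W - iq$ci_lo),
               tolerance = 1e-10)
  # the interval is centred on W by construction and W is finite
  expect_true(iq$ci_lo < iq$W && iq$W < iq$ci_hi)
})
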