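test_that("parameter draws are reproducible and respect degenerate intervals", {
  spec <- list(
    mc_parameter("slope", 5.8, 2.45, 9.15, "normal_positive"),
    mc_parameter("fixed", 0.7, 0.7, 0.7, "beta"),
    mc_parameter("cost", 2000, 1400, 2600, "gamma")
  )
  a <- sample_parameters(spec, 200, seed = 5)
  b <- sample_parameters(spec, 200, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$fixed == 0.7))
  expect_true(all(a$slope > 0))
  expect_true(all(a$cost > 0))
})

test_that("invalid parameter specifications are rejected", {
  expect_error(mc_parameter("x", 5, 6, 9), "central outside")
  expect_error(mc_parameter("x", 1, -1, 2, family = "lognormal"), "positive")
  expect_error(mc_parameter("x", 0.5, 0.2, 1.4, family = "beta"), "\\[0, 1\\]")
})

test_that("salt-BP slope draws reproduce the published 95% interval", {
  spec <- list(mc_parameter("slope", 5.8, 2.45, 9.15, "normal_positive"))
  draws <- sample_parameters(spec, 10000, seed = 11)$slope
  q <- quantile(draws, c(0.025, 0.975))
  expect_lt(abs(q[[1]] - 2.45), 0.12)
  expect_lt(abs(q[[2]] - 9.15), 0.12)
  expect_lt(abs(median(draws) - 5.8), 0.06)
})

test_that("interval widths in draws are monotone in the specified CI", {
  narrow <- sample_parameters(list(mc_parameter("r", 1, 0.9, 1.1, "lognormal")), 500, seed = 3)$r
  wide <- sample_parameters(list(mc_parameter("r", 1, 0.5, 2.0, "lognormal")), 500, seed = 3)$r
  expect_lt(diff(quantile(narrow, c(0.025, 0.975))), diff(quantile(wide, c(0.025, 0.975))))
  # common random numbers: same seed preserves the direction of each draw
  expect_true(all((narrow > 1) == (wide > 1)))
})

test_that("degenerate intervals collapse the uncertainty intervals to the point", {
  epi <- fast_epi()
  salt_change <- list(
    female = list(central = 0.93, ci_low = 0.93, ci_high = 0.93),
    male = list(central = 1.34, ci_low = 1.34, ci_high = 1.34)
  )
  spec <- default_mc_parameters(epi, salt_change, salt_bp_slope(5.8, 5.8, 5.8))
  spec <- lapply(spec, function(p) mc_parameter(p$name, p$central, p$central, p$central, p$family))
  mc <- run_monte_carlo(epi, salt_change, n_iter = 5, seed = 2, spec = spec)
  expect_equal(mc$table$lo95, mc$table$point, tolerance = 1e-9)
  expect_equal(mc$table$hi95, mc$table$point, tolerance = 1e-9)
})

test_that("uncertainty intervals bracket the point estimate and widen with RR uncertainty", {
  epi <- fast_epi()
  salt_change <- list(
    female = list(central = 0.93, ci_low = 0.85, ci_high = 1.02),
    male = list(central = 1.34, ci_low = 1.22, ci_high = 1.47)
  )
  mc <- run_monte_carlo(epi, salt_change, n_iter = 40, seed = 9)
  tab <- mc$table
  expect_true(all(tab$lo95 <= tab$point + 1e-9))
  expect_true(all(tab$hi95 >= tab$point - 1e-9))
  expect_equal(mc$failures, 0)

  # widen the relative-risk interval, keep the same seed ladder
  spec <- default_mc_parameters(epi, salt_change)
  wide <- lapply(spec, function(p) {
    if (grepl("^rr_scale_", p$name)) {
      mc_parameter(p$name, p$central, p$ci_low^2, p$ci_high^2, p$family)
    } else {
      p
    }
  })
  mc_wide <- run_monte_carlo(epi, salt_change, n_iter = 40, seed = 9, spec = wide)
  pick <- function(t, o) t[t$outcome == o, ]
  for (o in c("male.20y.ihd_cases", "female.20y.stroke_cases")) {
    w0 <- pick(mc$table, o)$hi95 - pick(mc$table, o)$lo95
    w1 <- pick(mc_wide$table, o)$hi95 - pick(mc_wide$table, o)$lo95
    expect_gt(w1, w0)
  }
})

test_that("reduced and larger draw counts give consistent BP-shift intervals", {
  spec <- list(
    mc_parameter("slope", 5.8, 2.45, 9.15, "normal_positive"),
    mc_parameter("salt", 1.12, 1.05, 1.20, "normal_positive")
  )
  ui <- function(n, seed) {
    d <- sample_parameters(spec, n, seed)
    quantile(d$salt * d$slope / 5.88, c(0.025, 0.975))
  }
  small <- ui(500, 21)
  large <- ui(10000, 22)
  expect_lt(max(abs(small - large)), 0.12) # percentile sampling error at n = 500
})

test_that("the BP-shift interval covers the true value in most replicates", {
  true_slope <- 5.8
  true_salt <- 1.12
  truth <- true_salt * true_slope / 5.88
  spec <- list(
    mc_parameter("slope", true_slope, 2.45, 9.15, "normal_positive"),
    mc_parameter("salt", true_salt, 1.05, 1.20, "normal_positive")
  )
  covered <- vapply(1:100, function(rep) {
    d <- sample_parameters(spec, 200, seed = 1000 + rep)
    q <- quantile(d$salt * d$slope / 5.88, c(0.025, 0.975))
    q[[1]] <= truth && truth <= q[[2]]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
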