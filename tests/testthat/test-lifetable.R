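test_that("the validator rejects out-of-range rates with coordinates", {
  epi <- fast_epi()
  expect_silent(validate_epi(epi))

  bad <- epi
  i <- which(bad$disease_rates$disease == "ihd" & bad$disease_rates$sex == "male" &
    bad$disease_rates$age == 60)
  bad$disease_rates$case_fatality[i] <- 1.2
  expect_error(validate_epi(bad), "case_fatality.*ihd.*male.*60")

  dom <- epi
  j <- which(dom$all_cause$sex == "female" & dom$all_cause$age == 70)
  dom$all_cause$rate[j] <- 1e-6
  expect_error(validate_epi(dom), "exceeds all-cause.*female.*70")
})

test_that("the 3-state lifetable matches hand-multiplied Markov products", {
  inc <- c(0.1, 0.1, 0.1)
  cf <- c(0.5, 0.5, 0.5)
  out <- run_disease_lifetable(inc, cf)
  qi <- 1 - exp(-0.1)
  qf <- 1 - exp(-0.5)
  # year 1 occupancies by hand
  expect_equal(out$healthy[2], 1 - qi, tolerance = 1e-12)
  expect_equal(out$diseased[2], qi, tolerance = 1e-12)
  # year 2 by hand
  expect_equal(out$healthy[3], (1 - qi)^2, tolerance = 1e-12)
  expect_equal(out$diseased[3], qi * (1 - qf) + (1 - qi) * qi, tolerance = 1e-12)
  expect_equal(out$dead[3], qi * qf, tolerance = 1e-12)
  # flows
  expect_equal(out$new_cases[1], qi, tolerance = 1e-12)
  expect_equal(out$disease_deaths[2], qi * qf, tolerance = 1e-12)
})

test_that("disease-lifetable limits: no incidence and null multipliers", {
  none <- run_disease_lifetable(rep(0, 10), rep(0.3, 10))
  expect_true(all(none$new_cases == 0))
  expect_true(all(none$disease_deaths == 0))
  expect_true(all(none$healthy == 1))

  inc <- seq(0.01, 0.1, length.out = 10)
  cf <- rep(0.2, 10)
  base <- run_disease_lifetable(inc, cf)
  null_mult <- run_disease_lifetable(inc, cf, multipliers = rep(1, 10))
  expect_identical(base, null_mult)
})

test_that("state occupancies conserve mass to 1e-9", {
  out <- run_disease_lifetable(runif(50, 0, 0.2), runif(50, 0, 0.4),
    init_prevalence = 0.05
  )
  expect_true(all(abs(out$healthy + out$diseased + out$dead - 1) < 1e-9))
})

test_that("discounting matches closed forms", {
  expect_equal(discount_stream(c(10, 20, 30), 0), 60)
  expect_equal(discount_stream(c(0, 100), 0.035), 100 / 1.035)
  expect_equal(discount_stream(c(0, 0, 100), 0.035), 100 / 1.035^2)
  expect_error(discount_stream(1:3, -0.1))
})

test_that("trend derivation recovers geometric rate histories exactly", {
  hist <- data.frame(
    disease = rep(c("ihd", "stroke"), each = 11),
    year = rep(-10:0, 2),
    incidence_index = c(0.97^(-10:0), 0.99^(-10:0)),
    case_fatality_index = c(0.95^(-10:0), 0.98^(-10:0))
  )
  tr <- derive_trends(hist)
  expect_equal(tr$incidence_factor[tr$disease == "ihd"], 0.97, tolerance = 1e-12)
  expect_equal(tr$case_fatality_factor[tr$disease == "stroke"], 0.98, tolerance = 1e-12)
})

test_that("a null intervention produces exactly zero differences", {
  epi <- fast_epi()
  out <- run_population(epi, shift_by_sex = list(female = 0, male = 0))
  expect_true(all(out$summary$difference == 0))
  expect_equal(out$life_expectancy$delta_days, c(0, 0))
})

test_that("population accounting conserves persons year over year", {
  epi <- fast_epi()
  out <- run_population(epi, shift_by_sex = list(female = 1, male = 1.5))
  for (s in c("female", "male")) {
    a <- out$annual[out$annual$sex == s, ]
    n0 <- a$person_years_baseline[1]
    expect_true(all(abs(
      a$person_years_baseline[-1] -
        (a$person_years_baseline[-nrow(a)] - a$deaths_baseline[-nrow(a)])
    ) < 1e-9 * n0))
    # everyone dies by the terminal age
    expect_equal(sum(a$deaths_baseline), n0, tolerance = 1e-9)
    expect_equal(sum(a$deaths_scenario), a$person_years_scenario[1], tolerance = 1e-9)
  }
})

test_that("lowering incidence never harms survival, QALYs or disease deaths", {
  epi <- fast_epi()
  out <- run_population(epi, shift_by_sex = list(female = 1.2, male = 1.8))
  sm <- out$summary
  expect_true(all(sm$difference[sm$measure == "qalys"] >= 0))
  expect_true(all(sm$difference[sm$measure == "life_years"] >= 0))
  expect_true(all(sm$difference[grepl("_cases|_deaths", sm$measure)] <= 1e-9))
  expect_true(all(out$life_expectancy$delta_days >= 0))
})

test_that("the phase-in and lag gate the incidence response", {
  epi <- fast_epi()
  out <- run_population(epi,
    shift_by_sex = list(female = 2, male = 2),
    timeline = intervention_timeline(phase_in_years = 4, lag_years = 5)
  )
  ad <- out$annual_disease
  early <- ad[ad$year <= 5, ]
  expect_equal(early$new_cases_scenario, early$new_cases_baseline, tolerance = 1e-12)
  later <- ad[ad$year == 10 & ad$disease == "ihd" & ad$sex == "male", ]
  expect_lt(later$new_cases_scenario, later$new_cases_baseline)
})

test_that("zero discounting makes lifetime QALYs the plain annual sum", {
  epi <- fast_epi()
  out <- run_population(epi,
    shift_by_sex = list(female = 1, male = 1),
    discount = discount_spec(0)
  )
  a <- out$annual
  sm <- out$summary
  for (s in c("female", "male")) {
    lifetime <- sm[sm$sex == s & sm$horizon == "lifetime" & sm$measure == "qalys", ]
    undisc <- sum(a$qalys_undiscounted_scenario[a$sex == s]) -
      sum(a$qalys_undiscounted_baseline[a$sex == s])
    expect_equal(lifetime$difference, undisc, tolerance = 1e-9)
  }
})

test_that("life-expectancy deltas convert to days as published", {
  expect_equal(life_expectancy_delta(c(1, 0.5), c(1, 0.5))$days, 0)
  expect_equal(round(life_expectancy_delta(c(1, 0.5), c(1, 0.5174))$days, 2), 6.35)
  expect_equal(signif(life_expectancy_delta(c(1, 0.5), c(1, 0.5418))$days, 3), 15.3)
  # matrix form with cohort weights
  lb <- rbind(c(1, 0.6), c(1, 0.4))
  ls <- rbind(c(1, 0.62), c(1, 0.4))
  expect_equal(
    life_expectancy_delta(lb, ls, weights = c(3, 1))$years,
    0.02 * 3 / 4,
    tolerance = 1e-12
  )
})

test_that("outcome differences scale near-proportionally with the effect", {
  epi <- fast_epi()
  base_args <- list(epi = epi, shift_by_sex = list(female = 1.0, male = 1.4))
  full <- run_population(epi, list(female = 1.0, male = 1.4))
  q_full <- sum(full$summary$difference[full$summary$measure == "qalys" &
    full$summary$horizon == "lifetime"])
  c_full <- sum(full$summary$difference[full$summary$measure == "costs" &
    full$summary$horizon == "lifetime"])
  for (scale in c(0.8, 0.6)) {
    out <- run_population(epi, list(female = 1.0, male = 1.4),
      timeline = intervention_timeline(effect_scale = scale)
    )
    q <- sum(out$summary$difference[out$summary$measure == "qalys" &
      out$summary$horizon == "lifetime"])
    cc <- sum(out$summary$difference[out$summary$measure == "costs" &
      out$summary$horizon == "lifetime"])
    expect_lt(abs(q / q_full / scale - 1), 0.1)
    expect_lt(abs(cc / c_full / scale - 1), 0.1)
  }
})

test_that("overlong horizons are truncated with a warning", {
  epi <- fast_epi()
  expect_warning(
    out <- run_population(epi, list(female = 1, male = 1), horizons = c(20, 500)),
    "truncated"
  )
  expect_setequal(unique(out$summary$horizon), c("20y", "lifetime"))
})
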