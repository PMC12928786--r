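test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 1, n_persons = 50)
  a <- generate_diet_survey(cfg)
  b <- generate_diet_survey(cfg)
  expect_identical(a, b)
  expect_identical(generate_epi_inputs(cfg), generate_epi_inputs(cfg))
  ra <- generate_reference_intakes(a$persons, a$records, cfg)
  rb <- generate_reference_intakes(b$persons, b$records, cfg)
  expect_identical(ra, rb)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_persons = 0), "positive integer")
  expect_error(synthetic_config(n_categories = -3), "positive integer")
  expect_error(synthetic_config(fraction_out_of_home = 1.4), "\\[0, 1\\]")
  expect_error(synthetic_config(true_underreporting_factor = 0), "positive")
})

test_that("zero salt excess means targets are already met everywhere", {
  cfg <- small_config(seed = 3, n_persons = 80, mean_salt_excess_over_target = 0)
  sv <- generate_diet_survey(cfg)
  base <- baseline_salt(sv$records, sv$persons)
  scen <- baseline_salt(apply_targets(sv$records, sv$targets), sv$persons)
  expect_equal(scen, base, tolerance = 1e-12)
})

test_that("matched records have salt at or above target; weights normalised", {
  cfg <- small_config(seed = 5, n_persons = 100)
  sv <- generate_diet_survey(cfg)
  expect_equal(mean(sv$persons$survey_weight), 1, tolerance = 1e-12)
  expect_true(all(sv$persons$survey_weight > 0))
  m <- sv$records[sv$records$match_status == "matched", ]
  expect_true(all(m$category_id %in% sv$targets$category_id))
  idx <- match(m$category_id, sv$targets$category_id)
  per100 <- sv$targets$target_type[idx] == "per_100g"
  expect_true(all(m$salt_per_100g[per100] >= sv$targets$target_value[idx][per100] - 1e-12))
  per_serv <- !per100
  daily <- m$grams_per_day[per_serv] * m$salt_per_100g[per_serv] / 100
  expect_true(all(daily >= sv$targets$target_value[idx][per_serv] - 1e-9))
  expect_true(all(sv$records$person_id %in% sv$persons$person_id))
})

test_that("realized weighted mean intake sits within 3 SE of the closed-form mean", {
  cfg <- synthetic_config(seed = 1, n_persons = 200, n_categories = 20)
  sv <- generate_diet_survey(cfg)
  x <- baseline_salt(sv$records, sv$persons)
  w <- sv$persons$survey_weight
  m <- weighted_mean(x, w)
  se <- sqrt(sum((w / sum(w))^2 * (x - m)^2))
  expect_lt(abs(m - expected_baseline_intake(cfg)), 3 * se)
})

test_that("reference intakes encode the configured under-reporting factor", {
  cfg <- small_config(seed = 2, n_persons = 120, true_underreporting_factor = 1.0)
  sv <- generate_diet_survey(cfg)
  ref <- generate_reference_intakes(sv$persons, sv$records, cfg)
  expect_equal(ref$reference_mean, ref$estimated_mean, tolerance = 1e-12)

  factors <- c(
    "female:19-34" = 1.25, "female:35-49" = 1, "female:50-64" = 1,
    "male:19-34" = 1, "male:35-49" = 1, "male:50-64" = 1
  )
  cfg2 <- small_config(seed = 2, n_persons = 120, true_underreporting_factor = factors)
  ref2 <- generate_reference_intakes(sv$persons, sv$records, cfg2)
  one <- ref2[ref2$stratum == "female:19-34", ]
  expect_equal(one$reference_mean, 1.25 * one$estimated_mean, tolerance = 1e-12)
  others <- ref2[ref2$stratum != "female:19-34", ]
  expect_equal(others$reference_mean, others$estimated_mean, tolerance = 1e-12)
})

test_that("empty strata are omitted from the reference table with a warning", {
  cfg <- small_config(seed = 4, n_persons = 60, age_range = c(19L, 30L))
  sv <- generate_diet_survey(cfg)
  expect_warning(
    ref <- generate_reference_intakes(sv$persons, sv$records, cfg),
    "zero persons"
  )
  expect_setequal(unique(ref$age_group), "19-34")
})

test_that("zero incidence gives zero prevalence and cause-specific mortality", {
  cfg <- synthetic_config(
    seed = 1,
    epi = synthetic_epi_params(incidence_scale = c(ihd = 0, stroke = 0))
  )
  epi <- generate_epi_inputs(cfg)
  expect_true(all(epi$disease_rates$prevalence == 0))
  expect_true(all(epi$disease_rates$mortality == 0))
  expect_silent(validate_epi(epi))
})

test_that("generated prevalence matches an independent forward simulation", {
  epi <- generate_epi_inputs(synthetic_config(seed = 6))
  for (d in epi$diseases) {
    m <- epi$disease_rates[epi$disease_rates$disease == d & epi$disease_rates$sex == "male", ]
    m <- m[order(m$age), ]
    # independent oracle: explicit 3-state cohort simulation
    s <- 1
    c_ <- 0
    prev <- numeric(nrow(m))
    for (a in seq_len(nrow(m))) {
      prev[a] <- if (s + c_ > 0) c_ / (s + c_) else 0
      qi <- 1 - exp(-m$incidence[a])
      qf <- 1 - exp(-m$case_fatality[a])
      new <- s * qi
      dead <- c_ * qf
      s <- s - new
      c_ <- c_ + new - dead
    }
    expect_equal(m$prevalence, prev, tolerance = 1e-9)
  }
})

test_that("synthetic epidemiology passes the engine validator unadjusted", {
  epi <- generate_epi_inputs(synthetic_config(seed = 9))
  expect_silent(validate_epi(epi))
  # mortality dominance holds with margin
  for (s in c("female", "male")) {
    ac <- epi$all_cause[epi$all_cause$sex == s, ]
    ac <- ac[order(ac$age), ]
    cause <- rowSums(sapply(epi$diseases, function(d) {
      m <- epi$disease_rates[epi$disease_rates$sex == s & epi$disease_rates$disease == d, ]
      m$mortality[order(m$age)]
    }))
    expect_true(all(ac$rate >= cause - 1e-12))
  }
})
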