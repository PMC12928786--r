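test_that("baseline intake sums matched, non-homemade records", {
  sv <- mini_survey()
  intake <- baseline_salt(sv$records, sv$persons)
  # person a: 200 x 1.2/100 + 100 x 0.5/100 = 2.4 + 0.5
  expect_equal(unname(intake["a"]), 2.9)
  # person b: homemade record excluded; 350 x 0.6/100
  expect_equal(unname(intake["b"]), 2.1)

  two <- data.frame(
    person_id = c("a", "a"), food_id = c("f1", "f2"),
    category_id = c("g1", "g2"), match_status = "matched",
    grams_per_day = c(100, 50), salt_per_100g = c(0.5, 2.0),
    takeaway_flag = FALSE, stringsAsFactors = FALSE
  )
  expect_equal(unname(baseline_salt(two, sv$persons)["a"]), 1.5)

  all_home <- sv$records
  all_home$match_status <- "homemade"
  expect_equal(unname(baseline_salt(all_home, sv$persons)), c(0, 0))
})

test_that("invalid records are rejected by name", {
  sv <- mini_survey()
  bad <- sv$records
  bad$grams_per_day[2] <- -5
  expect_error(baseline_salt(bad, sv$persons), "f2")
  orphan <- sv$records
  orphan$person_id[1] <- "ghost"
  expect_error(baseline_salt(orphan, sv$persons), "unknown person")
})

test_that("target substitution follows the per-100g and per-serving rules", {
  sv <- mini_survey()
  scen <- apply_targets(sv$records, sv$targets)
  intake <- baseline_salt(scen, sv$persons)
  # person a: 200 x 0.9/100 + 100 x 0.4/100 = 1.8 + 0.4
  expect_equal(unname(intake["a"]), 2.2)
  # person b: out-of-home record counts as one serving at 1.1 g regardless
  # of its 350 g volume; homemade unchanged and excluded
  expect_equal(unname(intake["b"]), 1.1)
  expect_equal(scen$salt_per_100g[scen$food_id == "f4"], 2.0)

  # substitution is unconditional: salt below target is raised to it
  low <- sv$records
  low$salt_per_100g[1] <- 0.1
  scen_low <- apply_targets(low, sv$targets)
  expect_equal(scen_low$salt_per_100g[1], 0.9)

  # missing categories fail loudly
  expect_error(apply_targets(sv$records, sv$targets[-1, ]), "g1")
})

test_that("a servings cap lets large records count as several servings", {
  sv <- mini_survey()
  capped <- apply_targets(sv$records, sv$targets, servings_cap = 3, serving_grams = 175)
  daily <- capped$grams_per_day * capped$salt_per_100g / 100
  expect_equal(daily[capped$food_id == "f3"], 2 * 1.1) # 350 g = 2 servings
})

test_that("correction factors are reference over estimated means", {
  reference <- data.frame(stratum = c("s1", "s2"), reference_mean = c(8.0, 5.0))
  estimated <- data.frame(stratum = c("s1", "s2"), estimated_mean = c(6.0, 5.0))
  f <- correction_factors(reference, estimated)
  expect_equal(f$factor[f$stratum == "s1"], 4 / 3)
  expect_equal(f$factor[f$stratum == "s2"], 1.0)
  estimated$estimated_mean[1] <- 0
  expect_error(correction_factors(reference, estimated), "undefined")
})

test_that("the correction recovers the generator's true under-reporting factor", {
  cfg <- small_config(seed = 8, n_persons = 150, true_underreporting_factor = 1.25)
  sv <- generate_diet_survey(cfg)
  ref <- generate_reference_intakes(sv$persons, sv$records, cfg)
  est <- stratified_intake_means(baseline_salt(sv$records, sv$persons), sv$persons)
  f <- correction_factors(ref, est)
  expect_equal(f$factor, rep(1.25, nrow(f)), tolerance = 1e-12)
})

test_that("summaries are survey-weighted with bootstrap intervals", {
  persons <- data.frame(
    person_id = c("a", "b"), sex = c("female", "male"),
    age = c(30L, 40L), survey_weight = c(1, 3), stringsAsFactors = FALSE
  )
  base <- c(a = 4, b = 8)
  out <- summarize_change(base, base, persons, NULL, n_boot = 50, seed = 1)
  overall <- out$summary[out$summary$group == "overall", ]
  expect_equal(overall$baseline_mean, 7.0) # (1*4 + 3*8)/4
  # null intervention: zero change with an interval containing 0
  expect_equal(overall$absolute_change, 0)
  expect_lte(overall$change_lo, 0)
  expect_gte(overall$change_hi, 0)
})

test_that("corrected means scale with the factor, published-style", {
  # a 1.164 correction on a 5.21 g/d sample mean gives about 6.06 g/d
  persons <- data.frame(
    person_id = "a", sex = "female", age = 30L, survey_weight = 1,
    stringsAsFactors = FALSE
  )
  factors <- data.frame(stratum = "female:19-34", factor = 1.164)
  out <- summarize_change(c(a = 5.21), c(a = 4.3), persons, factors, n_boot = 1, seed = 1)
  expect_equal(
    out$summary$baseline_mean[out$summary$group == "overall"],
    6.06,
    tolerance = 0.005
  )
})

test_that("relative change is invariant to correction factors and weight scale", {
  cfg <- small_config(seed = 11, n_persons = 120)
  sv <- generate_diet_survey(cfg)
  base <- baseline_salt(sv$records, sv$persons)
  scen <- baseline_salt(apply_targets(sv$records, sv$targets), sv$persons)
  ref <- generate_reference_intakes(sv$persons, sv$records, cfg)
  f <- correction_factors(ref, stratified_intake_means(base, sv$persons))

  with_f <- summarize_change(base, scen, sv$persons, f, n_boot = 1, seed = 1)
  without_f <- summarize_change(base, scen, sv$persons, NULL, n_boot = 1, seed = 1)
  expect_equal(with_f$summary$relative_change, without_f$summary$relative_change,
    tolerance = 1e-12
  )

  rescaled <- sv$persons
  rescaled$survey_weight <- rescaled$survey_weight * 17
  scaled <- summarize_change(base, scen, rescaled, f, n_boot = 1, seed = 1)
  expect_equal(scaled$summary$baseline_mean, with_f$summary$baseline_mean, tolerance = 1e-12)
  expect_equal(scaled$summary$absolute_change, with_f$summary$absolute_change, tolerance = 1e-12)
})

test_that("scenario intake never exceeds baseline when targets sit below salt levels", {
  cfg <- small_config(seed = 13, n_persons = 150)
  sv <- generate_diet_survey(cfg)
  base <- baseline_salt(sv$records, sv$persons)
  scen <- baseline_salt(apply_targets(sv$records, sv$targets), sv$persons)
  expect_true(all(scen <= base + 1e-9))
})
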