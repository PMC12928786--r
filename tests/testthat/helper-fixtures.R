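# Shared fixtures: small survey configurations, a reduced-horizon
# epidemiology for fast lifetable runs, and hand-built mini tables.

small_config <- function(seed = 1L, n_persons = 150L, ...) {
  synthetic_config(seed = seed, n_persons = n_persons, n_categories = 30L, ...)
}

# Full-age epidemiology but with a lower terminal age, for fast engine runs.
fast_epi <- function(seed = 1L, terminal_age = 75L) {
  generate_epi_inputs(synthetic_config(
    seed = seed,
    epi = synthetic_epi_params(terminal_age = terminal_age)
  ))
}

# Single-disease epidemiology for the microsimulation oracle.
one_disease_epi <- function(terminal_age = 85L) {
  generate_epi_inputs(synthetic_config(
    seed = 42L,
    epi = synthetic_epi_params(
      incidence_scale = c(ihd = 6e-4),
      incidence_slope = c(ihd = 0.075),
      onset_age = c(ihd = 30),
      case_fatality_scale = c(ihd = 0.015),
      case_fatality_slope = c(ihd = 0.045),
      male_rate_ratio = c(ihd = 1.6),
      incidence_trend = c(ihd = 1),
      case_fatality_trend = c(ihd = 1),
      utility_decrement = c(ihd = 0.07),
      annual_cost = c(ihd = 2100),
      rr_log_slope_40 = c(ihd = 0.035),
      terminal_age = terminal_age
    )
  ))
}

# A four-record diary over two persons, for hand-arithmetic checks.
mini_survey <- function() {
  persons <- data.frame(
    person_id = c("a", "b"),
    sex = c("female", "male"),
    age = c(30L, 55L),
    survey_weight = c(1, 1),
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    person_id = c("a", "a", "b", "b"),
    food_id = paste0("f", 1:4),
    category_id = c("g1", "g2", "o1", NA),
    match_status = c("matched", "matched", "matched", "homemade"),
    grams_per_day = c(200, 100, 350, 120),
    salt_per_100g = c(1.2, 0.5, 0.6, 2.0),
    takeaway_flag = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  targets <- data.frame(
    category_id = c("g1", "g2", "o1"),
    sector = c("grocery", "grocery", "out_of_home"),
    target_type = c("per_100g", "per_100g", "per_serving"),
    target_value = c(0.9, 0.4, 1.1),
    stringsAsFactors = FALSE
  )
  list(persons = persons, records = records, targets = targets)
}
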