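#' Configuration for the synthetic-data generator
#'
#' Builds the seeded configuration from which every input table of the
#' pipeline is generated: a food-diary survey with category-specific salt
#' levels sitting above reformulation targets, urinary-sodium-style
#' reference intakes encoding a known under-reporting factor, and an
#' internally consistent disease epidemiology.
#'
#' The defaults emulate the study conditions of a UK-style adult diet
#' survey: roughly 600 adults aged 18-80, 108 food categories of which 24
#' belong to the out-of-home sector (per-serving targets), a reported
#' (uncorrected) population mean salt intake near 5.2 g/d, and an
#' under-reporting factor near 1.16 so that corrected intake lands near
#' 6 g/d.
#'
#' @param seed integer; fixes every random draw of the generator.
#' @param n_persons number of survey participants (>= 1).
#' @param n_categories number of salt-target food categories (>= 1).
#' @param fraction_out_of_home proportion of categories in the out-of-home
#'   sector, which carry per-serving targets.
#' @param fraction_intake_out_of_home share of mean reported salt intake
#'   contributed by the out-of-home sector (participation is calibrated to
#'   achieve it).
#' @param mean_salt_excess_over_target mean proportional excess of baseline
#'   salt content over the category target. Per-record excess is drawn from
#'   a normal truncated at zero with this location and coefficient of
#'   variation `salt_excess_cv`, so excess is never negative and setting the
#'   mean to 0 makes every food meet its target exactly.
#' @param salt_excess_cv coefficient of variation of the excess draw.
#' @param fraction_at_target proportion of matched records whose salt
#'   content already equals the target exactly.
#' @param target_mean_intake population mean reported (uncorrected) baseline
#'   salt intake, g/d; grocery consumption volumes are calibrated so the
#'   closed-form expectation equals this value.
#' @param true_underreporting_factor true ratio of actual to diary-reported
#'   intake; a single number applied to every calibration stratum, or a
#'   named vector keyed by `"<sex>:<age_group>"` (e.g. `"female:19-34"`).
#' @param age_range integer length-2, inclusive age range of participants.
#' @param consumption_sdlog log-scale SD of daily grams consumed within a
#'   category. Day-to-day variance structure of diet diaries is not pinned
#'   down by published summaries, so it is exposed as a parameter.
#' @param fraction_homemade expected share of diary records flagged
#'   homemade (excluded from target-based intake).
#' @param fraction_unmatched expected share of diary records that match no
#'   target category.
#' @param epi list of epidemiology-generator parameters; see
#'   [synthetic_epi_params()].
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_persons = 600L,
                             n_categories = 108L,
                             fraction_out_of_home = 24 / 108,
                             fraction_intake_out_of_home = 0.25,
                             mean_salt_excess_over_target = 0.23,
                             salt_excess_cv = 0.5,
                             fraction_at_target = 0.1,
                             target_mean_intake = 5.2,
                             true_underreporting_factor = 1.16,
                             age_range = c(18L, 80L),
                             consumption_sdlog = 0.5,
                             fraction_homemade = 0.08,
                             fraction_unmatched = 0.15,
                             epi = synthetic_epi_params()) {
  assert_positive_count(n_persons, "n_persons")
  assert_positive_count(n_categories, "n_categories")
  assert_proportion(fraction_out_of_home, "fraction_out_of_home")
  assert_proportion(fraction_intake_out_of_home, "fraction_intake_out_of_home")
  assert_proportion(fraction_at_target, "fraction_at_target")
  assert_proportion(fraction_homemade, "fraction_homemade")
  assert_proportion(fraction_unmatched, "fraction_unmatched")
  if (mean_salt_excess_over_target < 0) {
    stop("configuration error: `mean_salt_excess_over_target` must be >= 0")
  }
  if (any(true_underreporting_factor <= 0)) {
    stop("configuration error: under-reporting factors must be positive")
  }
  if (length(age_range) != 2 || age_range[1] < 0 || age_range[2] < age_range[1]) {
    stop("configuration error: `age_range` must be increasing and nonnegative")
  }
  if (target_mean_intake <= 0) {
    stop("configuration error: `target_mean_intake` must be positive")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_persons = as.integer(n_persons),
    n_categories = as.integer(n_categories),
    fraction_out_of_home = fraction_out_of_home,
    fraction_intake_out_of_home = fraction_intake_out_of_home,
    mean_salt_excess_over_target = mean_salt_excess_over_target,
    salt_excess_cv = salt_excess_cv,
    fraction_at_target = fraction_at_target,
    target_mean_intake = target_mean_intake,
    true_underreporting_factor = true_underreporting_factor,
    age_range = as.integer(age_range),
    consumption_sdlog = consumption_sdlog,
    fraction_homemade = fraction_homemade,
    fraction_unmatched = fraction_unmatched,
    epi = epi
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Parameters of the synthetic epidemiology generator
#'
#' Disease rates follow Gompertz-like age slopes on single-year ages 0-110:
#' incidence and case fatality rise exponentially with age from an onset
#' age, prevalence is produced by forward-simulating the 3-state disease
#' process (healthy / diseased / dead-from-disease), and cause-specific
#' mortality equals prevalence times case fatality, so the rate set is
#' internally consistent by construction. All-cause mortality is the sum of
#' an other-cause Gompertz hazard and the cause-specific rates, so
#' mortality dominance holds by construction.
#'
#' @param incidence_scale named numeric, per-disease incidence at onset age
#'   (annual rate); set a disease's scale to 0 for the no-disease limit.
#' @param incidence_slope named numeric, exponential age slope of incidence.
#' @param onset_age named numeric, age before which incidence is zero.
#' @param case_fatality_scale,case_fatality_slope Gompertz parameters of
#'   the annual case-fatality rate (anchored at age 40).
#' @param male_rate_ratio multiplier on male incidence.
#' @param other_mortality_scale,other_mortality_slope Gompertz parameters
#'   of non-modelled all-cause mortality.
#' @param incidence_trend,case_fatality_trend annual multiplicative change
#'   over the ten pre-baseline years (values < 1 encode declining rates).
#' @param sbp_mean_20,sbp_slope_per_year,sbp_sd mean systolic blood
#'   pressure at age 20, its annual age gradient (mmHg/year) and SD.
#' @param baseline_utility_20,utility_slope_per_year baseline health-state
#'   utility at age 20 and its annual decline.
#' @param utility_decrement named numeric, per-disease utility decrement.
#' @param annual_cost named numeric, annual healthcare cost per prevalent
#'   case (GBP).
#' @param rr_log_slope_40,rr_age_attenuation per-disease log relative risk
#'   per mmHg systolic blood pressure above the theoretical-minimum-risk
#'   level at age 40, and its proportional attenuation per decade of age.
#' @param population_per_age population count per single year of age and
#'   sex at young ages (tapered at older ages).
#' @param terminal_age closing age of the lifetable.
#' @return a list of class `synthetic_epi_params`.
#' @export
synthetic_epi_params <- function(incidence_scale = c(ihd = 6e-4, stroke = 2.5e-4),
                                 incidence_slope = c(ihd = 0.075, stroke = 0.085),
                                 onset_age = c(ihd = 30, stroke = 30),
                                 case_fatality_scale = c(ihd = 0.015, stroke = 0.03),
                                 case_fatality_slope = c(ihd = 0.045, stroke = 0.045),
                                 male_rate_ratio = c(ihd = 1.6, stroke = 1.2),
                                 other_mortality_scale = 6e-5,
                                 other_mortality_slope = 0.092,
                                 incidence_trend = c(ihd = 0.985, stroke = 0.99),
                                 case_fatality_trend = c(ihd = 0.98, stroke = 0.985),
                                 sbp_mean_20 = 112,
                                 sbp_slope_per_year = 0.45,
                                 sbp_sd = 14,
                                 baseline_utility_20 = 0.94,
                                 utility_slope_per_year = 0.0022,
                                 utility_decrement = c(ihd = 0.07, stroke = 0.12),
                                 annual_cost = c(ihd = 2100, stroke = 4300),
                                 rr_log_slope_40 = c(ihd = 0.035, stroke = 0.045),
                                 rr_age_attenuation = 0.12,
                                 population_per_age = 420000,
                                 terminal_age = 110L) {
  params <- list(
    diseases = names(incidence_scale),
    incidence_scale = incidence_scale,
    incidence_slope = incidence_slope,
    onset_age = onset_age,
    case_fatality_scale = case_fatality_scale,
    case_fatality_slope = case_fatality_slope,
    male_rate_ratio = male_rate_ratio,
    other_mortality_scale = other_mortality_scale,
    other_mortality_slope = other_mortality_slope,
    incidence_trend = incidence_trend,
    case_fatality_trend = case_fatality_trend,
    sbp_mean_20 = sbp_mean_20,
    sbp_slope_per_year = sbp_slope_per_year,
    sbp_sd = sbp_sd,
    baseline_utility_20 = baseline_utility_20,
    utility_slope_per_year = utility_slope_per_year,
    utility_decrement = utility_decrement,
    annual_cost = annual_cost,
    rr_log_slope_40 = rr_log_slope_40,
    rr_age_attenuation = rr_age_attenuation,
    population_per_age = population_per_age,
    terminal_age = as.integer(terminal_age)
  )
  stopifnot(!is.null(params$diseases), length(params$diseases) >= 1)
  class(params) <- "synthetic_epi_params"
  params
}

#' Look up the true under-reporting factor for each stratum
#' @param config a `synthetic_config`
#' @param stratum character vector of stratum labels (`"<sex>:<age_group>"`)
#' @return numeric vector of factors
#' @export
true_factor_for_stratum <- function(config, stratum) {
  f <- config$true_underreporting_factor
  if (is.null(names(f))) {
    return(rep(unname(f[1]), length(stratum)))
  }
  out <- unname(f[stratum])
  if (anyNA(out)) {
    stop(
      "configuration error: no under-reporting factor for strata: ",
      paste(unique(stratum[is.na(out)]), collapse = ", ")
    )
  }
  out
}
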