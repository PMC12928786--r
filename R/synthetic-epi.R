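# Synthetic epidemiology generator: population, disease rates consistent
# with the 3-state disease process by construction, blood-pressure
# distributions, utilities, unit costs and relative-risk slopes.

# Annual incidence rate by single year of age for one disease/sex.
synthetic_incidence <- function(age, disease, sex, p) {
  scale <- p$incidence_scale[[disease]]
  slope <- p$incidence_slope[[disease]]
  onset <- p$onset_age[[disease]]
  mult <- if (sex == "male") p$male_rate_ratio[[disease]] else 1
  rate <- ifelse(age < onset, 0, scale * mult * exp(slope * (age - onset)))
  pmin(rate, 0.95) # guard the extreme tail of the Gompertz curve
}

synthetic_case_fatality <- function(age, disease, p) {
  rate <- p$case_fatality_scale[[disease]] *
    exp(p$case_fatality_slope[[disease]] * (age - 40))
  pmin(rate, 0.95)
}

# Forward-simulate the 3-state process (healthy / diseased / dead from
# disease) over single-year ages to obtain the prevalent proportion among
# the living at the start of each age. Other-cause mortality cancels from
# the ratio because it hits both living states equally.
disease_prevalence_forward <- function(incidence, case_fatality) {
  n <- length(incidence)
  stopifnot(length(case_fatality) == n)
  prev <- numeric(n)
  s <- 1
  c_ <- 0
  for (a in seq_len(n)) {
    alive <- s + c_
    prev[a] <- if (alive > 0) c_ / alive else 0
    qi <- rate_to_prob(incidence[a])
    qf <- rate_to_prob(case_fatality[a])
    new_cases <- s * qi
    deaths <- c_ * qf
    s <- s - new_cases
    c_ <- c_ + new_cases - deaths
  }
  prev
}

#' Generate internally consistent synthetic epidemiology inputs
#'
#' Builds every rate table the lifetable engine needs, on single-year ages
#' 0 to the terminal age by sex. Incidence and case fatality follow
#' Gompertz-like age curves; prevalence is obtained by forward-simulating
#' the 3-state disease process with those rates, and cause-specific
#' mortality equals prevalence times case fatality, so the inputs are
#' mutually consistent by construction. All-cause mortality is the sum of
#' an other-cause hazard and the cause-specific rates, guaranteeing
#' mortality dominance. Ten pre-baseline years of incidence and
#' case-fatality indices are included for trend estimation.
#'
#' @param config a [synthetic_config()]; only `config$epi` and the seed are
#'   used.
#' @return a list of class `epi_inputs` with elements `population`,
#'   `all_cause`, `disease_rates`, `rate_history`, `sbp`, `utilities`,
#'   `decrements`, `costs`, `rr_slopes`, `diseases`, `terminal_age`
#' @export
generate_epi_inputs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$epi
  ages <- 0:p$terminal_age
  sexes <- c("female", "male")
  diseases <- p$diseases

  grid <- expand.grid(
    age = ages, sex = sexes,
    stringsAsFactors = FALSE
  )

  # population: plateau through midlife, exponential taper at older ages
  taper <- exp(-pmax(grid$age - 65, 0) * 0.055)
  population <- data.frame(
    sex = grid$sex, age = grid$age,
    count = round(p$population_per_age * taper)
  )

  disease_rates <- do.call(rbind, lapply(diseases, function(d) {
    do.call(rbind, lapply(sexes, function(s) {
      inc <- synthetic_incidence(ages, d, s, p)
      cf <- synthetic_case_fatality(ages, d, p)
      prev <- disease_prevalence_forward(inc, cf)
      data.frame(
        disease = d, sex = s, age = ages,
        incidence = inc, case_fatality = cf,
        prevalence = prev, mortality = prev * cf,
        stringsAsFactors = FALSE
      )
    }))
  }))

  bad <- disease_rates$incidence < 0 | disease_rates$incidence > 1 |
    disease_rates$case_fatality < 0 | disease_rates$case_fatality > 1
  if (any(bad)) {
    stop("generation error: disease rates outside [0, 1]; re-parameterize the epi settings")
  }

  # all-cause mortality dominates cause-specific mortality by construction
  other <- pmin(p$other_mortality_scale * exp(p$other_mortality_slope * grid$age), 1) *
    ifelse(grid$sex == "male", 1.25, 1)
  cause_sum <- rep(0, nrow(grid))
  for (d in diseases) {
    dr <- disease_rates[disease_rates$disease == d, ]
    key_grid <- paste(grid$sex, grid$age)
    key_dr <- paste(dr$sex, dr$age)
    cause_sum <- cause_sum + dr$mortality[match(key_grid, key_dr)]
  }
  all_cause <- data.frame(
    sex = grid$sex, age = grid$age,
    rate = pmin(other + cause_sum, 1)
  )

  # ten pre-baseline years of age-standardised rate indices (year 0 = 1)
  years <- -10:0
  rate_history <- do.call(rbind, lapply(diseases, function(d) {
    data.frame(
      disease = d, year = years,
      incidence_index = p$incidence_trend[[d]]^years,
      case_fatality_index = p$case_fatality_trend[[d]]^years,
      stringsAsFactors = FALSE
    )
  }))

  sbp <- data.frame(
    sex = grid$sex, age = grid$age,
    mean = p$sbp_mean_20 + p$sbp_slope_per_year * pmax(grid$age - 20, 0) +
      ifelse(grid$sex == "male", 2, 0),
    sd = p$sbp_sd
  )

  utilities <- data.frame(
    sex = grid$sex, age = grid$age,
    utility = pmax(p$baseline_utility_20 -
      p$utility_slope_per_year * pmax(grid$age - 20, 0), 0.3)
  )

  decrements <- data.frame(
    disease = diseases,
    decrement = unname(p$utility_decrement[diseases]),
    ci_low = unname(p$utility_decrement[diseases]) * 0.7,
    ci_high = unname(p$utility_decrement[diseases]) * 1.3,
    stringsAsFactors = FALSE
  )

  costs <- data.frame(
    disease = diseases,
    annual_cost = unname(p$annual_cost[diseases]),
    ci_low = unname(p$annual_cost[diseases]) * 0.7,
    ci_high = unname(p$annual_cost[diseases]) * 1.3,
    stringsAsFactors = FALSE
  )

  # log-RR per mmHg above the TMREL by 10-year age band, attenuating with
  # age as observed in cohort meta-analyses of blood pressure and CVD
  bands <- data.frame(age_low = c(0, seq(40, 90, 10)), age_high = c(39, seq(49, 89, 10), 200))
  rr_slopes <- do.call(rbind, lapply(diseases, function(d) {
    mid <- pmin(pmax((bands$age_low + pmin(bands$age_high, 110)) / 2, 35), 95)
    slope <- p$rr_log_slope_40[[d]] *
      pmax(1 - p$rr_age_attenuation * (mid - 40) / 10, 0.2)
    data.frame(
      disease = d,
      age_low = bands$age_low, age_high = bands$age_high,
      log_rr_per_mmhg = slope,
      ci_low = slope * 0.75, ci_high = slope * 1.25,
      stringsAsFactors = FALSE
    )
  }))

  epi <- list(
    population = population,
    all_cause = all_cause,
    disease_rates = disease_rates,
    rate_history = rate_history,
    sbp = sbp,
    utilities = utilities,
    decrements = decrements,
    costs = costs,
    rr_slopes = rr_slopes,
    diseases = diseases,
    terminal_age = p$terminal_age
  )
  class(epi) <- "epi_inputs"
  epi
}

#' Write all synthetic inputs as CSV files
#'
#' @param survey list from [generate_diet_survey()]
#' @param reference data.frame from [generate_reference_intakes()]
#' @param epi list from [generate_epi_inputs()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_synthetic_csvs <- function(survey, reference, epi, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(
    persons = survey$persons,
    food_records = survey$records,
    targets = survey$targets,
    reference_intakes = reference,
    population = epi$population,
    all_cause_mortality = epi$all_cause,
    disease_rates = epi$disease_rates,
    rate_history = epi$rate_history,
    sbp = epi$sbp,
    utilities = epi$utilities,
    utility_decrements = epi$decrements,
    costs = epi$costs,
    rr_slopes = epi$rr_slopes
  )
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}
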