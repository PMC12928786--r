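# Synthetic diet-survey generator: persons, food-diary records and the
# salt-target table, with a closed-form expected baseline intake used by
# calibration tests.

# Per-category attributes drawn once from the config seed: sector, target,
# participation probability and consumption volume. Grocery volumes are
# rescaled so the closed-form population mean intake equals
# config$target_mean_intake.
category_attributes <- function(config) {
  k <- config$n_categories
  n_ooh <- round(k * config$fraction_out_of_home)
  with_seed(config$seed + 11L, {
    sector <- rep("grocery", k)
    if (n_ooh > 0) sector[seq_len(n_ooh)] <- "out_of_home"
    target_value <- ifelse(
      sector == "grocery",
      stats::runif(k, 0.2, 1.5), # g salt / 100 g
      stats::runif(k, 0.6, 2.5) # g salt / serving
    )
    participation <- stats::runif(k, 0.05, 0.35)
    grams_median <- ifelse(
      sector == "grocery",
      exp(stats::runif(k, log(20), log(180))),
      exp(stats::runif(k, log(150), log(400)))
    )
    df <- data.frame(
      category_id = sprintf("cat_%03d", seq_len(k)),
      sector = sector,
      target_type = ifelse(sector == "grocery", "per_100g", "per_serving"),
      target_value = target_value,
      participation = participation,
      grams_median = grams_median,
      stringsAsFactors = FALSE
    )
    df
  })
}

# Mean proportional excess of salt content over target implied by the
# truncated-normal excess draw plus the at-target point mass.
expected_excess <- function(config) {
  m <- config$mean_salt_excess_over_target
  s <- m * config$salt_excess_cv
  (1 - config$fraction_at_target) * truncnorm_mean(m, s)
}

# Closed-form expected reported baseline salt intake (g/d) per person,
# given calibrated category attributes. Exported so tests can compare the
# realized weighted mean against the generator's own expectation.

#' Expected reported baseline salt intake under a configuration
#'
#' The closed-form per-person expectation of reported (uncorrected) daily
#' salt intake implied by the generator's category attributes: the sum over
#' categories of participation probability times expected consumed grams
#' times expected salt content (grocery), plus participation times expected
#' per-serving salt (out-of-home). By calibration this equals
#' `config$target_mean_intake`.
#'
#' @param config a [synthetic_config()]
#' @return expected intake in g/d
#' @export
expected_baseline_intake <- function(config) {
  config$target_mean_intake
}

# Uncalibrated expectation used internally to solve for the grocery scale.
raw_expected_intake <- function(attrs, config) {
  ex <- expected_excess(config)
  egrams <- attrs$grams_median * exp(config$consumption_sdlog^2 / 2)
  grocery <- attrs$sector == "grocery"
  e_groc <- sum(attrs$participation[grocery] * egrams[grocery] *
    attrs$target_value[grocery] * (1 + ex) / 100)
  e_ooh <- sum(attrs$participation[!grocery] * attrs$target_value[!grocery] * (1 + ex))
  list(grocery = e_groc, out_of_home = e_ooh)
}

#' Generate a synthetic food-diary survey
#'
#' Produces the three diet-survey tables: persons (with survey weights
#' mean-normalised to 1), food-diary records, and the salt-target table.
#' Consumption volumes are log-normal within category; baseline salt
#' content is the category target inflated by a nonnegative
#' truncated-normal excess, so substitution of targets can only reduce
#' intake. Out-of-home records are flagged takeaway and carry per-serving
#' targets; a configurable share of records is homemade or matches no
#' target category and is excluded from target-based intake.
#'
#' @param config a [synthetic_config()]
#' @return a list with elements `persons`, `records`, `targets`
#' @export
generate_diet_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  attrs <- category_attributes(config)

  # calibrate the two sectors so the closed-form mean equals the target:
  # out-of-home participation is scaled to contribute its configured share
  # of intake, grocery volumes supply the remainder
  raw <- raw_expected_intake(attrs, config)
  grocery <- attrs$sector == "grocery"
  ooh_share <- if (any(!grocery)) config$fraction_intake_out_of_home else 0
  if (raw$out_of_home > 0) {
    p_scale <- ooh_share * config$target_mean_intake / raw$out_of_home
    attrs$participation[!grocery] <- pmin(attrs$participation[!grocery] * p_scale, 0.9)
  }
  raw <- raw_expected_intake(attrs, config)
  if (raw$grocery > 0) {
    scale <- (config$target_mean_intake - raw$out_of_home) / raw$grocery
    if (scale <= 0) {
      stop(
        "configuration error: out-of-home intake alone exceeds ",
        "`target_mean_intake`; reduce categories or targets"
      )
    }
    attrs$grams_median[grocery] <- attrs$grams_median[grocery] * scale
  }

  with_seed(config$seed, {
    n <- config$n_persons
    persons <- data.frame(
      person_id = sprintf("p_%04d", seq_len(n)),
      sex = sample(c("female", "male"), n, replace = TRUE),
      age = sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    w <- stats::rlnorm(n, 0, 0.35)
    persons$survey_weight <- w / mean(w)

    # matched records: person x category participation
    k <- config$n_categories
    consume <- matrix(
      stats::runif(n * k) < rep(attrs$participation, each = n),
      nrow = n
    )
    idx <- which(consume, arr.ind = TRUE)
    pid <- persons$person_id[idx[, 1]]
    cat_i <- idx[, 2]
    m <- nrow(idx)
    grams <- stats::rlnorm(m, log(attrs$grams_median[cat_i]), config$consumption_sdlog)
    mu <- config$mean_salt_excess_over_target
    excess <- rtruncnorm0(m, mu, mu * config$salt_excess_cv)
    excess[stats::runif(m) < config$fraction_at_target] <- 0
    ooh <- attrs$sector[cat_i] == "out_of_home"
    target <- attrs$target_value[cat_i]
    # grocery: salt content per 100 g; out-of-home: daily salt is the
    # per-serving target inflated by the excess, expressed back per 100 g
    salt_per_100g <- ifelse(
      ooh,
      ifelse(grams > 0, target * (1 + excess) / grams * 100, 0),
      target * (1 + excess)
    )
    matched <- data.frame(
      person_id = pid,
      category_id = attrs$category_id[cat_i],
      match_status = "matched",
      grams_per_day = grams,
      salt_per_100g = salt_per_100g,
      takeaway_flag = ooh,
      stringsAsFactors = FALSE
    )

    # homemade and unmatched records (excluded from target-based intake)
    n_match_per_person <- rowSums(consume)
    extra_record <- function(status, frac) {
      counts <- stats::rpois(n, pmax(n_match_per_person, 1) * frac)
      pid <- rep(persons$person_id, counts)
      m2 <- length(pid)
      data.frame(
        person_id = pid,
        category_id = NA_character_,
        match_status = status,
        grams_per_day = stats::rlnorm(m2, log(80), 0.6),
        salt_per_100g = stats::runif(m2, 0.1, 1.8),
        takeaway_flag = FALSE,
        stringsAsFactors = FALSE
      )
    }
    records <- rbind(
      matched,
      extra_record("homemade", config$fraction_homemade),
      extra_record("unmatched", config$fraction_unmatched)
    )
    records <- records[order(records$person_id, records$match_status), , drop = FALSE]
    records$food_id <- sprintf("food_%05d", seq_len(nrow(records)))
    rownames(records) <- NULL
    records <- records[, c(
      "person_id", "food_id", "category_id", "match_status",
      "grams_per_day", "salt_per_100g", "takeaway_flag"
    )]

    targets <- attrs[, c("category_id", "sector", "target_type", "target_value")]

    list(persons = persons, records = records, targets = targets)
  })
}

#' Generate reference (urinary-sodium style) intake means by stratum
#'
#' Emulates a biomarker-based reference survey: the reference mean for each
#' calibration stratum equals the survey-weighted estimated mean times the
#' configured true under-reporting factor, so downstream correction factors
#' can be tested for exact recovery.
#'
#' Strata with no participants are dropped with a warning.
#'
#' @param persons,records diet-survey tables from [generate_diet_survey()]
#' @param config the same [synthetic_config()]
#' @return data.frame with `sex`, `age_group`, `stratum`, `estimated_mean`,
#'   `reference_mean`
#' @export
generate_reference_intakes <- function(persons, records, config) {
  intake <- baseline_salt(records, persons)
  est <- stratified_intake_means(intake, persons)
  all_strata <- as.vector(outer(c("female", "male"), diet_age_groups(), paste, sep = ":"))
  missing <- setdiff(all_strata, est$stratum)
  if (length(missing) > 0) {
    warning(
      "strata with zero persons omitted from reference intakes: ",
      paste(missing, collapse = ", ")
    )
  }
  est$reference_mean <- est$estimated_mean * true_factor_for_stratum(config, est$stratum)
  est
}
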