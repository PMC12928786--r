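# Diet-scenario stage: per-person baseline and target-compliant salt
# intake, under-reporting correction, and survey-weighted stratified
# summaries with bootstrap confidence intervals.

#' Per-person baseline salt intake
#'
#' Sums daily salt (g/d) over a person's diary records that are matched to
#' a target category. Records flagged homemade, and records matching no
#' target category, are excluded; persons with no qualifying records get
#' an intake of 0.
#'
#' @param records food-diary records (see [generate_diet_survey()]):
#'   columns `person_id`, `food_id`, `category_id`, `match_status`,
#'   `grams_per_day`, `salt_per_100g`
#' @param persons person table with `person_id`
#' @return named numeric vector of g/d, one entry per person in `persons`
#' @export
baseline_salt <- function(records, persons) {
  bad <- records$grams_per_day < 0 | records$salt_per_100g < 0
  if (any(bad)) {
    stop(
      "validation error: negative grams or salt content in records: ",
      paste(utils::head(records$food_id[bad], 5), collapse = ", ")
    )
  }
  if (!all(records$person_id %in% persons$person_id)) {
    stop("validation error: records reference unknown person ids")
  }
  keep <- records$match_status == "matched"
  salt <- records$grams_per_day[keep] * records$salt_per_100g[keep] / 100
  sums <- tapply(salt, factor(records$person_id[keep], levels = persons$person_id), sum)
  out <- as.numeric(sums)
  out[is.na(out)] <- 0
  names(out) <- persons$person_id
  out
}

#' Substitute category salt targets into the diary records
#'
#' Applies full compliance with the reformulation targets: for per-100g
#' (grocery) categories the record's salt content is replaced by the
#' category target; for per-serving (out-of-home) categories the record's
#' total daily salt is set to the target, treating each reported record as
#' exactly one serving regardless of reported grams. Substitution is
#' unconditional — records already at or below the target are also set to
#' it. Homemade and unmatched records pass through unchanged.
#'
#' @param records food-diary records
#' @param targets target table: `category_id`, `target_type`
#'   (`per_100g`/`per_serving`), `target_value`
#' @param servings_cap optional maximum number of servings a record can
#'   represent; `NULL` (default) treats every record as one serving. When
#'   set, records whose grams span several reference servings (grams /
#'   `serving_grams`) contribute up to the cap times the per-serving
#'   target.
#' @param serving_grams reference serving size in grams, used only with
#'   `servings_cap`.
#' @return records with scenario salt content
#' @export
apply_targets <- function(records, targets, servings_cap = NULL, serving_grams = 250) {
  out <- records
  matched <- records$match_status == "matched"
  idx <- match(records$category_id[matched], targets$category_id)
  if (anyNA(idx)) {
    missing <- unique(records$category_id[matched][is.na(idx)])
    stop(
      "validation error: matched records reference categories absent from ",
      "the target table: ", paste(missing, collapse = ", ")
    )
  }
  type <- targets$target_type[idx]
  value <- targets$target_value[idx]
  grams <- records$grams_per_day[matched]
  salt <- records$salt_per_100g[matched]

  per100 <- type == "per_100g"
  salt[per100] <- value[per100]

  per_serv <- type == "per_serving"
  servings <- rep(1, length(grams))
  if (!is.null(servings_cap)) {
    servings <- pmin(pmax(round(grams / serving_grams), 1), servings_cap)
  }
  # total daily salt equals servings x target; express back per 100 g so
  # the intake formula grams x salt/100 still applies
  salt[per_serv] <- ifelse(
    grams[per_serv] > 0,
    servings[per_serv] * value[per_serv] / grams[per_serv] * 100,
    0
  )
  out$salt_per_100g[matched] <- salt
  out
}

# Survey-weighted mean baseline intake by calibration stratum.
#' Stratified survey-weighted intake means
#'
#' @param intake named per-person intake vector (g/d)
#' @param persons person table with `sex`, `age`, `survey_weight`
#' @return data.frame with `sex`, `age_group`, `stratum`, `estimated_mean`,
#'   `n`
#' @export
stratified_intake_means <- function(intake, persons) {
  st <- diet_stratum(persons$age, persons$sex)
  x <- intake[persons$person_id]
  parts <- split(seq_len(nrow(persons)), st$stratum)
  out <- do.call(rbind, lapply(names(parts), function(s) {
    i <- parts[[s]]
    data.frame(
      sex = st$sex[i[1]],
      age_group = st$age_group[i[1]],
      stratum = s,
      estimated_mean = weighted_mean(x[i], persons$survey_weight[i]),
      n = length(i),
      stringsAsFactors = FALSE
    )
  }))
  out[order(out$sex, out$age_group), , drop = FALSE]
}

#' Under-reporting correction factors
#'
#' The correction factor for a stratum is the ratio of the
#' biomarker-reference mean intake to the diet-diary estimated mean; both
#' baseline and scenario per-person intakes are later multiplied by the
#' person's stratum factor, so relative change is unaffected.
#'
#' @param reference data.frame with `stratum`, `reference_mean`
#' @param estimated data.frame with `stratum`, `estimated_mean`
#' @return data.frame with `stratum`, `factor`
#' @export
correction_factors <- function(reference, estimated) {
  common <- intersect(reference$stratum, estimated$stratum)
  if (length(common) == 0) stop("no common strata between reference and estimated means")
  est <- estimated$estimated_mean[match(common, estimated$stratum)]
  ref <- reference$reference_mean[match(common, reference$stratum)]
  if (any(est == 0)) {
    stop(
      "undefined correction factor: estimated mean is zero in strata: ",
      paste(common[est == 0], collapse = ", ")
    )
  }
  data.frame(stratum = common, factor = ref / est, stringsAsFactors = FALSE)
}

# Correction factor per person via the nearest calibration stratum.
person_factors <- function(persons, factors) {
  st <- diet_stratum(persons$age, persons$sex)
  f <- factors$factor[match(st$stratum, factors$stratum)]
  if (anyNA(f)) {
    stop(
      "no correction factor for strata: ",
      paste(unique(st$stratum[is.na(f)]), collapse = ", ")
    )
  }
  f
}

#' Summarise the stratified change in salt intake
#'
#' Applies the under-reporting correction to baseline and scenario
#' per-person intakes, then reports survey-weighted means by sex, age group
#' and overall, with absolute and relative change and percentile bootstrap
#' confidence intervals from a survey-weighted person-level resample
#' (persons resampled with replacement, their weights carried).
#'
#' @param baseline,scenario named per-person intake vectors (g/d)
#' @param persons person table
#' @param factors correction-factor table from [correction_factors()], or
#'   `NULL` for no adjustment (all factors 1)
#' @param n_boot bootstrap replicates (>= 1)
#' @param seed integer seed for the bootstrap
#' @param conf confidence level
#' @return list with `summary` (one row per stratum plus `overall`) and
#'   `person` (per-person corrected intakes for distribution plots)
#' @export
summarize_change <- function(baseline, scenario, persons, factors = NULL,
                             n_boot = 2000, seed = 1L, conf = 0.95) {
  stopifnot(n_boot >= 1)
  if (all(persons$survey_weight == 0)) stop("all survey weights are zero")
  f <- if (is.null(factors)) rep(1, nrow(persons)) else person_factors(persons, factors)
  b <- baseline[persons$person_id] * f
  s <- scenario[persons$person_id] * f
  w <- persons$survey_weight

  groups <- c(
    list(overall = seq_len(nrow(persons))),
    split(seq_len(nrow(persons)), persons$sex),
    split(seq_len(nrow(persons)), diet_stratum(persons$age, persons$sex)$age_group)
  )

  stat_row <- function(i, bb, ss, ww) {
    bm <- weighted_mean(bb[i], ww[i])
    sm <- weighted_mean(ss[i], ww[i])
    c(
      baseline_mean = bm, scenario_mean = sm,
      absolute_change = bm - sm,
      relative_change = if (bm > 0) (bm - sm) / bm else 0
    )
  }

  point <- t(vapply(groups, stat_row, numeric(4), bb = b, ss = s, ww = w))

  boot <- with_seed(seed, {
    reps <- array(NA_real_, dim = c(n_boot, length(groups), 4))
    n <- nrow(persons)
    for (r in seq_len(n_boot)) {
      take <- sample.int(n, n, replace = TRUE)
      bb <- b[take]
      ss <- s[take]
      ww <- w[take]
      grp <- c(
        list(overall = seq_len(n)),
        split(seq_len(n), persons$sex[take]),
        split(seq_len(n), diet_stratum(persons$age[take], persons$sex[take])$age_group)
      )
      for (g in seq_along(groups)) {
        gi <- grp[[names(groups)[g]]]
        if (!is.null(gi) && length(gi) > 0) {
          reps[r, g, ] <- stat_row(gi, bb, ss, ww)
        }
      }
    }
    reps
  })

  alpha <- (1 - conf) / 2
  qs <- apply(boot, c(2, 3), stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)

  summary <- data.frame(
    group = names(groups),
    baseline_mean = point[, 1],
    baseline_lo = qs[1, , 1], baseline_hi = qs[2, , 1],
    scenario_mean = point[, 2],
    scenario_lo = qs[1, , 2], scenario_hi = qs[2, , 2],
    absolute_change = point[, 3],
    change_lo = qs[1, , 3], change_hi = qs[2, , 3],
    relative_change = point[, 4],
    relative_lo = qs[1, , 4], relative_hi = qs[2, , 4],
    row.names = NULL, stringsAsFactors = FALSE
  )

  person <- data.frame(
    person_id = persons$person_id,
    sex = persons$sex,
    age = persons$age,
    survey_weight = w,
    baseline_intake = unname(b),
    scenario_intake = unname(s),
    stringsAsFactors = FALSE
  )

  list(summary = summary, person = person)
}
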