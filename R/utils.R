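#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("intake", "weight", "arm"))

# Shared small helpers. All randomness in the package flows through
# local RNG state so callers' streams are never disturbed.

#' Evaluate an expression under a private, seeded RNG state
#'
#' Saves and restores `.Random.seed`, so generators are reproducible under a
#' fixed seed without side effects on the caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Survey-weighted mean
#'
#' @param x numeric values
#' @param w positive weights (recycled checking lengths match)
#' @return weighted mean
#' @export
weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w))
  if (all(w == 0)) stop("all weights are zero")
  if (any(w < 0)) stop("negative survey weights")
  sum(x * w) / sum(w)
}

# Annual rate -> annual transition probability.
rate_to_prob <- function(rate) {
  1 - exp(-rate)
}

# Mean of N(mean, sd) truncated below at 0.
truncnorm_mean <- function(mean, sd) {
  if (sd == 0) {
    return(max(mean, 0))
  }
  alpha <- -mean / sd
  mean + sd * stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
}

# Draw from N(mean, sd) truncated below at 0 by inverse-CDF, so draws are
# deterministic functions of runif and reproducible under seed.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(max(mean, 0), n))
  }
  p0 <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, p0, 1)
  stats::qnorm(u, mean, sd)
}

assert_positive_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("configuration error: `%s` must be a positive integer count", name))
  }
  invisible(as.integer(x))
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("configuration error: `%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Age-group labels used for the diet-survey under-reporting calibration.
diet_age_groups <- function() {
  c("19-34", "35-49", "50-64")
}

#' Assign a person to a diet-calibration stratum
#'
#' Calibration strata are the three adult age groups (19-34, 35-49, 50-64)
#' crossed with sex. Ages outside the calibrated range take the nearest
#' group (18s use 19-34; 65+ use 50-64), a minimal extrapolation.
#'
#' @param age integer vector of ages in years
#' @param sex character vector, "female"/"male"
#' @return data.frame with columns `sex`, `age_group`, `stratum`
#' @export
diet_stratum <- function(age, sex) {
  grp <- ifelse(age <= 34, "19-34", ifelse(age <= 49, "35-49", "50-64"))
  data.frame(
    sex = sex,
    age_group = grp,
    stratum = paste(sex, grp, sep = ":"),
    stringsAsFactors = FALSE
  )
}
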