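# Risk stage: salt -> systolic blood pressure conversion, categorical
# exposure distributions, blood-pressure relative risks above the
# theoretical-minimum-risk level, and population impact fractions.

# Systolic BP response per 100 mmol sodium (2.30 g sodium, 5.88 g salt)
# from meta-analysis of sodium-reduction trials.
SALT_PER_100_MMOL_SODIUM <- 5.88

#' Salt-to-blood-pressure conversion slope
#'
#' Central estimate 5.80 mmHg (95% CI 2.45-9.15) systolic reduction per
#' 5.88 g/d of salt (100 mmol sodium), applied linearly.
#'
#' @param central,ci_low,ci_high mmHg per 5.88 g/d salt
#' @return list of class `salt_bp_slope`
#' @export
salt_bp_slope <- function(central = 5.80, ci_low = 2.45, ci_high = 9.15) {
  if (central < ci_low || central > ci_high) {
    stop("slope central value must lie within its confidence interval")
  }
  structure(
    list(
      central = central, ci_low = ci_low, ci_high = ci_high,
      salt_per_unit = SALT_PER_100_MMOL_SODIUM
    ),
    class = "salt_bp_slope"
  )
}

#' Convert a salt-intake change to a systolic blood-pressure change
#'
#' Linear conversion: a reduction of 5.88 g/d salt lowers systolic BP by
#' the slope's central value (5.80 mmHg by default). Negative inputs
#' (salt increases) yield negative BP reductions.
#'
#' @param delta_salt change in salt intake, g/d (positive = reduction)
#' @param slope a [salt_bp_slope()]; a bare number is also accepted and
#'   treated as the mmHg-per-5.88 g/d central value
#' @return change in systolic BP, mmHg
#' @export
delta_sbp <- function(delta_salt, slope = salt_bp_slope()) {
  central <- if (inherits(slope, "salt_bp_slope")) slope$central else as.numeric(slope)
  delta_salt * central / SALT_PER_100_MMOL_SODIUM
}

#' Discretize a normal blood-pressure distribution into exposure categories
#'
#' Cuts the N(mean, sd) systolic-BP distribution into bins of the given
#' width covering at least six SDs either side (of both the baseline and
#' shifted means), and returns, for each bin midpoint, the baseline
#' prevalence `p` and the prevalence `p_shifted` after the mean is reduced
#' by `shift`. Each prevalence vector is normalised to sum to one.
#'
#' @param mean,sd baseline distribution parameters (mmHg), `sd > 0`
#' @param shift downward shift of the mean (mmHg)
#' @param bin_width bin width (mmHg), > 0
#' @return data.frame with `sbp` (bin midpoint), `p`, `p_shifted`
#' @export
discretize_exposure <- function(mean, sd, shift = 0, bin_width = 1) {
  if (sd <= 0) stop("blood-pressure SD must be positive")
  if (bin_width <= 0) stop("bin width must be positive")
  lo <- floor((min(mean, mean - shift) - 6 * sd) / bin_width) * bin_width
  hi <- ceiling((max(mean, mean - shift) + 6 * sd) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  mass <- function(mu) {
    p <- diff(stats::pnorm(breaks, mu, sd))
    p / sum(p)
  }
  data.frame(
    sbp = utils::head(breaks, -1) + bin_width / 2,
    p = mass(mean),
    p_shifted = mass(mean - shift)
  )
}

#' Relative risk of disease at a systolic blood-pressure level
#'
#' Log-linear in BP above the theoretical-minimum-risk level (TMREL,
#' 115 mmHg): `RR = exp(slope * max(sbp - tmrel, 0))`, so RR is 1 at or
#' below the TMREL and monotone nondecreasing above it. The age-specific
#' log slope is supplied as data (see the `rr_slopes` table of
#' [generate_epi_inputs()]).
#'
#' @param sbp systolic BP, mmHg (vectorised)
#' @param log_slope log relative risk per mmHg above the TMREL
#' @param tmrel theoretical minimum risk exposure level, mmHg
#' @return relative risks
#' @export
relative_risk <- function(sbp, log_slope, tmrel = 115) {
  exp(log_slope * pmax(sbp - tmrel, 0))
}

# Age-band lookup of the log-RR slope for one disease.
rr_slope_at_age <- function(rr_slopes, disease, age) {
  rows <- rr_slopes[rr_slopes$disease == disease, ]
  i <- findInterval(age, rows$age_low)
  if (any(i == 0) || any(age > rows$age_high[i])) {
    stop("relative-risk slope table does not cover age ", paste(age, collapse = ", "))
  }
  rows$log_rr_per_mmhg[i]
}

#' Population impact fraction over exposure categories
#'
#' `PIF = (sum(p * RR) - sum(p' * RR)) / sum(p * RR)`, the proportional
#' change in the prevalence-weighted relative risk when the exposure
#' distribution moves from `p` to `p_prime`. Positive values mean reduced
#' incidence; a worsened exposure yields a negative PIF.
#'
#' @param p,p_prime baseline and scenario category prevalences (each sums
#'   to 1)
#' @param rr relative risk per category
#' @return the population impact fraction (<= 1)
#' @export
compute_pif <- function(p, p_prime, rr) {
  stopifnot(length(p) == length(p_prime), length(p) == length(rr))
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(p_prime) - 1) > 1e-6) {
    stop("exposure prevalences must each sum to 1")
  }
  denom <- sum(p * rr)
  if (denom == 0) stop("undefined PIF: sum(p * RR) is zero")
  (denom - sum(p_prime * rr)) / denom
}

#' Scenario incidence under a population impact fraction
#'
#' `I' = I * (1 - PIF)`, clamped to `[0, 1]` with a warning if a negative
#' PIF pushes the rate above 1.
#'
#' @param i_baseline baseline incidence rate in `[0, 1]`
#' @param pif population impact fraction
#' @return scenario incidence rate
#' @export
scenario_incidence <- function(i_baseline, pif) {
  stopifnot(all(i_baseline >= 0), all(i_baseline <= 1))
  out <- i_baseline * (1 - pif)
  if (any(out > 1)) {
    warning("scenario incidence clamped to 1 (negative PIF)")
    out <- pmin(out, 1)
  }
  pmax(out, 0)
}

#' Population impact fractions by disease, sex and age for a BP shift
#'
#' Discretizes each age/sex systolic-BP distribution, applies the
#' sex-specific downward shift, and evaluates the PIF with the disease's
#' age-band log-RR slope.
#'
#' @param epi an `epi_inputs` list (needs `sbp` and `rr_slopes`)
#' @param shift_by_sex named numeric, mmHg reduction per sex
#' @param bin_width exposure bin width, mmHg
#' @param tmrel theoretical minimum risk level, mmHg
#' @param rr_scale optional named-per-disease multiplier on the log-RR
#'   slopes (Monte Carlo draws)
#' @return data.frame with `disease`, `sex`, `age`, `pif`
#' @export
pif_table <- function(epi, shift_by_sex, bin_width = 1, tmrel = 115,
                      rr_scale = NULL) {
  out <- list()
  for (s in names(shift_by_sex)) {
    sbp <- epi$sbp[epi$sbp$sex == s, ]
    shift <- shift_by_sex[[s]]
    # common bin grid across ages; exposure masses column-normalised so the
    # categorical PIF formula applies exactly per age
    lo <- floor((min(sbp$mean - shift, sbp$mean) - 6 * max(sbp$sd)) / bin_width) * bin_width
    hi <- ceiling((max(sbp$mean) + 6 * max(sbp$sd)) / bin_width) * bin_width
    breaks <- seq(lo, hi, by = bin_width)
    mids <- utils::head(breaks, -1) + bin_width / 2
    cdf <- function(mu) stats::pnorm(outer(breaks, mu, "-") / rep(sbp$sd, each = length(breaks)))
    mass <- function(mu) {
      m <- apply(cdf(mu), 2, diff)
      sweep(m, 2, colSums(m), "/")
    }
    p <- mass(sbp$mean)
    p_shift <- mass(sbp$mean - shift)
    excess <- pmax(mids - tmrel, 0)
    for (d in epi$diseases) {
      scale_d <- if (is.null(rr_scale)) 1 else rr_scale[[d]]
      slopes <- rr_slope_at_age(epi$rr_slopes, d, sbp$age) * scale_d
      rr <- exp(outer(excess, slopes)) # bins x ages
      denom <- colSums(p * rr)
      pif <- (denom - colSums(p_shift * rr)) / denom
      out[[paste(d, s)]] <- data.frame(
        disease = d, sex = s, age = sbp$age, pif = pif,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
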