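# Monte Carlo propagation of parameter uncertainty through the risk and
# lifetable stages, with percentile uncertainty intervals.

#' Define an uncertain parameter for Monte Carlo sampling
#'
#' Families are chosen by the parameter's support and the shape of its
#' interval: `normal_positive` (normal truncated at zero; used where the
#' published interval is arithmetic-symmetric, as for the salt-BP slope),
#' `lognormal` (median-matched on the log scale, for positive ratio-scale
#' quantities such as relative-risk multipliers), `beta` (moment-matched on
#' `[0, 1]`, for utilities and decrements), `beta_scaled` (moment-matched
#' beta on `[0, upper]`, for quantities near 1 that may exceed 1), `gamma`
#' (moment-matched, for costs) and `point`. A degenerate interval
#' (`ci_low == ci_high == central`) always collapses to a point mass.
#'
#' @param name parameter name
#' @param central central value
#' @param ci_low,ci_high 95% interval bounds
#' @param family one of `"normal_positive"`, `"lognormal"`, `"beta"`,
#'   `"beta_scaled"`, `"gamma"`, `"point"`
#' @return list of class `mc_parameter`
#' @export
mc_parameter <- function(name, central, ci_low = central, ci_high = central,
                         family = c(
                           "normal_positive", "lognormal", "beta",
                           "beta_scaled", "gamma", "point"
                         )) {
  family <- match.arg(family)
  if (ci_low > central || ci_high < central) {
    stop("parameter spec error for `", name, "`: central outside [ci_low, ci_high]")
  }
  if (family %in% c("lognormal", "gamma") && ci_low <= 0 && ci_low != ci_high) {
    stop("parameter spec error for `", name, "`: ", family, " requires positive bounds")
  }
  if (family == "beta" && (ci_low < 0 || ci_high > 1)) {
    stop("parameter spec error for `", name, "`: beta requires bounds in [0, 1]")
  }
  structure(
    list(name = name, central = central, ci_low = ci_low, ci_high = ci_high, family = family),
    class = "mc_parameter"
  )
}

Z95 <- stats::qnorm(0.975)

beta_moments <- function(mean, sd) {
  v <- sd^2
  v <- min(v, mean * (1 - mean) * 0.999) # keep the shape parameters valid
  k <- mean * (1 - mean) / v - 1
  c(a = mean * k, b = (1 - mean) * k)
}

# Transform one column of standard normals into draws of a parameter.
# Every family is a monotone map of z, so common random numbers across
# re-specifications preserve orderings.
draw_parameter <- function(par, z) {
  if (par$ci_low == par$ci_high) {
    return(rep(par$central, length(z)))
  }
  u <- stats::pnorm(z)
  switch(par$family,
    point = rep(par$central, length(z)),
    normal_positive = {
      sd <- (par$ci_high - par$ci_low) / (2 * Z95)
      p0 <- stats::pnorm(0, par$central, sd)
      stats::qnorm(p0 + u * (1 - p0), par$central, sd)
    },
    lognormal = {
      sdlog <- (log(par$ci_high) - log(par$ci_low)) / (2 * Z95)
      exp(log(par$central) + sdlog * z)
    },
    beta = {
      m <- beta_moments(par$central, (par$ci_high - par$ci_low) / (2 * Z95))
      stats::qbeta(u, m["a"], m["b"])
    },
    beta_scaled = {
      upper <- par$central + 3 * (par$ci_high - par$central)
      m <- beta_moments(par$central / upper, (par$ci_high - par$ci_low) / (2 * Z95) / upper)
      upper * stats::qbeta(u, m["a"], m["b"])
    },
    gamma = {
      sd <- (par$ci_high - par$ci_low) / (2 * Z95)
      shape <- (par$central / sd)^2
      stats::qgamma(u, shape = shape, rate = shape / par$central)
    }
  )
}

#' Sample a reproducible matrix of parameter draws
#'
#' Parameters are drawn independently; each is a monotone transform of its
#' own column of standard normals, so a fixed seed yields an identical draw
#' matrix and widening one parameter's interval widens its draws without
#' disturbing the others.
#'
#' @param spec list of [mc_parameter()]s
#' @param n_iter number of iterations (10,000 in the main analysis; 500 in
#'   sensitivity analyses)
#' @param seed master seed
#' @return data.frame of draws, one column per parameter
#' @export
sample_parameters <- function(spec, n_iter, seed) {
  stopifnot(n_iter >= 1)
  names(spec) <- vapply(spec, `[[`, character(1), "name")
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_iter * length(spec)), nrow = n_iter)
    out <- as.data.frame(
      lapply(seq_along(spec), function(j) draw_parameter(spec[[j]], z[, j])),
      col.names = names(spec)
    )
    out
  })
}

#' Default Monte Carlo parameter specification
#'
#' Covers the quantities the uncertainty analysis varies: the salt-to-BP
#' slope (arithmetic-symmetric published interval, so truncated-normal),
#' the per-sex intervention effect on salt intake (truncated-normal),
#' per-disease relative-risk multipliers (lognormal, from the slope table's
#' interval ratios), the baseline-utility multiplier (scaled beta),
#' per-disease utility decrements (beta) and unit costs (gamma).
#'
#' @param epi an `epi_inputs` list
#' @param salt_change named list per sex: `list(central=, ci_low=, ci_high=)`
#'   g/d reductions
#' @param slope a [salt_bp_slope()]
#' @param utility_ci half-width interval of the baseline-utility multiplier
#' @return list of [mc_parameter()]s
#' @export
default_mc_parameters <- function(epi, salt_change, slope = salt_bp_slope(),
                                  utility_ci = c(0.94, 1.06)) {
  spec <- list(
    mc_parameter("salt_bp_slope", slope$central, slope$ci_low, slope$ci_high, "normal_positive"),
    mc_parameter("utility_mult", 1, utility_ci[1], utility_ci[2], "beta_scaled")
  )
  for (s in names(salt_change)) {
    sc <- salt_change[[s]]
    spec <- c(spec, list(mc_parameter(
      paste0("salt_change_", s), sc$central, sc$ci_low, sc$ci_high, "normal_positive"
    )))
  }
  for (d in epi$diseases) {
    row <- epi$rr_slopes[epi$rr_slopes$disease == d, ][1, ]
    spec <- c(spec, list(
      mc_parameter(
        paste0("rr_scale_", d), 1,
        row$ci_low / row$log_rr_per_mmhg, row$ci_high / row$log_rr_per_mmhg,
        "lognormal"
      )
    ))
    dec <- epi$decrements[epi$decrements$disease == d, ]
    spec <- c(spec, list(
      mc_parameter(paste0("decrement_", d), dec$decrement, dec$ci_low, dec$ci_high, "beta")
    ))
    cost <- epi$costs[epi$costs$disease == d, ]
    spec <- c(spec, list(
      mc_parameter(paste0("cost_", d), cost$annual_cost, cost$ci_low, cost$ci_high, "gamma")
    ))
  }
  spec
}

# Flatten a cohort_outcomes object (plus BP shifts) into a named vector of
# scenario-minus-baseline differences.
outcome_vector <- function(out, shift_by_sex) {
  sm <- out$summary
  v <- stats::setNames(
    sm$difference,
    paste(sm$sex, sm$horizon, sm$measure, sep = ".")
  )
  le <- stats::setNames(out$life_expectancy$delta_days, paste0(out$life_expectancy$sex, ".le_days"))
  bp <- stats::setNames(unlist(shift_by_sex), paste0(names(shift_by_sex), ".delta_sbp"))
  c(bp, le, v)
}

#' Monte Carlo uncertainty intervals for the health-model outcomes
#'
#' Re-runs the risk and lifetable stages for each parameter draw and
#' summarises every outcome difference with percentile 95% uncertainty
#' intervals. The point estimate is the central-parameter run, not the
#' Monte Carlo mean. Iterations failing validation are skipped and logged;
#' more than 1% failures aborts.
#'
#' @param epi validated `epi_inputs`
#' @param salt_change named list per sex: `list(central=, ci_low=, ci_high=)`
#' @param n_iter iterations
#' @param seed master seed
#' @param spec parameter specification, default [default_mc_parameters()]
#' @param slope a [salt_bp_slope()]
#' @param conf interval level
#' @param ... further arguments to [run_population()] (timeline, trends,
#'   discount, horizons, min_age, bin_width, ...)
#' @return list of class `uncertainty_summary`: `table` (outcome, point,
#'   lo95, hi95, n_iter, seed), `draws`, `failures`, `point_run`
#' @export
run_monte_carlo <- function(epi, salt_change, n_iter = 500, seed = 1L,
                            spec = NULL, slope = salt_bp_slope(),
                            conf = 0.95, ...) {
  if (is.null(spec)) spec <- default_mc_parameters(epi, salt_change, slope)
  draws <- sample_parameters(spec, n_iter, seed)

  central_shift <- vapply(
    salt_change,
    function(sc) delta_sbp(sc$central, slope), numeric(1)
  )
  validate_epi(epi)
  point_run <- run_population(epi, shift_by_sex = as.list(central_shift), validate = FALSE, ...)
  point <- outcome_vector(point_run, as.list(central_shift))

  run_one <- function(i) {
    g <- draws[i, , drop = FALSE]
    shift <- vapply(names(salt_change), function(s) {
      g[[paste0("salt_change_", s)]] * g[["salt_bp_slope"]] / SALT_PER_100_MMOL_SODIUM
    }, numeric(1))
    rr_scale <- lapply(epi$diseases, function(d) g[[paste0("rr_scale_", d)]])
    names(rr_scale) <- epi$diseases
    decrements <- lapply(epi$diseases, function(d) min(g[[paste0("decrement_", d)]], 1))
    names(decrements) <- epi$diseases
    costs <- lapply(epi$diseases, function(d) g[[paste0("cost_", d)]])
    names(costs) <- epi$diseases
    out <- run_population(
      epi,
      shift_by_sex = as.list(shift),
      rr_scale = rr_scale, decrements = decrements, costs = costs,
      utility_multiplier = g[["utility_mult"]],
      validate = FALSE,
      ...
    )
    outcome_vector(out, as.list(shift))
  }

  results <- matrix(NA_real_, nrow = n_iter, ncol = length(point), dimnames = list(NULL, names(point)))
  failures <- 0
  for (i in seq_len(n_iter)) {
    r <- tryCatch(run_one(i), error = function(e) {
      message("Monte Carlo iteration ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(r)) {
      failures <- failures + 1
    } else {
      results[i, ] <- r
    }
  }
  if (failures > 0.01 * n_iter) {
    stop("more than 1% of Monte Carlo iterations failed (", failures, "/", n_iter, ")")
  }

  alpha <- (1 - conf) / 2
  qs <- apply(results, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  table <- data.frame(
    outcome = names(point),
    point = unname(point),
    lo95 = qs[1, ],
    hi95 = qs[2, ],
    n_iter = n_iter,
    seed = seed,
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  structure(
    list(table = table, draws = draws, results = results, failures = failures, point_run = point_run),
    class = "uncertainty_summary"
  )
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat("Monte Carlo uncertainty summary (", x$table$n_iter[1], " iterations)\n", sep = "")
  print(utils::head(x$table[, c("outcome", "point", "lo95", "hi95")], 12), row.names = FALSE)
  invisible(x)
}
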