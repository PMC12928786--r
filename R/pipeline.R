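# Orchestration: configuration, the full pipeline run (inputs -> diet
# scenario -> risk -> lifetable -> uncertainty -> report bundle) and the
# named sensitivity variants.

#' Pipeline run configuration
#'
#' Exactly one input source: a [synthetic_config()] (the default) or a
#' directory of input CSVs with the schemas written by
#' [write_synthetic_csvs()].
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading files
#' @param input_dir directory of input CSVs, or `NULL`
#' @param effect_scale multiplier on the per-person salt reduction (1 main;
#'   0.8 / 0.6 in the shortfall sensitivity analyses)
#' @param discount_rate annual discount rate for QALYs and costs
#' @param underreporting_adjustment apply the under-reporting correction?
#' @param horizons case-count reporting horizons (years)
#' @param n_iter Monte Carlo iterations
#' @param n_boot bootstrap replicates for the salt-change CIs
#' @param seed master seed for bootstrap and Monte Carlo
#' @param out_dir output directory for the report bundle
#' @param min_age youngest simulated cohort
#' @param bin_width exposure discretization width, mmHg
#' @param make_plot write the intake-distribution figure?
#' @return list of class `run_config`
#' @export
run_config <- function(synthetic = synthetic_config(),
                       input_dir = NULL,
                       effect_scale = 1,
                       discount_rate = 0.035,
                       underreporting_adjustment = TRUE,
                       horizons = c(20, 30),
                       n_iter = 500,
                       n_boot = 500,
                       seed = 1L,
                       out_dir = tempfile("saltimpact_run_"),
                       min_age = 18,
                       bin_width = 1,
                       make_plot = TRUE) {
  if (is.null(synthetic) == is.null(input_dir)) {
    stop("configuration error: provide exactly one input source (`synthetic` or `input_dir`)")
  }
  if (effect_scale < 0 || effect_scale > 1) {
    stop("configuration error: `effect_scale` must lie in [0, 1]")
  }
  if (discount_rate < 0) stop("configuration error: `discount_rate` must be >= 0")
  stopifnot(n_iter >= 1, n_boot >= 1, all(horizons >= 1))
  structure(
    list(
      synthetic = synthetic, input_dir = input_dir,
      effect_scale = effect_scale, discount_rate = discount_rate,
      underreporting_adjustment = underreporting_adjustment,
      horizons = horizons, n_iter = n_iter, n_boot = n_boot,
      seed = as.integer(seed), out_dir = out_dir,
      min_age = min_age, bin_width = bin_width, make_plot = make_plot
    ),
    class = "run_config"
  )
}

#' Read pipeline inputs from a directory of CSV files
#'
#' Expects the schemas written by [write_synthetic_csvs()]. Missing files
#' or columns fail early with the offending names.
#'
#' @param dir input directory
#' @return list with `survey`, `reference`, `epi`
#' @export
read_model_inputs <- function(dir) {
  need <- function(name, cols) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing input file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    absent <- setdiff(cols, names(df))
    if (length(absent) > 0) {
      stop("input file ", name, ".csv lacks columns: ", paste(absent, collapse = ", "))
    }
    df
  }
  persons <- need("persons", c("person_id", "sex", "age", "survey_weight"))
  records <- need("food_records", c(
    "person_id", "food_id", "category_id", "match_status",
    "grams_per_day", "salt_per_100g", "takeaway_flag"
  ))
  targets <- need("targets", c("category_id", "sector", "target_type", "target_value"))
  reference <- need("reference_intakes", c("sex", "age_group", "stratum", "reference_mean"))
  disease_rates <- need("disease_rates", c(
    "disease", "sex", "age", "incidence", "case_fatality", "prevalence", "mortality"
  ))
  epi <- list(
    population = need("population", c("sex", "age", "count")),
    all_cause = need("all_cause_mortality", c("sex", "age", "rate")),
    disease_rates = disease_rates,
    rate_history = need("rate_history", c("disease", "year", "incidence_index", "case_fatality_index")),
    sbp = need("sbp", c("sex", "age", "mean", "sd")),
    utilities = need("utilities", c("sex", "age", "utility")),
    decrements = need("utility_decrements", c("disease", "decrement", "ci_low", "ci_high")),
    costs = need("costs", c("disease", "annual_cost", "ci_low", "ci_high")),
    rr_slopes = need("rr_slopes", c(
      "disease", "age_low", "age_high", "log_rr_per_mmhg", "ci_low", "ci_high"
    )),
    diseases = unique(disease_rates$disease),
    terminal_age = max(disease_rates$age)
  )
  class(epi) <- "epi_inputs"
  list(
    survey = list(persons = persons, records = records, targets = targets),
    reference = reference,
    epi = epi
  )
}

# Per-sex salt-change central value and CI from the scenario summary.
salt_change_by_sex <- function(salt_summary) {
  out <- list()
  for (s in c("female", "male")) {
    row <- salt_summary$summary[salt_summary$summary$group == s, ]
    out[[s]] <- list(
      central = row$absolute_change,
      ci_low = min(row$change_lo, row$absolute_change),
      ci_high = max(row$change_hi, row$absolute_change)
    )
  }
  out
}

intake_distribution_plot <- function(person) {
  long <- rbind(
    data.frame(
      intake = person$baseline_intake, weight = person$survey_weight,
      arm = "baseline", stringsAsFactors = FALSE
    ),
    data.frame(
      intake = person$scenario_intake, weight = person$survey_weight,
      arm = "intervention", stringsAsFactors = FALSE
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = intake, weight = weight,
    colour = arm, fill = arm
  )) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::labs(
      x = "Salt intake (g/day)", y = "Survey-weighted density",
      colour = NULL, fill = NULL,
      title = "Salt intake distribution, baseline vs full target compliance"
    ) +
    ggplot2::theme_minimal()
}

#' Run the full pipeline and write the report bundle
#'
#' Generates (or reads) the inputs, computes baseline and target-compliant
#' salt intakes, applies the under-reporting correction, converts the
#' per-sex salt change to a blood-pressure shift, runs the proportional
#' multistate lifetable, propagates parameter uncertainty by Monte Carlo,
#' and writes `salt_summary.csv`, `pif.csv`, `outcomes.csv`,
#' `uncertainty.csv`, a run manifest and an intake-distribution figure to
#' `config$out_dir`.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with all intermediate objects and output paths
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- inputs ----
  if (!is.null(config$synthetic)) {
    survey <- generate_diet_survey(config$synthetic)
    reference <- generate_reference_intakes(survey$persons, survey$records, config$synthetic)
    epi <- generate_epi_inputs(config$synthetic)
  } else {
    inputs <- read_model_inputs(config$input_dir)
    survey <- inputs$survey
    reference <- inputs$reference
    epi <- inputs$epi
  }
  validate_epi(epi)
  n_matched <- sum(survey$records$match_status == "matched")
  message(sprintf(
    "inputs: %d persons, %d diary records (%d matched to %d target categories, %.0f%%)",
    nrow(survey$persons), nrow(survey$records), n_matched,
    nrow(survey$targets), 100 * n_matched / nrow(survey$records)
  ))

  # ---- diet scenario ----
  baseline <- baseline_salt(survey$records, survey$persons)
  scenario_records <- apply_targets(survey$records, survey$targets)
  scenario <- baseline_salt(scenario_records, survey$persons)
  # effect-shortfall scaling acts on the per-person salt reduction
  scenario <- baseline - config$effect_scale * (baseline - scenario)
  factors <- NULL
  if (config$underreporting_adjustment) {
    estimated <- stratified_intake_means(baseline, survey$persons)
    factors <- correction_factors(reference, estimated)
  }
  salt <- summarize_change(
    baseline, scenario, survey$persons, factors,
    n_boot = config$n_boot, seed = config$seed
  )
  overall <- salt$summary[salt$summary$group == "overall", ]
  message(sprintf(
    "salt: %.2f -> %.2f g/d (change %.2f g/d, %.1f%%)",
    overall$baseline_mean, overall$scenario_mean,
    overall$absolute_change, 100 * overall$relative_change
  ))

  # ---- risk + lifetable ----
  change <- salt_change_by_sex(salt)
  shift <- lapply(change, function(sc) delta_sbp(sc$central))
  pifs <- pif_table(epi, vapply(shift, identity, numeric(1)),
    bin_width = config$bin_width
  )
  outcomes <- run_population(
    epi,
    shift_by_sex = shift,
    timeline = intervention_timeline(),
    discount = discount_spec(config$discount_rate),
    horizons = config$horizons,
    min_age = config$min_age,
    bin_width = config$bin_width
  )
  message(sprintf(
    "lifetable: %s cohorts simulated to age %d; lifetime QALY difference %.0f",
    "all adult", epi$terminal_age,
    sum(outcomes$summary$difference[outcomes$summary$horizon == "lifetime" &
      outcomes$summary$measure == "qalys"])
  ))

  # ---- uncertainty ----
  mc <- run_monte_carlo(
    epi, change,
    n_iter = config$n_iter, seed = config$seed,
    discount = discount_spec(config$discount_rate),
    horizons = config$horizons, min_age = config$min_age,
    bin_width = config$bin_width
  )

  # ---- report bundle ----
  paths <- list()
  write_out <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    paths[[name]] <<- path
  }
  write_out(salt$summary, "salt_summary.csv")
  write_out(salt$person, "intake_distribution.csv")
  write_out(pifs, "pif.csv")
  long <- outcomes$summary
  outcomes_long <- rbind(
    data.frame(long[c("sex", "horizon", "measure")], simulation = "baseline", value = long$baseline),
    data.frame(long[c("sex", "horizon", "measure")], simulation = "scenario", value = long$scenario),
    data.frame(long[c("sex", "horizon", "measure")], simulation = "difference", value = long$difference)
  )
  write_out(outcomes_long, "outcomes.csv")
  write_out(outcomes$life_expectancy, "life_expectancy.csv")
  write_out(mc$table, "uncertainty.csv")

  if (isTRUE(config$make_plot)) {
    fig_path <- file.path(config$out_dir, "intake_distribution.png")
    ok <- tryCatch(
      {
        grDevices::png(fig_path, width = 1200, height = 800, res = 150)
        print(intake_distribution_plot(salt$person))
        grDevices::dev.off()
        TRUE
      },
      error = function(e) {
        warning("could not write figure: ", conditionMessage(e))
        FALSE
      }
    )
    if (ok) paths[["intake_distribution.png"]] <- fig_path
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("saltimpact")),
    seed = config$seed,
    settings = list(
      effect_scale = config$effect_scale,
      discount_rate = config$discount_rate,
      underreporting_adjustment = config$underreporting_adjustment,
      horizons = config$horizons,
      n_iter = config$n_iter, n_boot = config$n_boot,
      min_age = config$min_age, bin_width = config$bin_width,
      input_source = if (is.null(config$input_dir)) "synthetic" else config$input_dir,
      synthetic_seed = if (is.null(config$synthetic)) NULL else config$synthetic$seed
    ),
    record_counts = list(
      persons = nrow(survey$persons),
      records = nrow(survey$records),
      matched_records = n_matched,
      categories = nrow(survey$targets),
      mc_failures = mc$failures
    ),
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths[["manifest.json"]] <- manifest_path

  invisible(list(
    config = config, survey = survey, reference = reference, epi = epi,
    salt = salt, factors = factors, change = change, shift = shift,
    pifs = pifs, outcomes = outcomes, uncertainty = mc, paths = paths
  ))
}

#' Named sensitivity variants
#' @return character vector of valid variant names
#' @export
sensitivity_variants <- function() {
  c("shortfall20", "shortfall40", "discount15", "discount0", "no_underreporting")
}

#' Run one named sensitivity variant
#'
#' Applies exactly one override to a main-analysis configuration:
#' `shortfall20`/`shortfall40` scale the salt-reduction effect to 0.8/0.6;
#' `discount15`/`discount0` switch the discount rate to 1.5%/0%;
#' `no_underreporting` sets every correction factor to 1.
#'
#' @param config a [run_config()] describing the main analysis
#' @param variant one of [sensitivity_variants()]
#' @return the [run_full()] bundle for the variant
#' @export
run_sensitivity <- function(config, variant) {
  if (!variant %in% sensitivity_variants()) {
    stop(
      "unknown sensitivity variant `", variant, "`; valid variants: ",
      paste(sensitivity_variants(), collapse = ", ")
    )
  }
  cfg <- config
  cfg$out_dir <- file.path(config$out_dir, variant)
  if (variant == "shortfall20") cfg$effect_scale <- 0.8 * config$effect_scale
  if (variant == "shortfall40") cfg$effect_scale <- 0.6 * config$effect_scale
  if (variant == "discount15") cfg$discount_rate <- 0.015
  if (variant == "discount0") cfg$discount_rate <- 0
  if (variant == "no_underreporting") cfg$underreporting_adjustment <- FALSE
  run_full(cfg)
}
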