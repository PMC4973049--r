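#' Reproduce the printed probability derivations from raw counts
#'
#' Rebuilds every derived transition probability from the raw inputs the
#' evidence tables report: national incidence per 10,000 person-years, the
#' under-5 mid-year population, the medicinal / non-medicinal substance
#' share, England inpatient admissions with the England-to-UK scaling
#' factor, the severe-outcome rate, and the fatality counts. Intermediate
#' counts are rounded to whole cases exactly as the source arithmetic does,
#' so the derived probabilities match the printed values at their printed
#' precision.
#'
#' @param per_10000 Incidence of medically reported poisonings per 10,000
#'   person-years.
#' @param population Mid-year population of under 5 year olds.
#' @param substance_share Fraction of poisonings attributable to the
#'   variant's substance class (0.6 medicinal, 0.4 non-medicinal).
#' @param england_admissions Inpatient admissions recorded for England.
#' @param uk_scale England-to-UK population scaling factor.
#' @param severe_rate Proportion of admitted cases with a chronic outcome.
#' @param severe_cases Optional printed severe-case numerator; when supplied
#'   it overrides `round(severe_rate * admissions)` (the source tables round
#'   inconsistently between variants).
#' @param fatal_deaths,fatal_denominator Fatality count and its printed
#'   denominator.
#' @return A list with the intermediate counts (`cases_uk`, `numerator`,
#'   `admissions_uk`, `severe_cases`) and `dist_spec`s `pIngest`, `pAdmit`,
#'   `pSevere`, `pFatal`.
#' @examples
#' d <- derive_probability_inputs(30.1, 3996400, 0.6, 3909, 1.163, 0.0191,
#'                                87, 1, 86)
#' dist_mean(d$pIngest)  # 0.001806
#' @export
derive_probability_inputs <- function(per_10000, population, substance_share,
                                      england_admissions, uk_scale,
                                      severe_rate, severe_cases = NULL,
                                      fatal_deaths, fatal_denominator) {
  if (population <= 0 || per_10000 <= 0)
    stop("derivation error: zero or negative denominator", call. = FALSE)
  cases_uk <- round(per_10000 * population / 1e4)
  numerator <- round(cases_uk * substance_share)
  admissions_uk <- round(england_admissions * uk_scale)
  if (is.null(severe_cases))
    severe_cases <- round(severe_rate * admissions_uk)
  list(
    cases_uk = cases_uk,
    numerator = numerator,
    admissions_uk = admissions_uk,
    severe_cases = severe_cases,
    pIngest = beta_from_counts(numerator, population),
    pAdmit = beta_from_counts(admissions_uk, numerator),
    pSevere = beta_from_counts(severe_cases, admissions_uk),
    pFatal = beta_from_counts(fatal_deaths, fatal_denominator))
}

spec_from_yaml <- function(node, label = NULL) {
  fam <- node$family
  if (identical(fam, "beta") && !is.null(node$counts))
    return(beta_from_counts(node$counts$successes, node$counts$total))
  switch(fam,
    fixed = dist_spec("fixed", value = node$value, label = label),
    gamma = gamma_from_mean_se(node$mean, node$se),
    normal = dist_spec("normal", mean = node$mean, se = node$se,
                       label = label),
    stop("unknown distribution family in configuration: ", fam,
         call. = FALSE))
}

#' Load a model configuration
#'
#' Reads the structured text (YAML) parameter file for one model variant
#' and assembles everything a run needs: distribution specifications for
#' probabilities, costs and utility decrements; the per-arm effectiveness
#' summaries and their joint sampling model; the arm definitions with offer
#' costs; the age-indexed baseline utility vector; the background-mortality
#' lifetable; and the run settings.
#'
#' @param variant `"medicinal"` or `"nonmedicinal"`, or a path to a
#'   configuration file in the same schema.
#' @param lifetable Optional lifetable data.frame (`age`, `qx`); defaults
#'   to the packaged synthetic lifetable.
#' @return A `model_config` object.
#' @examples
#' cfg <- load_model_config("medicinal")
#' dist_mean(cfg$prob$pIngest)
#' @export
load_model_config <- function(variant = c("medicinal", "nonmedicinal"),
                              lifetable = NULL) {
  path <- if (file.exists(variant[1])) variant[1] else {
    variant <- match.arg(variant)
    system.file("extdata", paste0(variant, ".yaml"),
                package = "poisoncea", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, 1L) && !identical(raw$schema, 1))
    stop("unsupported configuration schema version", call. = FALSE)

  inc <- raw$probabilities$incidence
  derived <- derive_probability_inputs(
    inc$per_10000, inc$population, inc$substance_share,
    inc$england_admissions, inc$uk_scale, inc$severe_rate,
    inc$severe_cases, inc$fatal$deaths, inc$fatal$denominator)

  prob <- list(
    pSafe = spec_from_yaml(raw$probabilities$pSafe, "pSafe"),
    pAccept = spec_from_yaml(raw$probabilities$pAccept, "pAccept"),
    pIngest = derived$pIngest,
    logOrIngest = dist_spec("normal", mean = raw$probabilities$orIngest$log_or,
                            se = raw$probabilities$orIngest$se,
                            label = "logOrIngest"),
    pAmb = spec_from_yaml(raw$probabilities$pAmb, "pAmb"),
    pAdmit = derived$pAdmit,
    pSevere = derived$pSevere,
    pFatal = derived$pFatal)

  eff <- lapply(raw$effectiveness$arms, function(a)
    arm_effect_summary(a$arm, a$median, a$lower, a$upper))

  comp <- unlist(raw$costs$components)
  cost_names <- c("cFixed", "cAccept", "cAmb", "cED1", "cED2",
                  "cAdmit1", "cAdmit2", "cChro", "cFatal", "cGP")
  costs <- lapply(cost_names, function(nm) spec_from_yaml(raw$costs[[nm]], nm))
  names(costs) <- cost_names

  upop <- numeric(100)
  for (band in raw$utilities$uPop)
    upop[(band$age_from:band$age_to) + 1] <- band$mean
  dec <- lapply(raw$utilities$decrements, function(d)
    beta_from_mean_se(d$mean, d$se))

  if (is.null(lifetable)) lifetable <- default_lifetable()
  lifetable <- validate_lifetable(lifetable)

  st <- raw$settings
  settings <- list(
    cohort_size = st$cohort_size, reporting_scale = st$reporting_scale,
    cycle_length = st$cycle_length, horizon = st$horizon,
    preschool_years = st$preschool_years,
    discount_costs = st$discount_costs,
    discount_utilities = st$discount_utilities,
    half_cycle_correction = isTRUE(st$half_cycle_correction),
    children_per_household = st$children_per_household,
    costing_policy = st$costing_policy,
    rho = st$rho, predictive_inflation = st$predictive_inflation,
    sigma_inflation = 1, decrement_se_multiplier = 1)

  structure(list(
    variant = raw$variant, description = raw$description,
    prob = prob, derived = derived,
    effectiveness = eff,
    arms = arm_definitions(comp), components = comp,
    amb_cost_weight = raw$probabilities$pAmb$cost_weight,
    costs = costs,
    upop = upop, decrements = dec,
    lifetable = lifetable, settings = settings),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>", x$variant, "-", x$description, "\n")
  cat("  arms:", paste(x$arms$label, collapse = ", "), "\n")
  cat(sprintf("  pIngest %.6f, pAdmit %.4f, pSevere %.4f, pFatal %.4f\n",
              dist_mean(x$prob$pIngest), dist_mean(x$prob$pAdmit),
              dist_mean(x$prob$pSevere), dist_mean(x$prob$pFatal)))
  cat(sprintf("  horizon %d y, discount %.1f%%/%.1f%%, cohort %d households\n",
              x$settings$horizon, 100 * x$settings$discount_costs,
              100 * x$settings$discount_utilities, x$settings$cohort_size))
  invisible(x)
}
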