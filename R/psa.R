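#' Sensitivity-analysis scenario ladder
#'
#' Returns the ids of the supported scenarios: `"base"` plus `"SA1"` to
#' `"SA12"`.
#'
#' \describe{
#'   \item{SA1}{Effectiveness sampled from an approximate predictive
#'     distribution: every arm's logit-scale spread inflated by the
#'     configured factor (default 1.5).}
#'   \item{SA2}{Baseline prevalence of safe storage set to 0.93.}
#'   \item{SA3}{Baseline prevalence of safe storage set to 0.50.}
#'   \item{SA4}{Intervention acceptance reduced from 0.90 to 0.50.}
#'   \item{SA5}{Admission probability raised to 0.833, preserving the
#'     Beta's coefficient of variation.}
#'   \item{SA6}{Equipment component priced as two pop-it locks (2 x 2.65).}
#'   \item{SA7}{Equipment component priced as two magnetic locks
#'     (2 x 4.80).}
#'   \item{SA8}{Children per household raised from 1 to 1.8.}
#'   \item{SA9}{Poisoning incidence raised to 44.9 per 10,000
#'     person-years (4th deprivation quintile).}
#'   \item{SA10}{Poisoning incidence raised to 48.5 per 10,000
#'     person-years (5th deprivation quintile).}
#'   \item{SA11}{Utility-decrement standard errors doubled (20% of mean).}
#'   \item{SA12}{Utility-decrement standard errors at 50% of mean.}
#' }
#' @return Character vector of scenario ids.
#' @export
scenario_ids <- function() c("base", paste0("SA", 1:12))

#' Apply a sensitivity scenario to a model configuration
#'
#' Each scenario modifies only its stated parameters; the base scenario is
#' a no-op. See [scenario_ids()] for the ladder.
#'
#' @param config A `model_config`.
#' @param scenario A scenario id.
#' @return The modified `model_config`.
#' @export
apply_scenario <- function(config, scenario = "base") {
  stopifnot(inherits(config, "model_config"))
  if (!scenario %in% scenario_ids())
    stop("unknown scenario id: ", scenario, call. = FALSE)
  cfg <- config
  cfg$scenario <- scenario
  switch(scenario,
    base = NULL,
    SA1 = {
      cfg$settings$sigma_inflation <- cfg$settings$predictive_inflation
    },
    SA2 = { cfg$prob$pSafe <- dist_spec("fixed", value = 0.93) },
    SA3 = { cfg$prob$pSafe <- dist_spec("fixed", value = 0.50) },
    SA4 = { cfg$prob$pAccept <- dist_spec("fixed", value = 0.50) },
    SA5 = {
      cfg$prob$pAdmit <- beta_rescale_mean(cfg$prob$pAdmit, 0.833)
    },
    SA6 = { cfg <- reprice_equipment(cfg, 2 * 2.65) },
    SA7 = { cfg <- reprice_equipment(cfg, 2 * 4.80) },
    SA8 = { cfg$settings$children_per_household <- 1.8 },
    SA9 = { cfg <- reprice_incidence(cfg, 44.9) },
    SA10 = { cfg <- reprice_incidence(cfg, 48.5) },
    SA11 = { cfg$settings$decrement_se_multiplier <- 2 },
    SA12 = { cfg$settings$decrement_se_multiplier <- 5 })
  cfg
}

# New Beta with the requested mean, preserving the coefficient of variation
# of the original Beta (effective sample size is rescaled accordingly).
beta_rescale_mean <- function(spec, new_mean) {
  stopifnot(spec$family == "beta")
  a <- spec$params$shape1; b <- spec$params$shape2
  m <- a / (a + b); nu <- a + b
  cv2 <- (1 - m) / (m * (nu + 1))
  nu_new <- (1 - new_mean) / (new_mean * cv2) - 1
  dist_spec("beta", shape1 = new_mean * nu_new,
            shape2 = (1 - new_mean) * nu_new,
            derivation = list(rescaled_from = spec$params,
                              new_mean = new_mean))
}

reprice_equipment <- function(cfg, equipment_cost) {
  cfg$components[["equipment"]] <- equipment_cost
  cfg$arms <- arm_definitions(cfg$components)
  cfg
}

# Recompute the annual ingestion probability from a new incidence rate.
# Admission/severity/fatality probabilities describe the clinical pathway
# of a case and are left at their base values.
reprice_incidence <- function(cfg, per_10000) {
  d <- cfg$derived
  pop <- cfg$prob$pIngest$derivation$total
  share <- round(d$numerator / d$cases_uk, 1)
  cases_uk <- round(per_10000 * pop / 1e4)
  numerator <- round(cases_uk * share)
  cfg$prob$pIngest <- beta_from_counts(numerator, pop)
  cfg$derived$cases_uk <- cases_uk
  cfg$derived$numerator <- numerator
  cfg
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples `n_draws` joint parameter realizations and runs the three-stage
#' model for all seven arms on every draw (common random numbers: all arms
#' share each draw, so paired increments are far less variable than the
#' marginals). Reproducible bit-for-bit for a given seed.
#'
#' @param config A `model_config`, or a variant name passed to
#'   [load_model_config()].
#' @param n_draws Number of Monte-Carlo draws (default 4000).
#' @param seed Integer seed for the random number stream.
#' @param scenario Scenario id (see [scenario_ids()]).
#' @param point_estimate If `TRUE`, a single deterministic draw at the
#'   parameter point estimates.
#' @return A `psa_results` object: matrices `cases`, `cost_cea`,
#'   `cost_cua`, `qalys` (draws x arms, per 1,000 households), the
#'   parameter `draws`, `arms`, and run metadata.
#' @export
run_psa <- function(config, n_draws = 4000, seed = 1L, scenario = "base",
                    point_estimate = FALSE) {
  if (is.character(config)) config <- load_model_config(config)
  cfg <- apply_scenario(config, scenario)
  set.seed(seed)
  draws <- sample_parameters(cfg, n_draws, point_estimate = point_estimate)
  n <- nrow(draws)
  k <- nrow(cfg$arms)
  cases <- cost_cea <- cost_cua <- qalys <- cost_int <-
    matrix(0, n, k, dimnames = list(NULL, cfg$arms$label))
  for (i in seq_len(k)) {
    res <- run_model_arm(cfg$arms[i, ], draws, cfg)
    cases[, i] <- res$cases
    cost_int[, i] <- res$cost_intervention
    cost_cea[, i] <- res$cost_cea
    cost_cua[, i] <- res$cost_cua
    qalys[, i] <- res$qalys
  }
  structure(list(
    cases = cases, cost_intervention = cost_int, cost_cea = cost_cea,
    cost_cua = cost_cua, qalys = qalys,
    draws = draws, arms = cfg$arms,
    variant = cfg$variant, scenario = scenario,
    seed = seed, n_draws = n, point_estimate = point_estimate,
    settings = cfg$settings),
    class = "psa_results")
}

#' @export
print.psa_results <- function(x, ...) {
  cat(sprintf("<psa_results> %s / %s: %d draws, seed %d%s\n", x$variant,
              x$scenario, x$n_draws, x$seed,
              if (x$point_estimate) " (point estimates)" else ""))
  s <- summarize_arms(x)
  print(data.frame(arm = s$label, cases = round(s$cases, 3),
                   cost_cea = round(s$cost_cea), qalys = round(s$qalys, 3),
                   cost_cua = round(s$cost_cua)), row.names = FALSE)
  invisible(x)
}

#' Run the PSA for one model variant
#'
#' Convenience wrapper: loads the packaged parameter file for the variant
#' and runs [run_psa()]. The medicinal and non-medicinal configurations
#' differ only in their probability and effectiveness inputs; costs and
#' utilities are identical.
#'
#' @param variant `"medicinal"` or `"nonmedicinal"`.
#' @inheritParams run_psa
#' @return A `psa_results` object.
#' @export
run_variant <- function(variant = c("medicinal", "nonmedicinal"),
                        n_draws = 4000, seed = 1L, scenario = "base",
                        point_estimate = FALSE) {
  variant <- match.arg(variant)
  run_psa(load_model_config(variant), n_draws = n_draws, seed = seed,
          scenario = scenario, point_estimate = point_estimate)
}
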