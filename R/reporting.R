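#' Results table in the published layout
#'
#' One row per arm, ordered by arm id: expected benefit (poison cases for
#' the cost-effectiveness analysis, QALYs for the cost-utility analysis)
#' and expected cost with 95% credible intervals, paired increments versus
#' usual care, the ICER versus usual care or a dominance flag, and the
#' probability the arm is the most cost-effective at the 30,000 and 50,000
#' GBP thresholds.
#'
#' Dominance is classified at the precision the published tables print
#' their benefit columns (three decimals per 1,000 households,
#' `effect_tol = 1e-3`): two strategies whose mean benefits agree to the
#' printed precision count as equally effective, and the costlier one is
#' dominated.
#'
#' @param psa A [run_psa()] result.
#' @param analysis `"cea"` (cases) or `"cua"` (QALYs).
#' @param thresholds Willingness-to-pay thresholds for the probability
#'   columns.
#' @param reference Reference arm id.
#' @param effect_tol Effect tolerance for dominance classification, see
#'   [incremental_analysis()].
#' @return A data.frame with full-precision numeric columns plus
#'   `icer_display` (ICER rounded to whole pounds, or the literal token
#'   `"Dominated"`).
#' @export
results_table <- function(psa, analysis = c("cea", "cua"),
                          thresholds = c(30000, 50000), reference = 1L,
                          effect_tol = 1e-3) {
  analysis <- match.arg(analysis)
  effect_measure <- if (analysis == "cea") "cases" else "qalys"
  s <- summarize_arms(psa, reference)
  inc <- incremental_analysis(psa, effect_measure, reference,
                              effect_tol = effect_tol)
  inc <- inc[match(s$arm, inc$arm), ]
  cc <- ceac(psa, thresholds, effect_measure)
  probs <- vapply(thresholds, function(th)
    cc$probability[cc$threshold == th][match(s$arm,
                                             cc$arm[cc$threshold == th])],
    numeric(nrow(s)))
  ci <- t(vapply(seq_len(nrow(s)), function(i) {
    d_e <- if (analysis == "cea") psa$cases[, reference] - psa$cases[, i]
           else psa$qalys[, i] - psa$qalys[, reference]
    d_c <- if (analysis == "cea")
             psa$cost_cea[, i] - psa$cost_cea[, reference]
           else psa$cost_cua[, i] - psa$cost_cua[, reference]
    icer_credible_interval(d_c, d_e)
  }, c(lower = 0, upper = 0, prop_used = 0)))
  if (analysis == "cea") {
    out <- data.frame(
      arm = s$arm, label = s$label,
      benefit = s$cases, benefit_lo = s$cases_lo, benefit_hi = s$cases_hi,
      cost = s$cost_cea, cost_lo = s$cost_cea_lo, cost_hi = s$cost_cea_hi,
      d_benefit = s$d_cases, d_benefit_lo = s$d_cases_lo,
      d_benefit_hi = s$d_cases_hi,
      d_cost = s$d_cost_cea, d_cost_lo = s$d_cost_cea_lo,
      d_cost_hi = s$d_cost_cea_hi)
  } else {
    out <- data.frame(
      arm = s$arm, label = s$label,
      benefit = s$qalys, benefit_lo = s$qalys_lo, benefit_hi = s$qalys_hi,
      cost = s$cost_cua, cost_lo = s$cost_cua_lo, cost_hi = s$cost_cua_hi,
      d_benefit = s$d_qalys, d_benefit_lo = s$d_qalys_lo,
      d_benefit_hi = s$d_qalys_hi,
      d_cost = s$d_cost_cua, d_cost_lo = s$d_cost_cua_lo,
      d_cost_hi = s$d_cost_cua_hi)
  }
  out$icer <- ifelse(out$arm == reference, NA_real_,
                     out$d_cost / out$d_benefit)
  out$icer_lo <- ci[, 1]; out$icer_hi <- ci[, 2]
  out$dominance <- inc$dominance
  out$icer_display <- ifelse(
    out$arm == reference, "",
    ifelse(out$dominance != "", "Dominated",
           as.character(round(out$icer))))
  for (j in seq_along(thresholds))
    out[[sprintf("prob_ce_%d", thresholds[j])]] <- round(probs[, j], 3)
  attr(out, "analysis") <- analysis
  attr(out, "note") <- paste(
    "Thresholds are GBP per", if (analysis == "cea")
      "poison case averted (the source labels this column per QALY)"
    else "QALY gained")
  out
}

#' Write / read a results table as delimited text
#'
#' Numeric columns are serialised at full (17 significant digit) precision
#' so a write/read round trip reproduces the values exactly; the
#' `icer_display` column carries the rounded presentation value or the
#' literal token `"Dominated"`.
#'
#' @param table A [results_table()] (or any data.frame).
#' @param path Output file.
#' @return `path`, invisibly (for `write_cea_table`); the parsed data.frame
#'   (for `read_cea_table`).
#' @export
write_cea_table <- function(table, path) {
  fmt <- table
  for (nm in names(fmt))
    if (is.numeric(fmt[[nm]]))
      fmt[[nm]] <- sprintf("%.17g", fmt[[nm]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cea_table
#' @export
read_cea_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  for (nm in setdiff(names(out), c("label", "dominance", "icer_display")))
    if (is.character(out[[nm]])) out[[nm]] <- as.numeric(out[[nm]])
  out
}

# small stable checksum of a serialized R object (djb2 over raw bytes,
# exact in double arithmetic)
config_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run one full analysis and write its result bundle
#'
#' Executes the PSA for a variant/scenario, builds the cost-effectiveness
#' and/or cost-utility tables, the cost-effectiveness acceptability curves
#' and the cost-effectiveness plane coordinates, and writes everything as
#' delimited text to `out_dir` together with a YAML run log carrying the
#' seed, draw count and configuration hash needed to reproduce the run
#' bit-for-bit.
#'
#' @param variant `"medicinal"` or `"nonmedicinal"`.
#' @param analysis `"cea"`, `"cua"` or `"both"`.
#' @param n_draws,seed,scenario,point_estimate Passed to [run_psa()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing and returns the bundle only.
#' @return A `result_bundle` list: `tables`, `ceac`, `plane`, `psa`,
#'   `metadata`.
#' @export
run_analysis <- function(variant = c("medicinal", "nonmedicinal"),
                         analysis = c("both", "cea", "cua"),
                         n_draws = 4000, seed = 1L, scenario = "base",
                         point_estimate = FALSE, out_dir = NULL) {
  variant <- match.arg(variant)
  analysis <- match.arg(analysis)
  config <- load_model_config(variant)
  psa <- run_psa(config, n_draws = n_draws, seed = seed,
                 scenario = scenario, point_estimate = point_estimate)
  which_tab <- if (analysis == "both") c("cea", "cua") else analysis
  tables <- lapply(which_tab, function(a) results_table(psa, a))
  names(tables) <- which_tab
  curves <- lapply(which_tab, function(a)
    ceac(psa, effect_measure = if (a == "cea") "cases" else "qalys"))
  names(curves) <- which_tab
  planes <- lapply(which_tab, function(a)
    ce_plane(psa, effect_measure = if (a == "cea") "cases" else "qalys"))
  names(planes) <- which_tab
  metadata <- list(
    variant = variant, scenario = scenario, analysis = analysis,
    n_draws = n_draws, seed = seed, point_estimate = point_estimate,
    package_version = as.character(utils::packageVersion("poisoncea")),
    config_hash = config_hash(apply_scenario(config, scenario)),
    threshold_note = paste(
      "cost-effectiveness analysis thresholds are GBP per poison case",
      "averted; the source table heading reads 'per QALY' while its text",
      "reads 'per poison case avoided'"))
  bundle <- structure(list(tables = tables, ceac = curves, plane = planes,
                           psa = psa, metadata = metadata),
                      class = "result_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(out_dir, paste(variant, scenario, sep = "_"))
    for (a in which_tab) {
      write_cea_table(tables[[a]], paste0(stem, "_", a, "_table.csv"))
      utils::write.csv(curves[[a]], paste0(stem, "_", a, "_ceac.csv"),
                       row.names = FALSE)
      utils::write.csv(planes[[a]], paste0(stem, "_", a, "_plane.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(metadata, paste0(stem, "_runlog.yaml"))
  }
  bundle
}

#' Exact-arithmetic validation battery
#'
#' Recomputes every printed derivation the configuration encodes - derived
#' probabilities, per-arm intervention offer costs and acute unit costs -
#' and compares them with the published point values at their printed
#' precision.
#'
#' @param variant `"medicinal"` or `"nonmedicinal"`.
#' @return A data.frame with columns `quantity`, `computed`, `printed`,
#'   `tolerance`, `ok`.
#' @export
validate_derivations <- function(variant = c("medicinal", "nonmedicinal")) {
  variant <- match.arg(variant)
  cfg <- load_model_config(variant)
  printed <- if (variant == "medicinal") {
    list(pSafe = c(0.75, 0.005), pIngest = c(0.001806, 1e-6),
         pAdmit = c(0.63, 0.005), pSevere = c(0.0191, 1e-4),
         pFatal = c(0.0116, 1e-4))
  } else {
    list(pSafe = c(0.83, 0.005), pIngest = c(0.001204, 1e-6),
         pAdmit = c(0.3318, 1e-4), pSevere = c(0.0191, 0.0005),
         pFatal = c(0.033, 5e-4))
  }
  rows <- lapply(names(printed), function(nm) {
    computed <- dist_mean(cfg$prob[[nm]])
    data.frame(quantity = nm, computed = computed,
               printed = printed[[nm]][1], tolerance = printed[[nm]][2])
  })
  offer <- data.frame(
    quantity = paste0("offer_", cfg$arms$label),
    computed = cfg$arms$offer_cost,
    printed = c(0, 3.67, 7.45, 11.12, 19.78, 18.19, 21.86),
    tolerance = 1e-9)
  pe <- point_parameters(cfg)
  acute <- data.frame(
    quantity = c("acute_minor", "acute_moderate", "acute_severe"),
    computed = c(acute_event_cost("minor", pe, cfg$amb_cost_weight),
                 acute_event_cost("moderate", pe, cfg$amb_cost_weight),
                 acute_event_cost("severe", pe, cfg$amb_cost_weight)),
    printed = c(175.12, 795.12, 2670.12),
    tolerance = 1e-9)
  out <- rbind(do.call(rbind, rows), offer, acute)
  out$ok <- abs(out$computed - out$printed) <= out$tolerance
  rownames(out) <- NULL
  out
}
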