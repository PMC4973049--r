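#' Discount factor
#'
#' `(1 + rate)^(-years)`: the present value at time zero of one unit
#' accruing `years` years later.
#'
#' @param rate Annual discount rate (>= 0).
#' @param years Elapsed years (>= 0).
#' @return Discount factor in (0, 1].
#' @export
discount_factor <- function(rate, years) {
  if (any(rate < 0)) stop("negative discount rate", call. = FALSE)
  if (any(years < 0)) stop("negative time", call. = FALSE)
  (1 + rate)^(-years)
}

#' Per-arm summaries of a probabilistic sensitivity analysis
#'
#' Means and 2.5/97.5 percentiles of poison cases, costs and QALYs per
#' 1,000 households, plus the paired increments versus the reference arm.
#'
#' @param psa A [run_psa()] result.
#' @param reference Reference arm id (default 1, usual care).
#' @return A data.frame with one row per arm.
#' @export
summarize_arms <- function(psa, reference = 1L) {
  stopifnot(inherits(psa, "psa_results"))
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  ref <- which(psa$arms$arm == reference)
  out <- lapply(seq_len(nrow(psa$arms)), function(i) {
    d_cases <- psa$cases[, ref] - psa$cases[, i]       # cases averted
    d_cost_cea <- psa$cost_cea[, i] - psa$cost_cea[, ref]
    d_qaly <- psa$qalys[, i] - psa$qalys[, ref]
    d_cost_cua <- psa$cost_cua[, i] - psa$cost_cua[, ref]
    data.frame(
      arm = psa$arms$arm[i], label = psa$arms$label[i],
      cases = mean(psa$cases[, i]),
      cases_lo = qs(psa$cases[, i])[1], cases_hi = qs(psa$cases[, i])[2],
      cost_cea = mean(psa$cost_cea[, i]),
      cost_cea_lo = qs(psa$cost_cea[, i])[1],
      cost_cea_hi = qs(psa$cost_cea[, i])[2],
      qalys = mean(psa$qalys[, i]),
      qalys_lo = qs(psa$qalys[, i])[1], qalys_hi = qs(psa$qalys[, i])[2],
      cost_cua = mean(psa$cost_cua[, i]),
      cost_cua_lo = qs(psa$cost_cua[, i])[1],
      cost_cua_hi = qs(psa$cost_cua[, i])[2],
      d_cases = mean(d_cases),
      d_cases_lo = qs(d_cases)[1], d_cases_hi = qs(d_cases)[2],
      d_cost_cea = mean(d_cost_cea),
      d_cost_cea_lo = qs(d_cost_cea)[1], d_cost_cea_hi = qs(d_cost_cea)[2],
      d_qalys = mean(d_qaly),
      d_qalys_lo = qs(d_qaly)[1], d_qalys_hi = qs(d_qaly)[2],
      d_cost_cua = mean(d_cost_cua),
      d_cost_cua_lo = qs(d_cost_cua)[1], d_cost_cua_hi = qs(d_cost_cua)[2])
  })
  do.call(rbind, out)
}

#' Incremental cost-effectiveness analysis with dominance classification
#'
#' Orders strategies by mean effect, flags strict dominance (another
#' strategy costs no more and is at least as effective, with at least one
#' strict inequality), then iteratively removes extended dominance
#' (a strategy whose incremental ICER along the effect-ordered frontier
#' exceeds that of the next more effective strategy). ICERs are ratios of
#' mean increments, reported both against the reference arm and
#' sequentially between adjacent frontier strategies; frontier ICERs are
#' non-decreasing in effect by construction.
#'
#' Strategies whose mean effects differ by no more than `effect_tol` are
#' treated as equally effective, with the tie broken by lower cost (the
#' cheaper strategy dominates). The default is an exact comparison
#' (`effect_tol = 0`); [results_table()] classifies at the printed
#' precision of the published tables instead, which is how those tables
#' themselves judge "the same QALY gain for a higher cost".
#'
#' @param arms A data.frame with columns `arm`, `label`, `effect`, `cost`
#'   (means per 1,000 households), or a [run_psa()] result combined with
#'   `effect_measure`.
#' @param effect_measure When `arms` is a `psa_results`: `"cases"` (cases
#'   averted relative to the reference) or `"qalys"`.
#' @param reference Reference arm id (default 1).
#' @param effect_tol Absolute tolerance below which two mean effects count
#'   as equal in the strict-dominance comparison.
#' @return A `cea_table` data.frame sorted by effect with columns
#'   `d_effect_ref`, `d_cost_ref`, `icer_ref`, `icer_frontier`, and
#'   `dominance` (`""`, `"dominated"` or `"ext dominated"`).
#' @export
incremental_analysis <- function(arms, effect_measure = c("cases", "qalys"),
                                 reference = 1L, effect_tol = 0) {
  effect_measure <- match.arg(effect_measure)
  if (inherits(arms, "psa_results")) {
    s <- summarize_arms(arms, reference)
    arms <- data.frame(arm = s$arm, label = s$label,
                       effect = if (effect_measure == "cases") -s$cases
                                else s$qalys,
                       cost = if (effect_measure == "cases") s$cost_cea
                              else s$cost_cua)
  }
  stopifnot(nrow(arms) >= 2, all(c("arm", "effect", "cost") %in% names(arms)))
  tab <- arms[order(arms$effect, arms$cost), ]
  n <- nrow(tab)
  dominance <- character(n)
  for (i in seq_len(n)) {
    others <- tab[-i, ]
    if (any((others$effect >= tab$effect[i] - effect_tol &
               others$cost < tab$cost[i]) |
              (others$effect > tab$effect[i] + effect_tol &
                 others$cost <= tab$cost[i])))
      dominance[i] <- "dominated"
  }
  repeat {
    front <- which(dominance == "")
    if (length(front) < 3) break
    icers <- diff(tab$cost[front]) / diff(tab$effect[front])
    bad <- which(utils::head(icers, -1) > utils::tail(icers, -1))
    if (!length(bad)) break
    dominance[front[bad[1] + 1]] <- "ext dominated"
  }
  front <- which(dominance == "")
  icer_frontier <- rep(NA_real_, n)
  if (length(front) > 1)
    icer_frontier[front[-1]] <- diff(tab$cost[front]) /
      diff(tab$effect[front])
  ref_i <- which(tab$arm == reference)
  d_effect <- tab$effect - tab$effect[ref_i]
  d_cost <- tab$cost - tab$cost[ref_i]
  icer_ref <- ifelse(seq_len(n) == ref_i | dominance != "",
                     NA_real_, d_cost / d_effect)
  out <- cbind(tab, d_effect_ref = d_effect, d_cost_ref = d_cost,
               icer_ref = icer_ref, icer_frontier = icer_frontier,
               dominance = dominance)
  rownames(out) <- NULL
  class(out) <- c("cea_table", "data.frame")
  out
}

psa_effect_cost <- function(psa, effect_measure, analysis_cost = NULL) {
  if (effect_measure == "cases")
    list(effect = -psa$cases, cost = psa$cost_cea)
  else
    list(effect = psa$qalys, cost = psa$cost_cua)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that each arm
#' maximises net monetary benefit (`lambda * effect - cost`) across the
#' PSA draws. Ties are split equally across the tied arms, so the
#' probabilities sum to exactly one at every threshold.
#'
#' @param psa A [run_psa()] result.
#' @param thresholds Willingness-to-pay grid (GBP per unit of effect).
#' @param effect_measure `"cases"` (effect is cases averted; the threshold
#'   is GBP per case averted) or `"qalys"`.
#' @return A `ceac_curve` data.frame: `threshold`, `arm`, `label`,
#'   `probability`.
#' @export
ceac <- function(psa, thresholds = seq(0, 1e5, by = 2500),
                 effect_measure = c("cases", "qalys")) {
  stopifnot(inherits(psa, "psa_results"))
  effect_measure <- match.arg(effect_measure)
  if (!nrow(psa$cases)) stop("empty draws", call. = FALSE)
  ec <- psa_effect_cost(psa, effect_measure)
  k <- ncol(ec$effect)
  out <- lapply(thresholds, function(lam) {
    nmb <- lam * ec$effect - ec$cost
    best <- nmb == matrixStats_rowMaxs(nmb)
    p <- colMeans(best / rowSums(best))
    data.frame(threshold = lam, arm = psa$arms$arm,
               label = psa$arms$label, probability = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ceac_curve", "data.frame")
  out
}

# row maxima without a matrixStats dependency
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' Cost-effectiveness plane coordinates
#'
#' Per-draw incremental effect and cost of every arm against the reference,
#' preserving the draw pairing (common random numbers), for plotting the
#' simulated ICER cloud.
#'
#' @param psa A [run_psa()] result.
#' @param reference Reference arm id (default 1).
#' @param effect_measure `"cases"` (incremental effect is cases averted)
#'   or `"qalys"`.
#' @return A data.frame: `draw`, `arm`, `label`, `d_effect`, `d_cost`.
#' @export
ce_plane <- function(psa, reference = 1L,
                     effect_measure = c("cases", "qalys")) {
  stopifnot(inherits(psa, "psa_results"))
  effect_measure <- match.arg(effect_measure)
  ec <- psa_effect_cost(psa, effect_measure)
  ref <- which(psa$arms$arm == reference)
  if (!length(ref)) stop("reference arm not present", call. = FALSE)
  n <- nrow(ec$effect)
  out <- lapply(seq_len(ncol(ec$effect)), function(i)
    data.frame(draw = seq_len(n), arm = psa$arms$arm[i],
               label = psa$arms$label[i],
               d_effect = ec$effect[, i] - ec$effect[, ref],
               d_cost = ec$cost[, i] - ec$cost[, ref]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Credible interval for an ICER from paired PSA draws
#'
#' 2.5/97.5 percentiles of the per-draw incremental cost over incremental
#' effect ratio, restricted to draws with positive incremental effect
#' (ratios are not sign-stable across quadrants; the restriction is the
#' documented caveat).
#'
#' @param d_cost,d_effect Paired per-draw increments.
#' @return Named vector `lower`, `upper`, plus `prop_used`.
#' @export
icer_credible_interval <- function(d_cost, d_effect) {
  keep <- d_effect > 0
  if (!any(keep)) return(c(lower = NA_real_, upper = NA_real_,
                           prop_used = 0))
  q <- stats::quantile(d_cost[keep] / d_effect[keep], c(0.025, 0.975),
                       names = FALSE)
  c(lower = q[1], upper = q[2], prop_used = mean(keep))
}
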