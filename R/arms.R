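#' The seven home-safety intervention strategies
#'
#' Arm 1 is usual care; the six active strategies combine education,
#' provision of low cost/free safety equipment (two cupboard locks), a home
#' safety inspection, and fitting of the equipment.
#'
#' @param components Named component costs in GBP per offered household
#'   (`education`, `equipment`, `inspection`, `fitting`, `travel`). The
#'   default values are the 2012 unit-cost build-up; travel is charged only
#'   when an inspection or fitting requires a dedicated visit.
#' @return A data.frame with one row per arm: `arm`, `label`, logical
#'   component flags, and `offer_cost` (GBP per offered household; 0 for
#'   usual care).
#' @examples
#' arm_definitions()
#' @export
arm_definitions <- function(components = c(education = 3.67,
                                           equipment = 7.45,
                                           inspection = 3.67,
                                           fitting = 2.08,
                                           travel = 4.99)) {
  flags <- rbind(
    c(FALSE, FALSE, FALSE, FALSE),
    c(TRUE,  FALSE, FALSE, FALSE),
    c(FALSE, TRUE,  FALSE, FALSE),
    c(TRUE,  TRUE,  FALSE, FALSE),
    c(TRUE,  TRUE,  TRUE,  FALSE),
    c(TRUE,  TRUE,  FALSE, TRUE),
    c(TRUE,  TRUE,  TRUE,  TRUE))
  colnames(flags) <- c("education", "equipment", "inspection", "fitting")
  out <- data.frame(
    arm = 1:7,
    label = c("UC", "E", "FE", "E+FE", "E+FE+HSI", "E+FE+F",
              "E+FE+HSI+F"),
    flags)
  out$offer_cost <- vapply(seq_len(7), function(i)
    compute_offer_cost(out[i, ], components), 0)
  out
}

#' Offer cost of one intervention arm
#'
#' Sums the per-household component costs; travel is added when the arm
#' includes a home safety inspection or fitting (a dedicated visit).
#' Education alone is 3.67; education + equipment 11.12; all four
#' components 21.86 (2012 GBP).
#'
#' @param arm One row of [arm_definitions()] (or any list with logical
#'   `education`, `equipment`, `inspection`, `fitting`).
#' @param components Named component costs (see [arm_definitions()]).
#' @return Offer cost in GBP per offered household.
#' @export
compute_offer_cost <- function(arm, components = c(education = 3.67,
                                                   equipment = 7.45,
                                                   inspection = 3.67,
                                                   fitting = 2.08,
                                                   travel = 4.99)) {
  cost <- 0
  for (comp in c("education", "equipment", "inspection", "fitting"))
    if (isTRUE(arm[[comp]])) cost <- cost + components[[comp]]
  if (isTRUE(arm[["inspection"]]) || isTRUE(arm[["fitting"]]))
    cost <- cost + components[["travel"]]
  cost
}

#' Stage-1 allocation of households to safe / unsafe storage
#'
#' Converts baseline prevalence of safe storage, intervention acceptance and
#' arm effectiveness into the initial cohort split. Two allocation rules
#' are supported:
#' \describe{
#'   \item{`"blend"`}{`propSafe = pAccept * pEff + (1 - pAccept) * pSafe`:
#'     accepting households take the arm's absolute safe-storage
#'     probability, non-acceptors stay at the baseline prevalence. Used for
#'     usual care, whose "effectiveness" is the absolute control-arm
#'     safe-storage probability from the evidence network.}
#'   \item{`"convert"`}{`propSafe = pSafe + (1 - pSafe) * pAccept * pEff`:
#'     households that already store safely stay safe; an offered, accepted
#'     intervention converts an unsafe household with probability `pEff`.
#'     Used for the six active arms. This asymmetric pairing is the only
#'     rule that reproduces the published per-arm expected case counts
#'     (see the methods vignette).}
#' }
#'
#' All arguments are vectorised over parameter draws.
#'
#' @param pSafe Baseline prevalence of safe storage in \[0, 1\].
#' @param pAccept Probability the offered intervention is accepted.
#' @param pEff Arm effectiveness (absolute safe-storage probability).
#' @param rule `"blend"` or `"convert"`.
#' @return A list with `prop_safe` and `prop_unsafe` (summing to 1).
#' @examples
#' allocate_states(0.75, 0.9, 0.87, rule = "blend")   # usual care
#' allocate_states(0.75, 0.9, 0.90, rule = "convert") # active arm
#' @export
allocate_states <- function(pSafe, pAccept, pEff,
                            rule = c("convert", "blend")) {
  rule <- match.arg(rule)
  stopifnot(all(pSafe >= 0 & pSafe <= 1), all(pAccept >= 0 & pAccept <= 1),
            all(pEff >= 0 & pEff <= 1))
  prop_safe <- switch(rule,
    blend = pAccept * pEff + (1 - pAccept) * pSafe,
    convert = pSafe + (1 - pSafe) * pAccept * pEff)
  list(prop_safe = prop_safe, prop_unsafe = 1 - prop_safe)
}

#' Intervention cost per household in the cohort
#'
#' Usual care costs nothing. An active arm charges the scheme set-up cost
#' (`cFixed` spread over the 100,000-household cohort) plus, for each
#' targeted household that accepts, the arm's offer cost and the
#' household's acceptance cost. Under the default `"target-unsafe"` policy
#' the offer is made only to the `(1 - pSafe)` households without safe
#' storage; `"offer-all"` offers to every household.
#'
#' @param arm One row of [arm_definitions()].
#' @param pSafe,pAccept Baseline prevalence and acceptance (vectorised).
#' @param cFixed Scheme set-up cost per `cohort_size` households.
#' @param cAccept Cost incurred by an accepting household.
#' @param policy `"target-unsafe"` (default) or `"offer-all"`.
#' @param cohort_size Households sharing `cFixed` (default 100,000).
#' @return Cost in GBP per household in the cohort (vectorised).
#' @export
arm_cost_per_household <- function(arm, pSafe, pAccept, cFixed, cAccept,
                                   policy = c("target-unsafe", "offer-all"),
                                   cohort_size = 1e5) {
  policy <- match.arg(policy)
  if (arm$arm == 1L) return(rep(0, length(pSafe)))
  targeting <- if (policy == "target-unsafe") (1 - pSafe) else 1
  targeting * pAccept * (arm$offer_cost + cAccept) + cFixed / cohort_size
}
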