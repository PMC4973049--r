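#' Annual ingestion risk by storage stratum
#'
#' The annual ingestion probability `pIngest` is interpreted as the risk in
#' the no-safe-storage stratum; the safe-storage risk is obtained on the
#' odds scale with the signed log odds ratio as reported
#' (`odds_safe = odds_unsafe * exp(logOrIngest)`). A negative log-OR is
#' protective (medicinal model), a positive one harmful (non-medicinal).
#'
#' Vectorised over draws.
#'
#' @param pIngest Annual ingestion probability, unsafe stratum, in (0, 1).
#' @param logOrIngest Signed log odds ratio, safe vs unsafe storage.
#' @return List with `risk_unsafe` and `risk_safe`.
#' @examples
#' risk_by_stratum(0.001806, -0.604)
#' @export
risk_by_stratum <- function(pIngest, logOrIngest) {
  stopifnot(all(pIngest >= 0 & pIngest < 1))
  odds <- pIngest / (1 - pIngest) * exp(logOrIngest)
  list(risk_unsafe = pIngest, risk_safe = odds / (1 + odds))
}

#' Severity split of an ingestion event
#'
#' Conditional on a medically attended ingestion, the event is minor
#' (no admission), moderate (admitted, no chronic outcome), severe with
#' survival (admitted, chronic outcome), or fatal. The four probabilities
#' sum to one by construction.
#'
#' @param pAdmit Probability of inpatient admission.
#' @param pSevere Probability of a chronic (severe) outcome given admission.
#' @param pFatal Probability of death given a severe outcome.
#' @return List with `minor`, `moderate`, `severe_survive`, `death`.
#' @export
severity_split <- function(pAdmit, pSevere, pFatal) {
  stopifnot(all(pAdmit >= 0 & pAdmit <= 1), all(pSevere >= 0 & pSevere <= 1),
            all(pFatal >= 0 & pFatal <= 1))
  list(minor = 1 - pAdmit,
       moderate = pAdmit * (1 - pSevere),
       severe_survive = pAdmit * pSevere * (1 - pFatal),
       death = pAdmit * pSevere * pFatal)
}

#' Acute healthcare cost of one poisoning event
#'
#' Every medically attended case reaches the emergency department; an
#' ambulance cost is charged for the fraction `amb_weight` of cases
#' arriving by emergency transfer. Minor cases take ED treatment without
#' admission; moderate cases a short non-elective stay; severe cases a long
#' stay. A GP follow-up consultation is attached to every surviving
#' medically attended case; a fatality follows the severe inpatient pathway
#' and adds the fatality cost instead of the GP follow-up.
#'
#' With 2012 reference costs the build-up gives 175.12 (minor), 795.12
#' (moderate) and 2670.12 (severe) before the GP add-on.
#'
#' @param severity `"minor"`, `"moderate"`, `"severe"` or `"fatal"`.
#' @param draws A "parameter_draws" data.frame (uses `cAmb`, `cED1`,
#'   `cED2`, `cAdmit1`, `cAdmit2`, `cFatal`, `cGP`).
#' @param amb_weight Ambulance weighting (default 0.24, the rounded value
#'   used by the printed unit-cost arithmetic).
#' @param gp Include the GP follow-up add-on for surviving cases
#'   (default FALSE, giving the bare unit cost).
#' @return Cost in GBP per event (vectorised over draws).
#' @export
acute_event_cost <- function(severity = c("minor", "moderate", "severe",
                                          "fatal"),
                             draws, amb_weight = 0.24, gp = FALSE) {
  severity <- match.arg(severity)
  amb <- amb_weight * draws$cAmb
  base <- switch(severity,
    minor = amb + draws$cED1,
    moderate = amb + draws$cED2 + draws$cAdmit1,
    severe = amb + draws$cED2 + draws$cAdmit2,
    fatal = amb + draws$cED2 + draws$cAdmit2 + draws$cFatal)
  if (gp && severity != "fatal") base <- base + draws$cGP
  base
}

#' Utility decrement applied in the cycle of a poisoning event
#'
#' Minor, moderate and severe events lose `uMinor`, `uModerate` and
#' `uSevere` respectively for the event cycle; the severe decrement already
#' contains the chronic-state loss for that first year. From the following
#' cycle onwards a chronic survivor loses `uChronic` every year.
#'
#' @param severity `"minor"`, `"moderate"` or `"severe"`.
#' @param draws A "parameter_draws" data.frame.
#' @return QALY decrement (vectorised over draws).
#' @export
event_utility_decrement <- function(severity = c("minor", "moderate",
                                                 "severe"), draws) {
  severity <- match.arg(severity)
  switch(severity, minor = draws$uMinor, moderate = draws$uModerate,
         severe = draws$uSevere)
}

#' Preschool six-state Markov cohort model (ages 0-4)
#'
#' Propagates the cohort through the states safe storage (S1), unsafe
#' storage (S2), safe + chronic injury (S3), unsafe + chronic injury (S4),
#' poisoning death (S5, absorbing) and other-cause death (S6, absorbing),
#' with one annual cycle per year of age. Each cycle applies background
#' mortality first, then the stratum-specific ingestion risk with the
#' severity split; severe survivors move to the chronic state of their
#' stratum, fatalities to S5. Costs and QALYs are discounted at end of
#' cycle (no half-cycle correction). All quantities are per child entering
#' the model; scaling to households is done by the arm-level runner.
#'
#' @param prop_safe Initial share of households with safe storage
#'   (vectorised over draws).
#' @param draws A "parameter_draws" data.frame with one row per draw.
#' @param config A `model_config` (lifetable, baseline utilities,
#'   discount rates, preschool years).
#' @return A list: `cases` (expected events per child over the stage),
#'   `cost_health` and `qalys` (discounted totals per child), `exit`
#'   (occupancy shares `alive_no_chronic`, `alive_chronic`, `dead_poison`,
#'   `dead_other`), and `trace` (per-cycle matrices of cases, discounted
#'   cost and QALYs, and end-of-cycle state occupancy).
#' @export
run_preschool <- function(prop_safe, draws, config) {
  st <- config$settings
  n <- nrow(draws)
  stopifnot(length(prop_safe) == n, all(prop_safe >= 0 & prop_safe <= 1))
  ny <- st$preschool_years
  r <- risk_by_stratum(draws$pIngest, draws$logOrIngest)
  sev <- severity_split(draws$pAdmit, draws$pSevere, draws$pFatal)
  w <- config$amb_cost_weight
  cost_per_case <-
    sev$minor * acute_event_cost("minor", draws, w, gp = TRUE) +
    sev$moderate * acute_event_cost("moderate", draws, w, gp = TRUE) +
    sev$severe_survive * acute_event_cost("severe", draws, w, gp = TRUE) +
    sev$death * acute_event_cost("fatal", draws, w)
  dec_per_case <- sev$minor * draws$uMinor + sev$moderate * draws$uModerate +
    sev$severe_survive * draws$uSevere

  s1 <- prop_safe; s2 <- 1 - prop_safe
  s3 <- s4 <- s5 <- s6 <- numeric(n)
  cases_t <- cost_t <- qaly_t <- matrix(0, n, ny)
  occ <- array(0, c(n, 6, ny))
  for (a in seq_len(ny) - 1L) {
    qx <- config$lifetable$qx[a + 1L]
    s6 <- s6 + (s1 + s2 + s3 + s4) * qx
    s1 <- s1 * (1 - qx); s2 <- s2 * (1 - qx)
    s3 <- s3 * (1 - qx); s4 <- s4 * (1 - qx)
    chronic_pre <- s3 + s4
    c1 <- s1 * r$risk_safe;   c2 <- s2 * r$risk_unsafe
    c3 <- s3 * r$risk_safe;   c4 <- s4 * r$risk_unsafe
    cases <- c1 + c2 + c3 + c4
    s1 <- s1 - c1 * (sev$severe_survive + sev$death)
    s2 <- s2 - c2 * (sev$severe_survive + sev$death)
    s3 <- s3 + c1 * sev$severe_survive - c3 * sev$death
    s4 <- s4 + c2 * sev$severe_survive - c4 * sev$death
    s5 <- s5 + cases * sev$death
    alive <- s1 + s2 + s3 + s4
    total <- alive + s5 + s6
    if (any(abs(total - 1) > 1e-12))
      stop("conservation error: state occupancy drifted beyond 1e-12",
           call. = FALSE)
    dfc <- discount_factor(st$discount_costs, a + 1)
    dfu <- discount_factor(st$discount_utilities, a + 1)
    cases_t[, a + 1L] <- cases
    cost_t[, a + 1L] <- dfc * (cases * cost_per_case +
                                 chronic_pre * draws$cChro)
    qaly_t[, a + 1L] <- dfu * (alive * config$upop[a + 1L] -
                                 cases * dec_per_case -
                                 chronic_pre * draws$uChronic)
    occ[, , a + 1L] <- cbind(s1, s2, s3, s4, s5, s6)
  }
  list(cases = rowSums(cases_t), cost_health = rowSums(cost_t),
       qalys = rowSums(qaly_t),
       exit = list(alive_no_chronic = s1 + s2, alive_chronic = s3 + s4,
                   dead_poison = s5, dead_other = s6),
       trace = list(cases = cases_t, cost = cost_t, qalys = qaly_t,
                    occupancy = occ))
}

#' Long-term three-state Markov model (age 5 to the horizon)
#'
#' Quantifies the remaining lifetime discounted costs and QALYs for the
#' cohort leaving the preschool model: alive without chronic injury, alive
#' with chronic injury (permanent; accrues the annual chronic-care cost and
#' loses `uChronic` each year), and dead (absorbing). No further poisoning
#' events occur after age 5. Discounting continues on the clock started at
#' age 0.
#'
#' @param exit Exit distribution from [run_preschool()] (shares summing to
#'   at most 1; the remainder is already dead).
#' @param draws A "parameter_draws" data.frame.
#' @param config A `model_config`.
#' @return List with discounted `cost` and `qalys` per child over the
#'   remaining horizon, plus `dead_final`.
#' @export
run_longterm <- function(exit, draws, config) {
  st <- config$settings
  nc <- exit$alive_no_chronic; ch <- exit$alive_chronic
  if (any(nc + ch > 1 + 1e-12))
    stop("entry shares exceed 1", call. = FALSE)
  dead <- 1 - nc - ch
  cost <- qaly <- numeric(length(nc))
  from <- st$preschool_years
  for (a in from:(st$horizon - 1L)) {
    qx <- config$lifetable$qx[a + 1L]
    dead <- dead + (nc + ch) * qx
    nc <- nc * (1 - qx); ch <- ch * (1 - qx)
    dfc <- discount_factor(st$discount_costs, a + 1)
    dfu <- discount_factor(st$discount_utilities, a + 1)
    cost <- cost + dfc * ch * draws$cChro
    qaly <- qaly + dfu * (nc * config$upop[a + 1L] +
                            ch * (config$upop[a + 1L] - draws$uChronic))
  }
  list(cost = cost, qalys = qaly, dead_final = dead)
}

#' Run the full three-stage model for one intervention arm
#'
#' Stage 1 allocates households to safe / unsafe storage and prices the
#' intervention: usual care uses the `"blend"` allocation of its absolute
#' control-arm effect, active arms the `"convert"` rule (see
#' [allocate_states()]). Stages 2 and 3 accumulate discounted costs and
#' QALYs. Health consequences (cases, healthcare costs, QALYs) scale with
#' `children_per_household`; intervention costs are per household.
#'
#' @param arm_row One row of [arm_definitions()].
#' @param draws A "parameter_draws" data.frame.
#' @param config A `model_config`.
#' @return A list of per-1000-household outcomes: `cases`,
#'   `cost_intervention`, `cost_cea` (stage-2 horizon: intervention +
#'   acute/chronic care to age 5), `cost_cua` (lifetime), `qalys`
#'   (lifetime), and the underlying `prop_safe`.
#' @export
run_model_arm <- function(arm_row, draws, config) {
  st <- config$settings
  rule <- if (arm_row$arm == 1L) "blend" else "convert"
  alloc <- allocate_states(draws$pSafe, draws$pAccept,
                           draws[[paste0("pEff", arm_row$arm)]], rule = rule)
  ci <- arm_cost_per_household(arm_row, draws$pSafe, draws$pAccept,
                               draws$cFixed, draws$cAccept,
                               policy = st$costing_policy,
                               cohort_size = st$cohort_size)
  ps <- run_preschool(alloc$prop_safe, draws, config)
  lt <- run_longterm(ps$exit, draws, config)
  k <- st$children_per_household
  scale <- st$reporting_scale
  list(cases = k * ps$cases * scale,
       cost_intervention = ci * scale,
       cost_cea = (ci + k * ps$cost_health) * scale,
       cost_cua = (ci + k * (ps$cost_health + lt$cost)) * scale,
       qalys = k * (ps$qalys + lt$qalys) * scale,
       prop_safe = alloc$prop_safe)
}
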