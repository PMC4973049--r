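#' Individual-level microsimulation oracle
#'
#' Simulates children one at a time, year by year, with exactly the same
#' probabilities, event logic, discounting and time discretisation as the
#' cohort engine ([run_preschool()] + [run_longterm()]), so the cohort
#' model's outputs equal the microsimulation's expectations (not merely
#' approximately). Used to validate the cohort engine; it is Monte-Carlo
#' noisy and much slower, never the production path.
#'
#' @param n Number of simulated children.
#' @param draws A single-row "parameter_draws" data.frame (one parameter
#'   set).
#' @param prop_safe Initial probability of safe storage.
#' @param config A `model_config`.
#' @param seed Integer seed.
#' @return A list of per-child means with Monte-Carlo standard errors:
#'   `cases`, `cost_preschool` (discounted healthcare cost to age 5),
#'   `cost_total` (lifetime), `qalys` (lifetime discounted), each as
#'   `c(mean, se)`.
#' @export
simulate_households <- function(n, draws, prop_safe, config, seed = 1L) {
  stopifnot(n >= 1, nrow(draws) == 1)
  st <- config$settings
  set.seed(seed)
  r <- risk_by_stratum(draws$pIngest, draws$logOrIngest)
  sev <- severity_split(draws$pAdmit, draws$pSevere, draws$pFatal)
  cut1 <- sev$minor
  cut2 <- cut1 + sev$moderate
  cut3 <- cut2 + sev$severe_survive
  w <- config$amb_cost_weight
  ev_cost <- c(acute_event_cost("minor", draws, w, gp = TRUE),
               acute_event_cost("moderate", draws, w, gp = TRUE),
               acute_event_cost("severe", draws, w, gp = TRUE),
               acute_event_cost("fatal", draws, w))
  ev_dec <- c(draws$uMinor, draws$uModerate, draws$uSevere, 0)

  safe <- stats::runif(n) < prop_safe
  alive <- rep(TRUE, n)
  chronic <- rep(FALSE, n)
  cases <- cost_pre <- cost_all <- qaly <- numeric(n)
  for (a in 0:(st$horizon - 1L)) {
    qx <- config$lifetable$qx[a + 1L]
    alive <- alive & (stats::runif(n) >= qx)
    chronic_pre <- chronic & alive
    dfc <- discount_factor(st$discount_costs, a + 1)
    dfu <- discount_factor(st$discount_utilities, a + 1)
    ccost <- chronic_pre * draws$cChro
    if (a < st$preschool_years) {
      risk <- ifelse(safe, r$risk_safe, r$risk_unsafe)
      ev <- alive & (stats::runif(n) < risk)
      u <- stats::runif(n)
      grade <- ifelse(u < cut1, 1L, ifelse(u < cut2, 2L,
                      ifelse(u < cut3, 3L, 4L)))
      grade[!ev] <- 0L
      alive[grade == 4L] <- FALSE
      chronic <- chronic | (grade == 3L)
      cases <- cases + ev
      acost <- ifelse(ev, ev_cost[pmax(grade, 1L)], 0)
      cost_pre <- cost_pre + dfc * (acost + ccost)
      cost_all <- cost_all + dfc * (acost + ccost)
      qaly <- qaly + dfu * (alive * config$upop[a + 1L] -
                              ifelse(ev & alive, ev_dec[pmax(grade, 1L)], 0) -
                              chronic_pre * draws$uChronic)
    } else {
      cost_all <- cost_all + dfc * ccost
      qaly <- qaly + dfu * (alive * config$upop[a + 1L] -
                              chronic_pre * draws$uChronic)
    }
  }
  msd <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(n))
  list(cases = msd(cases), cost_preschool = msd(cost_pre),
       cost_total = msd(cost_all), qalys = msd(qaly), n = n)
}
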