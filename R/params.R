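#' Sample complete parameter draws for the probabilistic analysis
#'
#' Produces `n` joint realizations of every uncertain quantity in the model:
#' probabilities, the log odds ratio of ingestion under safe storage, unit
#' costs, utility decrements, and the seven correlated arm effectiveness
#' probabilities. Fixed parameters are identical across draws. Sampling
#' order is deterministic, so a seeded random number stream yields
#' bit-identical draws on repetition. Baseline age-band utilities and the
#' lifetable are treated as fixed (see the methods vignette).
#'
#' @param config A [load_model_config()] object (possibly modified by
#'   [apply_scenario()]).
#' @param n Number of draws.
#' @param point_estimate If `TRUE`, returns a single deterministic draw
#'   with every distribution collapsed to its point estimate (means;
#'   posterior medians for effectiveness).
#' @return A data.frame of `n` rows ("parameter_draws") with one column per
#'   parameter (`pEff1`..`pEff7` for effectiveness).
#' @export
sample_parameters <- function(config, n, point_estimate = FALSE) {
  stopifnot(inherits(config, "model_config"))
  jm <- joint_effect_model(config$effectiveness, rho = config$settings$rho,
                           sigma_inflation = config$settings$sigma_inflation)
  dm <- config$settings$decrement_se_multiplier
  decs <- config$decrements
  if (dm != 1)
    decs <- lapply(decs, function(d) {
      der <- d$derivation
      beta_from_mean_se(der$mean, der$se * dm)
    })

  if (point_estimate) {
    n <- 1L
    draw1 <- function(spec) dist_point(spec)
    eff <- matrix(point_joint(jm), 1,
                  dimnames = list(NULL, paste0("pEff", config$arms$arm)))
  } else {
    draw1 <- function(spec) dist_sample(spec, n)
    eff <- sample_joint(jm, n)
  }

  out <- data.frame(
    pSafe = draw1(config$prob$pSafe),
    pAccept = draw1(config$prob$pAccept),
    pIngest = draw1(config$prob$pIngest),
    logOrIngest = draw1(config$prob$logOrIngest),
    pAmb = draw1(config$prob$pAmb),
    pAdmit = draw1(config$prob$pAdmit),
    pSevere = draw1(config$prob$pSevere),
    pFatal = draw1(config$prob$pFatal),
    cFixed = draw1(config$costs$cFixed),
    cAccept = draw1(config$costs$cAccept),
    cAmb = draw1(config$costs$cAmb),
    cED1 = draw1(config$costs$cED1),
    cED2 = draw1(config$costs$cED2),
    cAdmit1 = draw1(config$costs$cAdmit1),
    cAdmit2 = draw1(config$costs$cAdmit2),
    cChro = draw1(config$costs$cChro),
    cFatal = draw1(config$costs$cFatal),
    cGP = draw1(config$costs$cGP),
    uMinor = draw1(decs$uMinor),
    uModerate = draw1(decs$uModerate),
    uSevere = draw1(decs$uSevere),
    uChronic = draw1(decs$uChronic))
  out <- cbind(out, eff)
  class(out) <- c("parameter_draws", "data.frame")
  out
}

#' @rdname sample_parameters
#' @export
point_parameters <- function(config) sample_parameters(config, 1L,
                                                       point_estimate = TRUE)

#' Random but valid parameter draws for property-based testing
#'
#' Generates draws from wide uniform ranges that respect every type
#' invariant (probabilities in \[0, 1\], non-negative costs, decrements
#' below any plausible baseline utility). Intended for fuzzing structural
#' invariants such as occupancy conservation, not for inference.
#'
#' @param n Number of random parameter sets.
#' @return A "parameter_draws" data.frame of `n` rows.
#' @export
random_parameter_set <- function(n = 1) {
  runifv <- function(lo, hi) stats::runif(n, lo, hi)
  eff <- matrix(stats::runif(n * 7, 0.05, 0.99), n, 7,
                dimnames = list(NULL, paste0("pEff", 1:7)))
  out <- data.frame(
    pSafe = runifv(0.05, 0.95),
    pAccept = runifv(0, 1),
    pIngest = runifv(1e-5, 0.2),
    logOrIngest = runifv(-2, 2),
    pAmb = runifv(0, 1),
    pAdmit = runifv(0.05, 0.95),
    pSevere = runifv(0.001, 0.5),
    pFatal = runifv(0.001, 0.5),
    cFixed = runifv(0, 2e5),
    cAccept = runifv(0, 5),
    cAmb = runifv(50, 500),
    cED1 = runifv(50, 300),
    cED2 = runifv(50, 400),
    cAdmit1 = runifv(200, 2000),
    cAdmit2 = runifv(1000, 6000),
    cChro = runifv(50, 1000),
    cFatal = runifv(0, 1000),
    cGP = runifv(10, 100),
    uMinor = runifv(0.005, 0.08),
    uModerate = runifv(0.01, 0.1),
    uSevere = runifv(0.05, 0.3),
    uChronic = runifv(0.02, 0.3))
  out <- cbind(out, eff)
  class(out) <- c("parameter_draws", "data.frame")
  out
}
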