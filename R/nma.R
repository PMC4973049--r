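#' Summary of one arm's safe-storage effectiveness posterior
#'
#' The network meta-analysis behind the effectiveness evidence is consumed
#' as printed per-arm summaries: the posterior median probability of safe
#' storage under each strategy with its 95% credible interval. Printed
#' bounds of exactly 0 or 1 (rounded in the source) are clamped to
#' `clamp` / `1 - clamp` so a logit-scale fit exists.
#'
#' @param arm Integer arm id (1 = usual care).
#' @param median,lower,upper Posterior median and 95% credible bounds.
#' @param clamp Clamping margin for degenerate printed bounds
#'   (default 0.005).
#' @return An `arm_effect_summary` object.
#' @export
arm_effect_summary <- function(arm, median, lower, upper, clamp = 0.005) {
  lower <- max(lower, clamp)
  upper <- min(upper, 1 - clamp)
  if (!(lower > 0 && upper < 1 && lower <= median && median <= upper))
    stop("inconsistent summary: need 0 < lower <= median <= upper < 1",
         call. = FALSE)
  structure(list(arm = as.integer(arm), median = median,
                 lower = lower, upper = upper),
            class = "arm_effect_summary")
}

#' Logit-normal approximation to an arm's effectiveness posterior
#'
#' Matches the posterior median and 95% credible interval on the logit
#' scale: `mu = logit(median)`, `sigma = (logit(upper) - logit(lower)) /
#' (2 * 1.959964)`. The logit-normal family mirrors the geometry of a
#' network-meta-analysis posterior for an absolute probability (normal on
#' the linear-predictor scale). A Beta fit matched to the same quantiles is
#' available as an alternative via `family = "beta"`.
#'
#' @param summary An [arm_effect_summary()].
#' @param family `"logitnormal"` (default) or `"beta"` (quantile-matched by
#'   optimisation).
#' @return A `dist_spec` whose back-transformed median equals the input
#'   median (logit-normal) or approximates it (beta).
#' @examples
#' fit_logit_normal(arm_effect_summary(1, 0.87, 0.56, 0.98))
#' @export
fit_logit_normal <- function(summary, family = c("logitnormal", "beta")) {
  stopifnot(inherits(summary, "arm_effect_summary"))
  family <- match.arg(family)
  z975 <- stats::qnorm(0.975)
  mu <- stats::qlogis(summary$median)
  sigma <- (stats::qlogis(summary$upper) - stats::qlogis(summary$lower)) /
    (2 * z975)
  if (family == "logitnormal")
    return(dist_spec("logitnormal", mu = mu, sigma = sigma,
                     derivation = unclass(summary)))
  obj <- function(par) {
    q <- stats::qbeta(c(0.025, 0.5, 0.975), exp(par[1]), exp(par[2]))
    sum((q - c(summary$lower, summary$median, summary$upper))^2)
  }
  start <- log(pmax(c(summary$median, 1 - summary$median) *
                      (summary$median * (1 - summary$median) /
                         ((summary$upper - summary$lower) / 4)^2 - 1),
                    0.01))
  fit <- stats::optim(start, obj)
  dist_spec("beta", shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]),
            derivation = unclass(summary))
}

#' Joint sampling model for the seven arm effectiveness probabilities
#'
#' The original evidence synthesis produced a full joint posterior over
#' the arm effects; only the per-arm marginals are recoverable from its
#' printed summaries. The joint model therefore couples the per-arm
#' logit-normal fits through a shared latent factor: on the logit scale,
#' `z_k = mu_k + sigma_k * (sqrt(rho) * F + sqrt(1 - rho) * e_k)` with `F`
#' and `e_k` independent standard normals. Every arm's marginal is exactly
#' its fitted logit-normal for any `rho` in \[0, 1\]; `rho` only controls
#' the cross-arm correlation (rho = 1: perfectly rank-correlated arms).
#'
#' @param summaries List of [arm_effect_summary()] objects (one per arm).
#' @param rho Shared-baseline correlation in \[0, 1\].
#' @param sigma_inflation Multiplier applied to every `sigma`
#'   (\eqn{\ge 1}); used by the predictive-distribution scenario.
#' @return A `joint_effect_model` with elements `fits` (list of
#'   `dist_spec`), `rho`, `arms`.
#' @export
joint_effect_model <- function(summaries, rho = 0.9, sigma_inflation = 1) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  fits <- lapply(summaries, function(s) {
    f <- fit_logit_normal(s)
    f$params$sigma <- f$params$sigma * sigma_inflation
    f
  })
  structure(list(fits = fits, rho = rho,
                 arms = vapply(summaries, `[[`, 1L, "arm")),
            class = "joint_effect_model")
}

#' Sample correlated per-arm effectiveness probabilities
#'
#' @param model A [joint_effect_model()].
#' @param n Number of draws.
#' @return An `n` x (number of arms) matrix of probabilities, columns named
#'   `pEff1`, `pEff2`, ...
#' @export
sample_joint <- function(model, n) {
  stopifnot(inherits(model, "joint_effect_model"), n >= 1)
  k <- length(model$fits)
  f <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * k), n, k)
  z <- sqrt(model$rho) * f + sqrt(1 - model$rho) * e
  p <- vapply(seq_len(k), function(j) {
    par <- model$fits[[j]]$params
    stats::plogis(par$mu + par$sigma * z[, j])
  }, numeric(n))
  p <- matrix(p, n, k)
  colnames(p) <- paste0("pEff", model$arms)
  p
}

#' Point estimates (posterior medians) of the arm effectiveness vector
#' @param model A [joint_effect_model()].
#' @return Named numeric vector of medians.
#' @export
point_joint <- function(model) {
  p <- vapply(model$fits, function(f) stats::plogis(f$params$mu), 0)
  names(p) <- paste0("pEff", model$arms)
  p
}
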