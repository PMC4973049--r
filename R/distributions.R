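#' Declarative specification of one uncertain model parameter
#'
#' A `dist_spec` couples a distribution family with its parameters and,
#' where applicable, the raw derivation inputs (event counts, mean/SE) from
#' which the parameters were obtained. All probabilistic sensitivity
#' analysis draws go through [dist_sample()].
#'
#' Supported families:
#' \describe{
#'   \item{`beta`}{`shape1`, `shape2` (> 0); support (0, 1).}
#'   \item{`gamma`}{`shape`, `scale` (> 0); support (0, Inf).}
#'   \item{`normal`}{`mean`, `se` (>= 0).}
#'   \item{`fixed`}{`value`; degenerate, identical across draws.}
#'   \item{`logitnormal`}{`mu`, `sigma` on the logit scale; support (0, 1).}
#' }
#'
#' @param family Distribution family, one of `"beta"`, `"gamma"`,
#'   `"normal"`, `"fixed"`, `"logitnormal"`.
#' @param ... Named family-specific parameters (see Details).
#' @param derivation Optional list of raw inputs recording how the
#'   parameters were derived (kept for provenance; not used in sampling).
#' @param label Optional human-readable label.
#' @return An object of class `dist_spec`.
#' @seealso [beta_from_counts()], [gamma_from_mean_se()],
#'   [beta_from_mean_se()], [dist_sample()], [dist_mean()]
#' @export
dist_spec <- function(family = c("beta", "gamma", "normal", "fixed",
                                 "logitnormal"),
                      ..., derivation = NULL, label = NULL) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    beta = c("shape1", "shape2"),
    gamma = c("shape", "scale"),
    normal = c("mean", "se"),
    fixed = "value",
    logitnormal = c("mu", "sigma"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("dist_spec(", family, "): missing parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- params[need]
  switch(family,
    beta = if (params$shape1 <= 0 || params$shape2 <= 0)
      stop("beta requires both shape parameters > 0", call. = FALSE),
    gamma = if (params$shape <= 0 || params$scale <= 0)
      stop("gamma requires shape and scale > 0", call. = FALSE),
    normal = if (params$se < 0)
      stop("normal requires se >= 0", call. = FALSE),
    logitnormal = if (params$sigma < 0)
      stop("logitnormal requires sigma >= 0", call. = FALSE))
  structure(list(family = family, params = params,
                 derivation = derivation, label = label),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
             collapse = ", ")
  cat(sprintf("<dist_spec> %s(%s)", x$family, p))
  if (!is.null(x$label)) cat("  [", x$label, "]", sep = "")
  cat("  mean =", signif(dist_mean(x), 6), "\n")
  invisible(x)
}

#' Beta distribution from event counts
#'
#' Parameterises a Beta distribution directly from `successes` events out of
#' `total` trials as `Beta(successes, total - successes)`, so that the mean
#' equals the observed proportion `successes/total` exactly. The alternative
#' posterior-style parameterisation `Beta(successes + 1, total - successes
#' + 1)` (uniform prior) is available via `prior = "uniform"`.
#'
#' @param successes Number of events (0 < successes < total).
#' @param total Number of trials.
#' @param prior `"none"` (default; mean matches the raw proportion) or
#'   `"uniform"` (adds 1 to each shape).
#' @return A `dist_spec` of family `beta`.
#' @examples
#' beta_from_counts(1527, 2033)  # mean 0.751
#' @export
beta_from_counts <- function(successes, total, prior = c("none", "uniform")) {
  prior <- match.arg(prior)
  if (!is.finite(successes) || !is.finite(total) ||
      successes <= 0 || successes >= total)
    stop("degenerate counts: need 0 < successes < total", call. = FALSE)
  add <- if (prior == "uniform") 1 else 0
  dist_spec("beta", shape1 = successes + add,
            shape2 = total - successes + add,
            derivation = list(successes = successes, total = total,
                              prior = prior))
}

#' Gamma distribution from a mean and standard error
#'
#' Method-of-moments fit: `shape = (mean/se)^2`, `scale = se^2/mean`, so the
#' fitted distribution has exactly the requested mean and SD.
#'
#' @param mean,se Positive mean and standard error (e.g. a unit cost in GBP).
#' @return A `dist_spec` of family `gamma`.
#' @examples
#' gamma_from_mean_se(263, 21.48)
#' @export
gamma_from_mean_se <- function(mean, se) {
  if (!is.finite(mean) || !is.finite(se) || mean <= 0 || se <= 0)
    stop("invalid moments: mean and se must be > 0", call. = FALSE)
  dist_spec("gamma", shape = (mean / se)^2, scale = se^2 / mean,
            derivation = list(mean = mean, se = se))
}

#' Beta distribution from a mean and standard error
#'
#' Method-of-moments fit on (0, 1): `shape1 + shape2 = mean(1-mean)/se^2 - 1`.
#' Used for utility decrements where the source reports a mean with SE taken
#' as a fraction of the mean.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean(1-mean)`.
#' @return A `dist_spec` of family `beta`.
#' @export
beta_from_mean_se <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("invalid moments: mean must be in (0, 1)", call. = FALSE)
  if (!is.finite(se) || se <= 0 || se^2 >= mean * (1 - mean))
    stop("invalid moments: need 0 < se^2 < mean(1-mean)", call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  dist_spec("beta", shape1 = mean * nu, shape2 = (1 - mean) * nu,
            derivation = list(mean = mean, se = se))
}

#' Analytic mean of a distribution specification
#' @param spec A `dist_spec`.
#' @return The distribution mean.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    beta = p$shape1 / (p$shape1 + p$shape2),
    gamma = p$shape * p$scale,
    normal = p$mean,
    fixed = p$value,
    logitnormal = stats::integrate(
      function(z) stats::plogis(p$mu + p$sigma * z) * stats::dnorm(z),
      -10, 10)$value)
}

#' Point estimate used when the PSA is collapsed to a deterministic run
#'
#' Means for beta/gamma/normal/fixed; the median (back-transformed `mu`) for
#' logit-normal fits, matching how network-meta-analysis summaries are
#' printed (medians with credible intervals).
#' @param spec A `dist_spec`.
#' @return A single number.
#' @export
dist_point <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$family == "logitnormal") stats::plogis(spec$params$mu)
  else dist_mean(spec)
}

#' Sample from a distribution specification
#'
#' Draws are taken from the current R random number stream; seed management
#' is the caller's responsibility (see [run_psa()]). Values sampled from
#' families with (0, 1) support are checked, never clamped: a draw outside
#' the support raises an error.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  p <- spec$params
  x <- switch(spec$family,
    beta = stats::rbeta(n, p$shape1, p$shape2),
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    normal = stats::rnorm(n, p$mean, p$se),
    fixed = rep(p$value, n),
    logitnormal = stats::plogis(stats::rnorm(n, p$mu, p$sigma)))
  if (spec$family %in% c("beta", "logitnormal") &&
      any(x < 0 | x > 1))
    stop("sampled value outside [0, 1] support", call. = FALSE)
  x
}
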