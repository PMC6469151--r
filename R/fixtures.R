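#' Effect descriptions for synthetic scenarios
#'
#' * `no_effect()` — X is independent of Y given Z by construction (the
#'   global null).
#' * `threshold_effect(tau, delta)` — a step effect: the linear predictor is
#'   shifted by `delta` (log-odds / log-rate / mean units, per family) for
#'   subjects with X at or above its sample quantile `tau`.
#' * `transform_effect(spec, coef)` — a smooth effect acting through a named
#'   coding (e.g. a Box-Cox or FP transform): the realized columns of `spec`
#'   enter the linear predictor with coefficients `coef`.
#'
#' @param tau Quantile level of the threshold.
#' @param delta Linear-predictor shift above the threshold.
#' @param spec A [coding_spec] describing the transformation.
#' @param coef Coefficient(s) for the transform columns.
#' @name scenario_effects
NULL

#' @rdname scenario_effects
#' @export
no_effect <- function() structure(list(type = "none"), class = "scenario_effect")

#' @rdname scenario_effects
#' @export
threshold_effect <- function(tau, delta) {
  stopifnot(tau > 0, tau < 1)
  structure(list(type = "threshold", tau = tau, delta = delta),
            class = "scenario_effect")
}

#' @rdname scenario_effects
#' @export
transform_effect <- function(spec, coef) {
  stopifnot(inherits(spec, "coding_spec"))
  structure(list(type = "transform", spec = spec, coef = coef),
            class = "scenario_effect")
}

#' Describe a synthetic scenario
#'
#' Declarative description of a reproducible synthetic dataset: sample size,
#' model family, adjustment-covariate design, true adjustment coefficients,
#' the effect of the variable of interest (none, threshold, or smooth
#' transform), and the marginal distribution of X. The default X
#' distribution is lognormal so that Box-Cox and fractional-polynomial
#' codings apply without an origin shift; `x_dist = "normal"` exercises the
#' shift path.
#'
#' Either `intercept` is given directly, or `target_mean` requests that the
#' intercept be calibrated (on the realized covariates) so the average fitted
#' mean under the null part of the model equals the target — e.g. a
#' case-control-like prevalence.
#'
#' @param n Sample size.
#' @param family,link Model family and link (see [family_link()]).
#' @param z_dists Character vector of adjustment-covariate distributions,
#'   one covariate each: `"normal"` (standard normal) or `"binary"`
#'   (Bernoulli(0.5)). May be empty / `NULL` for an intercept-only null.
#' @param gamma_z True coefficients of the adjustment covariates (same
#'   length as `z_dists`).
#' @param intercept True intercept (ignored when `target_mean` is given).
#' @param target_mean Marginal mean of Y to calibrate the intercept to
#'   (prevalence for binomial, rate for poisson, mean for gaussian).
#' @param effect A [scenario_effects] object; default `no_effect()`.
#' @param x_dist `"lognormal"`, `"normal"` or `"uniform"`.
#' @param sigma Gaussian residual standard deviation.
#' @param seed Integer seed; same spec + same seed give an identical dataset.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n, family = "binomial", link = NULL,
                          z_dists = "normal", gamma_z = rep(0.3, length(z_dists)),
                          intercept = 0, target_mean = NULL,
                          effect = no_effect(), x_dist = c("lognormal", "normal", "uniform"),
                          sigma = 1, seed) {
  x_dist <- match.arg(x_dist)
  if (missing(seed)) stop("scenario_spec requires an explicit seed", call. = FALSE)
  if (length(gamma_z) != length(z_dists))
    stop("gamma_z must match z_dists in length", call. = FALSE)
  if (!all(z_dists %in% c("normal", "binary")))
    stop("z_dists entries must be 'normal' or 'binary'", call. = FALSE)
  stopifnot(inherits(effect, "scenario_effect"))
  structure(list(n = n, fl = family_link(family, link), z_dists = z_dists,
                 gamma_z = gamma_z, intercept = intercept,
                 target_mean = target_mean, effect = effect,
                 x_dist = x_dist, sigma = sigma, seed = seed),
            class = "scenario_spec")
}

#' Generate a synthetic dataset from a scenario
#'
#' Draws (Y, X, Z) per the scenario description. Under `no_effect()` the
#' outcome depends on Z only, so X carries no signal — the global null holds
#' by construction. The generated dataset is a plain `data.frame` with
#' columns `y`, `x`, and `z1`, `z2`, ... for the adjustment covariates; the
#' realized scenario (including the calibrated intercept, if any) is attached
#' as attribute `"scenario"`.
#'
#' @param spec A [scenario_spec()].
#' @return A `data.frame` with `n` rows.
#' @examples
#' dat <- generate_scenario(scenario_spec(n = 311, target_mean = 33 / 311,
#'                                        seed = 42))
#' mean(dat$y)
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n
  fl <- spec$fl

  q1 <- length(spec$z_dists)
  Zc <- if (q1 > 0) {
    cols <- lapply(spec$z_dists, function(d) {
      switch(d,
             normal = stats::rnorm(n),
             binary = stats::rbinom(n, 1L, 0.5))
    })
    do.call(cbind, cols)
  } else NULL

  x <- switch(spec$x_dist,
              lognormal = stats::rlnorm(n, meanlog = 0, sdlog = 0.6),
              normal = stats::rnorm(n),
              uniform = stats::runif(n))

  eta_z <- if (q1 > 0) as.numeric(Zc %*% spec$gamma_z) else rep(0, n)

  intercept <- spec$intercept
  if (!is.null(spec$target_mean)) {
    tm <- spec$target_mean
    intercept <- stats::uniroot(
      function(g0) mean(fl$linkinv(g0 + eta_z)) - tm,
      interval = c(-30, 30), tol = 1e-10)$root
  }

  eta <- intercept + eta_z
  ef <- spec$effect
  if (ef$type == "threshold") {
    eta <- eta + ef$delta * as.numeric(x >= empirical_quantile(x, ef$tau))
  } else if (ef$type == "transform") {
    cols <- realize_coding(ef$spec, x)$columns
    eta <- eta + as.numeric(cols %*% rep(ef$coef, length.out = ncol(cols)))
  }

  mu <- fl$linkinv(eta)
  phi <- if (fl$family == "gaussian") spec$sigma^2 else 1
  y <- fl$simulate(mu, phi)

  dat <- data.frame(y = y, x = x)
  if (q1 > 0) {
    colnames(Zc) <- paste0("z", seq_len(q1))
    dat <- cbind(dat, as.data.frame(Zc))
  }
  realized <- spec
  realized$intercept <- intercept
  attr(dat, "scenario") <- realized
  dat
}

#' PAQUID-like nested case-control scenario
#'
#' Convenience wrapper for a low-prevalence logistic scenario shaped after a
#' nested case-control study of 311 subjects (33 cases, 278 controls) with
#' a positive continuous exposure and a handful of adjustment covariates:
#' n = 311, binomial-logit, lognormal X, four adjustment covariates (two
#' continuous, two binary), intercept calibrated to prevalence 33/311.
#'
#' @param seed Integer seed.
#' @param effect A [scenario_effects] object; default null.
#' @return A [scenario_spec()].
#' @export
paquid_like_scenario <- function(seed, effect = no_effect()) {
  scenario_spec(n = 311, family = "binomial", link = "logit",
                z_dists = c("normal", "normal", "binary", "binary"),
                gamma_z = c(0.3, -0.2, 0.4, -0.3),
                target_mean = 33 / 311, effect = effect,
                x_dist = "lognormal", seed = seed)
}

#' Write a generated dataset to CSV
#'
#' Plain-text CSV with a header row naming the outcome, interest and
#' adjustment columns, suitable for the command-line front end.
#'
#' @param dat Data frame from [generate_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(dat, path) {
  utils::write.csv(dat, path, row.names = FALSE)
  invisible(path)
}
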