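#' Supported exponential-family / link combinations
#'
#' Constructs the family-link object used throughout the package. Only the
#' four generalized linear models the methodology covers are constructible:
#' gaussian-identity, binomial-logit, binomial-probit and poisson-log.
#' The object bundles the mean function \eqn{\mu(\eta)}, its derivative
#' \eqn{d\mu/d\eta}, the variance function \eqn{V(\mu)} and the dispersion
#' mode (fixed at 1 for binomial and poisson, estimated by maximum
#' likelihood for gaussian).
#'
#' @param family One of `"gaussian"`, `"binomial"`, `"poisson"`.
#' @param link One of `"identity"`, `"logit"`, `"probit"`, `"log"`. Defaults
#'   to the canonical link of `family` (probit must be requested explicitly).
#'
#' @return An object of class `family_link` with components `family`,
#'   `link`, `linkinv` (\eqn{\mu(\eta)}), `mu_eta` (\eqn{d\mu/d\eta}),
#'   `variance` (\eqn{V(\mu)}), `dispersion` (`"fixed"` or `"estimated"`),
#'   `simulate` (draws outcomes given means and dispersion) and
#'   `check_response` (validates outcome support).
#' @examples
#' fl <- family_link("binomial", "logit")
#' fl$linkinv(0)      # 0.5
#' fl$variance(0.25)  # 0.1875
#' @export
family_link <- function(family = c("gaussian", "binomial", "poisson"),
                        link = NULL) {
  family <- match.arg(family)
  if (is.null(link)) {
    link <- switch(family, gaussian = "identity", binomial = "logit",
                   poisson = "log")
  }
  allowed <- list(gaussian = "identity",
                  binomial = c("logit", "probit"),
                  poisson = "log")
  if (!link %in% allowed[[family]]) {
    stop(sprintf(
      "unsupported family/link combination '%s'-'%s'; supported models are %s",
      family, link,
      "gaussian-identity, binomial-logit, binomial-probit, poisson-log"),
      call. = FALSE)
  }

  linkinv <- switch(link,
    identity = function(eta) eta,
    logit    = function(eta) stats::plogis(eta),
    probit   = function(eta) stats::pnorm(eta),
    log      = function(eta) exp(eta))
  mu_eta <- switch(link,
    identity = function(eta) rep(1, length(eta)),
    logit    = function(eta) { p <- stats::plogis(eta); p * (1 - p) },
    probit   = function(eta) stats::dnorm(eta),
    log      = function(eta) exp(eta))
  variance <- switch(family,
    gaussian = function(mu) rep(1, length(mu)),
    binomial = function(mu) mu * (1 - mu),
    poisson  = function(mu) mu)
  simulate <- switch(family,
    gaussian = function(mu, phi) stats::rnorm(length(mu), mu, sqrt(phi)),
    binomial = function(mu, phi) stats::rbinom(length(mu), 1L, mu),
    poisson  = function(mu, phi) stats::rpois(length(mu), mu))
  check_response <- switch(family,
    gaussian = function(y) {
      if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
        stop("gaussian outcome must be finite numeric", call. = FALSE)
    },
    binomial = function(y) {
      if (anyNA(y) || !all(y %in% c(0, 1)))
        stop("binomial outcome must be coded 0/1", call. = FALSE)
    },
    poisson = function(y) {
      if (anyNA(y) || any(y < 0) || any(y != round(y)))
        stop("poisson outcome must be non-negative integers", call. = FALSE)
    })

  structure(
    list(family = family, link = link,
         linkinv = linkinv, mu_eta = mu_eta, variance = variance,
         dispersion = if (family == "gaussian") "estimated" else "fixed",
         simulate = simulate, check_response = check_response),
    class = "family_link")
}

#' @export
print.family_link <- function(x, ...) {
  cat(sprintf("<family_link> %s(link = %s), dispersion %s\n",
              x$family, x$link, x$dispersion))
  invisible(x)
}

# the matching stats::family object, for delegation to glm.fit
.stats_family <- function(fl) {
  switch(fl$family,
    gaussian = stats::gaussian(identity),
    binomial = stats::binomial(link = fl$link),
    poisson  = stats::poisson(log))
}
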