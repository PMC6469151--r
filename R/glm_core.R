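#' Fit the null generalized linear model (adjustment covariates only)
#'
#' Fits, by iteratively reweighted least squares, the GLM with canonical-scale
#' linear predictor \eqn{\eta_i = \gamma' Z_i} — the model under the global
#' null hypothesis that no coding of the variable of interest enters. All
#' score tests and all resampling procedures are anchored at this fit.
#'
#' The gaussian dispersion is the maximum-likelihood estimate RSS/\eqn{n}
#' (not RSS/\eqn{(n-q)}), so that the parametric bootstrap simulates from the
#' MLE of the null model; set `dispersion = "unbiased"` for the usual
#' REML-style divisor.
#'
#' @param y Outcome vector (0/1 for binomial, non-negative integers for
#'   poisson).
#' @param Z Adjustment design matrix including the intercept column
#'   (a vector is treated as a one-column matrix). Must be full column rank.
#' @param fl A [family_link()] object.
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @param dispersion `"mle"` (default, RSS/n) or `"unbiased"` (RSS/(n-q));
#'   gaussian only.
#'
#' @return An object of class `null_fit`: coefficients `gamma`, linear
#'   predictors `eta`, fitted means `mu`, working weights `w`
#'   (\eqn{(d\mu/d\eta)^2 / (V(\mu) a(\phi))}), score weights `d`
#'   (\eqn{(d\mu/d\eta) / (V(\mu) a(\phi))}), dispersion `phi`, `converged`,
#'   `iter`, `loglik`, and the data (`y`, `Z`) needed by the score tests.
#' @seealso [score_test()], [score_correlation()]
#' @export
fit_null <- function(y, Z, fl, tol = 1e-9, max_iter = 100L,
                     dispersion = c("mle", "unbiased")) {
  dispersion <- match.arg(dispersion)
  stopifnot(inherits(fl, "family_link"))
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)) - 1L)
  n <- length(y)
  q <- ncol(Z)
  if (nrow(Z) != n) stop("y and Z have different numbers of rows", call. = FALSE)
  if (n <= q) stop("need more observations than null-model coefficients", call. = FALSE)
  fl$check_response(y)

  qrZ <- qr(Z)
  if (qrZ$rank < q) {
    dropped <- colnames(Z)[qrZ$pivot[(qrZ$rank + 1L):q]]
    stop(sprintf("adjustment design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }

  fit <- stats::glm.fit(x = Z, y = y, family = .stats_family(fl),
                        control = stats::glm.control(epsilon = tol,
                                                     maxit = max_iter))
  if (!fit$converged) {
    stop(sprintf(
      "null-model IRLS did not converge in %d iterations (deviance %.6g)",
      fit$iter, fit$deviance), call. = FALSE)
  }

  gamma <- fit$coefficients
  eta <- as.numeric(Z %*% gamma)
  mu <- fl$linkinv(eta)
  dmu <- fl$mu_eta(eta)
  Vmu <- fl$variance(mu)

  if (fl$family == "gaussian") {
    rss <- sum((y - mu)^2)
    phi <- if (dispersion == "mle") rss / n else rss / (n - q)
  } else {
    phi <- 1
  }
  a_phi <- phi

  w <- dmu^2 / (Vmu * a_phi)
  d <- dmu / (Vmu * a_phi)
  loglik <- switch(fl$family,
    gaussian = sum(stats::dnorm(y, mu, sqrt(phi), log = TRUE)),
    binomial = sum(stats::dbinom(y, 1L, mu, log = TRUE)),
    poisson  = sum(stats::dpois(y, mu, log = TRUE)))

  structure(
    list(gamma = gamma, eta = eta, mu = mu, w = w, d = d,
         phi = phi, converged = fit$converged, iter = fit$iter,
         loglik = loglik, y = y, Z = Z, fl = fl,
         tol = tol, max_iter = max_iter, dispersion_mode = dispersion),
    class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("<null_fit> %s(%s), n = %d, q = %d, logLik = %.4f (%d IRLS iterations)\n",
              x$fl$family, x$fl$link, length(x$y), ncol(x$Z), x$loglik, x$iter))
  print(x$gamma)
  invisible(x)
}

# Efficient-score machinery shared by score_test, score_correlation and the
# resampling procedures. Given null-fit quantities (mu, w, d) and the coded
# columns C (n x p), returns the score vector U = C'd(y - mu), the projected
# columns Xt = C - Z (Z'WZ)^{-1} Z'W C, and their null covariance Xt' W Xt.
.score_parts <- function(y, Z, mu, w, d, C) {
  C <- as.matrix(C)
  WZ <- Z * w
  ZtWZ <- crossprod(Z, WZ)
  Xt <- C - Z %*% solve(ZtWZ, crossprod(WZ, C))
  U <- as.numeric(crossprod(C, d * (y - mu)))
  V <- crossprod(Xt, Xt * w)
  list(U = U, V = V, Xt = Xt)
}

# statistic + p-value from score parts for one coded block
.score_from_parts <- function(U, V, df, label) {
  if (df == 1L) {
    v <- as.numeric(V)
    if (v <= .Machine$double.eps^0.75 * max(1, abs(U)))
      stop(sprintf("degenerate coded column in coding '%s': score variance is zero",
                   label), call. = FALSE)
    stat <- U / sqrt(v)
    p <- 2 * stats::pnorm(-abs(stat))
  } else {
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * 1e-12)
      stop(sprintf("singular score covariance for coding '%s' (collinear or degenerate columns)",
                   label), call. = FALSE)
    stat <- as.numeric(crossprod(U, solve(V, U)))
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(stat = stat, p = p)
}

#' Rao score test for adding one coded block to the null model
#'
#' Tests \eqn{H_{0,k}: \beta_k = 0} for one coding \eqn{X(k)} of the variable
#' of interest, using the efficient score evaluated at the null fit with
#' expected information. The efficient score is
#' \deqn{U_k = X(k)' \mathrm{diag}\{(d\mu/d\eta)_i / (V(\hat\mu_i) a(\hat\phi))\} (y - \hat\mu)}
#' and its null covariance is \eqn{V_k = \tilde X_k' W \tilde X_k}, where
#' \eqn{\tilde X_k} projects the adjustment directions out of \eqn{X(k)}
#' under the working-weight inner product. One-column codings give the signed
#' statistic \eqn{T_k = U_k/\sqrt{V_k}} with a two-sided normal p-value;
#' multi-column codings give the quadratic form
#' \eqn{Q_k = U_k' V_k^{-1} U_k} against a chi-square with
#' \eqn{m_k - 1} degrees of freedom.
#'
#' @param nf A [fit_null()] object.
#' @param design A [coded_design] (see [realize_coding()]), or a plain
#'   numeric matrix/vector of coded columns.
#' @return An object of class `score_test_result`: `label`, `statistic`
#'   (signed normal scale for 1 df, chi-square scale otherwise), `df`,
#'   `p_value`.
#' @examples
#' set.seed(1)
#' x <- rlnorm(120)
#' y <- rbinom(120, 1, 0.3)
#' nf <- fit_null(y, cbind(1, rnorm(120)), family_link("binomial", "logit"))
#' score_test(nf, realize_coding(dichotomous_spec(0.5), x))
#' @export
score_test <- function(nf, design) {
  stopifnot(inherits(nf, "null_fit"))
  C <- if (inherits(design, "coded_design")) design$columns else as.matrix(design)
  label <- if (inherits(design, "coded_design")) design$label else "coding"
  if (nrow(C) != length(nf$y))
    stop("coded design and null fit have different numbers of rows", call. = FALSE)
  parts <- .score_parts(nf$y, nf$Z, nf$mu, nf$w, nf$d, C)
  res <- .score_from_parts(parts$U, parts$V, ncol(C), label)
  structure(list(label = label, statistic = res$stat, df = ncol(C),
                 p_value = res$p),
            class = "score_test_result")
}

#' @export
print.score_test_result <- function(x, ...) {
  scale <- if (x$df == 1L) "T" else "Q"
  cat(sprintf("score test [%s]: %s = %.4f, df = %d, p = %.4g\n",
              x$label, scale, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Joint null correlation of score statistics across 1-df codings
#'
#' Under the global null the vector of 1-df score statistics
#' \eqn{(T_1, \dots, T_K)} is asymptotically multivariate normal with unit
#' variances and correlation
#' \deqn{R_{kl} = \tilde X_k' W \tilde X_l / \sqrt{(\tilde X_k' W \tilde X_k)(\tilde X_l' W \tilde X_l)}.}
#' This matrix drives the exact maxT correction. Tiny negative eigenvalues
#' from finite-precision arithmetic are clipped at zero and the diagonal
#' renormalized.
#'
#' @param nf A [fit_null()] object.
#' @param designs List of 1-column coded designs (or matrices).
#' @return A K x K correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite).
#' @export
score_correlation <- function(nf, designs) {
  stopifnot(inherits(nf, "null_fit"))
  cols <- lapply(designs, function(dsg) {
    C <- if (inherits(dsg, "coded_design")) dsg$columns else as.matrix(dsg)
    if (ncol(C) != 1L)
      stop("the exact method requires 1-df codings; got a multi-column design",
           call. = FALSE)
    C
  })
  C <- do.call(cbind, cols)
  parts <- .score_parts(nf$y, nf$Z, nf$mu, nf$w, nf$d, C)
  v <- diag(parts$V)
  if (any(v <= 0))
    stop("degenerate coded column: zero score variance", call. = FALSE)
  R <- parts$V / sqrt(outer(v, v))
  R <- (R + t(R)) / 2
  ee <- eigen(R, symmetric = TRUE)
  if (min(ee$values) < 0) {
    if (min(ee$values) < -1e-6)
      warning("score correlation matrix strongly non-PSD; check for collinear codings")
    vals <- pmax(ee$values, 0)
    R <- ee$vectors %*% (vals * t(ee$vectors))
    s <- sqrt(diag(R))
    R <- R / outer(s, s)
    R <- (R + t(R)) / 2
  }
  diag(R) <- 1
  R
}
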