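#' Bonferroni adjustment of the minimum p-value
#'
#' Classical single-step correction: with K codings tried, the global null is
#' rejected at level alpha when the minimum p-value is below alpha/K,
#' i.e. the adjusted p-value is `min(1, K * p_min)`. Conservative when the
#' score statistics are correlated, which they always are for codings of one
#' variable.
#'
#' @param p_min Observed minimum p-value across codings.
#' @param K Number of codings tried.
#' @return The adjusted p-value.
#' @export
bonferroni_adjust <- function(p_min, K) {
  if (p_min < 0 || p_min > 1) stop("p_min must be in [0, 1]", call. = FALSE)
  if (K < 1 || K != round(K)) stop("K must be a positive integer", call. = FALSE)
  min(1, K * p_min)
}

#' Exact asymptotic maxT adjustment
#'
#' Computes the multiplicity-adjusted p-value of the maximum absolute score
#' statistic from the joint asymptotic null distribution of the K statistics,
#' which is multivariate normal with correlation matrix R (see
#' [score_correlation()]):
#' \deqn{p^{maxT} = 1 - P(-t_{max} < Z_k < t_{max},\ k = 1..K),\quad Z \sim N(0, R),}
#' with \eqn{t_{max} = \max_k |t_k|}. The rectangle probability is evaluated
#' by the Genz-Bretz quasi-Monte-Carlo algorithm (`mvtnorm::pmvnorm`).
#' Only 1-df codings are admissible: dichotomies, raw single cutpoints,
#' Box-Cox transforms and degree-1 fractional polynomials.
#'
#' Codings that are perfectly correlated with an earlier one (|r| = 1 up to
#' 1e-12) are collapsed to a single representative before integration; the
#' rectangle probability is unchanged and the integrand stays non-singular.
#'
#' @param t_obs Vector of observed 1-df score statistics.
#' @param R Their null correlation matrix.
#' @param abseps Absolute tolerance for the numerical integration.
#' @param maxpts Maximum integrand evaluations.
#' @return Adjusted p-value, with attributes `error` (integration error
#'   estimate) and `t_max`.
#' @export
exact_adjust <- function(t_obs, R, abseps = 1e-5, maxpts = 250000L) {
  K <- length(t_obs)
  R <- as.matrix(R)
  if (!all(dim(R) == K)) stop("R must be K x K", call. = FALSE)
  t_max <- max(abs(t_obs))

  # collapse |r| = 1 duplicates
  keep <- 1L
  if (K > 1L) {
    for (k in 2:K) {
      if (all(abs(R[k, keep]) < 1 - 1e-12)) keep <- c(keep, k)
    }
  }
  Rk <- R[keep, keep, drop = FALSE]

  if (length(keep) == 1L) {
    p <- 2 * stats::pnorm(-t_max)
    attr(p, "error") <- 0
    attr(p, "t_max") <- t_max
    return(p)
  }
  pr <- mvtnorm::pmvnorm(lower = rep(-t_max, length(keep)),
                         upper = rep(t_max, length(keep)),
                         corr = Rk,
                         algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                        maxpts = maxpts))
  p <- min(1, max(0, 1 - as.numeric(pr)))
  attr(p, "error") <- attr(pr, "error")
  attr(p, "t_max") <- t_max
  p
}

# minimum p-value over the coding blocks for one (possibly resampled) dataset;
# C is the column-stacked coded matrix, blocks a list of column-index vectors
.block_min_p <- function(y, Z, mu, w, d, C, blocks, labels) {
  parts <- .score_parts(y, Z, mu, w, d, C)
  ps <- vapply(seq_along(blocks), function(k) {
    j <- blocks[[k]]
    .score_from_parts(parts$U[j], parts$V[j, j, drop = FALSE],
                      length(j), labels[k])$p
  }, numeric(1))
  min(ps)
}

.minp_estimate <- function(p_star, p_min, B, add_one) {
  hits <- sum(p_star < p_min)
  p_hat <- if (add_one) (hits + 1) / (B + 1) else hits / B
  list(p_adjusted = p_hat, mc_se = sqrt(p_hat * (1 - p_hat) / B))
}

#' Permutation minP adjustment
#'
#' Estimates the adjusted significance of the minimum p-value by permuting
#' the variable of interest across subjects while the outcome and adjustment
#' covariates stay in place — valid under the exchangeability assumption that
#' X carries no information about (Y, Z) under the global null. Because the
#' null model excludes X, the null fit is unchanged by permutation and is
#' reused across replicates; the realized coded columns are row-permuted
#' (quantile thresholds are permutation-invariant, and raw cutpoints see the
#' same marginal sample, so re-deriving the codings replicate-by-replicate
#' would give identical columns).
#'
#' The estimate is \eqn{\hat p = B^{-1} \sum_b 1\{p^{*b}_{min} < p_{min}\}}
#' with the strict inequality as defined; `add_one = TRUE` switches to the
#' never-zero estimator \eqn{(\sum_b 1\{\cdot\} + 1)/(B + 1)}.
#'
#' @param nf A [fit_null()] object.
#' @param designs List of realized `coded_design` objects.
#' @param B Number of permutation replicates.
#' @param seed Integer seed (required; no silent clock seeding).
#' @param add_one Use the add-one estimator (default `FALSE`).
#' @return An object of class `minp_state`: `p_min`, per-coding `p_k`,
#'   `p_adjusted`, `mc_se`, `B`, `seed`, `p_star_min` (the B resampled
#'   minima), `n_redrawn` (degenerate replicates redrawn; always 0 for
#'   permutation), `method`.
#' @export
permutation_adjust <- function(nf, designs, B = 1000L, seed, add_one = FALSE) {
  stopifnot(inherits(nf, "null_fit"))
  .check_resample_args(B, seed)
  C <- do.call(cbind, lapply(designs, `[[`, "columns"))
  blocks <- .design_blocks(designs)
  labels <- vapply(designs, `[[`, "", "label")
  n <- length(nf$y)

  p_k <- vapply(seq_along(blocks), function(k) {
    score_test(nf, designs[[k]])$p_value
  }, numeric(1))
  p_min <- min(p_k)

  set.seed(seed)
  p_star <- numeric(B)
  n_redrawn <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n)
    res <- tryCatch(
      .block_min_p(nf$y, nf$Z, nf$mu, nf$w, nf$d,
                   C[idx, , drop = FALSE], blocks, labels),
      error = function(e) NULL)
    if (is.null(res)) { n_redrawn <- n_redrawn + 1L; next }
    p_star[b] <- res
    b <- b + 1L
  }
  est <- .minp_estimate(p_star, p_min, B, add_one)
  structure(list(method = "permutation", p_min = p_min, p_k = p_k,
                 p_adjusted = est$p_adjusted, mc_se = est$mc_se,
                 B = B, seed = seed, p_star_min = p_star,
                 n_redrawn = n_redrawn, add_one = add_one),
            class = "minp_state")
}

#' Parametric-bootstrap minP adjustment
#'
#' Estimates the adjusted significance of the minimum p-value by simulating
#' new outcomes from the null model fitted to the observed data: the null GLM
#' (adjustment covariates only) is fitted once to obtain the MLE of gamma,
#' and each replicate draws \eqn{Y^*_i} from the fitted family (Bernoulli
#' with mean \eqn{\hat\mu_i}, Poisson(\eqn{\hat\mu_i}), or Normal
#' (\eqn{\hat\mu_i}, \eqn{\hat\phi})), keeping X and Z fixed so the coded
#' columns are computed once. The null model is re-fitted on each simulated
#' outcome before the K score tests are re-run. Replicates whose null re-fit
#' fails to converge are redrawn; more than 1% of B such failures aborts.
#'
#' @inheritParams permutation_adjust
#' @return A `minp_state` object (see [permutation_adjust()]).
#' @export
bootstrap_adjust <- function(nf, designs, B = 1000L, seed, add_one = FALSE) {
  stopifnot(inherits(nf, "null_fit"))
  .check_resample_args(B, seed)
  C <- do.call(cbind, lapply(designs, `[[`, "columns"))
  blocks <- .design_blocks(designs)
  labels <- vapply(designs, `[[`, "", "label")
  fl <- nf$fl
  fam <- .stats_family(fl)
  Z <- nf$Z
  n <- length(nf$y)
  max_fail <- max(1, ceiling(0.01 * B))

  p_k <- vapply(seq_along(blocks), function(k) {
    score_test(nf, designs[[k]])$p_value
  }, numeric(1))
  p_min <- min(p_k)

  set.seed(seed)
  p_star <- numeric(B)
  n_redrawn <- 0L
  b <- 1L
  while (b <= B) {
    ystar <- fl$simulate(nf$mu, nf$phi)
    res <- tryCatch({
      refit <- suppressWarnings(
        stats::glm.fit(x = Z, y = ystar, family = fam,
                       control = stats::glm.control(epsilon = nf$tol,
                                                    maxit = nf$max_iter)))
      if (!refit$converged) stop("replicate null fit did not converge")
      eta <- as.numeric(Z %*% refit$coefficients)
      mu <- fl$linkinv(eta)
      dmu <- fl$mu_eta(eta)
      Vmu <- fl$variance(mu)
      a_phi <- if (fl$family == "gaussian") sum((ystar - mu)^2) / n else 1
      .block_min_p(ystar, Z, mu, dmu^2 / (Vmu * a_phi), dmu / (Vmu * a_phi),
                   C, blocks, labels)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_fail)
        stop(sprintf(
          "parametric bootstrap: more than 1%% of replicates failed (%d of %d attempted); check data quality",
          n_redrawn, B), call. = FALSE)
      next
    }
    p_star[b] <- res
    b <- b + 1L
  }
  est <- .minp_estimate(p_star, p_min, B, add_one)
  structure(list(method = "bootstrap", p_min = p_min, p_k = p_k,
                 p_adjusted = est$p_adjusted, mc_se = est$mc_se,
                 B = B, seed = seed, p_star_min = p_star,
                 n_redrawn = n_redrawn, add_one = add_one),
            class = "minp_state")
}

.design_blocks <- function(designs) {
  dfs <- vapply(designs, `[[`, 0L, "df")
  ends <- cumsum(dfs)
  starts <- ends - dfs + 1L
  lapply(seq_along(dfs), function(k) starts[k]:ends[k])
}

.check_resample_args <- function(B, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("an explicit integer seed is required for resampling (no clock seeding)",
         call. = FALSE)
  if (B < 1 || B != round(B)) stop("B must be a positive integer", call. = FALSE)
}

#' @export
print.minp_state <- function(x, ...) {
  cat(sprintf("%s minP adjustment: p_min = %.4g -> adjusted p = %.4g (MC-SE %.4g, B = %d, seed = %d)\n",
              x$method, x$p_min, x$p_adjusted, x$mc_se, x$B, x$seed))
  invisible(x)
}

#' Best coding under the union-intersection rule
#'
#' When the global null is rejected, the retained coding is the one with the
#' largest absolute test statistic — equivalently, the smallest individual
#' p-value (the two rules coincide for 1-df menus; the p-value rule extends
#' to mixed-df menus). Exact ties go to the first coding in menu order and
#' are flagged.
#'
#' @param results List of [score_test()] results.
#' @return List with `label`, `index`, `p_value`, `tied`.
#' @export
best_coding <- function(results) {
  if (length(results) == 0L) stop("no score-test results", call. = FALSE)
  ps <- vapply(results, `[[`, numeric(1), "p_value")
  i <- which.min(ps)
  list(label = results[[i]]$label, index = i, p_value = ps[i],
       tied = sum(ps == ps[i]) > 1L)
}

#' Multiplicity-adjusted testing of a coding menu
#'
#' The package's main entry point. Fits the null GLM (intercept +
#' adjustment covariates, no X), realizes every coding of the menu on the
#' variable of interest, computes the K score tests, and adjusts the minimum
#' p-value by the requested methods:
#'
#' * `"bonferroni"` — `min(1, K * p_min)`;
#' * `"exact"` — asymptotic maxT correction via the joint normal
#'   distribution of the score statistics; applicable only when every coding
#'   has one degree of freedom, otherwise reported "not applicable";
#' * `"permutation"` — minP by permutation of X ([permutation_adjust()]);
#' * `"bootstrap"` — minP by parametric bootstrap of Y
#'   ([bootstrap_adjust()]).
#'
#' When both resampling methods run, their seed streams are derived from
#' `seed` by fixed offsets, so a single seed reproduces the whole report.
#'
#' @param y Outcome vector.
#' @param x Continuous variable of interest.
#' @param z Optional adjustment covariates (vector or matrix, without
#'   intercept; an intercept is always included).
#' @param fl A [family_link()] object.
#' @param menu A [coding_menu()] or list of [coding_spec]s.
#' @param methods Subset of `c("bonferroni", "exact", "permutation",
#'   "bootstrap")`.
#' @param B Resampling replicates (ignored when no resampling method is
#'   requested).
#' @param seed Integer seed; required when a resampling method is requested.
#' @param add_one Use add-one resampling estimators.
#' @param exact_abseps Integration tolerance for the exact method.
#' @return An object of class `adjusted_report`; see [print.adjusted_report()]
#'   and [report_to_json()].
#' @examples
#' dat <- generate_scenario(scenario_spec(n = 200, seed = 7,
#'   effect = threshold_effect(0.5, 1.2)))
#' fl <- family_link("binomial", "logit")
#' adjust_codings(dat$y, dat$x, dat[, "z1"], fl,
#'   menu = coding_menu(nb_dicho = 3), methods = c("bonferroni", "exact"))
#' @export
adjust_codings <- function(y, x, z = NULL, fl, menu,
                           methods = c("bonferroni", "exact",
                                       "permutation", "bootstrap"),
                           B = 1000L, seed = NULL, add_one = FALSE,
                           exact_abseps = 1e-5) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(menu) == 0L) stop("empty coding menu", call. = FALSE)
  n <- length(y)
  if (length(x) != n) stop("y and x differ in length", call. = FALSE)
  Z <- if (is.null(z)) matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
       else {
         zm <- as.matrix(z)
         if (is.null(colnames(zm))) colnames(zm) <- paste0("z", seq_len(ncol(zm)))
         cbind("(intercept)" = 1, zm)
       }
  needs_resampling <- any(c("permutation", "bootstrap") %in% methods)
  if (needs_resampling && (is.null(seed) || is.na(seed)))
    stop("an explicit integer seed is required when resampling methods are requested",
         call. = FALSE)

  nf <- fit_null(y, Z, fl)
  designs <- realize_menu(menu, x)
  tests <- lapply(designs, function(dsg) score_test(nf, dsg))
  p_k <- vapply(tests, `[[`, numeric(1), "p_value")
  K <- length(tests)
  p_min <- min(p_k)
  best <- best_coding(tests)
  all_1df <- all(vapply(designs, `[[`, 0L, "df") == 1L)

  out <- list(tests = tests, designs = designs, best = best,
              K = K, n = n, p_min = p_min,
              family = fl$family, link = fl$link,
              methods = methods, seed = seed, null_fit = nf)

  if ("bonferroni" %in% methods)
    out$bonferroni <- bonferroni_adjust(p_min, K)

  if ("exact" %in% methods) {
    if (all_1df) {
      t_obs <- vapply(tests, `[[`, numeric(1), "statistic")
      R <- score_correlation(nf, designs)
      if (!is.null(seed)) set.seed(seed + 3000000L)
      p_ex <- exact_adjust(t_obs, R, abseps = exact_abseps)
      out$exact <- list(applicable = TRUE, p_adjusted = as.numeric(p_ex),
                        error = attr(p_ex, "error"), t_max = attr(p_ex, "t_max"))
      out$correlation <- R
    } else {
      out$exact <- list(applicable = FALSE, p_adjusted = NA_real_,
        reason = "exact correction requires 1-df codings only (no categorical codings with more than two classes)")
    }
  }

  if ("permutation" %in% methods)
    out$permutation <- permutation_adjust(nf, designs, B = B,
                                          seed = seed + 1000000L,
                                          add_one = add_one)
  if ("bootstrap" %in% methods)
    out$bootstrap <- bootstrap_adjust(nf, designs, B = B,
                                      seed = seed + 2000000L,
                                      add_one = add_one)
  out$B <- if (needs_resampling) B else NA_integer_
  structure(out, class = "adjusted_report")
}

#' Print an adjusted report
#'
#' One row per coding (label, statistic, df, p-value), one row per correction
#' method (adjusted p, uncertainty, applicability), then the best-coding
#' line.
#'
#' @param x An `adjusted_report`.
#' @param ... Unused.
#' @export
print.adjusted_report <- function(x, ...) {
  cat(sprintf("Multiplicity-adjusted coding analysis: %s(%s), n = %d, K = %d codings\n\n",
              x$family, x$link, x$n, x$K))
  tab <- data.frame(
    coding = vapply(x$tests, `[[`, "", "label"),
    statistic = round(vapply(x$tests, `[[`, numeric(1), "statistic"), 4),
    df = vapply(x$tests, `[[`, 0L, "df"),
    p_value = signif(vapply(x$tests, `[[`, numeric(1), "p_value"), 4))
  print(tab, row.names = FALSE)
  cat(sprintf("\nnaive minimum p-value: %.4g\n", x$p_min))
  if (!is.null(x$bonferroni))
    cat(sprintf("Bonferroni adjusted p: %.4g\n", x$bonferroni))
  if (!is.null(x$exact)) {
    if (x$exact$applicable)
      cat(sprintf("exact (maxT) adjusted p: %.4g (integration error %.2g)\n",
                  x$exact$p_adjusted, x$exact$error))
    else
      cat(sprintf("exact (maxT): not applicable — %s\n", x$exact$reason))
  }
  for (m in c("permutation", "bootstrap")) {
    if (!is.null(x[[m]]))
      cat(sprintf("%s adjusted p: %.4g (MC-SE %.3g, B = %d)\n",
                  m, x[[m]]$p_adjusted, x[[m]]$mc_se, x[[m]]$B))
  }
  cat(sprintf("\nbest coding: %s (p = %.4g)%s\n", x$best$label,
              x$best$p_value, if (x$best$tied) " [tied; first in menu order]" else ""))
  invisible(x)
}

#' @export
summary.adjusted_report <- function(object, ...) print(object, ...)
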