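test_that("null fit recovers closed-form intercepts", {
  # gaussian intercept-only: MLE is the sample mean
  nf <- fit_null(c(1, 2, 3), matrix(1, 3), fl_gauss)
  expect_equal(unname(nf$gamma), 2)
  expect_equal(nf$mu, rep(2, 3))
  expect_equal(nf$phi, mean((c(1, 2, 3) - 2)^2))  # MLE dispersion RSS/n

  # binomial-logit intercept-only with 25% ones: logit of the proportion
  y <- rep(c(1, 0, 0, 0), 10)
  nf <- fit_null(y, matrix(1, 40), fl_logit)
  expect_equal(unname(nf$gamma), log(0.25 / 0.75), tolerance = 1e-8)
})

test_that("null fit agrees with an independent GLM fitter and is near truth", {
  set.seed(101)
  n <- 500
  z <- rnorm(n)
  y <- rpois(n, exp(0.3 - 0.5 * z))
  nf <- fit_null(y, cbind(1, z), fl_pois)
  ref <- glm(y ~ z, family = poisson)
  expect_equal(unname(nf$gamma), unname(coef(ref)), tolerance = 1e-7)
  se <- sqrt(diag(vcov(ref)))
  expect_true(all(abs(nf$gamma - c(0.3, -0.5)) < 3 * se))
  expect_true(nf$converged)
  expect_gt(nf$iter, 0)
})

test_that("rank-deficient adjustment designs fail naming the collinear column", {
  Z <- cbind(intercept = 1, a = rnorm(20))
  Z <- cbind(Z, b = 2 * Z[, "a"])
  expect_error(fit_null(rnorm(20), Z, fl_gauss), "collinear.*b")
})

test_that("score test reproduces the Pearson chi-square of the 2x2 table", {
  # binomial-logit, intercept-only null, one binary coding
  y  <- c(rep(1, 8), rep(0, 12), rep(1, 14), rep(0, 6))
  xc <- c(rep(0, 20), rep(1, 20))
  nf <- fit_null(y, matrix(1, 40), fl_logit)
  st <- score_test(nf, matrix(xc))
  expect_equal(st$statistic^2, pearson_2x2(12, 8, 6, 14), tolerance = 1e-10)
  expect_equal(st$p_value, 2 * pnorm(-abs(st$statistic)))
})

test_that("coded column orthogonal to the residuals gives T = 0, p = 1", {
  # balanced 0/1 outcome, coded column with equal case share in both halves
  y  <- rep(c(0, 1), 20)
  xc <- rep(c(0, 0, 1, 1), 10)  # same number of ones among cases and controls
  nf <- fit_null(y, matrix(1, 40), fl_logit)
  st <- score_test(nf, matrix(xc))
  expect_equal(st$statistic, 0, tolerance = 1e-12)
  expect_equal(st$p_value, 1)
})

test_that("gaussian score statistic matches the OLS t statistic at large n", {
  set.seed(7)
  n <- 2000
  z <- rnorm(n); x <- rnorm(n)
  y <- rnorm(n, 1 + 0.2 * z)
  nf <- fit_null(y, cbind(1, z), fl_gauss)
  st <- score_test(nf, matrix(x))
  tt <- summary(lm(y ~ z + x))$coefficients["x", "t value"]
  expect_equal(st$statistic, tt, tolerance = 10 / n)
})

test_that("score test matches the base-R Rao score test across families", {
  set.seed(20)
  n <- 250
  z <- rnorm(n); x <- rlnorm(n)
  xc <- as.numeric(x >= median(x))
  cases <- list(
    list(fl = fl_logit,  y = rbinom(n, 1, plogis(-0.5 + 0.4 * z)), fam = binomial()),
    list(fl = family_link("binomial", "probit"),
         y = rbinom(n, 1, pnorm(-0.5 + 0.4 * z)), fam = binomial(probit)),
    list(fl = fl_pois,   y = rpois(n, exp(0.2 - 0.3 * z)), fam = poisson()))
  for (cs in cases) {
    nf <- fit_null(cs$y, cbind(1, z), cs$fl, tol = 1e-12)
    st <- score_test(nf, matrix(xc))
    y <- cs$y
    rao <- anova(glm(y ~ z + xc, family = cs$fam,
                     control = glm.control(epsilon = 1e-12)), test = "Rao")$Rao[3]
    expect_equal(st$statistic^2, rao, tolerance = 1e-6,
                 label = paste(cs$fl$family, cs$fl$link))
  }
})

test_that("1-df statistic is invariant to affine rescaling of the coded column", {
  set.seed(33)
  dat <- make_logit_data(150, seed = 33)
  nf <- fit_null(dat$y, cbind(1, dat$z1), fl_logit)
  xc <- as.numeric(dat$x >= median(dat$x))
  t0 <- score_test(nf, matrix(xc))$statistic
  expect_equal(score_test(nf, matrix(3.2 * xc + 7))$statistic, t0)
  expect_equal(score_test(nf, matrix(-1.5 * xc + 2))$statistic, -t0)
})

test_that("multi-df statistic is invariant to invertible reparameterization", {
  set.seed(44)
  dat <- make_logit_data(200, seed = 44)
  nf <- fit_null(dat$y, cbind(1, dat$z1), fl_logit)
  C <- realize_coding(categorical_spec(c(0.3, 0.7)), dat$x)$columns
  M <- matrix(c(2, 1, -1, 3), 2, 2)
  q0 <- score_test(nf, C)
  q1 <- score_test(nf, C %*% M)
  expect_equal(q1$statistic, q0$statistic, tolerance = 1e-10)
  expect_equal(q0$df, 2L)
  expect_equal(q0$p_value, pchisq(q0$statistic, 2, lower.tail = FALSE))
})

test_that("under a gaussian null the score statistic is standard normal", {
  set.seed(55)
  n <- 60
  z <- rnorm(n)
  x <- rnorm(n)
  xc <- as.numeric(x >= median(x))
  Ts <- replicate(2000, {
    y <- rnorm(n, 0.5 + 0.3 * z)
    nf <- fit_null(y, cbind(1, z), fl_gauss)
    score_test(nf, matrix(xc))$statistic
  })
  expect_gt(ks.test(Ts, pnorm)$p.value, 0.01)
})

test_that("degenerate coded columns are rejected with the coding named", {
  nf <- fit_null(rnorm(30), matrix(1, 30), fl_gauss)
  dsg <- structure(list(label = "flat", columns = matrix(1, 30), df = 1L),
                   class = "coded_design")
  expect_error(score_test(nf, dsg), "flat")
})

test_that("score correlation has the stated structure", {
  set.seed(66)
  dat <- make_logit_data(200, seed = 66)
  nf <- fit_null(dat$y, cbind(1, dat$z1), fl_logit)
  ds <- realize_menu(coding_menu(nb_dicho = 3), dat$x)
  R <- score_correlation(nf, ds)
  expect_equal(dim(R), c(3, 3))
  expect_equal(diag(R), rep(1, 3))
  expect_equal(R, t(R))
  expect_true(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  # duplicated coding: perfect correlation
  R2 <- score_correlation(nf, list(ds[[1]], ds[[1]]))
  expect_equal(R2[1, 2], 1)
  # W-orthogonalized column: zero correlation
  C1 <- ds[[1]]$columns
  p1 <- multicoding:::.score_parts(nf$y, nf$Z, nf$mu, nf$w, nf$d, C1)
  C2 <- ds[[2]]$columns
  p2 <- multicoding:::.score_parts(nf$y, nf$Z, nf$mu, nf$w, nf$d, C2)
  C2o <- C2 - C1 * as.numeric(crossprod(p1$Xt, nf$w * p2$Xt) / crossprod(p1$Xt, nf$w * p1$Xt))
  R3 <- score_correlation(nf, list(C1, C2o))
  expect_equal(R3[1, 2], 0, tolerance = 1e-10)
  # multi-column designs are refused
  cat2 <- realize_coding(categorical_spec(c(0.3, 0.7)), dat$x)
  expect_error(score_correlation(nf, list(ds[[1]], cat2)), "1-df")
})

test_that("score correlation matches the empirical correlation of bootstrap statistics", {
  set.seed(77)
  dat <- make_logit_data(300, seed = 77)
  Z <- cbind(1, dat$z1)
  nf <- fit_null(dat$y, Z, fl_logit)
  ds <- realize_menu(coding_menu(nb_dicho = 3), dat$x)
  R <- score_correlation(nf, ds)
  Ts <- replicate(5000, {
    ys <- rbinom(length(dat$y), 1, nf$mu)
    nfb <- fit_null(ys, Z, fl_logit)
    vapply(ds, function(d) score_test(nfb, d)$statistic, numeric(1))
  })
  expect_lt(max(abs(R - cor(t(Ts)))), 0.05)
})
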