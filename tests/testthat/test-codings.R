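test_that("empirical quantile is the type-7 linear interpolation", {
  expect_equal(empirical_quantile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(empirical_quantile(c(1, 2, 3, 4), 0.5), 2.5)
  # brute-force interpolation formula on 0..100
  x <- 0:100
  p <- 0.7
  h <- (length(x) - 1) * p + 1
  expect_equal(empirical_quantile(x, p),
               x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)]))
  expect_equal(empirical_quantile(x, 0.7), 70)
  expect_error(empirical_quantile(numeric(0), 0.5), "empty")
  expect_error(empirical_quantile(1:5, 1.2), "in \\(0, 1\\)")
})

test_that("dichotomous coding thresholds at the requested quantile, >= goes up", {
  d <- realize_coding(rawcut_spec(2.5), c(1, 2, 3, 4))
  expect_equal(as.numeric(d$columns), c(0, 0, 1, 1))

  x <- c(1, 2, 3, 4)
  d2 <- realize_coding(dichotomous_spec(0.5), x)
  expect_equal(d2$thresholds, 2.5)
  expect_equal(as.numeric(d2$columns), c(0, 0, 1, 1))
  # boundary value enters the upper class
  d3 <- realize_coding(rawcut_spec(3), x)
  expect_equal(as.numeric(d3$columns), c(0, 0, 1, 1))
  expect_equal(d3$df, 1L)

  expect_error(realize_coding(dichotomous_spec(0.5), rep(2, 10)), "degenerate|constant")
  expect_error(realize_coding(rawcut_spec(99), x), "degenerate")
})

test_that("quantile dichotomy levels follow the deciles convention", {
  x <- 1:100
  specs <- lapply(c(0.2, 0.5, 0.7), dichotomous_spec)
  thr <- vapply(specs, function(s) realize_coding(s, x)$thresholds, numeric(1))
  expect_equal(thr, quantile(x, c(0.2, 0.5, 0.7), names = FALSE))
})

test_that("categorical coding yields exclusive dummies with the documented class sizes", {
  x <- 1:10
  d <- realize_coding(categorical_spec(c(0.3, 0.7)), x)
  expect_equal(d$df, 2L)
  expect_true(all(d$columns %in% c(0, 1)))
  expect_true(all(rowSums(d$columns) <= 1))
  cls <- as.numeric(d$columns %*% 1:2)
  expect_equal(as.numeric(table(cls)), c(3, 4, 3))

  # empty classes are an error, with counts listed
  expect_error(realize_coding(rawcut_spec(c(0, 11)), x), "class counts")
})

test_that("categorical with a single raw cutoff equals the dichotomy there", {
  x <- rlnorm(50)
  thr <- unname(quantile(x, 0.4))
  a <- realize_coding(rawcut_spec(thr), x)
  b <- realize_coding(dichotomous_spec(0.4), x)
  expect_equal(unname(a$columns), unname(b$columns))
})

test_that("Box-Cox coding follows the power formula with log at zero", {
  expect_equal(as.numeric(realize_coding(boxcox_spec(0), c(1, exp(1)))$columns),
               c(0, 1))
  expect_equal(as.numeric(realize_coding(boxcox_spec(0.5), c(1, 4))$columns),
               c(0, 2))
  # negative exponents use the same standard Box-Cox formula
  x <- c(1, 2, 4)
  expect_equal(as.numeric(realize_coding(boxcox_spec(-1), x)$columns),
               (x^-1 - 1) / -1)
  expect_error(realize_coding(boxcox_spec(0.5), c(-1, 2)), "positive")
})

test_that("fractional polynomial recursion handles repeated powers and ln X", {
  x <- c(1, exp(1), 4)
  # powers (0): X^(0) = ln X
  expect_equal(as.numeric(realize_coding(fracpoly_spec(0), x)$columns), log(x))
  # powers (1): identity (no shift needed for positive X)
  expect_equal(as.numeric(realize_coding(fracpoly_spec(1), x)$columns), x)
  # repeated powers multiply in another ln X: (2, 2) -> x^2, x^2 ln x
  d <- realize_coding(fracpoly_spec(c(2, 2)), x)
  expect_equal(unname(d$columns), cbind(x^2, x^2 * log(x)))
  expect_equal(d$columns[2, ], c(exp(2), exp(2)), ignore_attr = TRUE)
  # degrees follow the power-vector length; unsorted input is sorted
  expect_equal(realize_coding(fracpoly_spec(-2), x)$df, 1L)
  expect_equal(realize_coding(fracpoly_spec(c(0.5, 1, -0.5, 2)), x)$df, 4L)
  expect_equal(realize_coding(fracpoly_spec(c(-0.5, 1)), x)$df, 2L)
  expect_equal(unname(realize_coding(fracpoly_spec(c(0.5, 1, -0.5, 2)), x)$columns),
               cbind(x^-0.5, x^0.5, x, x^2), ignore_attr = TRUE)
})

test_that("fractional polynomials shift non-positive X by the rounding-interval zeta", {
  x <- c(-2, 0, 1, 3.5)
  d <- realize_coding(fracpoly_spec(1), x)
  delta <- min(diff(sort(unique(x))))  # smallest positive gap = 1
  expect_equal(d$zeta, min(x) - delta)
  expect_equal(as.numeric(d$columns), x - d$zeta)
  expect_true(all(x - d$zeta > 0))
  # explicit zeta override
  d2 <- realize_coding(fracpoly_spec(1, zeta = -10), x)
  expect_equal(as.numeric(d2$columns), x + 10)
  expect_error(realize_coding(fracpoly_spec(1, zeta = 0.5), x), "positive")
})

test_that("automatic menus use the quantile sequences", {
  expect_equal(vapply(auto_dichotomies(3), `[[`, 0, "level"), c(0.25, 0.5, 0.75))
  expect_equal(vapply(auto_dichotomies(2), `[[`, 0, "level"), c(1, 2) / 3)
  expect_equal(vapply(auto_dichotomies(1), `[[`, 0, "level"), 0.5)

  m <- auto_categoricals(3)
  expect_equal(m[[1]]$levels, c(1, 2) / 3)        # terciles -> 3 classes
  expect_equal(m[[2]]$levels, c(1, 2, 3) / 4)     # quartiles -> 4 classes
  expect_equal(m[[3]]$levels, c(1, 2, 3, 4) / 5)  # quintiles -> 5 classes
  expect_length(auto_categoricals(1), 1)
})

test_that("menu assembly enforces argument exclusivity and label uniqueness", {
  expect_error(coding_menu(dicho = 0.5, nb_dicho = 2), "only one of")
  expect_error(coding_menu(categ = list(c(0.3, 0.7)), nb_categ = 2), "only one of")
  expect_error(coding_menu(), "empty")
  expect_error(coding_menu(boxcox = c(0, 0)), "duplicate")
  # NA-padded matrix rows give mixed class counts
  m <- coding_menu(categ = rbind(c(0.3, 0.7, NA), c(0.2, 0.5, 0.8)))
  expect_length(m[[1]]$levels, 2)  # 3-class coding
  expect_length(m[[2]]$levels, 3)  # 4-class coding
  # the motivating menu shape: K = 6
  full <- coding_menu(nb_dicho = 3, categ = list(c(0.3, 0.7)),
                      boxcox = 0, fp = list(c(-0.5, 1)))
  expect_length(full, 6)
})

test_that("quantile codings are permutation-invariant in their realized thresholds", {
  set.seed(9)
  x <- rlnorm(97)
  menu <- coding_menu(nb_dicho = 3, categ = list(c(0.3, 0.7)))
  d1 <- realize_menu(menu, x)
  d2 <- realize_menu(menu, sample(x))
  for (k in seq_along(d1))
    expect_equal(d1[[k]]$thresholds, d2[[k]]$thresholds)
})
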