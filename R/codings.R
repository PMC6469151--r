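#' Coding specifications
#'
#' A coding spec describes one transformation \eqn{g_k} of the continuous
#' variable of interest before any data are seen. Five kinds are supported:
#'
#' * `dichotomous_spec(level)` — binary indicator \eqn{1\{X \ge c\}} with the
#'   cutoff \eqn{c} taken as the sample quantile at `level`;
#' * `categorical_spec(levels)` — \eqn{m-1} ordered quantile cutoffs giving an
#'   \eqn{m}-class categorical variable coded as \eqn{m-1} dummy columns
#'   (reference class = lowest);
#' * `rawcut_spec(cutoffs)` — the same, but with cutoffs given on the raw
#'   scale of X (one cutoff gives a dichotomy);
#' * `boxcox_spec(lambda)` — Box-Cox power transform
#'   \eqn{\lambda^{-1}(X^\lambda - 1)} (\eqn{\log X} at \eqn{\lambda = 0});
#' * `fracpoly_spec(powers, zeta)` — fractional polynomial of degree
#'   \eqn{m} with sorted powers from the Royston-Altman set; `zeta` optionally
#'   overrides the automatic positivity shift.
#'
#' Every spec carries a stable human-readable `label` used in all reports;
#' labels must be unique within a menu.
#'
#' @param level,levels Quantile level(s), strictly inside (0, 1), strictly
#'   increasing.
#' @param cutoffs Strictly increasing raw-scale thresholds.
#' @param lambda Box-Cox exponent.
#' @param powers Numeric vector of fractional-polynomial powers (sorted
#'   non-decreasing internally; the repeated-power rule needs the sorted
#'   order).
#' @param zeta Optional origin shift for fractional polynomials; default
#'   (`NULL`) auto-selects `min(X) - delta` when X has non-positive values,
#'   where delta is the smallest positive gap between distinct sorted values.
#' @param label Optional label override.
#' @return An object of class `coding_spec`.
#' @name coding_spec
NULL

.new_spec <- function(kind, label, ...) {
  structure(list(kind = kind, label = label, ...), class = "coding_spec")
}

.check_levels <- function(lv, what) {
  if (length(lv) < 1L || anyNA(lv) || any(lv <= 0) || any(lv >= 1))
    stop(sprintf("%s must lie strictly inside (0, 1)", what), call. = FALSE)
  if (is.unsorted(lv, strictly = TRUE))
    stop(sprintf("%s must be strictly increasing", what), call. = FALSE)
}

#' @rdname coding_spec
#' @export
dichotomous_spec <- function(level, label = NULL) {
  .check_levels(level, "dichotomy quantile level")
  if (length(level) != 1L) stop("a dichotomy has exactly one cutoff level", call. = FALSE)
  .new_spec("dichotomous",
            label %||% sprintf("dichotomy(q=%g)", level),
            level = level)
}

#' @rdname coding_spec
#' @export
categorical_spec <- function(levels, label = NULL) {
  .check_levels(levels, "categorical quantile levels")
  if (length(levels) < 2L)
    stop("a categorical coding needs at least two cutoffs (use dichotomous_spec for one)",
         call. = FALSE)
  .new_spec("categorical",
            label %||% sprintf("categorical(q=%s)", paste(levels, collapse = ",")),
            levels = levels)
}

#' @rdname coding_spec
#' @export
rawcut_spec <- function(cutoffs, label = NULL) {
  if (length(cutoffs) < 1L || anyNA(cutoffs) ||
      is.unsorted(cutoffs, strictly = TRUE))
    stop("raw cutoffs must be non-missing and strictly increasing", call. = FALSE)
  .new_spec("rawcut",
            label %||% sprintf("rawcut(%s)", paste(cutoffs, collapse = ",")),
            cutoffs = cutoffs)
}

#' @rdname coding_spec
#' @export
boxcox_spec <- function(lambda, label = NULL) {
  if (length(lambda) != 1L || is.na(lambda))
    stop("lambda must be a single number", call. = FALSE)
  .new_spec("boxcox", label %||% sprintf("boxcox(lambda=%g)", lambda),
            lambda = lambda)
}

#' @rdname coding_spec
#' @export
fracpoly_spec <- function(powers, zeta = NULL, label = NULL) {
  if (length(powers) < 1L || anyNA(powers))
    stop("powers must be a non-missing numeric vector", call. = FALSE)
  powers <- sort(powers)  # the FP basis needs a_1 <= ... <= a_m
  pmax_ <- max(3, length(powers))
  pset <- c(-(pmax_:3), -2, -1, -0.5, 0, 0.5, 1, 2, if (pmax_ >= 3) 3:pmax_)
  if (!all(powers %in% pset))
    warning(sprintf("power(s) %s outside the conventional set {-max(3,m),...,-2,-1,-0.5,0,0.5,1,2,...,max(3,m)}",
                    paste(setdiff(powers, pset), collapse = ", ")))
  .new_spec("fracpoly",
            label %||% sprintf("FP(%s)", paste(powers, collapse = ",")),
            powers = powers, zeta = zeta)
}

#' @export
print.coding_spec <- function(x, ...) {
  cat(sprintf("<coding_spec> %s: %s\n", x$kind, x$label))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear-interpolation sample quantile
#'
#' The type-7 (linear interpolation) sample quantile used for every
#' quantile-based coding. Deterministic and permutation-invariant, which the
#' permutation procedure relies on.
#'
#' @param x Non-empty numeric sample.
#' @param p Quantile level in (0, 1).
#' @return The threshold value.
#' @export
empirical_quantile <- function(x, p) {
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  if (any(p <= 0) || any(p >= 1)) stop("quantile level must be in (0, 1)", call. = FALSE)
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# dummy-column block for ordered thresholds: class j (1..m-1) when
# X >= t_j (boundary goes to the UPPER class); class 0 (reference) otherwise
.dummy_block <- function(x, thresholds, label) {
  m1 <- length(thresholds)
  cls <- rowSums(outer(x, thresholds, `>=`))
  counts <- tabulate(cls + 1L, nbins = m1 + 1L)
  if (any(counts == 0L)) {
    stop(sprintf(
      "degenerate coding '%s': empty class(es) on this sample (class counts: %s)",
      label, paste(counts, collapse = "/")), call. = FALSE)
  }
  cols <- matrix(0, length(x), m1)
  for (j in seq_len(m1)) cols[, j] <- as.numeric(cls == j)
  cols
}

#' Realize a coding spec on a concrete sample
#'
#' Turns a [coding_spec] into a `coded_design`: the realized matrix of coded
#' columns for the variable of interest, with its degrees of freedom and any
#' realized thresholds. Degenerate codings (a constant column, an empty
#' categorical class, Box-Cox on non-positive values) are hard errors, never
#' silent drops: silently removing a coding would change K and every
#' correction.
#'
#' @param spec A [coding_spec].
#' @param x Numeric vector, the variable of interest.
#' @return An object of class `coded_design` with fields `label`, `columns`
#'   (n x df matrix), `df`, `thresholds` (realized raw thresholds for
#'   quantile/raw cut codings, `NULL` otherwise), `zeta` (fractional
#'   polynomials only).
#' @examples
#' realize_coding(dichotomous_spec(0.5), c(1, 2, 3, 4))
#' @export
realize_coding <- function(spec, x) {
  stopifnot(inherits(spec, "coding_spec"))
  if (anyNA(x)) stop("variable of interest contains missing values", call. = FALSE)
  out <- switch(spec$kind,
    dichotomous = {
      thr <- empirical_quantile(x, spec$level)
      cols <- .dummy_block(x, thr, spec$label)
      list(columns = cols, thresholds = thr)
    },
    categorical = {
      thr <- empirical_quantile(x, spec$levels)
      if (any(diff(thr) <= 0))
        stop(sprintf("degenerate coding '%s': tied quantile cutoffs (%s)",
                     spec$label, paste(signif(thr, 6), collapse = ", ")),
             call. = FALSE)
      list(columns = .dummy_block(x, thr, spec$label), thresholds = thr)
    },
    rawcut = {
      list(columns = .dummy_block(x, spec$cutoffs, spec$label),
           thresholds = spec$cutoffs)
    },
    boxcox = {
      if (any(x <= 0))
        stop(sprintf(
          "coding '%s': Box-Cox requires strictly positive values; shift the variable first",
          spec$label), call. = FALSE)
      lam <- spec$lambda
      col <- if (lam == 0) log(x) else (x^lam - 1) / lam
      list(columns = matrix(col, ncol = 1), thresholds = NULL)
    },
    fracpoly = {
      zeta <- spec$zeta
      if (is.null(zeta)) {
        zeta <- if (min(x) > 0) 0 else .default_zeta(x)
      }
      xs <- x - zeta
      if (any(xs <= 0))
        stop(sprintf("coding '%s': shifted values X - zeta must be strictly positive (zeta = %g)",
                     spec$label, zeta), call. = FALSE)
      list(columns = .fp_columns(xs, spec$powers), thresholds = NULL,
           zeta = zeta)
    },
    stop("unknown coding kind", call. = FALSE))

  cols <- as.matrix(out$columns)
  rng <- apply(cols, 2, function(cc) diff(range(cc)))
  if (any(rng <= 0))
    stop(sprintf("degenerate coding '%s': constant coded column", spec$label),
         call. = FALSE)
  structure(list(label = spec$label, columns = cols, df = ncol(cols),
                 thresholds = out$thresholds, zeta = out$zeta,
                 spec = spec),
            class = "coded_design")
}

# default positivity shift: min(x) minus the smallest positive gap between
# distinct sorted values (the "rounding interval" of the sample)
.default_zeta <- function(x) {
  ux <- sort(unique(x))
  if (length(ux) < 2L)
    stop("variable of interest is constant; no coding is possible", call. = FALSE)
  min(x) - min(diff(ux))
}

# fractional polynomial columns H_1..H_m with H_0 = 1, a_0 = 0,
# X^(0) = ln X, and repeated powers multiplying in another ln X
.fp_columns <- function(xs, powers) {
  m <- length(powers)
  lx <- log(xs)
  H <- matrix(0, length(xs), m)
  prev_a <- 0
  prev_H <- rep(1, length(xs))  # H_0
  for (j in seq_len(m)) {
    a <- powers[j]
    H[, j] <- if (a == prev_a) prev_H * lx
              else if (a == 0) lx
              else xs^a
    prev_H <- H[, j]
    prev_a <- a
  }
  H
}

#' @export
print.coded_design <- function(x, ...) {
  cat(sprintf("<coded_design> %s: %d column(s), df = %d", x$label,
              ncol(x$columns), x$df))
  if (!is.null(x$thresholds))
    cat(sprintf(", thresholds = %s", paste(signif(x$thresholds, 6), collapse = ", ")))
  if (!is.null(x$zeta) && x$zeta != 0) cat(sprintf(", zeta = %g", x$zeta))
  cat("\n")
  invisible(x)
}

#' Quantile-based automatic menus
#'
#' `auto_dichotomies(nb)` returns `nb` dichotomy specs at the quantile levels
#' `j/(nb+1)`, `j = 1..nb`: one transformation uses the median, two use the
#' terciles, three the quartiles, and so on.
#'
#' `auto_categoricals(nb)` returns `nb` categorical specs where transformation
#' `j` uses the full interior quantile set of order `j+2` as cutoffs — the
#' terciles (3 classes), then quartiles (4 classes), then quintiles (5
#' classes), ...
#'
#' @param nb Number of transformations (>= 1).
#' @return List of [coding_spec] objects.
#' @export
auto_dichotomies <- function(nb) {
  if (length(nb) != 1L || is.na(nb) || nb < 1 || nb != round(nb))
    stop("nb must be a positive integer", call. = FALSE)
  lapply(seq_len(nb), function(j) dichotomous_spec(j / (nb + 1)))
}

#' @rdname auto_dichotomies
#' @export
auto_categoricals <- function(nb) {
  if (length(nb) != 1L || is.na(nb) || nb < 1 || nb != round(nb))
    stop("nb must be a positive integer", call. = FALSE)
  lapply(seq_len(nb), function(j) {
    ord <- j + 2L
    categorical_spec(seq_len(ord - 1L) / ord,
                     label = sprintf("categorical(%d classes)", ord))
  })
}

#' Assemble a coding menu
#'
#' Builds the list of coding specs from the user-facing arguments. Exactly
#' one of `dicho`/`nb_dicho` may be given (or neither), and likewise for
#' `categ`/`nb_categ`. `categ` and `cutpoint` accept a matrix (one
#' transformation per row, right-padded with `NA`) or a list of vectors.
#' Labels must be unique across the whole menu.
#'
#' @param dicho Vector of quantile levels, one dichotomy per level.
#' @param nb_dicho Number of automatic quantile dichotomies.
#' @param categ Matrix or list of quantile-level cutoff sets (>= 2 cutoffs
#'   per row).
#' @param nb_categ Number of automatic categorical codings.
#' @param cutpoint Matrix or list of raw-scale threshold sets (1 threshold =
#'   a dichotomy).
#' @param boxcox Vector of Box-Cox exponents.
#' @param fp Matrix or list of fractional-polynomial power vectors.
#' @param zeta Optional fractional-polynomial shift override.
#' @return List of [coding_spec] objects (class `coding_menu`).
#' @export
coding_menu <- function(dicho = NULL, nb_dicho = NULL, categ = NULL,
                        nb_categ = NULL, cutpoint = NULL, boxcox = NULL,
                        fp = NULL, zeta = NULL) {
  if (!is.null(dicho) && !is.null(nb_dicho))
    stop("only one of 'dicho' and 'nb_dicho' can be used", call. = FALSE)
  if (!is.null(categ) && !is.null(nb_categ))
    stop("only one of 'categ' and 'nb_categ' can be used", call. = FALSE)

  rows_of <- function(m) {
    if (is.list(m)) return(lapply(m, function(r) r[!is.na(r)]))
    m <- as.matrix(m)
    lapply(seq_len(nrow(m)), function(i) {
      r <- m[i, ]
      r[!is.na(r)]
    })
  }

  menu <- list()
  if (!is.null(dicho)) menu <- c(menu, lapply(dicho, dichotomous_spec))
  if (!is.null(nb_dicho)) menu <- c(menu, auto_dichotomies(nb_dicho))
  if (!is.null(categ)) menu <- c(menu, lapply(rows_of(categ), categorical_spec))
  if (!is.null(nb_categ)) menu <- c(menu, auto_categoricals(nb_categ))
  if (!is.null(cutpoint)) menu <- c(menu, lapply(rows_of(cutpoint), rawcut_spec))
  if (!is.null(boxcox)) menu <- c(menu, lapply(boxcox, boxcox_spec))
  if (!is.null(fp))
    menu <- c(menu, lapply(rows_of(fp), function(p) fracpoly_spec(p, zeta = zeta)))

  if (length(menu) == 0L)
    stop("empty coding menu: supply at least one transformation", call. = FALSE)
  labels <- vapply(menu, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop(sprintf("duplicate coding labels in menu: %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  structure(menu, class = c("coding_menu", "list"))
}

#' @export
print.coding_menu <- function(x, ...) {
  cat(sprintf("<coding_menu> K = %d transformations:\n", length(x)))
  for (s in x) cat("  -", s$label, "\n")
  invisible(x)
}

#' Realize a whole menu on a sample
#'
#' @param menu A [coding_menu()] or list of specs.
#' @param x Variable of interest.
#' @return List of `coded_design` objects.
#' @export
realize_menu <- function(menu, x) {
  lapply(menu, realize_coding, x = x)
}
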