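#' Shapiro-Wilk normality screen
#'
#' Two-sided p-value of the W statistic; used to decide between parametric
#' and rank-based demographic comparisons.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return Tibble with `statistic` (W) and `p.value`.
#' @export
normality_screen <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk needs 3 to 5000 observations", call. = FALSE)
  }
  if (var(x) == 0) stop("sample is constant", call. = FALSE)
  s <- shapiro.test(x)
  tibble::tibble(statistic = unname(s$statistic), p.value = s$p.value)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent samples: exact enumeration when
#' both groups have <= 8 observations and no ties, tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @return Tibble with `u` (Mann-Whitney U of `x` over `y`, ties counted half
#'   to each) and `p.value`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  # U with ties counted half: W statistic of wilcox.test is exactly this
  tibble::tibble(u = unname(wt$statistic), p.value = wt$p.value)
}

#' Pearson chi-square test on an r x c contingency table
#'
#' No continuity correction; expected counts must all be positive.
#'
#' @param tab Matrix of counts.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd <= 0)) stop("all expected counts must be positive", call. = FALSE)
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values within an outcome family
#'
#' Step-up false-discovery-rate adjustment with the enforced monotonicity
#' pass: q_(i) = min over j >= i of p_(j) * m / j. Applied within a declared
#' family of outcomes (6 tissues, 4 lobes, or 3 global features).
#'
#' @param p Vector of p-values in [0, 1] (NA passed through).
#' @param family Optional family label stored alongside.
#' @return Tibble with `p`, `q`, and `family`.
#' @export
bh_fdr <- function(p, family = NA_character_) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, family = family)
}

#' Two-way random-effects, absolute-agreement, single-measure ICC
#'
#' ICC(A,1) from the standard two-way ANOVA mean squares: with items as rows
#' and raters as columns,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Used to summarise inter-rater reliability of repeated manual segmentations.
#'
#' @param ratings Numeric matrix, items x raters (>= 3 items, >= 2 raters).
#' @return Tibble with `icc`, `ms_rows`, `ms_cols`, `ms_error`.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3) stop("need at least 3 items", call. = FALSE)
  if (k < 2) stop("need at least 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  tibble::tibble(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse)
}

#' Growth-curve fit of a brain outcome against gestational age
#'
#' Exponential fits (`y = exp(a + b GA)`, least squares on the log scale) for
#' tissue volumes and linear fits for folding features, matching how the two
#' outcome families grow over the second half of gestation.
#'
#' @param ga Gestational ages, weeks.
#' @param y Outcome values (strictly positive for exponential).
#' @param form "exponential" or "linear".
#' @return Object of class `growth_fit`: list with `form`, `coef`
#'   (`c(a, b)`), and `fitted(ga)` function.
#' @export
growth_fit <- function(ga, y, form = c("exponential", "linear")) {
  form <- match.arg(form)
  ok <- !is.na(ga) & !is.na(y)
  ga <- ga[ok]; y <- y[ok]
  if (length(ga) < 2) stop("need at least 2 points", call. = FALSE)
  if (form == "exponential") {
    if (any(y <= 0)) {
      stop("exponential fit needs strictly positive outcomes", call. = FALSE)
    }
    cf <- coef(lm(log(y) ~ ga))
    fitted_fun <- function(g) exp(cf[[1]] + cf[[2]] * g)
  } else {
    cf <- coef(lm(y ~ ga))
    fitted_fun <- function(g) cf[[1]] + cf[[2]] * g
  }
  structure(list(form = form, coef = c(a = cf[[1]], b = cf[[2]]),
                 fitted = fitted_fun),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", x$form, ": a =", signif(x$coef[["a"]], 5),
      ", b =", signif(x$coef[["b"]], 5), "\n")
  invisible(x)
}
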