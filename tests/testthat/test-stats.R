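test_that("normality screen keeps its nominal size and catches skew", {
  set.seed(14)
  # type-I under the null (reduced replicate count; the acceptance suite
  # runs the full calibration)
  rej <- mean(replicate(400, normality_screen(rnorm(100))$p.value < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
  # power against lognormal data
  pow <- mean(replicate(100, normality_screen(exp(rnorm(100)))$p.value < 0.05))
  expect_gt(pow, 0.9)
  expect_error(normality_screen(rep(1, 10)), "constant")
  expect_error(normality_screen(c(1, 2)), "3 to 5000")
})

test_that("rank-sum test: exact enumeration, identities, null behavior", {
  # exact two-sided p over the C(6,3) = 20 orderings
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)
  expect_equal(res$u, 0)
  # U(x, y) + U(y, x) = nx * ny, ties counted half to each
  x <- c(1, 2, 2, 5, 7); y <- c(2, 3, 3, 8)
  expect_equal(mann_whitney(x, y)$u + mann_whitney(y, x)$u,
               length(x) * length(y))
  # identical samples: no evidence against the null
  z <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_gte(mann_whitney(z, z)$p.value, 0.99)
  expect_error(mann_whitney(numeric(0), z), "non-empty")
})

test_that("chi-square on contingency tables, no continuity correction", {
  r <- chi_square(matrix(c(10, 20, 20, 10), 2))
  expect_equal(r$statistic, 20 / 3)
  expect_equal(r$df, 1)
  # proportional rows: statistic 0, p 1
  r0 <- chi_square(matrix(c(10, 20, 30, 60), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  # invariance to row/column permutation
  tab <- matrix(c(5, 9, 2, 11, 4, 7), 2)
  expect_equal(chi_square(tab)$statistic,
               chi_square(tab[2:1, c(2, 3, 1)])$statistic)
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2)), "positive")
})

test_that("BH q-values match the brute-force step-up oracle", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  expect_equal(bh_fdr(p)$q, bh_oracle(p))
  # single p: q = p; all-equal p: all q equal that p
  expect_equal(bh_fdr(0.03)$q, 0.03)
  expect_equal(bh_fdr(rep(0.2, 5))$q, rep(0.2, 5))
  # q >= p elementwise and monotone in the sorted order
  set.seed(3)
  for (i in 1:20) {
    pv <- runif(sample(3:12, 1))
    q <- bh_fdr(pv)$q
    expect_true(all(q >= pv - 1e-12))
    expect_true(all(diff(q[order(pv)]) >= -1e-12))
    expect_equal(q, bh_oracle(pv))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("ICC(A,1) from mean squares: perfect, null, and hand-checked", {
  m <- matrix(rnorm(20), ncol = 2)
  m[, 2] <- m[, 1]
  expect_equal(icc_agreement(m)$icc, 1)
  # independent raters: ICC near 0
  set.seed(4)
  noise <- matrix(rnorm(2000), ncol = 2)
  expect_lt(abs(icc_agreement(noise)$icc), 0.1)
  # 6 x 2 toy matrix against the hand-computed ANOVA decomposition
  toy <- matrix(c(9, 2, 5, 8, 6, 7, 2, 1, 10, 9, 8, 3), ncol = 2)
  res <- icc_agreement(toy)
  n <- 6; k <- 2
  grand <- mean(toy)
  msr <- k * sum((rowMeans(toy) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(toy) - grand)^2) / (k - 1)
  mse <- (sum((toy - grand)^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  expect_equal(res$icc, (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)))
  # cross-checked against pingouin ICC(A,1) during development: 0.157895
  expect_equal(res$icc, 0.157895, tolerance = 1e-5)
  expect_error(icc_agreement(toy[1:2, ]), "3 items")
})

test_that("growth fits recover noiseless parameters exactly", {
  ga <- seq(18, 38, by = 0.5)
  fe <- growth_fit(ga, 2 * exp(0.1 * ga), form = "exponential")
  expect_equal(unname(fe$coef), c(log(2), 0.1), tolerance = 1e-8)
  fl <- growth_fit(ga, 5 - 0.3 * ga, form = "linear")
  expect_equal(unname(fl$coef), c(5, -0.3), tolerance = 1e-10)
  expect_equal(fe$fitted(30), 2 * exp(3), tolerance = 1e-8)
  expect_error(growth_fit(ga, c(-1, rep(1, length(ga) - 1)), "exponential"),
               "positive")
})
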