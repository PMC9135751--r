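test_that("GEE matches an independent reference implementation", {
  # oracle: Python statsmodels GEE on the same deterministic dataset
  # (gaussian/identity, robust covariance), values frozen below
  df <- gee_fixture()
  fit <- fit_gee(df, y ~ cohort + ga + sex, id = "subject_id")
  expect_equal(unname(fit$coefficients),
               c(3.77560182, -1.76367695, 0.84027981, 1.26880374),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               c(1.05488789, 0.67761251, 0.02609274, 0.52881131),
               tolerance = 1e-6)
  expect_equal(fit$alpha, 0.54022808, tolerance = 1e-6)

  ind <- fit_gee(df, y ~ cohort + ga + sex, id = "subject_id",
                 corstr = "independence")
  expect_equal(unname(ind$coefficients),
               c(3.49492878, -1.73728843, 0.85454586, 1.16334870),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(ind$vcov))),
               c(1.18711892, 0.63669454, 0.03198125, 0.54391071),
               tolerance = 1e-6)
})

test_that("GEE reduces to OLS when every cluster is a single scan", {
  df <- gee_fixture()
  df$subject_id <- seq_len(nrow(df))  # force singleton clusters
  fit <- fit_gee(df, y ~ cohort + ga + sex, id = "subject_id")
  ols <- coef(lm(y ~ cohort + ga + sex, data = df))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
  # independence option must not change singleton-cluster results
  ind <- fit_gee(df, y ~ cohort + ga + sex, id = "subject_id",
                 corstr = "independence")
  expect_equal(fit$coefficients, ind$coefficients, tolerance = 1e-10)
})

test_that("constant outcomes and degenerate designs are handled explicitly", {
  df <- gee_fixture()
  df$y <- 4.2
  fit <- fit_gee(df, y ~ cohort + ga, id = "subject_id")
  expect_equal(unname(fit$coefficients), c(4.2, 0, 0))
  df2 <- gee_fixture()
  df2$ga2 <- df2$ga * 2  # collinear
  expect_error(fit_gee(df2, y ~ ga + ga2, id = "subject_id"), "rank deficient")
  expect_error(fit_gee(df2[1:2, ], y ~ ga, id = "subject_id"), "clusters")
})

test_that("exchangeable correlation estimate respects its bounds", {
  set.seed(2)
  for (rep in 1:10) {
    df <- gee_fixture()
    df$y <- df$y + rnorm(nrow(df), 0, rep)
    fit <- fit_gee(df, y ~ cohort + ga, id = "subject_id")
    expect_gt(fit$alpha, -1 / (2 - 1))
    expect_lt(fit$alpha, 1)
  }
})

test_that("LS-means reproduce the cohort coefficient and raw means", {
  df <- gee_fixture()
  fit <- fit_gee(df, y ~ cohort + ga + sex, id = "subject_id")
  lsm <- ls_means(fit)
  expect_equal(lsm$lsmean[lsm$group == 1] - lsm$lsmean[lsm$group == 0],
               unname(fit$coefficients["cohort"]), tolerance = 1e-10)

  # balanced orthogonal design: LS-means equal raw group means
  bal <- data.frame(
    subject_id = 1:40,
    cohort = rep(c(0, 1), each = 20),
    x = rep(c(-1, 1), 20)  # orthogonal to cohort
  )
  set.seed(9)
  bal$y <- 3 + 2 * bal$cohort + 0.5 * bal$x + rnorm(40)
  fitb <- fit_gee(bal, y ~ cohort + x, id = "subject_id")
  lsb <- ls_means(fitb)
  expect_equal(lsb$lsmean, c(mean(bal$y[bal$cohort == 0]),
                             mean(bal$y[bal$cohort == 1])),
               tolerance = 1e-8)

  # one-covariate toy, hand-solved normal equations
  toy <- data.frame(subject_id = 1:5, cohort = c(0, 0, 0, 1, 1),
                    y = c(1, 2, 3, 6, 8))
  fit_toy <- fit_gee(toy, y ~ cohort, id = "subject_id")
  # OLS by hand: intercept = mean(y | cohort 0) = 2; beta = 7 - 2 = 5
  expect_equal(unname(fit_toy$coefficients), c(2, 5), tolerance = 1e-10)
  lst <- ls_means(fit_toy)
  expect_equal(lst$lsmean, c(2, 7), tolerance = 1e-10)
})

test_that("tidy and glance expose the battery-facing summaries", {
  fit <- fit_gee(gee_fixture(), y ~ cohort + ga, id = "subject_id")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 2 + 1)
  expect_true(all(td$p.value >= 0 & td$p.value <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 30)
  expect_true(gl$converged)
})
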