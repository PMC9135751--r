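test_that("model enumeration reproduces every printed battery count", {
  counts <- c(step1 = 12, step2 = 90, step3 = 36, distress = 72,
              interaction = 12, sensitivity = 180, laterality = 36,
              parental = 72)
  for (b in names(counts)) {
    expect_equal(nrow(enumerate_models(b)), unname(counts[[b]]), label = b)
  }
  # step 2 decomposes into 18 base + 72 distress-adjusted models
  s2 <- enumerate_models("step2")
  expect_equal(sum(!grepl("ssai|stai|pss|epds", s2$rhs)), 18)
  expect_equal(sum(grepl("ssai|stai|pss|epds", s2$rhs)), 72)
  # step 3 decomposes into 24 volume + 12 global-feature models
  s3 <- enumerate_models("step3")
  expect_equal(sum(grepl("^vol_", s3$outcome)), 24)
  expect_equal(sum(grepl("global", s3$outcome)), 12)
  expect_error(enumerate_models("step9"), "unknown step")
})

test_that("enumeration is deterministic, order-stable, and carries FDR families", {
  a <- enumerate_models("step2")
  b <- enumerate_models("step2")
  expect_identical(a, b)
  # volume models share a 6-strong family; lobar features 4-strong families
  fam <- table(a$fdr_family)
  expect_true(all(fam[grepl("volumes", names(fam))] == 6))
  expect_true(all(fam[grepl("area|lgi|depth", names(fam))] == 4))
  # outcomes never appear among their own covariates
  expect_true(all(!mapply(grepl, a$outcome, a$rhs)))
})

test_that("a battery runs end to end with q-values within families", {
  sc <- simulate_cohort(cohort_spec(
    n_subjects = c(pre = 60, pandemic = 40),
    effects = list(volumes = c(wm = -10, hippocampus = -0.2)),
    seed = 21
  ))
  res <- run_battery(sc, enumerate_models("step2"))
  expect_equal(nrow(res), 90)
  expect_true(all(!is.na(res$p)))
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))
  # q-values within each family match the brute-force oracle
  for (fam in unique(res$fdr_family)) {
    sel <- res$fdr_family == fam
    expect_equal(res$q[sel], bh_oracle(res$p[sel]), tolerance = 1e-12)
  }
  # the planted WM deficit is detected
  wm <- res[res$outcome == "vol_wm" & res$rhs == "cohort + ga_mri_weeks + sex", ]
  expect_lt(wm$estimate, 0)
  expect_lt(wm$p, 0.05)
})

test_that("interaction and laterality batteries target the right terms", {
  sc <- simulate_cohort(cohort_spec(n_subjects = c(pre = 50, pandemic = 50),
                                    seed = 33))
  ix <- run_battery(sc, enumerate_models("interaction"))
  expect_true(all(ix$term == "cohort:ga_mri_weeks"))
  expect_true(all(!is.na(ix$estimate)))
  lat <- enumerate_models("laterality")
  expect_true(all(grepl("_left$|_right$", lat$outcome)))
  res_lat <- run_battery(sc, lat[lat$outcome %in% c("vol_wm_left", "vol_wm_right"), ])
  expect_true(all(!is.na(res_lat$p)))
})

test_that("subset filters drop the excluded scans", {
  sc <- simulate_cohort(cohort_spec(n_subjects = c(pre = 80, pandemic = 80),
                                    seed = 44))
  sens <- enumerate_models("sensitivity")
  ga_row <- sens[sens$subset == "ga_mri_weeks >= 28" & sens$outcome == "vol_wm" &
                   sens$rhs == "cohort + ga_mri_weeks + sex", ][1, ]
  res <- run_battery(sc, ga_row)
  expect_equal(res$n_obs, sum(sc$ga_mri_weeks >= 28))
})

test_that("stratified LS-means produce the Table-3/4 layout", {
  sc <- simulate_cohort(cohort_spec(n_subjects = c(pre = 80, pandemic = 80),
                                    seed = 55))
  lsm <- stratified_ls_means(sc)
  expect_equal(nrow(lsm), 2 * 2 * 9)  # {pss, epds} x {low, high} x 9 outcomes
  ok <- !is.na(lsm$lsmean_pre)
  expect_true(any(ok))
  expect_true(all(lsm$se_pre[ok] > 0))
})
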