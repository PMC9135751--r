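test_that("cohort simulation honors its structural contracts", {
  sc <- simulate_cohort(cohort_spec(seed = 5))
  # repeat scans share a subject id with strictly increasing GA
  reps <- split(sc$ga_mri_weeks, sc$subject_id)
  expect_true(all(vapply(reps, function(g) length(g) == 1 || diff(g) > 0,
                         logical(1))))
  expect_true(all(lengths(reps) <= 2))
  # GA inside the study scan window
  expect_true(all(sc$ga_mri_weeks >= 16.7 & sc$ga_mri_weeks <= 39.1))
  # distress scores inside scale bounds wherever present
  b <- distress_bounds()
  for (nm in names(b)) {
    v <- sc[[nm]][!is.na(sc[[nm]])]
    expect_true(all(v >= b[[nm]][1] & v <= b[[nm]][2]), label = nm)
  }
  # ground-truth phantom parameters recorded on every scan row
  expect_true(all(c("true_wm_radius", "true_fold_amplitude",
                    "true_cgm_thickness") %in% names(sc)))
  expect_true(all(sc$true_fold_amplitude >= 0))
})

test_that("fixed seed reproduces the cohort bit for bit", {
  a <- simulate_cohort(cohort_spec(seed = 99))
  b <- simulate_cohort(cohort_spec(seed = 99))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(cohort_spec(seed = 100))
  expect_false(identical(a$ga_mri_weeks, c$ga_mri_weeks))
})

test_that("zero repeat fraction gives one scan per subject", {
  sc <- simulate_cohort(cohort_spec(n_subjects = c(pre = 40, pandemic = 20),
                                    repeat_scan_fraction = 0, seed = 2))
  expect_equal(nrow(sc), 60)
  expect_equal(length(unique(sc$subject_id)), 60)
})

test_that("null cohorts carry no systematic between-epoch differences", {
  # replicate null cohorts; the mean cohort difference of each outcome must
  # sit within 3 Monte-Carlo standard errors of zero
  set.seed(31)
  outc <- c("vol_wm", "vol_cgm", "vol_hippocampus", "area_frontal",
            "lgi_parietal", "depth_occipital", "pss", "epds")
  reps <- 60
  diffs <- t(replicate(reps, {
    d <- simulate_cohort(cohort_spec(
      n_subjects = c(pre = 60, pandemic = 60),
      cortical_missing_fraction = 0, missing_distress_fraction = 0,
      distress = list(ssai = list(mean = c(33, 33), sd = 10),
                      stai = list(mean = c(33, 33), sd = 10),
                      pss = list(mean = c(12, 12), sd = 6),
                      epds = list(mean = c(5, 5), sd = 4.5)),
      seed = sample.int(2^30, 1)
    ))
    vapply(outc, function(oc) {
      mean(d[[oc]][d$cohort == 1]) - mean(d[[oc]][d$cohort == 0])
    }, numeric(1))
  }))
  z <- abs(colMeans(diffs)) / (apply(diffs, 2, sd) / sqrt(reps))
  expect_true(all(z < 3), info = paste(names(z), round(z, 2), collapse = "; "))
})

test_that("impossible truncation is rejected", {
  expect_error(
    cohort_spec(distress = list(pss = list(mean = c(400, 400), sd = 0.1))),
    "impossible truncation"
  )
  expect_error(rtruncnorm(5, 0, 1, 2, 1), "exceed")
})

test_that("configured volume effects shift the generated outcomes", {
  eff <- simulate_cohort(cohort_spec(
    n_subjects = c(pre = 300, pandemic = 300),
    effects = list(volumes = c(wm = -8)), seed = 8
  ))
  # regress out GA to isolate the cohort shift
  res <- stats::residuals(lm(vol_wm ~ ga_mri_weeks, data = eff))
  shift <- mean(res[eff$cohort == 1]) - mean(res[eff$cohort == 0])
  expect_equal(shift, -8, tolerance = 0.35)
})

test_that("phantom specs built from scan rows are valid and render", {
  sc <- simulate_cohort(cohort_spec(seed = 12))
  spec <- phantom_spec_for_scan(sc[3, ], spacing = c(2.5, 2.5, 2.5))
  expect_s3_class(spec, "phantom_spec")
  expect_equal(spec$wm_radius, sc$true_wm_radius[3])
})
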