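test_that("phantom digitization matches analytic volumes at zero amplitude", {
  spec <- phantom_spec(wm_radius = 25, fold_amplitude = 0, cgm_thickness = 3,
                       spacing = c(1, 1, 1))
  ph <- make_phantom(spec)
  tv <- tissue_volumes(ph$segmentation)
  an <- phantom_analytic_volumes(spec)
  # digitization error scales with surface/volume: large structures tight,
  # small ellipsoids (a few hundred voxels) looser
  tol <- c(wm = 0.01, cgm = 0.01, dgm = 0.03, cerebellum = 0.03,
           brainstem = 0.08, hippocampus = 0.08, ventricles = 0.08)
  for (ti in names(tol)) {
    got <- unname(tv$volume_cm3[tv$tissue == ti] * 1000)
    want <- unname(an$volume_mm3[an$tissue == ti])
    expect_equal(got, want, tolerance = tol[[ti]],
                 label = paste("digitized", ti),
                 expected.label = paste("analytic", ti))
  }
})

test_that("phantom generation is deterministic and validates its invariants", {
  spec <- small_phantom_spec(0.1, r = 15)
  a <- make_phantom(spec, seed = 1)
  b <- make_phantom(spec, seed = 1)
  expect_identical(a$segmentation$data, b$segmentation$data)
  expect_identical(a$parcellation$data, b$parcellation$data)

  expect_error(phantom_spec(wm_radius = -1), "positive")
  expect_error(phantom_spec(fold_amplitude = -0.1), "amplitude")
  # explicit grid too small for the folded cortex
  expect_error(
    phantom_spec(wm_radius = 30, fold_amplitude = 0.2, cgm_thickness = 3,
                 spacing = c(1, 1, 1), grid_shape = c(40, 40, 40)),
    "fit"
  )
})

test_that("thicker cortical shell strictly increases the CGM voxel count", {
  thin <- make_phantom(phantom_spec(wm_radius = 15, cgm_thickness = 2,
                                    spacing = c(1.25, 1.25, 1.25)))
  thick <- make_phantom(phantom_spec(wm_radius = 15, cgm_thickness = 4,
                                     spacing = c(1.25, 1.25, 1.25)))
  n_thin <- sum(thin$segmentation$data == segmentation_labels()[["cgm"]])
  n_thick <- sum(thick$segmentation$data == segmentation_labels()[["cgm"]])
  expect_gt(n_thick, n_thin)
  # and the digitized shell volumes straddle the analytic values
  expect_equal(n_thin * voxel_volume(c(1.25, 1.25, 1.25)),
               4 / 3 * pi * (17^3 - 15^3), tolerance = 0.05)
})

test_that("digitized primitive volume converges to the closed form", {
  # offset ellipsoid (no accidental symmetry cancellation)
  inside <- function(X, Y, Z) {
    ((X - 0.37) / 15.3)^2 + ((Y + 0.21) / 11.7)^2 + ((Z - 0.13) / 9.4)^2 <= 1
  }
  true_vol <- 4 / 3 * pi * 15.3 * 11.7 * 9.4
  err <- vapply(c(2, 1, 0.5), function(sp) {
    seg <- digitize_solid(inside, 22, sp)
    abs(sum(seg$data == 1L) * voxel_volume(rep(sp, 3)) / true_vol - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[2], 0.02)
})

test_that("parcellation sectors partition the cerebrum with both hemispheres", {
  ph <- make_phantom(small_phantom_spec(0, r = 15))
  parc <- ph$parcellation$data
  seg <- ph$segmentation$data
  labs <- segmentation_labels()
  cerebrum <- seg %in% labs[c("cgm", "wm", "hippocampus", "dgm", "ventricles")]
  expect_true(all(parc[cerebrum] > 0))
  expect_true(all(parc[!cerebrum] == 0 |
                    parc[!cerebrum] %in% c(0L)))  # cerebellum/brainstem unlabeled
  regs <- sort(unique(as.integer(parc[parc > 0])))
  expect_true(all(regs %in% c(1:10, 11:20)))
  expect_true(any(regs <= 10) && any(regs > 10))
})
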