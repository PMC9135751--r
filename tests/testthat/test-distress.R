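test_that("scale bounds admit their endpoints and reject outsiders", {
  expect_silent(validate_scores(list(ssai = 80)))   # upper bound accepted
  expect_silent(validate_scores(list(pss = 0)))     # lower bound accepted
  expect_error(validate_scores(list(ssai = 81)), "SSAI")
  expect_error(validate_scores(list(epds = -1)), "EPDS")
  expect_error(validate_scores(list(stai = 19)), "STAI")
  # missing values pass through
  out <- validate_scores(tibble::tibble(pss = c(10, NA), epds = c(NA, 5)))
  expect_equal(nrow(out), 2)
})

test_that("classification uses strict greater-than thresholds", {
  expect_equal(classify_distress("pss", 15), "low")
  expect_equal(classify_distress("pss", 16), "high")
  expect_equal(classify_distress("epds", 10), "low")
  expect_equal(classify_distress("ssai", 41), "high")
  expect_equal(classify_distress("ssai", 40), "low")
  expect_true(is.na(classify_distress("stai", NA)))
  expect_error(classify_distress("bogus", 5), "unknown")
  # threshold overrides change behavior predictably
  expect_equal(classify_distress("pss", 16, thresholds = c(pss = 20)), "low")
})

test_that("raising a score never flips high back to low", {
  thr <- distress_thresholds()
  for (m in names(thr)) {
    b <- distress_bounds()[[m]]
    vals <- seq(b[1], b[2])
    cls <- classify_distress(m, vals)
    expect_true(all(diff(cls == "high") >= 0), label = m)
  }
})

test_that("any_elevated needs at least one strict exceedance", {
  thr <- distress_thresholds()
  at_thresholds <- tibble::as_tibble(as.list(thr))
  expect_false(any_elevated(at_thresholds))           # all exactly at cutoffs
  only_epds <- tibble::tibble(ssai = 30, stai = 30, pss = 10, epds = 11)
  expect_true(any_elevated(only_epds))
  minima <- tibble::tibble(ssai = 20, stai = 20, pss = 0, epds = 0)
  expect_false(any_elevated(minima))
  # missing measures count as non-elevated (with a message)
  expect_message(
    res <- any_elevated(tibble::tibble(ssai = NA, stai = NA, pss = 10,
                                       epds = NA)),
    "missing"
  )
  expect_false(res)
})
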