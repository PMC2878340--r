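test_that("an exact power law calibrates with slope 1 and inverts", {
  mfi <- c(100, 500, 2500, 12500, 62500)
  abc <- 20 * mfi
  cal <- fit_bead_calibration(abc, mfi)
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$r2, 1)
  expect_equal(abc_from_mfi(mfi, cal), abc, tolerance = 1e-9)
  expect_error(fit_bead_calibration(abc[1:3], mfi[1:3]), ">= 4")
  expect_error(abc_from_mfi(0, cal), "positive")
  expect_error(fit_bead_calibration(c(-1, abc[2:5]), mfi), "positive")
})

test_that("seeded bead panels recover the calibration and sample ABC", {
  bp <- gen_bead_panel(seed = 21, cv = 0.05)
  cal <- fit_bead_calibration(bp$beads$abc, bp$beads$mfi)
  expect_lt(abs(cal$slope - bp$truth$slope), 0.05)

  cm <- gen_cell_mfi(seed = 21, cv = 0.05)
  fr <- analyze_flow_run(bp$beads, cm$samples)
  est <- setNames(fr$results$abc, fr$results$sample)[names(cm$truth$abc)]
  rel_err <- abs(est / cm$truth$abc - 1)
  expect_lt(median(rel_err), 0.10)
})

test_that("the semiquantitative scale scores ratios into the six bins", {
  expect_equal(as.character(semiquant_label(2)), "-")
  expect_equal(as.character(semiquant_label(5)), "+/-")
  expect_equal(as.character(semiquant_label(10)), "1+")
  expect_equal(as.character(semiquant_label(35)), "2+")
  expect_equal(as.character(semiquant_label(75)), "3+")
  expect_equal(as.character(semiquant_label(150)), "4+")
  # the scale is a monotone step function of the ratio
  r <- sort(c(0.5, 2.999, 3, 3.001, 9.999, 10, 29.9, 30, 49.9, 50, 99.9, 100, 500))
  lab <- semiquant_label(r)
  expect_true(all(diff(as.integer(lab)) >= 0))

  sc <- semiquant_score(200, 10)
  expect_equal(as.character(sc), "1+")
  expect_equal(attr(sc, "ratio"), 20)
  expect_error(semiquant_score(10, 0), "positive")
})

test_that("fold expression uses presentation rounding", {
  expect_equal(fold_expression(204370, 12076), 17)
  expect_equal(fold_expression(12076, 5174), 2.3)
  expect_equal(fold_expression(100, 100), 1.0)
  expect_equal(fold_expression(204370, 12076, rounding = "none"),
               204370 / 12076)
  expect_equal(round_fold(41.8), 42)
  expect_equal(round_fold(9.26), 9.3)
  expect_error(fold_expression(-1, 2), "positive")
})

test_that("flow run analysis ties calibration, ABC and the scale together", {
  bp <- gen_bead_panel(seed = 2, cv = 0)
  cm <- gen_cell_mfi(seed = 2, cv = 0)
  fr <- analyze_flow_run(bp$beads, cm$samples)
  est <- setNames(fr$results$abc, fr$results$sample)[names(cm$truth$abc)]
  # noise-free round trip through calibrate -> estimate is exact
  expect_equal(est, cm$truth$abc, tolerance = 1e-6)
  expect_equal(fr$results$label,
               as.character(semiquant_label(fr$results$ratio)))
})
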