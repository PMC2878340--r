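test_that("plasmid concentration converts to copies by the molar formula", {
  # independent arithmetic: 1 ng in a 3000 bp plasmid at 650 g/mol/bp
  expect_equal(conc_to_copies(1, 1, 3000), 1e-9 * 6.022e23 / (3000 * 650))
  expect_equal(conc_to_copies(1, 1, 6000) * 2, conc_to_copies(1, 1, 3000))
  expect_equal(conc_to_copies(2e-2, 5, 4031),
               2e-2 * 5 * 1e-9 * 6.022e23 / (4031 * 650))
  expect_error(conc_to_copies(-1, 1, 3000), "positive")
})

test_that("a noise-free dilution series is fitted exactly", {
  copies <- 10^(2:7)
  ct <- 40 - 3.321928 * log10(copies)
  curve <- fit_standard_curve(ct, copies)
  expect_equal(curve$slope, -3.321928, tolerance = 1e-10)
  expect_equal(curve$intercept, 40, tolerance = 1e-10)
  expect_equal(curve$r2, 1)
  expect_equal(curve$efficiency, 2, tolerance = 1e-6)
  expect_equal(curve$qc, "pass")
  expect_error(fit_standard_curve(ct[1:3], copies[1:3]), ">= 4")
})

test_that("Pfaffl efficiency follows E = 10^(-1/slope)", {
  expect_lt(abs(efficiency_pfaffl(-3.321928) - 2), 1e-6)
  expect_equal(efficiency_pfaffl(-3.45), 10^(1 / 3.45))
  # slope -3.60 gives E ~1.90, below the 1.92 hard floor
  e <- efficiency_pfaffl(-3.60)
  expect_equal(e, 10^(1 / 3.6))
  expect_equal(qc_efficiency(e), "fail")
  expect_equal(qc_efficiency(1.94), "warn")
  expect_equal(qc_efficiency(1.98), "pass")
  expect_error(efficiency_pfaffl(3.3), "negative")
  # strictly decreasing in |slope|
  slopes <- -seq(3.0, 4.0, by = 0.1)
  expect_true(all(diff(efficiency_pfaffl(slopes)) < 0))
})

test_that("copy estimation inverts the standard-curve model", {
  copies <- 10^(2:7)
  curve <- fit_standard_curve(40 - 3.321928 * log10(copies), copies)
  expect_equal(copies_from_ct(40 - 3.321928 * 5, curve), 1e5,
               tolerance = 1e-9)
  expect_equal(copies_from_ct(curve$intercept, curve), 1, tolerance = 1e-9)
})

test_that("ratio, geometric mean and fold change behave as documented", {
  expect_equal(gmean(c(4, 9)), 6)
  expect_equal(gmean(rep(3.7, 5)), 3.7)
  set.seed(1)
  x <- runif(7, 0.1, 10)
  expect_equal(gmean(x), gmean(rev(x)))
  expect_equal(normalized_ratio(300, 150), 2)
  expect_equal(fold_change(2.5, 2.5), 1)
  expect_error(gmean(c(1, 0)), "positive")
  expect_error(normalized_ratio(1, 0), "positive")
  expect_error(fold_change(-1, 2), "positive")
})

test_that("a noise-free simulated run is recovered to machine precision", {
  qp <- gen_qpcr_run(seed = 4, noise_sd_ct = 0)
  run <- analyze_qpcr_run(qp$wells, plasmid_bp = 4031)
  for (tg in names(run$curves)) {
    expect_equal(run$curves[[tg]]$slope, unname(qp$truth$slope[tg]),
                 tolerance = 1e-8)
    expect_equal(run$curves[[tg]]$intercept, unname(qp$truth$intercept[tg]),
                 tolerance = 1e-8)
  }
  f72 <- run$folds[run$folds$timepoint_h == 72, ]
  expect_equal(setNames(f72$fold, f72$target)[names(qp$truth$fold_72h)],
               qp$truth$fold_72h, tolerance = 1e-8)
})

test_that("noisy runs recover the curve and the fold induction", {
  qp <- gen_qpcr_run(seed = 17, noise_sd_ct = 0.1)
  run <- analyze_qpcr_run(qp$wells, plasmid_bp = 4031)
  for (tg in names(run$curves)) {
    expect_lt(abs(run$curves[[tg]]$slope - qp$truth$slope[tg]), 0.05)
  }
  # the B*02:01 analogue is induced 41.8-fold at 72 h in truth
  f <- run$folds[run$folds$timepoint_h == 72 & run$folds$target == "B*02:01", ]
  expect_lt(abs(f$fold / qp$truth$fold_72h[["B*02:01"]] - 1), 0.10)
})

test_that("the run analyzer validates its inputs", {
  qp <- gen_qpcr_run(seed = 4)
  expect_error(analyze_qpcr_run(qp$wells[, -4], plasmid_bp = 4031), "lacks")
  expect_error(analyze_qpcr_run(qp$wells, plasmid_bp = 4031,
                                reference = "GAPDH"), "absent")
})
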