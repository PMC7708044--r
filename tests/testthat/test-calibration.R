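# The two-step fit: alpha from the ligated 21 bp-spacing beam, then beta
# from its nicked counterpart with alpha frozen.

lig <- design_preset("C170L")
nic <- design_preset("C170N")
m0 <- material_params()

test_that("alpha calibration matches the closed-form inversion", {
  a <- calibrate_alpha(181, lig, m0)
  expect_equal(a, oracle_invert_alpha(181, lig, m0), tolerance = 1e-6)
  expect_equal(a, 0.020728, tolerance = 1e-3)
})

test_that("beta calibration matches the closed-form inversion with alpha fixed", {
  a <- calibrate_alpha(181, lig, m0)
  b <- calibrate_beta(108, nic, m0, alpha = a)
  expect_equal(b, oracle_invert_beta(108, nic, m0, a), tolerance = 1e-6)
  expect_equal(b, 0.005715, tolerance = 1e-3)
})

test_that("calibration round-trips the forward map", {
  small_lig <- build_two_helix(1050, 21, ligated = TRUE)
  small_nic <- build_two_helix(1050, 21, ligated = FALSE)
  for (a0 in c(0.02, 0.3, 1)) {
    k <- nanobeam:::stiffness_scalar(small_lig, material_params(alpha = a0))
    expect_equal(calibrate_alpha(k, small_lig), a0, tolerance = 1e-6)
  }
  k <- nanobeam:::stiffness_scalar(small_nic, material_params(alpha = 0.05, beta = 0.7))
  expect_equal(calibrate_beta(k, small_nic, alpha = 0.05), 0.7, tolerance = 1e-6)
})

test_that("random parameter pairs are recovered by the two-step procedure", {
  small_lig <- build_two_helix(1050, 21, ligated = TRUE)
  small_nic <- build_two_helix(1050, 21, ligated = FALSE)
  pars <- withr::with_seed(42, {
    data.frame(a = exp(stats::runif(20, log(5e-3), 0)),
               b = exp(stats::runif(20, log(5e-3), 0)))
  })
  for (i in seq_len(nrow(pars))) {
    truth <- material_params(alpha = pars$a[i], beta = pars$b[i])
    k_lig <- nanobeam:::stiffness_scalar(small_lig, truth)
    k_nic <- nanobeam:::stiffness_scalar(small_nic, truth)
    cal <- calibrate_nanobeam(small_lig, small_nic, k_lig, k_nic, ci = FALSE)
    expect_lt(abs(cal$alpha - pars$a[i]) / pars$a[i], 1e-4)
    expect_lt(abs(cal$beta - pars$b[i]) / pars$b[i], 1e-4)
  }
})

test_that("calibration order matters: beta-first is not equivalent", {
  a <- calibrate_alpha(181, lig, m0)
  b <- calibrate_beta(108, nic, m0, alpha = a)
  # fitting beta first with the undegraded alpha absorbs junction softness
  # into the nicks and lands somewhere else
  b_first <- calibrate_beta(108, nic, m0, alpha = 1)
  expect_gt(abs(b_first - b) / b, 0.5)
})

test_that("unattainable targets raise range errors with the bracket reported", {
  expect_error(calibrate_alpha(5000, lig, m0), "attainable",
               class = "nanobeam_range_error")
  expect_error(calibrate_beta(5000, nic, m0, alpha = 0.02),
               class = "nanobeam_range_error")
})

test_that("design roles are enforced", {
  expect_error(calibrate_alpha(181, nic, m0), class = "nanobeam_validation_error")
  expect_error(calibrate_beta(108, lig, m0, alpha = 0.02),
               class = "nanobeam_validation_error")
  expect_error(calibrate_alpha(181, nanobeam_design(1, 100), m0),
               class = "nanobeam_validation_error")
})

test_that("edge targets return the bracket ends", {
  small_lig <- build_two_helix(1050, 21, ligated = TRUE)
  k_max <- nanobeam:::stiffness_scalar(small_lig, material_params(alpha = 1))
  expect_equal(calibrate_alpha(k_max, small_lig), 1, tolerance = 1e-6)
})

test_that("confidence intervals come from refitting at mean +/- sd", {
  ci <- calibration_interval(181, 82, lig, "alpha", m0)
  expect_equal(unname(ci["lo"]), oracle_invert_alpha(99, lig, m0), tolerance = 1e-5)
  expect_equal(unname(ci["hi"]), oracle_invert_alpha(263, lig, m0), tolerance = 1e-5)
  expect_equal(unname(ci), c(0.0110, 0.0311), tolerance = 2e-3)

  ci0 <- calibration_interval(181, 0, lig, "alpha", m0)
  expect_equal(unname(ci0["lo"]), unname(ci0["hi"]), tolerance = 1e-7)

  ci_wide <- calibration_interval(181, 120, lig, "alpha", m0)
  expect_lt(ci_wide["lo"], ci["lo"])
  expect_gt(ci_wide["hi"], ci["hi"])

  # upper endpoint beyond the stiffness of two intact helices: unattainable
  expect_error(calibration_interval(181, 2100, lig, "alpha", m0),
               class = "nanobeam_range_error")
})

test_that("the calibration object is tidy and predicts the remaining constructs", {
  cal <- calibrate_nanobeam(lig, nic, c(181, 82), c(108, 47), m0)
  expect_s3_class(cal, "nanobeam_calibration")
  expect_true(all(abs(cal$residuals_pN) < 1e-6 * c(181, 108)))
  expect_true(cal$alpha_ci["lo"] <= cal$alpha && cal$alpha <= cal$alpha_ci["hi"])
  expect_true(cal$beta_ci["lo"] <= cal$beta && cal$beta <= cal$beta_ci["hi"])

  td <- tidy(cal)
  expect_identical(td$term, c("alpha", "beta"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(cal)
  expect_identical(gl$n_targets, 2L)
  expect_lt(gl$max_abs_residual_pN, 1e-3)

  pred <- predict(cal, c("C85L", "C85N"))
  expect_identical(pred$name, c("C85L", "C85N"))
  expect_equal(pred$model_stiffness_pN[1],
               oracle_series_stiffness(design_preset("C85L"), cal$material),
               tolerance = 1e-9)
  expect_equal(pred$model_stiffness_pN, c(334.5, 205.9), tolerance = 1e-3)
})
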