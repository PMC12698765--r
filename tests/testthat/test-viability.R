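test_that("relative survival is the blank-corrected mock ratio", {
  expect_equal(as.numeric(relative_survival(500, 10500, 500)), 0)
  expect_equal(as.numeric(relative_survival(10500, 10500, 500)), 1)
  expect_equal(as.numeric(relative_survival(5500, 10500, 500)), 0.5)
  s <- relative_survival(c(300, 20500), 10500, 500)
  expect_equal(as.numeric(s), c(0, 2))       # clamped below, >1 allowed
  expect_true(attr(s, "clamped")[1])
  expect_error(relative_survival(1000, 400, 500), "plate failure")
})

test_that("relative survival is invariant under rescaling all fluorescences", {
  f <- c(8000, 4000, 1500)
  s1 <- as.numeric(relative_survival(f, 9000, 1000))
  s2 <- as.numeric(relative_survival(3.7 * f, 3.7 * 9000, 3.7 * 1000))
  expect_equal(s1, s2)
})

test_that("noise-free 4PL data is recovered essentially exactly", {
  d <- c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 20)
  s <- 0 + (1 - 0) / (1 + (d / 1)^1)
  f <- fit_dose_response(d, s)
  expect_true(f$converged)
  expect_equal(f$top, 1, tolerance = 1e-6)
  expect_equal(f$bottom, 0, tolerance = 1e-6)
  expect_equal(f$ec50, 1, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)
})

test_that("ec50 is recovered within 10% under 2% noise", {
  set.seed(400)
  d <- rep(10^seq(-2, 2, length.out = 8), each = 3)
  errs <- replicate(50, {
    ec50 <- 10^runif(1, -1, 1)
    s <- 0.02 + (1 - 0.02) / (1 + (d / ec50)^1.3) + rnorm(length(d), 0, 0.02)
    f <- fit_dose_response(d, s)
    abs(f$ec50 - ec50) / ec50
  })
  expect_lte(stats::median(errs), 0.10)
})

test_that("flat data is flagged degenerate and not inverted", {
  d <- c(0.1, 1, 10, 100)
  f <- fit_dose_response(d, rep(1, 4))
  expect_true(f$degenerate)
  expect_error(ec_x(f, 0.25), "degenerate")
})

test_that("ec_x inverts the fitted curve analytically", {
  d <- c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 20)
  s <- 1 / (1 + d / 1)
  f <- fit_dose_response(d, s)
  expect_equal(ec_x(f, 0.5), 1, tolerance = 1e-6)        # EC50 identity
  expect_equal(ec_x(f, 0.25), 1 / 3, tolerance = 1e-6)   # EC75 closed form
  # definitional: survival at the reported EC75 is 0.75
  expect_equal(predict_survival(f, ec_x(f, 0.25)), 0.75, tolerance = 1e-9)
  # unreachable target
  s2 <- 0.6 + 0.4 / (1 + d / 1)
  f2 <- fit_dose_response(d, s2)
  expect_error(ec_x(f2, 0.5), "outside the fitted asymptote")
})

test_that("genotype contrast flags synthetic lethality", {
  doses <- c(0.1, 0.3, 1, 3, 10)
  ctrl <- data.frame(dose = doses, survival = c(1, 1, 1, 0.98, 0.95))
  mut <- data.frame(dose = doses, survival = c(0.97, 0.9, 0.45, 0.2, 0.05))
  ct <- synthetic_lethality_contrast(ctrl, mut)
  expect_equal(ct$ratio[3], 0.45)
  expect_true(ct$synthetic_lethal[3])
  expect_true(attr(ct, "any_lethal"))
  # identical curves: all ratios 1, nothing flagged
  same <- synthetic_lethality_contrast(ctrl, ctrl)
  expect_equal(same$ratio, rep(1, 5))
  expect_false(any(same$synthetic_lethal))
  # dead control: ratio undefined
  ctrl0 <- data.frame(dose = doses, survival = c(1, 1, 0, 0, 0))
  ct0 <- synthetic_lethality_contrast(ctrl0, mut)
  expect_true(all(is.na(ct0$ratio[3:5])))
  expect_error(synthetic_lethality_contrast(ctrl, transform(mut, dose = dose * 7)),
               "non-overlapping")
})

test_that("contrast works on fitted curves over an explicit grid", {
  d <- c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 20)
  fit_ctrl <- fit_dose_response(d, 0.05 + 0.95 / (1 + (d / 50)^2))
  fit_mut <- fit_dose_response(d, 0.05 + 0.95 / (1 + (d / 0.5)^2))
  ct <- synthetic_lethality_contrast(fit_ctrl, fit_mut, doses = c(0.5, 1, 2))
  expect_true(any(ct$synthetic_lethal))
  expect_error(synthetic_lethality_contrast(fit_ctrl, fit_mut), "doses")
})
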