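test_that("calibration solves an analytic forward to 0.1% within the evaluation budget", {
  a <- 3.2e6
  fw <- function(G) a / G
  res <- calibrate_shear_modulus(40, fw, bounds = c(1e4, 5e5), tol = 0.01)
  expect_true(res$converged)
  expect_equal(res$G_hat, 8e4, tolerance = 1e-3)
  # bisection-style budget: converges in at most 12 forward runs at tol 1 mL
  res2 <- calibrate_shear_modulus(40, fw, bounds = c(1e4, 5e5), tol = 1)
  expect_lte(nrow(res2$evaluations), 12)
  expect_true(res2$converged)
})

test_that("calibration handles boundary targets and rejects bad brackets", {
  fw <- function(G) 3.2e6 / G
  # target equal to SV at the soft bound: returns the bound, converged
  res <- calibrate_shear_modulus(3.2e6 / 1e4, fw, bounds = c(1e4, 5e5), tol = 0.5)
  expect_true(res$converged)
  expect_equal(res$G_hat, 1e4)
  expect_error(calibrate_shear_modulus(1e9, fw, bounds = c(1e4, 5e5)), "outside")
  expect_error(calibrate_shear_modulus(40, function(G) G, bounds = c(1e4, 5e5)),
               "not decreasing")
})

test_that("median recovery stays within 10% under 5% multiplicative SV noise", {
  a <- 3.2e6; g_true <- 8e4
  errs <- vapply(1:20, function(seed) {
    set.seed(seed)
    fw <- function(G) a / G * (1 + rnorm(1, 0, 0.05))
    res <- tryCatch(
      calibrate_shear_modulus(a / g_true, fw, bounds = c(1e4, 5e5), tol = 0.5),
      error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    abs(res$G_hat - g_true) / g_true
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 0.10)
})

test_that("modulus relative difference reproduces the cross-calibration figure", {
  expect_equal(round(100 * modulus_relative_difference(79e3, 75e3)), 5)
  expect_equal(modulus_relative_difference(79e3, 75e3), 4 / 79, tolerance = 1e-12)
  expect_equal(modulus_relative_difference(5, 5), 0)
  # asymmetric by definition: the first argument is the reference
  expect_false(isTRUE(all.equal(modulus_relative_difference(79e3, 75e3),
                                modulus_relative_difference(75e3, 79e3))))
})

test_that("bulk-modulus matching Poisson ratio solves K equality exactly", {
  expect_equal(poisson_for_bulk_match(79e3, 0.4999, 79e3), 0.4999)
  nu_c <- poisson_for_bulk_match(79e3, 0.4999, 1e7)
  expect_equal(nu_c, 0.4875, tolerance = 2e-4)  # 0.48745 rounds to 0.4875
  K <- function(G, nu) 2 * G * (1 + nu) / (3 * (1 - 2 * nu))
  expect_equal(K(1e7, nu_c), K(79e3, 0.4999), tolerance = 1e-10 * K(79e3, 0.4999))
  expect_error(poisson_for_bulk_match(79e3, 0.01, 1e9), "0.5")
})

test_that("calcified material assignment keeps density and counts elements exactly", {
  mask <- c(rep(TRUE, 7), rep(FALSE, 13))
  mat <- assign_calcified_material(mask, g_tissue = 79e3, nu_tissue = 0.4999,
                                   g_calc = 1e7)
  expect_equal(mat$shear_modulus, 79e3)
  expect_equal(mat$shear_modulus_calcified, 1e7)
  expect_equal(sum(mat$calcified_mask), 7)
  mf <- valveverify:::material_fields(mat, 20)
  expect_equal(sum(mf$G == 1e7), 7)
  # empty mask: homogeneous
  hom <- assign_calcified_material(rep(FALSE, 5), 79e3)
  expect_null(hom$shear_modulus_calcified)
})

test_that("cross-validation reports every evaluated condition and is self-consistent", {
  a <- c(d0 = 3.2e6, d5 = 4.8e6, d10 = 5.2e6, d20 = 4.9e6)
  g_true <- 8e4
  fw <- function(G, cond) a[[cond]] / G
  targets <- vapply(names(a), function(cd) fw(g_true, cd), numeric(1))
  cv <- cross_validate("d5", c("d0", "d10", "d20"), targets, fw, tol = 0.01)
  expect_equal(nrow(cv$report), 3)
  expect_true(all(cv$report$rel_error < 0.10))
  expect_true(all(cv$report$within_uncertainty))
  # calibrating and evaluating on the same condition: error ~ 0
  cv2 <- cross_validate("d0", "d0", targets, fw, tol = 0.01)
  expect_lt(cv2$report$rel_error, 1e-3)
})
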