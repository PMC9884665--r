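ref_curve <- intensity_response(v_max = 0.8, k_half = 1e15, hill_n = 1)

# amplitudes that a pigment with the given template would produce
template_amplitudes <- function(lmax, curve, wl = led_wl, flux = 6.2e14,
                                reps = 1) {
  tpl <- spectral_template(lmax)
  s <- evaluate_template(tpl, wl) / evaluate_template(tpl, 470)
  do.call(rbind, lapply(seq_len(reps), function(r) {
    data.frame(amplitude = predict_response(curve, flux * s),
               wavelength_nm = wl, photon_flux = flux,
               replicate_id = paste0("r", r))
  }))
}

test_that("relative sensitivities invert amplitudes into flux ratios", {
  amps <- template_amplitudes(472, ref_curve)
  sens <- compute_relative_sensitivities(amps, ref_curve)
  tpl <- spectral_template(472)
  expected <- evaluate_template(tpl, led_wl)
  expected <- expected / max(expected)
  expect_equal(sens$rel_sensitivity, expected, tolerance = 1e-6)
  expect_equal(sum(sens$rel_sensitivity == 1), 1L)
  expect_true(all(sens$sem >= 0))
})

test_that("sensitivity scales with delivered flux and respects symmetry", {
  # equal amplitudes at equal flux -> equal sensitivity
  amps <- data.frame(amplitude = c(0.2, 0.2, 0.3),
                     wavelength_nm = c(430, 510, 470),
                     photon_flux = 6.2e14)
  sens <- compute_relative_sensitivities(amps, ref_curve)
  expect_equal(sens$rel_sensitivity[sens$wavelength_nm == 430],
               sens$rel_sensitivity[sens$wavelength_nm == 510])
  # same amplitude at half the flux -> sensitivity doubles (pre-normalization)
  amps2 <- data.frame(amplitude = c(0.2, 0.2, 0.3),
                      wavelength_nm = c(430, 510, 470),
                      photon_flux = c(6.2e14, 3.1e14, 6.2e14))
  sens2 <- compute_relative_sensitivities(amps2, ref_curve)
  r1 <- sens$rel_sensitivity[sens$wavelength_nm == 510] /
        sens$rel_sensitivity[sens$wavelength_nm == 430]
  r2 <- sens2$rel_sensitivity[sens2$wavelength_nm == 510] /
        sens2$rel_sensitivity[sens2$wavelength_nm == 430]
  expect_equal(r2 / r1, 2, tolerance = 1e-12)
})

test_that("non-invertible amplitudes are excluded per wavelength with a warning", {
  amps <- template_amplitudes(472, ref_curve, reps = 2)
  amps$amplitude[amps$wavelength_nm == 540] <- -0.01       # non-responder
  expect_warning(sens <- compute_relative_sensitivities(amps, ref_curve),
                 "540")
  expect_false(540 %in% sens$wavelength_nm)
  expect_equal(nrow(sens), 4L)

  few <- data.frame(amplitude = c(0.1, -0.1, 0.9),
                    wavelength_nm = c(430, 470, 510), photon_flux = 6.2e14)
  expect_error(suppressWarnings(compute_relative_sensitivities(few, ref_curve)),
               "fewer than 3")
})

test_that("rss_at matches the closed-form least-squares scale by hand", {
  # hand-computable 3-point case: template values replaced by exact ratios
  pts <- data.frame(wavelength_nm = c(430, 470, 510),
                    rel_sensitivity = c(0.3, 1.0, 0.5))
  t_i <- evaluate_template(spectral_template(472), c(430, 470, 510))
  a_star <- sum(pts$rel_sensitivity * t_i) / sum(t_i^2)
  by_hand <- sum((pts$rel_sensitivity - a_star * t_i)^2)
  got <- rss_at(pts, 472)
  expect_equal(got$scale_factor, a_star, tolerance = 1e-12)
  expect_equal(got$rss, by_hand, tolerance = 1e-12)

  # perfect fit: rss 0, scale 1
  perfect <- template_points(472)
  got2 <- rss_at(perfect, 472)
  expect_lt(got2$rss, 1e-12)
  expect_equal(got2$scale_factor, 1, tolerance = 1e-12)

  # all-zero data: degenerate closed form
  zero <- data.frame(wavelength_nm = c(430, 470, 510), rel_sensitivity = 0)
  got3 <- rss_at(zero, 472)
  expect_identical(got3$scale_factor, 0)
  expect_identical(got3$rss, 0)

  # fixed scale pins a* at 1
  got4 <- rss_at(pts, 472, free_scale = FALSE)
  expect_identical(got4$scale_factor, 1)
  expect_equal(got4$rss, sum((pts$rel_sensitivity - t_i)^2), tolerance = 1e-12)
})

test_that("lambda-max is recovered exactly from noise-free template points", {
  for (lmax in c(430, 455.5, 472, 500, 520)) {
    fit <- estimate_lambda_max(template_points(lmax))
    expect_lt(abs(fit$lambda_max_hat - lmax), 0.1)
    expect_lt(fit$rss_min, 1e-10)
  }
})

test_that("the estimate is scale-invariant with a free scale", {
  f1 <- estimate_lambda_max(template_points(500))
  f2 <- estimate_lambda_max(template_points(500, scale = 0.7))
  expect_equal(f2$lambda_max_hat, f1$lambda_max_hat, tolerance = 1e-4)
  expect_equal(f2$scale_factor, 0.7 * f1$scale_factor, tolerance = 1e-6)
})

test_that("the estimate is invariant to point order", {
  pts <- template_points(472)
  shuf <- pts[c(4, 1, 5, 3, 2), ]
  expect_equal(estimate_lambda_max(shuf)$lambda_max_hat,
               estimate_lambda_max(pts)$lambda_max_hat, tolerance = 1e-9)
})

test_that("the RSS profile is an evenly spaced grid with its minimum at the estimate", {
  fit <- estimate_lambda_max(template_points(472), grid_step = 2,
                             window_halfwidth = 20)
  expect_equal(unique(diff(fit$rss_profile$lambda_max)), 2)
  expect_equal(nrow(fit$rss_profile), 21L)
  expect_equal(fit$grid_window, c(452, 492))
  expect_lte(fit$rss_min, min(fit$rss_profile$rss))
  # on noise-free data the profile dips at the true value vs both neighbours
  i0 <- which(fit$rss_profile$lambda_max == 472)
  expect_lte(fit$rss_profile$rss[i0], fit$rss_profile$rss[i0 - 1])
  expect_lte(fit$rss_profile$rss[i0], fit$rss_profile$rss[i0 + 1])
})

test_that("noisy sensitivities still localize lambda-max to a few nm", {
  set.seed(99)
  err <- vapply(1:200, function(i) {
    pts <- template_points(472)
    pts$rel_sensitivity <- pts$rel_sensitivity +
      rowMeans(matrix(rnorm(15, 0, 0.05), 5, 3))  # n = 3 replicate means
    estimate_lambda_max(pts)$lambda_max_hat - 472
  }, numeric(1))
  expect_lte(median(abs(err)), 4)
})

test_that("an off-grid true peak triggers the boundary diagnostics only at range ends", {
  red_pts <- data.frame(wavelength_nm = c(560, 600, 640, 680),
                        rel_sensitivity = c(0.2, 0.4, 0.7, 1.0))
  expect_warning(estimate_lambda_max(red_pts), "boundary")
  fit <- suppressWarnings(estimate_lambda_max(red_pts))
  expect_true(fit$boundary_warning)
  fit_ok <- estimate_lambda_max(template_points(472))
  expect_false(fit_ok$boundary_warning)
})
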