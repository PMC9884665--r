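test_that("simulated effective dose honours the pigment template", {
  d <- assay_design(true_lambda_max = 472, noise_sd = 0, baseline_drift = 0,
                    tau_rise = NULL, tau_decay = NULL)
  # at the reference wavelength the effective dose is the delivered flux
  tr470 <- simulate_trace(d, 470, 6.2e14)
  a470 <- extract_amplitude(normalize_trace(tr470), smooth_s = 0)$amplitude
  expect_equal(a470, predict_response(d$dose, 6.2e14), tolerance = 1e-12)
  # off-peak wavelengths deliver template-attenuated doses
  tpl <- spectral_template(472)
  s <- evaluate_template(tpl, c(540, 470))
  tr540 <- simulate_trace(d, 540, 6.2e14)
  a540 <- extract_amplitude(normalize_trace(tr540), smooth_s = 0)$amplitude
  expect_equal(a540, predict_response(d$dose, 6.2e14 * s[1] / s[2]),
               tolerance = 1e-12)
})

test_that("noise-free step-kernel traces return the target amplitude exactly", {
  d <- assay_design(noise_sd = 0, baseline_drift = 0,
                    tau_rise = NULL, tau_decay = NULL)
  ex <- simulate_experiment(d)
  amps <- preprocess_traces(ex$traces, smooth_s = 0)
  key <- paste(amps$wavelength_nm, amps$photon_flux)
  truth_key <- paste(ex$truth$per_trace$wavelength_nm,
                     ex$truth$per_trace$photon_flux)
  expect_equal(amps$amplitude,
               ex$truth$per_trace$target_amplitude[match(key, truth_key)],
               tolerance = 1e-12)
})

test_that("rise-decay kinetics attenuate the peak by at most ~1%", {
  d <- assay_design(noise_sd = 0, baseline_drift = 0)  # default kinetics
  tr <- simulate_trace(d, 470, 6.2e14)
  v <- predict_response(d$dose, 6.2e14)
  a <- extract_amplitude(normalize_trace(tr), smooth_s = 0)$amplitude
  expect_lt(abs(a - v) / v, 0.01)
  expect_lte(a, v + 1e-12)
})

test_that("simulation is deterministic in its seeds", {
  d <- assay_design(noise_sd = 0.05, seed = 123L)
  t1 <- simulate_trace(d, 470, 6.2e14, replicate_seed = 1L)
  t2 <- simulate_trace(d, 470, 6.2e14, replicate_seed = 1L)
  expect_identical(t1$luminescence, t2$luminescence)
  t3 <- simulate_trace(d, 470, 6.2e14, replicate_seed = 2L)
  expect_false(identical(t1$luminescence, t3$luminescence))

  ex1 <- simulate_experiment(d)
  ex2 <- simulate_experiment(d)
  expect_identical(ex1$traces, ex2$traces)
  # byte-identical CSV output
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(ex1$traces, p1)
  write_traces_csv(ex2$traces, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the generator leaves the session RNG untouched", {
  set.seed(555)
  before <- .Random.seed
  invisible(simulate_trace(assay_design(noise_sd = 0.05), 470, 6.2e14, 1L))
  expect_identical(.Random.seed, before)
})

test_that("simulated amplitude is monotone in flux (noise-free)", {
  d <- assay_design(noise_sd = 0, baseline_drift = 0)
  fluxes <- 10^seq(13, 16.5, length.out = 8)
  amps <- vapply(fluxes, function(f) {
    extract_amplitude(normalize_trace(simulate_trace(d, 470, f)))$amplitude
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("the experiment mirrors the one-dish-one-stimulus design", {
  d <- assay_design(n_replicates = 3)
  ex <- simulate_experiment(d)
  per_dish <- unique(ex$traces[, c("replicate_id", "wavelength_nm",
                                   "photon_flux")])
  # every dish appears under exactly one stimulus
  expect_equal(nrow(per_dish), length(unique(ex$traces$replicate_id)))
  # 5 intensities + 5 LEDs, 3 dishes each
  expect_equal(nrow(per_dish), (5 + 5) * 3)
})

test_that("generator-analyzer adjointness holds through the whole pipeline", {
  for (lmax in c(440, 500)) {
    d <- assay_design(true_lambda_max = lmax, noise_sd = 0,
                      baseline_drift = 0, tau_rise = NULL, tau_decay = NULL)
    res <- run_pipeline(simulate_experiment(d)$traces)
    expect_lt(abs(res$fit$lambda_max_hat - lmax), 0.1)
    expect_equal(res$dose$v_max, d$dose$v_max, tolerance = 1e-6)
    expect_equal(res$dose$k_half, d$dose$k_half, tolerance = 1e-6)
    expect_equal(res$dose$hill_n, d$dose$hill_n, tolerance = 1e-6)
    tpl <- spectral_template(lmax)
    expected <- evaluate_template(tpl, d$led_wavelengths)
    expect_equal(res$sensitivities$rel_sensitivity, expected / max(expected),
                 tolerance = 1e-6)
  }
})

test_that("a design round-trips through JSON and YAML configuration", {
  cfg <- list(true_lambda_max = 500, v_max = 0.6, k_half = 5e14,
              noise_sd = 0, n_replicates = 4, seed = 11)
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, pj, auto_unbox = TRUE, digits = NA)
  d <- read_design(pj)
  expect_equal(d$true_lambda_max, 500)
  expect_equal(d$dose$v_max, 0.6)
  expect_equal(d$dose$k_half, 5e14)
  expect_equal(d$n_replicates, 4L)
  py <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, py)
  d2 <- read_design(py)
  expect_equal(d2$dose$k_half, d$dose$k_half)
  pj2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(lambda = 1), pj2, auto_unbox = TRUE)
  expect_error(read_design(pj2), "unknown design field")
})

test_that("a saturating design trips the documented exclusion rules", {
  # tiny v_max with fluxes far above k_half: measured amplitudes straddle the
  # fitted saturation level, so some replicates are not invertible
  d <- assay_design(v_max = 1e-3, k_half = 1e12, noise_sd = 0.05, seed = 9L,
                    intensity_series = 1e12 * 10^seq(-1, 3, length.out = 5))
  ex <- simulate_experiment(d)
  expect_warning(run_pipeline(ex$traces), "outside the invertible range")
})
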