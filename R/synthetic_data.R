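# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards; keeps simulation determinism independent of the
# surrounding session
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic action-spectroscopy assay design
#'
#' Describes one simulated heterologous action spectroscopy experiment: a
#' pigment with known \code{true_lambda_max}, a Hill intensity-response
#' relation at the 470 nm reference wavelength, a five-LED wavelength series
#' at fixed quantum flux, a five-point neutral-density intensity series at
#' 470 nm, and replicate dishes each irradiated exactly once. Traces carry a
#' slowly drifting baseline, a light-triggered rise-decay transient whose
#' amplitude follows the dose-response of the effective photon dose, and
#' additive Gaussian measurement noise proportional to the baseline.
#'
#' @param true_lambda_max True pigment peak, nm (default 472).
#' @param v_max,k_half,hill_n Dose-response parameters at 470 nm (defaults
#'   0.8, 1e15 photons cm^-2 s^-1, 1).
#' @param led_wavelengths LED peak wavelengths, nm (default
#'   c(410, 430, 470, 510, 540)).
#' @param wavelength_flux Photon flux of each LED in the wavelength series
#'   (default 6.2e14 photons cm^-2 s^-1; recycled to the LED count).
#' @param intensity_series Fluxes of the 470 nm neutral-density series
#'   (default 5 log-spaced values spanning \code{k_half} over +/- 1.5
#'   decades).
#' @param n_replicates Dishes per condition (default 3).
#' @param noise_sd SD of Gaussian noise on normalized luminescence
#'   (default 0.05; 0 for noise-free data).
#' @param baseline_level Baseline luminescence in luminometer counts
#'   (default 1000).
#' @param baseline_drift Exponential drift rate of the baseline, per second
#'   (default -1e-4, a slow decay; 0 for a flat baseline).
#' @param tau_rise,tau_decay Time constants (s) of the unit-peak rise-decay
#'   response kernel (defaults 60 and 600); set either to \code{NULL} for a
#'   step kernel (instantaneous, non-decaying response), which makes the
#'   extracted amplitude equal the generating amplitude exactly.
#' @param dt Sampling interval, s (default 2).
#' @param pre_stimulus Seconds of baseline recorded before onset (default
#'   90; must be >= 60).
#' @param post_stimulus Seconds recorded after onset (default 600).
#' @param seed Base integer seed for the experiment (default 1).
#' @return An object of class \code{assay_design}.
#' @export
assay_design <- function(true_lambda_max = 472,
                         v_max = 0.8, k_half = 1e15, hill_n = 1,
                         led_wavelengths = c(410, 430, 470, 510, 540),
                         wavelength_flux = 6.2e14,
                         intensity_series = NULL,
                         n_replicates = 3,
                         noise_sd = 0.05,
                         baseline_level = 1000,
                         baseline_drift = -1e-4,
                         tau_rise = 60, tau_decay = 600,
                         dt = 2, pre_stimulus = 90, post_stimulus = 600,
                         seed = 1L) {
  if (is.null(intensity_series)) {
    intensity_series <- k_half * 10^seq(-1.5, 1.5, length.out = 5)
  }
  stopifnot(all(intensity_series > 0), all(wavelength_flux > 0),
            pre_stimulus >= 60, noise_sd >= 0, n_replicates >= 1)
  wavelength_flux <- rep_len(wavelength_flux, length(led_wavelengths))
  structure(
    list(true_lambda_max = true_lambda_max,
         dose = intensity_response(v_max, k_half, hill_n,
                                   reference_wavelength = 470),
         led_wavelengths = led_wavelengths,
         wavelength_flux = wavelength_flux,
         intensity_series = intensity_series,
         n_replicates = as.integer(n_replicates),
         noise_sd = noise_sd,
         baseline_level = baseline_level,
         baseline_drift = baseline_drift,
         tau_rise = tau_rise, tau_decay = tau_decay,
         dt = dt, pre_stimulus = pre_stimulus, post_stimulus = post_stimulus,
         seed = as.integer(seed)),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("assay design: true lambda_max %g nm; Vmax %.3g, K %.3g, n %.3g @470 nm\n",
              x$true_lambda_max, x$dose$v_max, x$dose$k_half, x$dose$hill_n))
  cat(sprintf("  %d LEDs (%s nm), %d-point 470 nm intensity series, %d replicates, noise sd %.3g\n",
              length(x$led_wavelengths),
              paste(x$led_wavelengths, collapse = "/"),
              length(x$intensity_series), x$n_replicates, x$noise_sd))
  invisible(x)
}

# unit-peak rise-decay kernel; NULL tau => step kernel
.response_kernel <- function(t_rel, tau_rise, tau_decay) {
  k <- numeric(length(t_rel))
  on_ <- t_rel > 0
  if (is.null(tau_rise) || is.null(tau_decay)) {
    k[on_] <- 1
    return(k)
  }
  # peak of (1 - e^(-t/tr)) e^(-t/td) at t* = tr * log(1 + td/tr)
  t_star <- tau_rise * log(1 + tau_decay / tau_rise)
  peak <- (1 - exp(-t_star / tau_rise)) * exp(-t_star / tau_decay)
  k[on_] <- (1 - exp(-t_rel[on_] / tau_rise)) * exp(-t_rel[on_] / tau_decay) / peak
  k
}

# target amplitude for one stimulus under the design's pigment and dose model
.target_amplitude <- function(design, wavelength, flux) {
  tpl <- spectral_template(design$true_lambda_max)
  s <- evaluate_template(tpl, c(wavelength, 470))
  i_eff <- flux * s[1L] / s[2L]
  predict_response(design$dose, i_eff)
}

#' Simulate one luminescence trace
#'
#' Generates \code{baseline(t) * (1 + V * k(t - onset)) + noise}, where the
#' baseline drifts exponentially, \code{k} is a unit-peak rise-decay kernel,
#' \code{V} is the dose-response amplitude of the effective photon dose
#' \code{flux * S(wavelength) / S(470)} under the design's pigment template,
#' and the noise is i.i.d. Gaussian with SD \code{noise_sd * baseline(t)}.
#' Deterministic given \code{(design$seed, replicate_seed)}.
#'
#' @param design An [assay_design()].
#' @param wavelength Stimulus wavelength, nm.
#' @param flux Stimulus photon flux, photons cm^-2 s^-1.
#' @param replicate_seed Integer offset distinguishing replicate dishes.
#' @param replicate_id,construct_id Labels stored in the trace.
#' @return A [luminescence_trace()].
#' @export
simulate_trace <- function(design, wavelength, flux, replicate_seed = 0L,
                           replicate_id = paste0("r", replicate_seed),
                           construct_id = "synthetic_opsin") {
  stopifnot(inherits(design, "assay_design"))
  v <- .target_amplitude(design, wavelength, flux)
  onset <- design$pre_stimulus
  times <- seq(0, onset + design$post_stimulus, by = design$dt)
  base <- design$baseline_level * exp(design$baseline_drift * times)
  k <- .response_kernel(times - onset, design$tau_rise, design$tau_decay)
  y <- base * (1 + v * k)
  if (design$noise_sd > 0) {
    y <- y + .with_seed(design$seed + 7919L * replicate_seed, {
      stats::rnorm(length(y), 0, design$noise_sd * base)
    })
    y <- pmax(y, .Machine$double.eps * design$baseline_level)
  }
  luminescence_trace(times, y, stimulus_onset = onset,
                     stimulus_wavelength = wavelength, photon_flux = flux,
                     stimulus_duration = 5,
                     replicate_id = replicate_id, construct_id = construct_id)
}

#' Simulate a full action-spectroscopy experiment
#'
#' Produces one trace per (470 nm intensity x replicate) and per
#' (LED wavelength x replicate); every replicate is a distinct dish
#' irradiated once. Returns the long-format trace table together with the
#' ground truth used to generate it.
#'
#' @param design An [assay_design()].
#' @return List with \code{traces} (trace data.frame in the CSV dialect,
#'   intensity series first), \code{truth} (list: \code{true_lambda_max},
#'   \code{dose_params}, \code{per_trace} data.frame of generating
#'   amplitudes) and \code{design}.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  cond <- rbind(
    data.frame(series = "intensity", wavelength = 470,
               flux = design$intensity_series),
    data.frame(series = "wavelength", wavelength = design$led_wavelengths,
               flux = design$wavelength_flux)
  )
  traces <- list(); per_trace <- list(); idx <- 0L
  for (i in seq_len(nrow(cond))) {
    for (r in seq_len(design$n_replicates)) {
      idx <- idx + 1L
      rep_id <- sprintf("%s_w%g_f%03d_rep%d", cond$series[i],
                        cond$wavelength[i], i, r)
      traces[[idx]] <- simulate_trace(
        design, cond$wavelength[i], cond$flux[i],
        replicate_seed = idx,
        replicate_id = rep_id
      )
      per_trace[[idx]] <- data.frame(
        series = cond$series[i], replicate_id = rep_id,
        wavelength_nm = cond$wavelength[i], photon_flux = cond$flux[i],
        target_amplitude = .target_amplitude(design, cond$wavelength[i],
                                             cond$flux[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    traces = traces_to_table(traces),
    truth = list(
      true_lambda_max = design$true_lambda_max,
      dose_params = list(v_max = design$dose$v_max,
                         k_half = design$dose$k_half,
                         hill_n = design$dose$hill_n),
      per_trace = do.call(rbind, per_trace)
    ),
    design = design
  )
}

#' Run the full analysis pipeline on a trace table
#'
#' Convenience driver chaining the whole analysis: baseline normalization
#' and amplitude extraction, sigmoid intensity-response fit on the
#' reference-wavelength intensity series, conversion of the wavelength
#' series to relative sensitivities, and lambda-max estimation.
#'
#' The reference-wavelength rows are split into the intensity series (all
#' distinct fluxes at \code{reference_wavelength}) and the wavelength series
#' (all other wavelengths plus, if present among the wavelength-series
#' fluxes, the reference LED itself).
#'
#' @param traces Trace data.frame (see [read_traces_csv()]) or list of
#'   [luminescence_trace()] objects.
#' @param reference_wavelength Reference wavelength, nm (default 470).
#' @param led_flux Photon flux of the wavelength-series LEDs; reference-
#'   wavelength rows at this flux are treated as part of the wavelength
#'   series. If \code{NULL} (default), the most common flux among
#'   non-reference wavelengths is used.
#' @param window,smooth_s Passed to [extract_amplitude()].
#' @param grid_step,window_halfwidth,free_scale,include_beta Passed to
#'   [estimate_lambda_max()].
#' @return List with \code{amplitudes}, \code{dose} (the
#'   [intensity_response()] fit), \code{sensitivities} and \code{fit} (the
#'   \code{lambda_max_fit}).
#' @export
run_pipeline <- function(traces, reference_wavelength = 470, led_flux = NULL,
                         window = 600, smooth_s = 20,
                         grid_step = 2, window_halfwidth = 20,
                         free_scale = TRUE, include_beta = TRUE) {
  amps <- preprocess_traces(traces, window = window, smooth_s = smooth_s)
  is_ref <- amps$wavelength_nm == reference_wavelength
  if (is.null(led_flux)) {
    other <- amps$photon_flux[!is_ref]
    if (length(other) == 0L) {
      stop("no wavelengths besides the reference: cannot form a wavelength series",
           call. = FALSE)
    }
    led_flux <- as.numeric(names(sort(table(other), decreasing = TRUE))[1L])
  }
  wl_series <- !is_ref | (is_ref & amps$photon_flux == led_flux)
  dose <- fit_intensity_response(amps[is_ref, , drop = FALSE],
                                 reference_wavelength = reference_wavelength)
  sens <- compute_relative_sensitivities(amps[wl_series, , drop = FALSE], dose)
  fit <- estimate_lambda_max(sens, grid_step = grid_step,
                             window_halfwidth = window_halfwidth,
                             free_scale = free_scale,
                             include_beta = include_beta)
  list(amplitudes = amps, dose = dose, sensitivities = sens, fit = fit)
}
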