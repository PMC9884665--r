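#' Sigmoid intensity-response curve
#'
#' The intensity-response (dose-response) relation used throughout the
#' pipeline is the Hill sigmoid
#' \deqn{V = V_{max} \, I^n / (I^n + K^n)}
#' where \eqn{V} is the response amplitude, \eqn{I} the stimulus photon flux,
#' \eqn{K} the flux eliciting half-maximal response and \eqn{n} the Hill
#' exponent. At \eqn{I = K} the predicted response is exactly
#' \eqn{V_{max}/2}.
#'
#' @param v_max Maximum response amplitude (> 0), dimensionless.
#' @param k_half Half-saturating photon flux (> 0), photons cm^-2 s^-1.
#' @param hill_n Hill exponent, in (0.1, 10].
#' @param reference_wavelength Wavelength at which the curve was measured,
#'   nm (default 470).
#' @param fit_rss Residual sum of squares of the fit (NA for a curve stated
#'   rather than fitted).
#' @param n_points Number of distinct intensities behind the fit.
#' @return An object of class \code{intensity_response}.
#' @export
intensity_response <- function(v_max, k_half, hill_n,
                               reference_wavelength = 470,
                               fit_rss = NA_real_, n_points = NA_integer_) {
  if (!is.finite(v_max) || v_max <= 0) stop("`v_max` must be > 0", call. = FALSE)
  if (!is.finite(k_half) || k_half <= 0) stop("`k_half` must be > 0", call. = FALSE)
  if (!is.finite(hill_n) || hill_n <= 0.1 || hill_n > 10) {
    stop("`hill_n` must lie in (0.1, 10]", call. = FALSE)
  }
  structure(
    list(v_max = v_max, k_half = k_half, hill_n = hill_n,
         reference_wavelength = reference_wavelength,
         fit_rss = fit_rss, n_points = n_points),
    class = "intensity_response"
  )
}

#' @export
print.intensity_response <- function(x, ...) {
  cat(sprintf("intensity-response curve @ %g nm: Vmax = %.4g, K = %.4g photons/cm2/s, n = %.4g\n",
              x$reference_wavelength, x$v_max, x$k_half, x$hill_n))
  if (is.finite(x$fit_rss)) {
    cat(sprintf("  fit: RSS = %.4g over %d intensities\n", x$fit_rss, x$n_points))
  }
  invisible(x)
}

#' Predict response amplitude at a given photon flux
#'
#' @param curve An [intensity_response()] curve.
#' @param intensity Photon flux (>= 0), photons cm^-2 s^-1; vectorized.
#' @return Predicted amplitude(s): 0 at \code{I = 0}, strictly increasing,
#'   approaching \code{v_max}.
#' @export
predict_response <- function(curve, intensity) {
  stopifnot(inherits(curve, "intensity_response"))
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("`intensity` must be non-negative and finite", call. = FALSE)
  }
  # compute in ratio form for numerical stability at extreme fluxes
  r <- (intensity / curve$k_half)^curve$hill_n
  curve$v_max * r / (r + 1)
}

#' Invert the intensity-response curve
#'
#' Converts a response amplitude back into the photon flux that would elicit
#' it at the reference wavelength:
#' \eqn{I = K (V / (V_{max} - V))^{1/n}}. This is the step that transforms
#' wavelength-series amplitudes into equivalent photon numbers.
#'
#' @param curve An [intensity_response()] curve.
#' @param amplitude Amplitude(s) strictly inside (0, v_max); vectorized.
#' @return Equivalent photon flux(es), photons cm^-2 s^-1.
#' @export
invert_response <- function(curve, amplitude) {
  stopifnot(inherits(curve, "intensity_response"))
  if (any(amplitude <= 0)) {
    stop("amplitude below invertible range (<= 0)", call. = FALSE)
  }
  if (any(amplitude >= curve$v_max)) {
    stop(sprintf("amplitude at or above v_max = %g: response saturates, not invertible",
                 curve$v_max), call. = FALSE)
  }
  curve$k_half * (amplitude / (curve$v_max - amplitude))^(1 / curve$hill_n)
}

#' Fit the sigmoid intensity-response curve
#'
#' Fits \eqn{V = V_{max} I^n / (I^n + K^n)} to the replicate-mean response at
#' each distinct intensity of the reference-wavelength series, by bounded
#' nonlinear least squares (Levenberg-Marquardt). Replicates sharing an
#' intensity are averaged first; the fit is unweighted. The intensity axis is
#' rescaled internally by its maximum for conditioning, so the fit is
#' invariant to the choice of flux units up to the corresponding rescaling of
#' \code{k_half}.
#'
#' Starting values: \code{v_max0 = 1.05 * max(mean response)}, \code{k0} the
#' observed intensity whose mean response is nearest half of that, and
#' \code{n0 = 1}. Bounds: \code{hill_n} in (0.1, 10],
#' \code{k_half} within \[min(I)/100, max(I)*100\].
#'
#' @param amplitudes Data.frame of response amplitudes (see
#'   [extract_amplitude()]) measured at the reference wavelength, with
#'   columns \code{amplitude} and \code{photon_flux}. Rows at other
#'   wavelengths are dropped with a message.
#' @param reference_wavelength Reference wavelength in nm (default 470).
#' @return An [intensity_response()] carrying the fitted parameters,
#'   \code{fit_rss} and \code{n_points}.
#' @export
fit_intensity_response <- function(amplitudes, reference_wavelength = 470) {
  stopifnot(is.data.frame(amplitudes))
  if ("wavelength_nm" %in% names(amplitudes)) {
    keep <- amplitudes$wavelength_nm == reference_wavelength
    if (!all(keep)) {
      message(sum(!keep), " amplitude(s) not at the reference wavelength dropped")
    }
    amplitudes <- amplitudes[keep, , drop = FALSE]
  }
  mean_v <- tapply(amplitudes$amplitude, amplitudes$photon_flux, mean)
  intensity <- as.numeric(names(mean_v))
  mean_v <- as.numeric(mean_v)
  if (length(intensity) < 3L) {
    stop("need at least 3 distinct intensities to fit the sigmoid", call. = FALSE)
  }
  if (max(mean_v) <= 0) {
    stop("all mean responses are non-positive: no rising dose-response to fit",
         call. = FALSE)
  }

  i_scale <- max(intensity)
  xi <- intensity / i_scale
  v_max0 <- 1.05 * max(mean_v)
  k0 <- xi[which.min(abs(mean_v - v_max0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * x^n / (x^n + k^n),
      data = data.frame(v = mean_v, x = xi),
      start = list(vmax = v_max0, k = k0, n = 1),
      lower = c(vmax = 1e-12, k = min(xi) / 100, n = 0.1 + 1e-9),
      upper = c(vmax = 100 * max(mean_v), k = max(xi) * 100, n = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) {
      stop("intensity-response fit failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  p <- stats::coef(fit)
  intensity_response(
    v_max = unname(p["vmax"]),
    k_half = unname(p["k"]) * i_scale,
    hill_n = unname(p["n"]),
    reference_wavelength = reference_wavelength,
    fit_rss = sum(stats::residuals(fit)^2),
    n_points = length(intensity)
  )
}
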