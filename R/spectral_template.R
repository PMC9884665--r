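#' Govardovskii A1 visual pigment template
#'
#' Constructs the parametric spectral sensitivity curve of an A1-chromophore
#' (11-cis retinal) visual pigment, fully determined by its nominal peak
#' wavelength \code{lambda_max}. The curve is the sum of an alpha band
#' (a log-normal-like expression in \code{lambda_max / lambda}) and an
#' optional beta (cis) band modelled as a Gaussian; by default it is
#' renormalized to unit peak over a dense 0.1 nm scan of 300--700 nm, because
#' the analytic alpha + beta sum peaks only approximately at the nominal
#' \code{lambda_max} and only approximately at 1.
#'
#' @param lambda_max Nominal peak wavelength of the alpha band, in nm.
#'   Must lie in \[330, 650\].
#' @param include_beta Include the beta band (default \code{TRUE}). Blue
#'   pigments have a non-negligible beta contribution below ~420 nm.
#' @param normalized_peak Rescale the curve to unit maximum (default
#'   \code{TRUE}).
#' @return An object of class \code{spectral_template}.
#' @examples
#' tpl <- spectral_template(472)
#' evaluate_template(tpl, c(410, 470, 540))
#' @seealso [evaluate_template()], [template_vector()]
#' @export
spectral_template <- function(lambda_max, include_beta = TRUE,
                              normalized_peak = TRUE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      !is.finite(lambda_max)) {
    stop("`lambda_max` must be a single finite number (nm)", call. = FALSE)
  }
  if (lambda_max < 330 || lambda_max > 650) {
    stop(sprintf("lambda_max = %g nm is outside the supported range [330, 650] nm",
                 lambda_max), call. = FALSE)
  }
  tpl <- structure(
    list(lambda_max = lambda_max,
         chromophore = "A1",
         include_beta = isTRUE(include_beta),
         normalized_peak = isTRUE(normalized_peak),
         peak_value = 1),
    class = "spectral_template"
  )
  if (tpl$normalized_peak) {
    grid <- seq(300, 700, by = 0.1)
    tpl$peak_value <- max(.gov_a1_raw(lambda_max, grid, tpl$include_beta))
  }
  tpl
}

# raw (un-normalized) A1 template: alpha band + optional beta band
.gov_a1_raw <- function(lambda_max, wavelength, include_beta) {
  x <- lambda_max / wavelength
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s_alpha <- 1 / (exp(69.7 * (a - x)) +
                  exp(28   * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) +
                  0.674)
  if (!include_beta) return(s_alpha)
  lm_beta <- 189 + 0.315 * lambda_max
  b_beta  <- -40.5 + 0.195 * lambda_max
  s_alpha + 0.26 * exp(-((wavelength - lm_beta) / b_beta)^2)
}

#' Evaluate a spectral template
#'
#' Returns the relative sensitivity of the pigment template at one or more
#' wavelengths. Values are strictly positive on the supported range and, for
#' a unit-peak template, never exceed 1.
#'
#' @param template A [spectral_template()].
#' @param wavelength Wavelength(s) in nm, each in \[300, 700\].
#' @return Numeric vector of relative sensitivities, same length and order as
#'   \code{wavelength}.
#' @export
evaluate_template <- function(template, wavelength) {
  stopifnot(inherits(template, "spectral_template"))
  if (!is.numeric(wavelength) || length(wavelength) == 0L) {
    stop("`wavelength` must be a non-empty numeric vector (nm)", call. = FALSE)
  }
  bad <- !is.finite(wavelength) | wavelength < 300 | wavelength > 700
  if (any(bad)) {
    stop(sprintf("wavelength %g nm is outside the supported range [300, 700] nm",
                 wavelength[which(bad)[1L]]), call. = FALSE)
  }
  .gov_a1_raw(template$lambda_max, wavelength, template$include_beta) /
    template$peak_value
}

#' Evaluate a spectral template at a vector of wavelengths
#'
#' Thin order-preserving wrapper around [evaluate_template()] for explicit
#' vector use; errors on an empty wavelength list.
#'
#' @inheritParams evaluate_template
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @return Numeric vector of sensitivities in the input order.
#' @export
template_vector <- function(template, wavelengths) {
  if (length(wavelengths) == 0L) {
    stop("`wavelengths` must contain at least one value", call. = FALSE)
  }
  evaluate_template(template, wavelengths)
}

#' @export
print.spectral_template <- function(x, ...) {
  cat(sprintf("A1 visual pigment template: lambda_max = %g nm (%s beta band, %s)\n",
              x$lambda_max,
              if (x$include_beta) "with" else "without",
              if (x$normalized_peak) "unit peak" else "raw scale"))
  invisible(x)
}
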