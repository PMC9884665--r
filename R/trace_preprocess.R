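#' A single luminescence assay time series
#'
#' Container for one raw GloSensor-style luminescence trace together with its
#' stimulus metadata. The trace must start at least 60 s before stimulus
#' onset so the baseline window is defined, luminescence must be strictly
#' positive (baseline division must be well defined) and times strictly
#' increasing.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param luminescence Luminometer readings, strictly positive, same length
#'   as \code{times}.
#' @param stimulus_onset Irradiation onset time in seconds.
#' @param stimulus_wavelength Stimulus wavelength in nm.
#' @param photon_flux Stimulus photon flux, photons cm^-2 s^-1.
#' @param stimulus_duration Stimulus duration in seconds (default 5).
#' @param replicate_id,construct_id Opaque labels identifying the dish and
#'   the expressed construct.
#' @return An object of class \code{lum_trace}.
#' @export
luminescence_trace <- function(times, luminescence, stimulus_onset,
                               stimulus_wavelength, photon_flux,
                               stimulus_duration = 5,
                               replicate_id = "r1", construct_id = "opsin") {
  times <- as.numeric(times)
  luminescence <- as.numeric(luminescence)
  if (length(times) != length(luminescence)) {
    stop("`times` and `luminescence` must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(luminescence)) || any(luminescence <= 0)) {
    stop("`luminescence` must be strictly positive and finite", call. = FALSE)
  }
  if (times[1L] > stimulus_onset - 60) {
    stop("trace must start at least 60 s before stimulus onset (baseline window)",
         call. = FALSE)
  }
  structure(
    list(times = times, luminescence = luminescence,
         stimulus_onset = as.numeric(stimulus_onset),
         stimulus_wavelength = as.numeric(stimulus_wavelength),
         photon_flux = as.numeric(photon_flux),
         stimulus_duration = as.numeric(stimulus_duration),
         replicate_id = as.character(replicate_id),
         construct_id = as.character(construct_id),
         normalized = FALSE),
    class = "lum_trace"
  )
}

#' @export
print.lum_trace <- function(x, ...) {
  cat(sprintf("luminescence trace: %s / %s, %d samples, %g nm at %.3g photons/cm2/s%s\n",
              x$construct_id, x$replicate_id, length(x$times),
              x$stimulus_wavelength, x$photon_flux,
              if (x$normalized) " (baseline-normalized)" else ""))
  invisible(x)
}

#' Baseline-normalize a luminescence trace
#'
#' Divides the whole trace by the mean luminescence over the 60 s immediately
#' preceding irradiation (samples with \code{t} in
#' \code{[stimulus_onset - 60, stimulus_onset)}), so the baseline window mean
#' of the output is exactly 1. Idempotent up to floating point.
#'
#' @param trace A [luminescence_trace()].
#' @return The trace in normalized units (baseline mean 1), times unchanged.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "lum_trace"))
  in_bl <- trace$times >= trace$stimulus_onset - 60 &
           trace$times <  trace$stimulus_onset
  if (sum(in_bl) < 2L) {
    stop("insufficient baseline: fewer than 2 samples in the 60 s window before onset",
         call. = FALSE)
  }
  trace$luminescence <- trace$luminescence / mean(trace$luminescence[in_bl])
  trace$normalized <- TRUE
  trace
}

#' Extract a scalar response amplitude from a normalized trace
#'
#' The response amplitude is the peak of the baseline-normalized luminescence
#' within a post-stimulus window, minus 1. An optional centered moving-average
#' smoother (width \code{smooth_s} seconds) is applied before peak picking to
#' keep the statistic from tracking single-sample shot noise; it is exact on
#' traces whose response plateau is wider than the smoothing window.
#' The statistic is invariant to any positive gain applied to the raw trace,
#' and negative amplitudes (non-responding constructs) are reported, not
#' clipped.
#'
#' @param trace A baseline-normalized [luminescence_trace()] (see
#'   [normalize_trace()]).
#' @param window Post-stimulus search window in seconds (default 600).
#' @param smooth_s Width of the moving-average smoother in seconds
#'   (default 20; 0 disables smoothing).
#' @return A one-row data.frame with columns \code{amplitude},
#'   \code{wavelength_nm}, \code{photon_flux}, \code{replicate_id},
#'   \code{construct_id}.
#' @export
extract_amplitude <- function(trace, window = 600, smooth_s = 20) {
  stopifnot(inherits(trace, "lum_trace"))
  if (!isTRUE(trace$normalized)) {
    stop("trace must be baseline-normalized first (see normalize_trace)",
         call. = FALSE)
  }
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  y <- trace$luminescence
  if (smooth_s > 0 && length(y) > 2L) {
    dt <- stats::median(diff(trace$times))
    k <- max(1L, round(smooth_s / dt))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L && k < length(y)) {
      ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
      keep <- !is.na(ys)
      y <- ifelse(keep, ys, y)  # raw values at the edges
    }
  }
  in_win <- trace$times > trace$stimulus_onset &
            trace$times <= trace$stimulus_onset + window
  if (!any(in_win)) {
    stop("no samples inside the post-stimulus window", call. = FALSE)
  }
  data.frame(
    amplitude = max(y[in_win]) - 1,
    wavelength_nm = trace$stimulus_wavelength,
    photon_flux = trace$photon_flux,
    replicate_id = trace$replicate_id,
    construct_id = trace$construct_id,
    stringsAsFactors = FALSE
  )
}

#' Preprocess a table of traces into response amplitudes
#'
#' Convenience wrapper: baseline-normalizes every trace in a long-format
#' trace table (see [read_traces_csv()]) and extracts one response amplitude
#' per trace.
#'
#' @param traces A long-format trace data.frame or a list of
#'   [luminescence_trace()] objects.
#' @inheritParams extract_amplitude
#' @return A data.frame of response amplitudes, one row per trace.
#' @export
preprocess_traces <- function(traces, window = 600, smooth_s = 20) {
  if (is.data.frame(traces)) traces <- traces_from_table(traces)
  out <- lapply(traces, function(tr) {
    extract_amplitude(normalize_trace(tr), window = window, smooth_s = smooth_s)
  })
  do.call(rbind, out)
}
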