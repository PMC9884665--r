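#' Read a long-format trace CSV
#'
#' The trace dialect is one row per sample with columns
#' \code{construct_id, replicate_id, time_s, luminescence, stimulus_onset_s,
#' wavelength_nm, photon_flux, stimulus_duration_s}. One trace is identified
#' by the combination of \code{construct_id}, \code{replicate_id},
#' \code{wavelength_nm} and \code{photon_flux} (each dish is irradiated only
#' once, so a replicate never carries more than one stimulus).
#'
#' @param path Path to a CSV file.
#' @return A data.frame in the trace dialect.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("construct_id", "replicate_id", "time_s", "luminescence",
           "stimulus_onset_s", "wavelength_nm", "photon_flux",
           "stimulus_duration_s")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("trace CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a long-format trace CSV
#'
#' @param traces A trace data.frame (see [read_traces_csv()]) or a list of
#'   [luminescence_trace()] objects.
#' @param path Output path.
#' @export
write_traces_csv <- function(traces, path) {
  if (!is.data.frame(traces)) traces <- traces_to_table(traces)
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a long-format trace table into trace objects
#'
#' @param df A trace data.frame (see [read_traces_csv()]).
#' @return A list of [luminescence_trace()] objects, one per
#'   (construct, replicate, wavelength, flux) combination, each validated
#'   against the trace invariants.
#' @export
traces_from_table <- function(df) {
  key <- interaction(df$construct_id, df$replicate_id, df$wavelength_nm,
                     df$photon_flux, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    luminescence_trace(
      times = g$time_s,
      luminescence = g$luminescence,
      stimulus_onset = g$stimulus_onset_s[1L],
      stimulus_wavelength = g$wavelength_nm[1L],
      photon_flux = g$photon_flux[1L],
      stimulus_duration = g$stimulus_duration_s[1L],
      replicate_id = g$replicate_id[1L],
      construct_id = g$construct_id[1L]
    )
  })
}

#' Flatten trace objects into the long-format table
#'
#' @param traces A list of [luminescence_trace()] objects.
#' @return A trace data.frame in the CSV dialect.
#' @export
traces_to_table <- function(traces) {
  if (inherits(traces, "lum_trace")) traces <- list(traces)
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(
      construct_id = tr$construct_id,
      replicate_id = tr$replicate_id,
      time_s = tr$times,
      luminescence = tr$luminescence,
      stimulus_onset_s = tr$stimulus_onset,
      wavelength_nm = tr$stimulus_wavelength,
      photon_flux = tr$photon_flux,
      stimulus_duration_s = tr$stimulus_duration,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write an intensity-response fit as JSON
#'
#' @param curve An [intensity_response()] fit.
#' @param path Output path.
#' @export
write_dose_json <- function(curve, path) {
  stopifnot(inherits(curve, "intensity_response"))
  jsonlite::write_json(
    list(v_max = curve$v_max, k_half = curve$k_half, hill_n = curve$hill_n,
         reference_wavelength = curve$reference_wavelength,
         fit_rss = curve$fit_rss, n_points = curve$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an intensity-response fit from JSON
#'
#' @param path Path to a JSON fit record written by [write_dose_json()].
#' @return An [intensity_response()] object.
#' @export
read_dose_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  intensity_response(v_max = x$v_max, k_half = x$k_half, hill_n = x$hill_n,
                     reference_wavelength = x$reference_wavelength,
                     fit_rss = x$fit_rss, n_points = x$n_points)
}
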