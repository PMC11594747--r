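#' Parameters of the synthetic per-element ERG waveform
#'
#' The localized cone-driven response to one white presentation of a
#' stimulus element is modelled as a positive P1 peak followed by the
#' photopic negative response (PhNR) trough, each a Gaussian bump in time.
#' The trough must fall in the 50-90 ms implicit-time window in which the
#' mfPhNR is measured.
#'
#' @param p1_time Implicit time of the positive P1 peak, ms.
#' @param p1_amp P1 amplitude density, nV/deg^2 (positive).
#' @param trough_time Implicit time of the PhNR trough, ms; must lie in
#'   `[50, 90]`.
#' @param trough_amp Magnitude of the trough amplitude density, nV/deg^2
#'   (stored positive; the bump is negative-going).
#' @param component_width Gaussian standard deviation of each bump, ms.
#' @param sampling_rate Sampling rate of the synthetic recording, Hz
#'   (at least 250).
#'
#' @return A list of class `waveform_params`.
#' @export
#' @examples
#' waveform_params(trough_amp = 25)
waveform_params <- function(p1_time = 35,
                            p1_amp = 30,
                            trough_time = 70,
                            trough_amp = 25,
                            component_width = 8,
                            sampling_rate = 1000) {
  if (trough_time < 50 || trough_time > 90) {
    abort("trough_time must lie in the 50-90 ms implicit-time window",
      class = "mfphnr_domain_error"
    )
  }
  if (trough_amp < 0 || p1_amp < 0) {
    abort("amplitudes are stored as non-negative magnitudes",
      class = "mfphnr_domain_error"
    )
  }
  if (sampling_rate < 250) {
    abort("sampling_rate must be at least 250 Hz", class = "mfphnr_domain_error")
  }
  structure(
    list(
      p1_time = p1_time, p1_amp = p1_amp,
      trough_time = trough_time, trough_amp = trough_amp,
      component_width = component_width, sampling_rate = sampling_rate
    ),
    class = "waveform_params"
  )
}

#' Synthetic response template of one stimulus element
#'
#' Builds the noise-free voltage response (nV) of a single element to one
#' white presentation: a positive Gaussian bump at the P1 implicit time
#' plus a negative Gaussian bump at the trough implicit time, scaled by the
#' element's area so that the amplitude *density* (nV/deg^2) equals the
#' nominal `p1_amp` and `trough_amp`. The template is anchored to zero at
#' stimulus onset (t = 0), so the pre-stimulus baseline of an extracted
#' kernel is flat.
#'
#' @param params A [waveform_params()].
#' @param area Element area in deg^2.
#' @param epoch_ms Template duration, ms; at least 100 so the trough
#'   window is covered. Defaults to one stimulation period at 7 Hz,
#'   quantized to the sample grid.
#'
#' @return A numeric vector of voltages (nV), sampled at
#'   `params$sampling_rate`, starting at t = 0.
#' @export
#' @examples
#' tpl <- element_response_template(waveform_params(trough_amp = 25), area = 1)
#' min(tpl) # close to -25 nV
element_response_template <- function(params, area, epoch_ms = NULL) {
  stopifnot(inherits(params, "waveform_params"))
  fs <- params$sampling_rate
  if (is.null(epoch_ms)) epoch_ms <- (round(fs / 7) - 1) / fs * 1000
  if (epoch_ms < 100) {
    abort("epoch length must be at least 100 ms", class = "mfphnr_domain_error")
  }
  if (area <= 0) abort("area must be positive", class = "mfphnr_domain_error")
  t_ms <- seq(0, epoch_ms, by = 1000 / fs)
  bump <- function(mu) exp(-0.5 * ((t_ms - mu) / params$component_width)^2)
  v <- area * (params$p1_amp * bump(params$p1_time) -
    params$trough_amp * bump(params$trough_time))
  v - v[1]
}
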