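#' Simulate a multifocal ERG trace set
#'
#' Builds the raw recording the amplifier would see during one full
#' m-sequence cycle: at every sequence step, each element whose state is
#' white (+1) contributes its response template to the single recorded
#' channel, and white Gaussian instrument noise is added on top. Each
#' element follows a distinct cyclic shift of the base m-sequence (see
#' [element_state_matrix()]), which is what lets [first_order_kernel()]
#' separate the per-element responses again.
#'
#' @param elements Element table from [build_dartboard()] (or any tibble
#'   with `element_id` and `area_deg2`).
#' @param mseq Base +1/-1 m-sequence from [generate_mseq()].
#' @param params A single [waveform_params()] applied to every element, or
#'   a list with one `waveform_params` per element.
#' @param noise_sd Standard deviation of the additive white noise, nV.
#' @param seed Optional integer seed; fixing it makes the trace set
#'   reproducible.
#' @param stimulus_frequency Stimulation rate, Hz; one m-sequence step per
#'   period. The step duration is quantized to the sample grid.
#' @param eye_id Identifier carried through to downstream tables.
#'
#' @return An object of class `trace_set`: a list with `trace` (numeric,
#'   nV), `states` (steps x elements matrix of +1/-1), `elements`,
#'   `sampling_rate`, `stimulus_frequency`, `samples_per_step`, `eye_id`.
#' @export
#' @examples
#' els <- build_dartboard()
#' ts <- simulate_trace_set(els[1:3, ], generate_mseq(4),
#'   waveform_params(),
#'   noise_sd = 0
#' )
#' length(ts$trace)
simulate_trace_set <- function(elements,
                               mseq,
                               params = waveform_params(),
                               noise_sd = 0,
                               seed = NULL,
                               stimulus_frequency = 7,
                               eye_id = "sim") {
  if (inherits(params, "waveform_params")) {
    params <- rep(list(params), nrow(elements))
  }
  if (length(params) != nrow(elements)) {
    abort("need one waveform parameter set per element",
      class = "mfphnr_domain_error"
    )
  }
  fs <- params[[1]]$sampling_rate
  spp <- as.integer(round(fs / stimulus_frequency))
  epoch_ms <- (spp - 1) / fs * 1000
  states <- element_state_matrix(mseq, nrow(elements))
  templates <- vapply(
    seq_len(nrow(elements)),
    function(i) {
      element_response_template(params[[i]], elements$area_deg2[i], epoch_ms)
    },
    numeric(spp)
  )
  # steps x samples epoch matrix: each on-state adds the element's template
  on <- (states + 1L) / 2L
  epochs <- on %*% t(templates)
  trace <- as.vector(t(epochs))
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) trace <- trace + rnorm(length(trace), 0, noise_sd)
  structure(
    list(
      trace = trace,
      states = states,
      elements = elements,
      sampling_rate = fs,
      stimulus_frequency = stimulus_frequency,
      samples_per_step = spp,
      eye_id = eye_id,
      rejected = integer(0)
    ),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(
    "<trace_set> eye", x$eye_id, "-", ncol(x$states), "elements,",
    nrow(x$states), "m-sequence steps,",
    length(x$trace), "samples @", x$sampling_rate, "Hz\n"
  )
  if (length(x$rejected)) {
    cat("  ", length(x$rejected), "epochs flagged as artifacts\n")
  }
  invisible(x)
}
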