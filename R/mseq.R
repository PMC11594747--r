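# Feedback tap positions of primitive polynomials over GF(2), one maximal
# LFSR per register length 2..16 (Fibonacci form; taps are the exponents of
# the feedback polynomial excluding the constant term).
mseq_taps <- list(
  `2` = c(2L, 1L), `3` = c(3L, 2L), `4` = c(4L, 3L), `5` = c(5L, 3L),
  `6` = c(6L, 5L), `7` = c(7L, 6L), `8` = c(8L, 6L, 5L, 4L),
  `9` = c(9L, 5L), `10` = c(10L, 7L), `11` = c(11L, 9L),
  `12` = c(12L, 11L, 10L, 4L), `13` = c(13L, 12L, 11L, 8L),
  `14` = c(14L, 13L, 12L, 2L), `15` = c(15L, 14L), `16` = c(16L, 15L, 13L, 4L)
)

#' Generate a binary maximum-length sequence (m-sequence)
#'
#' Produces the two-level pseudorandom sequence that drives each element of
#' the multifocal stimulus. A linear-feedback shift register with a
#' primitive feedback polynomial of the requested order is clocked through
#' one full period of `2^order - 1` steps. In the returned +1/-1 coding the
#' sequence is balanced (one more `+1` than `-1`) and its periodic
#' autocorrelation at every nonzero lag equals -1, which is what makes the
#' per-element responses separable by cross-correlation.
#'
#' @param order Register length in bits (2 to 16). The recording protocol
#'   uses order 12, i.e. 4095 steps.
#' @param seed_state Optional initial register content: a vector of 0/1 of
#'   length `order`, not all zero. Defaults to all ones. Different seed
#'   states produce cyclic shifts of the same sequence.
#'
#' @return An integer vector of +1/-1 of length `2^order - 1`.
#' @export
#' @examples
#' s <- generate_mseq(4)
#' length(s)
#' sum(s) # balance: +1 excess of exactly one
generate_mseq <- function(order, seed_state = NULL) {
  order <- as.integer(order)
  if (is.na(order) || order < 2L || order > 16L) {
    abort("order must be an integer between 2 and 16", class = "mfphnr_domain_error")
  }
  taps <- mseq_taps[[as.character(order)]]
  if (is.null(seed_state)) seed_state <- rep(1L, order)
  seed_state <- as.integer(seed_state)
  if (length(seed_state) != order || any(!seed_state %in% c(0L, 1L))) {
    abort("seed_state must be a 0/1 vector of length `order`",
      class = "mfphnr_domain_error"
    )
  }
  if (all(seed_state == 0L)) {
    abort("seed_state must not be all zero", class = "mfphnr_domain_error")
  }
  n <- 2L^order - 1L
  state <- seed_state
  bits <- integer(n)
  for (i in seq_len(n)) {
    bits[i] <- state[order]
    fb <- Reduce(bitwXor, state[taps])
    state <- c(fb, state[-order])
  }
  2L * bits - 1L
}

#' Per-element stimulus state sequences
#'
#' In multifocal stimulation every element follows the same m-sequence,
#' cyclically shifted by a distinct lag so that the elements are mutually
#' decorrelated. Lags are spaced `floor(length(mseq) / n_elements)` steps
#' apart, keeping neighbouring lags far enough apart that one element's
#' response epoch never overlaps another element's lag.
#'
#' @param mseq A +1/-1 m-sequence from [generate_mseq()].
#' @param n_elements Number of stimulus elements.
#'
#' @return An integer matrix of +1/-1 with `length(mseq)` rows (sequence
#'   steps) and `n_elements` columns.
#' @export
element_state_matrix <- function(mseq, n_elements) {
  n <- length(mseq)
  if (n_elements > n) {
    abort("more elements than m-sequence steps", class = "mfphnr_domain_error")
  }
  spacing <- n %/% n_elements
  lags <- (seq_len(n_elements) - 1L) * spacing
  vapply(
    lags,
    function(l) mseq[((seq_len(n) - 1L + l) %% n) + 1L],
    integer(n)
  )
}
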