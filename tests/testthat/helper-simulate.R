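# Shared helpers: small in-code fixtures for the signal-chain tests.

# A trace set small enough for brute-force oracles: a handful of elements
# driven by a short m-sequence.
small_trace_set <- function(n_elements = 3, order = 4, noise_sd = 0, seed = NULL,
                            params = waveform_params()) {
  els <- build_dartboard()[round(seq(1, 60, length.out = n_elements)), ]
  simulate_trace_set(els, generate_mseq(order), params,
    noise_sd = noise_sd, seed = seed
  )
}

# Literal per-epoch state-averaging kernel estimator: an independent code
# path against the vectorized implementation. Computes, for one element,
# mean(+1 epochs) - (N-1)/(N+1) * mean(-1 epochs) by looping over epochs.
brute_force_kernel <- function(trace_set, element, pre_ms = 10) {
  states <- trace_set$states[, element]
  n_steps <- length(states)
  spp <- trace_set$samples_per_step
  fs <- trace_set$sampling_rate
  pre <- round(pre_ms * fs / 1000)
  total <- n_steps * spp
  kept <- setdiff(seq_len(n_steps), trace_set$rejected)
  acc_pos <- acc_neg <- numeric(pre + spp)
  n_pos <- n_neg <- 0
  for (t in kept) {
    pos0 <- (t - 1) * spp
    epoch <- trace_set$trace[((pos0 + (-pre):(spp - 1)) %% total) + 1]
    if (states[t] == 1) {
      acc_pos <- acc_pos + epoch
      n_pos <- n_pos + 1
    } else {
      acc_neg <- acc_neg + epoch
      n_neg <- n_neg + 1
    }
  }
  acc_pos / n_pos - (n_steps - 1) / (n_steps + 1) * acc_neg / n_neg
}

# Direct-sum Pearson correlation (covariance formula), oracle for pearson_cor.
brute_force_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

example_cohort <- function() load_cohort(mfphnr_example("oag_cohort.csv"))
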