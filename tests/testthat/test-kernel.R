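test_that("band-pass is zero-phase, rejects DC, and preserves the signal band", {
  fs <- 1000
  # constant (pure DC) input is suppressed essentially to zero
  y <- bandpass(rep(5, 2000), fs)
  expect_lt(max(abs(y)), 1e-3 * 5)

  # 50 Hz sinusoid amplitude preserved within 12% (FFT oracle on the
  # impulse response gives the gain away from the edges)
  n <- 8192
  imp <- rep(0, n)
  imp[n / 2] <- 1
  H <- abs(fft(bandpass(imp, fs)))[1:(n / 2)]
  f <- (0:(n / 2 - 1)) * fs / n
  expect_equal(H[which.min(abs(f - 50))], 1, tolerance = 0.12)
  # passband ripple below 1 dB between 6 and 80 Hz
  core <- f >= 6 & f <= 80
  expect_lt(max(abs(20 * log10(H[core]))), 1)

  # zero phase: peak of a band-limited pulse is not shifted
  t <- seq(0, 1, by = 1 / fs)
  pulse <- exp(-0.5 * ((t - 0.5) / 0.02)^2)
  expect_equal(which.max(bandpass(pulse, fs)), which.max(pulse))

  # filtering twice changes the result only within stacked ripple bounds
  x <- sin(2 * pi * 30 * t)
  y1 <- bandpass(x, fs)
  y2 <- bandpass(y1, fs)
  expect_equal(y2, y1, tolerance = 0.02)

  expect_error(bandpass(x, 150), class = "mfphnr_domain_error")
  expect_error(bandpass(x), class = "mfphnr_domain_error")
  expect_error(recording_config(bandpass_low = 0), class = "mfphnr_config_error")
})

test_that("artifact rejection excludes exactly the contaminated epochs", {
  ts <- small_trace_set(n_elements = 2, order = 5)
  peak <- max(abs(ts$trace))

  # clean recording, generous threshold: nothing rejected
  clean <- reject_artifacts(ts, recording_config(artifact_threshold = 10 * peak))
  expect_length(clean$rejected, 0)

  # one injected spike of 5x threshold: exactly that epoch goes
  thr <- 10 * peak
  spp <- ts$samples_per_step
  spiked <- ts
  spiked$trace[(7 - 1) * spp + 3] <- 5 * thr
  rej <- reject_artifacts(spiked, recording_config(artifact_threshold = thr))
  expect_equal(rej$rejected, 7L)

  # zero threshold rejects everything -> unusable recording
  expect_error(
    reject_artifacts(ts, recording_config(artifact_threshold = 0)),
    class = "mfphnr_recording_error"
  )
  # min_valid_fraction gate
  many <- ts
  many$trace[(seq_len(20) - 1) * spp + 1] <- 5 * thr
  expect_error(
    reject_artifacts(many, recording_config(
      artifact_threshold = thr,
      min_valid_fraction = 0.9
    )),
    class = "mfphnr_recording_error"
  )
})

test_that("vectorized kernel extraction equals brute-force state averaging", {
  for (seed in 1:3) {
    ts <- small_trace_set(n_elements = 3, order = 4, noise_sd = 1, seed = seed)
    ks <- first_order_kernel(ts)
    for (el in 1:3) {
      expect_equal(
        unname(ks$kernels[el, ]),
        brute_force_kernel(ts, el),
        tolerance = 1e-9
      )
    }
  }
  # and with rejected epochs in the mix
  ts <- small_trace_set(n_elements = 3, order = 5, noise_sd = 1, seed = 7)
  ts$rejected <- c(2L, 9L)
  ks <- first_order_kernel(ts)
  expect_equal(unname(ks$kernels[2, ]), brute_force_kernel(ts, 2), tolerance = 1e-9)
})

test_that("noise-free kernels recover the generating templates exactly", {
  els <- build_dartboard()
  ts <- simulate_trace_set(els, generate_mseq(12), waveform_params(), noise_sd = 0)
  ks <- first_order_kernel(ts)
  spp <- ts$samples_per_step
  epoch_ms <- (spp - 1) / ts$sampling_rate * 1000
  post <- ks$time_ms >= 0
  pre <- ks$time_ms < 0
  errs <- vapply(seq_len(nrow(els)), function(i) {
    tpl <- element_response_template(waveform_params(), els$area_deg2[i], epoch_ms)
    max(abs(ks$kernels[i, post] - tpl)) / max(abs(tpl))
  }, numeric(1))
  expect_lt(max(errs), 1e-6)
  # the pre-stimulus baseline of every kernel is flat at zero
  expect_lt(max(abs(ks$kernels[, pre])), 1e-6 * max(abs(ks$kernels)))
})

test_that("kernel extraction flags degenerate designs and respects linearity", {
  ts <- small_trace_set(n_elements = 2, order = 4)
  # two elements driven by the same sequence: not identifiable
  ts$states[, 2] <- ts$states[, 1]
  expect_error(first_order_kernel(ts), class = "mfphnr_recording_error")

  # sign-flipped recording gives sign-flipped kernels (both estimators)
  ts <- small_trace_set(n_elements = 2, order = 5)
  for (m in c("crosscorr", "state_diff")) {
    k1 <- first_order_kernel(ts, method = m)
    ts2 <- ts
    ts2$trace <- -ts$trace
    k2 <- first_order_kernel(ts2, method = m)
    expect_equal(k2$kernels, -k1$kernels)
  }
})

test_that("pure-noise kernel amplitude shrinks as one over sqrt(epochs)", {
  els <- build_dartboard()[1, ]
  p <- waveform_params(p1_amp = 0, trough_amp = 0, sampling_rate = 250)
  orders <- c(4, 6, 8, 10)
  rms <- vapply(orders, function(o) {
    vals <- vapply(1:3, function(rep) {
      ts <- simulate_trace_set(els, generate_mseq(o), p,
        noise_sd = 1, seed = 100 * o + rep
      )
      ks <- first_order_kernel(ts)
      sqrt(mean(ks$kernels^2))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  slope <- coef(lm(log(rms) ~ log(2^orders - 1)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.2)
})
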