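make_beat <- function(p = 300) {
  n <- seq_len(p)
  800 * exp(-(n - 150)^2 / (2 * 12^2)) - 300 * exp(-(n - 180)^2 / (2 * 8^2))
}

test_that("signal averaging of identical beats returns the beat", {
  b <- make_beat()
  avg <- signal_average(beat_ensemble(rep(list(b), 5)))
  expect_equal(avg$samples, b)
  expect_true(all(attr(avg, "kept")))
})

test_that("alignment recovers known integer shifts", {
  b <- make_beat()
  p <- length(b)
  shift_by <- function(x, k) { # delay by k samples (k may be negative)
    if (k >= 0) c(rep(x[1], k), x[1:(p - k)])
    else c(x[(1 - k):p], rep(x[p], -k))
  }
  ens <- beat_ensemble(list(b, shift_by(b, 7), shift_by(b, -4)))
  avg <- signal_average(ens)
  expect_equal(attr(avg, "shifts"), c(0, -7, 4))
  expect_equal(avg$samples, b, tolerance = 1e-8)
})

test_that("averaging N noisy beats suppresses noise by about sqrt(N)", {
  b <- make_beat()
  set.seed(77)
  sigma_n <- 20
  beats <- lapply(1:64, function(i) b + rnorm(length(b), sd = sigma_n))
  avg <- signal_average(beat_ensemble(beats), align = FALSE)
  resid_rms <- rms_of(avg$samples - b)
  expect_lt(abs(resid_rms - sigma_n / 8), 0.3 * sigma_n / 8)
})

test_that("the correlation gate rejects dissimilar beats", {
  b <- make_beat()
  ens <- beat_ensemble(list(b, rev(b)))
  avg <- signal_average(ens, reject_correlation_below = 0.98)
  expect_equal(attr(avg, "kept"), c(TRUE, FALSE))
  expect_error(signal_average(beat_ensemble(list(b, b)),
                              reject_correlation_below = 1.5),
               class = "aiqp_empty_ensemble")
})

test_that("Butterworth band edges show the textbook gains", {
  fs <- 2000
  t <- seq_len(8000) / fs
  gain <- function(freq, zero_phase) {
    x <- sin(2 * pi * freq * t)
    y <- bandpass_filter(x, 40, 250, order = 4, zero_phase = zero_phase, fs = fs)
    core <- 2000:6000  # steady state, away from edges
    rms_of(y[core]) / rms_of(x[core])
  }
  # mid-band: passband gain ~ 1
  fmid <- sqrt(40 * 250)
  expect_lt(abs(gain(fmid, FALSE) - 1), 0.05)
  # cutoff: -3 dB forward, squared (-6 dB) for the zero-phase cascade
  for (fc in c(40, 250)) {
    expect_lt(abs(gain(fc, FALSE) - 1 / sqrt(2)), 0.02 / sqrt(2))
    expect_lt(abs(gain(fc, TRUE) - 1 / 2), 0.02 / 2)
  }
  # DC is rejected
  dc <- bandpass_filter(rep(3, 4000), 40, 250, fs = fs)
  expect_lt(rms_of(dc[2000:4000]), 1e-3)
  expect_error(bandpass_filter(rnorm(100), 250, 40, fs = fs),
               class = "aiqp_invalid_parameter")
})

test_that("zero-phase filtering preserves the peak location of a symmetric pulse", {
  fs <- 2000
  n <- seq_len(1000)
  pulse <- exp(-(n - 500)^2 / (2 * 3^2))
  y <- bandpass_filter(pulse, 40, 250, zero_phase = TRUE, fs = fs)
  expect_lte(abs(which.max(y) - 500), 1)
})

test_that("vector magnitude is the pointwise Euclidean norm", {
  expect_equal(vector_magnitude(3, c(4), 0), 5)
  expect_equal(vector_magnitude(rep(0, 5), rep(0, 5), rep(0, 5)), rep(0, 5))
  x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
  expect_equal(vector_magnitude(x, y, z), vector_magnitude(-x, -y, -z))
  expect_error(vector_magnitude(1:3, 1:3, 1:4), class = "aiqp_invalid_input")
})

test_that("QRS bounds are found at the edges of a sustained pulse", {
  fs <- 2000
  set.seed(8)
  vm <- abs(rnorm(600, sd = 0.5))
  vm[201:400] <- 100
  b <- detect_qrs_bounds(vm, noise_window = c(1, 150), fs = fs)
  expect_equal(b$onset_idx, 201)
  expect_equal(b$offset_idx, 400)
  expect_equal(b$noise_rms, rms_of(vm[1:150]))

  # translation equivariance
  vm2 <- c(abs(rnorm(50, sd = 0.5)), vm)[1:600]
  b2 <- detect_qrs_bounds(vm2, noise_window = c(1, 150), fs = fs)
  expect_equal(b2$onset_idx, 251)

  expect_error(detect_qrs_bounds(abs(rnorm(600, sd = 0.5)),
                                 noise_window = c(1, 150), fs = fs),
               class = "aiqp_no_qrs_detected")
})

test_that("VLP parameters match closed forms on piecewise-constant signals", {
  fs <- 2000
  # constant 100 uV over a 100 ms QRS embedded in zeros
  vm <- rep(0, 600); vm[201:400] <- 100
  v <- vlp_params(vm, 201, 400, fs = fs)
  expect_equal(v$fqrsd_ms, (400 - 201) / fs * 1000)
  expect_equal(v$rms40_uV, 100)
  expect_equal(v$las40_ms, 0)

  # terminal 30 ms at 10 uV, 100 uV before: LAS40 = 30 ms and RMS40 from the
  # piecewise closed form sqrt((10 ms * 100^2 + 30 ms * 10^2) / 40 ms)
  vm2 <- rep(0, 600); vm2[201:340] <- 100; vm2[341:400] <- 10
  v2 <- vlp_params(vm2, 201, 400, fs = fs)
  expect_equal(v2$las40_ms, 30)
  expect_equal(v2$rms40_uV, sqrt((10 * 100^2 + 30 * 10^2) / 40))

  # everywhere below threshold: LAS40 saturates at fQRSD
  vm3 <- rep(0, 600); vm3[201:400] <- 20
  expect_equal(vlp_params(vm3, 201, 400, fs = fs)$las40_ms,
               vlp_params(vm3, 201, 400, fs = fs)$fqrsd_ms)

  expect_error(vlp_params(vm, 10, 50, fs = fs), class = "aiqp_invalid_input")
})

test_that("VLP parameters respond correctly to amplitude scaling", {
  fs <- 2000
  vm <- rep(0, 600); vm[201:340] <- 100; vm[341:400] <- 30
  v1 <- vlp_params(vm, 201, 400, fs = fs)
  v2 <- vlp_params(2 * vm, 201, 400, fs = fs)
  expect_equal(v2$rms40_uV, 2 * v1$rms40_uV)
  # 30 uV terminal segment crosses the 40 uV threshold when doubled
  expect_equal(v1$las40_ms, 30)
  expect_equal(v2$las40_ms, 0)
})
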