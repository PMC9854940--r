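local_peaks <- function(x) which(diff(sign(diff(x))) == -2) + 1

test_that("the synthetic generator places one beat per period", {
  sig <- generate_ecg(60, 10, 500)
  expect_equal(sig$fs, 500)
  expect_length(sig$samples, 5000)
  pk <- local_peaks(sig$samples)
  r_peaks <- pk[sig$samples[pk] > 0.5]
  expect_length(r_peaks, 10)
  expect_equal(unname(sig$samples[r_peaks]), rep(1, 10), tolerance = 0.02)
  # R peaks arrive once per second, centred in each beat interval
  expect_equal(signal_time(sig)[r_peaks], seq(0.5, 9.5), tolerance = 0.01)

  expect_true(all(generate_ecg(60, 2, 500, wave_amplitudes = c(R = 0))$samples
                  == 0))
  expect_identical(generate_ecg(72, 5, 250, seed = 1)$samples,
                   generate_ecg(72, 5, 250, seed = 1)$samples)
  expect_error(generate_ecg(20, 10, 500), "30, 220")
  expect_error(generate_ecg(60, 10, 50), "100 Hz")
})

test_that("baseline, drift and noise are added as declared", {
  sig <- generate_ecg(60, 10, 500)
  shifted <- add_baseline_and_noise(sig, baseline_mean = 3.00,
                                    drift_amplitude = 0, noise_sd = 0)
  expect_equal(shifted$samples, sig$samples + 3.00)

  flat <- ecg_signal(numeric(1e4), fs = 500)
  noisy <- add_baseline_and_noise(flat, baseline_mean = 0, drift_amplitude = 0,
                                  noise_sd = 0.01, seed = 6)
  expect_lt(abs(sd(noisy$samples) / 0.01 - 1), 0.05)
  expect_error(add_baseline_and_noise(sig, noise_sd = -1), ">= 0")
})

test_that("detrending removes ramps and slow wander, preserving fast content", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  ramp <- ecg_signal(0.5 + 0.3 * t, fs)
  out <- detrend_ecg(ramp)
  expect_lt(max(abs(out$samples)), 1e-9)

  sine <- sin(2 * pi * 10 * t)
  mixed <- detrend_ecg(ecg_signal(0.5 + 0.3 * t + sine, fs))
  expect_lt(abs(sd(mixed$samples) / sd(sine) - 1), 0.02)
  expect_lt(abs(mean(mixed$samples)), 1e-6)
  expect_equal(length(mixed$samples), length(t))

  # idempotence on an already-clean signal
  clean <- detrend_ecg(generate_ecg(60, 10, fs))
  again <- detrend_ecg(clean)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(again$samples - clean$samples), 0.02 * rms(clean$samples))
  expect_error(detrend_ecg(ecg_signal(1, fs)), "too short")
})

test_that("the zero-phase low-pass has a flat passband and a real stop band", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  pwr <- function(x) mean(x^2)
  tone40 <- ecg_signal(sin(2 * pi * 40 * t), fs)
  out40 <- lowpass_filter(tone40, cutoff_hz = 30)
  expect_lt(pwr(out40$samples) / pwr(tone40$samples), 0.05)

  tone5 <- ecg_signal(sin(2 * pi * 5 * t), fs)
  out5 <- lowpass_filter(tone5, cutoff_hz = 30)
  expect_lt(abs(pwr(out5$samples) / pwr(tone5$samples) - 1), 0.02)

  const <- ecg_signal(rep(2.5, 1000), fs)
  expect_equal(lowpass_filter(const, 30)$samples, const$samples,
               tolerance = 1e-6)
  expect_equal(out40$fs, fs)
  expect_length(out40$samples, length(t))
  expect_error(lowpass_filter(tone5, 250), "fs/2")
  expect_error(lowpass_filter(tone5, 0), "fs/2")
})

test_that("the two-sided power spectrum obeys its normalisation", {
  fs <- 100
  n <- 1001  # odd length: symmetric frequency grid about zero
  const <- ecg_signal(rep(3, n), fs)
  ps <- power_spectrum(const)
  expect_equal(max(ps$frequencies) + min(ps$frequencies), 0, tolerance = 1e-9)
  at0 <- which(ps$frequencies == 0)
  expect_equal(ps$power[at0], n * 9, tolerance = 1e-6)
  expect_lt(max(ps$power[-at0]), 1e-12 * ps$power[at0])

  t <- (0:(n - 1)) / fs
  tone <- ecg_signal(sin(2 * pi * 10 * t), fs)
  pst <- power_spectrum(tone)
  top2 <- order(pst$power, decreasing = TRUE)[1:2]
  expect_equal(sort(pst$frequencies[top2]), c(-10, 10), tolerance = 0.1)

  # Parseval under the 1/n normalisation
  x <- generate_ecg(60, 10, 500)
  psx <- power_spectrum(x)
  expect_equal(sum(psx$power), sum(x$samples^2), tolerance = 1e-6)
  expect_true(all(psx$power >= 0))
  expect_length(psx$power, length(psx$frequencies))
})

test_that("the spectrogram localises power in time and frequency", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  # stationary white noise: no temporal structure
  wn <- ecg_signal(pdf_sample(pdf_normal(0, 1), length(t), seed = 31), fs)
  sw <- ecg_spectrogram(wn, window_s = 0.25, overlap_fraction = 0.5)
  row_power <- rowSums(sw$power)
  expect_lt(sd(row_power) / mean(row_power), 0.5)
  expect_equal(nrow(sw$power), length(sw$time))
  expect_equal(ncol(sw$power), length(sw$frequencies))

  # frequency step at mid-record moves the dominant column
  chirp <- ecg_signal(ifelse(t < 2, sin(2 * pi * 10 * t),
                             sin(2 * pi * 40 * t)), fs)
  sc <- ecg_spectrogram(chirp, window_s = 0.25, overlap_fraction = 0.5)
  dom <- sc$frequencies[apply(sc$power, 1, which.max)]
  expect_lt(median(dom[sc$time < 1.8]), 15)
  expect_gt(median(dom[sc$time > 2.2]), 35)

  zero <- ecg_signal(numeric(2000), fs)
  expect_true(all(ecg_spectrogram(zero, 0.25, 0.5)$power == 0))
  expect_error(ecg_spectrogram(zero, window_s = 100), "window")
})

test_that("baseline and noise parameters are recovered from synthetic records", {
  sig <- generate_ecg(60, 10, 500)
  corrupted <- add_baseline_and_noise(sig, baseline_mean = 3.00,
                                      drift_amplitude = 0, noise_sd = 0.01,
                                      seed = 1)
  est <- estimate_noise_params(corrupted)
  expect_lt(abs(est[["baseline_mean"]] / 3.00 - 1), 0.01)
  expect_lt(abs(est[["noise_sd"]] / 0.01 - 1), 0.10)

  clean <- add_baseline_and_noise(sig, baseline_mean = 0, drift_amplitude = 0,
                                  noise_sd = 0)
  expect_lt(estimate_noise_params(clean)[["noise_sd"]], 1e-6)

  wn <- ecg_signal(pdf_sample(pdf_normal(0, 0.5), 5000, seed = 17), fs = 500)
  est_wn <- estimate_noise_params(wn)
  expect_lt(abs(est_wn[["baseline_mean"]]), 3 * 0.5 / sqrt(5000))
  expect_lt(abs(est_wn[["noise_sd"]] / 0.5 - 1), 0.10)

  # slow sinusoidal wander shows up as baseline spread, not noise
  wander <- add_baseline_and_noise(sig, baseline_mean = 3.00,
                                   drift_amplitude = 0.2, drift_freq = 0.2,
                                   noise_sd = 0.01, seed = 2)
  est_w <- estimate_noise_params(wander)
  expect_gt(est_w[["baseline_sd"]], 0.05)
  expect_lt(abs(est_w[["noise_sd"]] / 0.01 - 1), 0.15)
  expect_error(estimate_noise_params(generate_ecg(60, 2, 500)), "5 s")
})

test_that("filtering really empties the stop band of white noise", {
  fs <- 500
  wn <- ecg_signal(pdf_sample(pdf_normal(0, 1), 5000, seed = 23), fs)
  filt <- lowpass_filter(wn, cutoff_hz = 30)
  ps <- power_spectrum(filt)
  above <- abs(ps$frequencies) > 30
  expect_lt(sum(ps$power[above]) / sum(ps$power), 0.05)
})

test_that("detrend and low-pass nearly commute on generator output", {
  sig <- add_baseline_and_noise(generate_ecg(60, 10, 500), 3, 0.1, 0.2,
                                0.01, seed = 3)
  a <- lowpass_filter(detrend_ecg(sig), 30)$samples
  b <- detrend_ecg(lowpass_filter(sig, 30))$samples
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(a - b), 0.05 * rms(a))
})

test_that("signals round-trip through the CSV interchange format", {
  path <- withr::local_tempfile(fileext = ".csv")
  sig <- generate_ecg(75, 4, 250)
  write_ecg_csv(sig, path)
  back <- read_ecg_csv(path)
  expect_equal(back$fs, 250, tolerance = 1e-6)
  expect_equal(back$samples, sig$samples, tolerance = 1e-6)
  expect_error(read_ecg_csv(withr::local_tempfile(lines = "a,b\n1,2")),
               "time_s")
})
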