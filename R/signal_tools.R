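#' Sampled ECG-style signal container
#'
#' A plain container: an amplitude vector in millivolts, a sampling rate in
#' Hz and a start time. All signal utilities in the package take and return
#' this class, preserving sampling rate and sample count.
#'
#' @param samples Numeric amplitude vector (mV), non-empty.
#' @param fs Sampling rate (Hz), positive.
#' @param t0 Start time (s).
#' @return An object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, fs, t0 = 0) {
  if (!is.numeric(samples) || !length(samples)) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.3f s), range [%.3g, %.3g] mV\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Time axis of a signal
#' @param sig An [ecg_signal()].
#' @return Numeric vector of sample times (s).
#' @export
signal_time <- function(sig) {
  stopifnot(inherits(sig, "ecg_signal"))
  sig$t0 + (seq_along(sig$samples) - 1) / sig$fs
}

#' @export
as.data.frame.ecg_signal <- function(x, ...) {
  data.frame(time_s = signal_time(x), amplitude_mV = x$samples)
}

#' Read / write a signal as two-column CSV
#'
#' The on-disk format is a header line `time_s,amplitude_mV` followed by one
#' row per sample; the sampling rate is recovered from the median time step.
#'
#' @param path File path.
#' @param sig An [ecg_signal()] (for writing).
#' @return `read_ecg_csv` returns an [ecg_signal()]; `write_ecg_csv` returns
#'   `path` invisibly.
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mV") %in% names(df))) {
    stop("expected columns time_s and amplitude_mV in ", path, call. = FALSE)
  }
  dt <- stats::median(diff(df$time_s))
  if (!is.finite(dt) || dt <= 0) {
    stop("cannot infer a positive sampling interval from ", path,
         call. = FALSE)
  }
  ecg_signal(df$amplitude_mV, fs = 1 / dt, t0 = df$time_s[1])
}

#' @rdname read_ecg_csv
#' @export
write_ecg_csv <- function(sig, path) {
  stopifnot(inherits(sig, "ecg_signal"))
  utils::write.csv(as.data.frame(sig), path, row.names = FALSE)
  invisible(path)
}

#' Generate a clean synthetic ECG waveform
#'
#' Sums Gaussian-shaped P, Q, R, S and T deflections per beat at fixed
#' offsets around each R peak, producing a noiseless, drift-free periodic
#' waveform. R peaks fall at the centre of each beat interval, so a
#' `duration_s`-second record at `heart_rate_bpm` contains exactly
#' `duration_s * heart_rate_bpm / 60` beats (when that product is an
#' integer). This is a morphological stand-in for a recorded ECG, adequate
#' for exercising detrending, filtering and spectral tools — it does not
#' model heart-rate variability or beat-to-beat morphology changes.
#'
#' @param heart_rate_bpm Heart rate, 30–220 beats per minute.
#' @param duration_s Record length (s).
#' @param fs Sampling rate (Hz), at least 100.
#' @param wave_amplitudes Named vector of deflection amplitudes (mV) for
#'   `P`, `Q`, `R`, `S`, `T`.
#' @param seed Unused (the generator is deterministic); accepted so all
#'   generators share one signature.
#' @return An [ecg_signal()].
#' @examples
#' sig <- generate_ecg(60, 10, 500)
#' @export
generate_ecg <- function(heart_rate_bpm = 60, duration_s = 10, fs = 500,
                         wave_amplitudes = c(P = 0.15, Q = -0.10, R = 1.00,
                                             S = -0.25, T = 0.35),
                         seed = NULL) {
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220) {
    stop("`heart_rate_bpm` must lie in [30, 220]", call. = FALSE)
  }
  if (fs < 100) stop("`fs` must be at least 100 Hz", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  waves <- c(P = 0, Q = 0, R = 0, S = 0, T = 0)
  waves[names(wave_amplitudes)] <- wave_amplitudes
  # per-wave offset from the R peak (s) and Gaussian width (s), typical
  # adult morphology at rest
  offsets <- c(P = -0.200, Q = -0.030, R = 0, S = 0.030, T = 0.300)
  widths  <- c(P = 0.025, Q = 0.008, R = 0.010, S = 0.008, T = 0.040)

  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  period <- 60 / heart_rate_bpm
  n_beats <- ceiling(duration_s / period)
  r_times <- (seq_len(n_beats) - 0.5) * period
  x <- numeric(length(t))
  for (k in seq_along(r_times)) {
    for (w in names(waves)) {
      if (waves[[w]] == 0) next
      mu <- r_times[k] + offsets[[w]]
      x <- x + waves[[w]] * exp(-(t - mu)^2 / (2 * widths[[w]]^2))
    }
  }
  ecg_signal(x, fs = fs, t0 = 0)
}

#' Add baseline offset, slow drift and white noise to a signal
#'
#' Models the two environmental corruptions budgeted for the amplifier: a
#' baseline (constant offset plus optional slow sinusoidal wander) and
#' additive white Gaussian noise.
#'
#' @param sig An [ecg_signal()].
#' @param baseline_mean Constant offset (mV).
#' @param drift_amplitude Amplitude of the sinusoidal wander (mV).
#' @param drift_freq Wander frequency (Hz); keep well below 0.5 Hz so the
#'   detrending tools treat it as baseline.
#' @param noise_sd Standard deviation of the white noise (mV), >= 0.
#' @param seed Optional integer seed for the noise draw.
#' @return An [ecg_signal()].
#' @export
add_baseline_and_noise <- function(sig, baseline_mean = 3.00,
                                   drift_amplitude = 0, drift_freq = 0.2,
                                   noise_sd = 0.01, seed = NULL) {
  stopifnot(inherits(sig, "ecg_signal"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  t <- signal_time(sig)
  drift <- if (drift_amplitude != 0) {
    drift_amplitude * sin(2 * pi * drift_freq * t)
  } else 0
  noise <- if (noise_sd > 0) {
    draw <- function() stats::rnorm(length(t), 0, noise_sd)
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  } else 0
  ecg_signal(sig$samples + baseline_mean + drift + noise, sig$fs, sig$t0)
}

# running-median baseline estimate: robust to the brief PQRST deflections
# (which would bias a moving average by the per-beat DC of the waveform)
baseline_trend <- function(x, fs, window_s) {
  k <- min(round(window_s * fs), length(x) - 1)
  k <- max(3, if (k %% 2 == 0) k + 1 else k)
  if (k >= length(x)) k <- length(x) - (1 - length(x) %% 2)
  stats::runmed(x, k, endrule = "median")
}

#' Remove linear trend and slow baseline wander from a signal
#'
#' Subtracts the least-squares linear trend, then a running-median baseline
#' estimate over `baseline_window_s` seconds (default 2 s, i.e. content
#' below about 0.5 Hz, under the cardiac fundamentals), then re-centres so
#' the output mean is zero to within 1e-6 mV. Sample count and sampling
#' rate are preserved.
#'
#' @param sig An [ecg_signal()] with at least 2 samples.
#' @param baseline_window_s Baseline window length (s).
#' @return Detrended [ecg_signal()].
#' @export
detrend_ecg <- function(sig, baseline_window_s = 2) {
  stopifnot(inherits(sig, "ecg_signal"))
  x <- sig$samples
  if (length(x) < 2) stop("signal too short to detrend", call. = FALSE)
  t <- signal_time(sig)
  linfit <- stats::lm.fit(cbind(1, t), x)
  y <- unname(linfit$residuals)
  y <- y - baseline_trend(y, sig$fs, baseline_window_s)
  ecg_signal(y - mean(y), sig$fs, sig$t0)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass (default order 4, 30 Hz cut-off — the
#' noise-removal threshold used for this front-end) forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion, unit DC gain and a
#' flat passband: amplitudes at or below half the cut-off are preserved
#' within 2 %. Length and sampling rate are preserved.
#'
#' @param sig An [ecg_signal()].
#' @param cutoff_hz Cut-off frequency, `0 < cutoff_hz < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered [ecg_signal()].
#' @export
lowpass_filter <- function(sig, cutoff_hz = 30, order = 4) {
  stopifnot(inherits(sig, "ecg_signal"))
  if (cutoff_hz <= 0 || cutoff_hz >= sig$fs / 2) {
    stop("`cutoff_hz` must lie strictly between 0 and fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (sig$fs / 2), type = "low")
  x <- sig$samples
  n <- length(x)
  # odd-symmetric reflection padding tames the forward-backward filter's
  # edge transients (the transient decays over ~fs/cutoff samples)
  npad <- min(n - 1, ceiling(10 * sig$fs / cutoff_hz))
  if (npad >= 1) {
    left <- 2 * x[1] - x[seq(npad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - npad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y <- y[seq(npad + 1, npad + n)]
  } else {
    y <- signal::filtfilt(bf, x)
  }
  ecg_signal(y, sig$fs, sig$t0)
}

#' Two-sided power spectrum centred at zero frequency
#'
#' The squared magnitude of the signal's discrete Fourier transform,
#' normalised by the number of frequency samples and re-ordered so the
#' frequency axis runs from negative to positive through zero. Under this
#' normalisation Parseval's identity reads
#' `sum(power) == sum(samples^2)`, and a constant signal `c` of length `n`
#' carries all its power, `n * c^2`, at zero frequency.
#'
#' @param sig An [ecg_signal()].
#' @return An object of class `spectrum_result` with fields `frequencies`
#'   (Hz) and `power` (mV^2).
#' @export
power_spectrum <- function(sig) {
  stopifnot(inherits(sig, "ecg_signal"))
  x <- sig$samples
  n <- length(x)
  pow <- Mod(stats::fft(x))^2 / n
  k <- seq_len(n) - 1
  f <- k * sig$fs / n
  f[k >= (n + 1) / 2] <- f[k >= (n + 1) / 2] - sig$fs
  ord <- order(f)
  structure(list(frequencies = f[ord], power = pow[ord], fs = sig$fs),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  pk <- which.max(x$power)
  cat(sprintf("<spectrum_result> %d bins, %g Hz resolution, peak %.4g mV^2 at %.3g Hz\n",
              length(x$power), x$fs / length(x$power), x$power[pk],
              x$frequencies[pk]))
  invisible(x)
}

#' Short-time power spectrogram
#'
#' Power spectra on a sliding Hann window ([signal::specgram()]), one-sided
#' in frequency, squared magnitude normalised by the window length so each
#' row is comparable with [power_spectrum()] of its segment. Rows index
#' time, columns index frequency.
#'
#' @param sig An [ecg_signal()].
#' @param window_s Window length (s), shorter than the signal.
#' @param overlap_fraction Fractional window overlap in `[0, 1)`.
#' @return An object of class `ecg_spectrogram` with fields `time` (s,
#'   window centres), `frequencies` (Hz) and `power` (time x frequency
#'   matrix, mV^2).
#' @export
ecg_spectrogram <- function(sig, window_s = 0.25, overlap_fraction = 0.5) {
  stopifnot(inherits(sig, "ecg_signal"))
  n <- length(sig$samples)
  nw <- round(window_s * sig$fs)
  if (nw < 4 || nw > n) {
    stop("`window_s` must give a window of at least 4 samples and no longer than the signal",
         call. = FALSE)
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must lie in [0, 1)", call. = FALSE)
  }
  sg <- signal::specgram(sig$samples, n = nw, Fs = sig$fs,
                         overlap = floor(nw * overlap_fraction))
  structure(
    list(time = sig$t0 + as.numeric(sg$t),
         frequencies = as.numeric(sg$f),
         power = t(Mod(sg$S)^2) / nw,
         fs = sig$fs, window_s = nw / sig$fs),
    class = "ecg_spectrogram"
  )
}

#' @export
print.ecg_spectrogram <- function(x, ...) {
  cat(sprintf("<ecg_spectrogram> %d windows (%.3g s each) x %d frequency bins up to %g Hz\n",
              nrow(x$power), x$window_s, ncol(x$power), max(x$frequencies)))
  invisible(x)
}

# mean white-noise power transfer of (identity - zero-phase lowpass); used
# to rescale an out-of-band residual sd to the full band
residual_bandwidth_factor <- function(fs, cutoff_hz, order) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  h <- signal::freqz(bf, n = 2048, Fs = fs)
  mean((1 - Mod(h$h)^2)^2)
}

# robust scale of the stop-band residual: a first-pass MAD flags burst
# samples (QRS spectral leakage), the flag is dilated by +-mask_s so the
# correlated leakage around each burst is excluded too, and the MAD is
# recomputed on the quiet samples
masked_residual_scale <- function(resid, fs, mask_s = 0.05) {
  r0 <- resid - stats::median(resid)
  s1 <- stats::mad(r0)
  if (s1 == 0) return(0)
  idx <- which(abs(r0) > 3 * s1)
  keep <- rep(TRUE, length(r0))
  if (length(idx)) {
    w <- round(mask_s * fs)
    for (i in idx) keep[max(1, i - w):min(length(r0), i + w)] <- FALSE
  }
  if (!any(keep)) return(s1)
  stats::mad(r0[keep])
}

#' Estimate baseline and noise parameters of a recorded signal
#'
#' Decomposes a signal into a slow baseline and a broadband noise residual
#' and reports the statistics the amplifier's uncertainty model needs:
#'
#' * baseline: mean and standard deviation of the running-median trend over
#'   `baseline_window_s` seconds (content below about 0.5 Hz; the median is
#'   robust to the brief PQRST deflections);
#' * noise: the residual above the `noise_cutoff_hz` zero-phase low-pass.
#'   QRS complexes genuinely contain energy above 30 Hz, so the residual is
#'   summarised by a two-pass robust scale: a first-pass median absolute
#'   deviation flags burst samples, the flag is dilated by 50 ms to cover
#'   the correlated leakage around each burst, and the MAD is recomputed on
#'   the remaining quiet samples. That scale is then rescaled by the
#'   filter's white-noise residual bandwidth (computed from its frequency
#'   response) so the returned value estimates the full-band standard
#'   deviation of spectrally flat noise.
#'
#' @param sig An [ecg_signal()] of at least 5 s.
#' @param baseline_window_s Baseline window (s), default 2.
#' @param noise_cutoff_hz Noise boundary (Hz), default 30.
#' @return Named numeric vector `c(baseline_mean, baseline_sd, noise_sd)`
#'   in mV.
#' @examples
#' sig <- add_baseline_and_noise(generate_ecg(60, 10, 500),
#'                               baseline_mean = 3, noise_sd = 0.01, seed = 1)
#' estimate_noise_params(sig)
#' @export
estimate_noise_params <- function(sig, baseline_window_s = 2,
                                  noise_cutoff_hz = 30) {
  stopifnot(inherits(sig, "ecg_signal"))
  if (length(sig$samples) / sig$fs < 5) {
    stop("signal must be at least 5 s long", call. = FALSE)
  }
  trend <- baseline_trend(sig$samples, sig$fs, baseline_window_s)
  resid <- sig$samples - lowpass_filter(sig, noise_cutoff_hz)$samples
  rho <- residual_bandwidth_factor(sig$fs, noise_cutoff_hz, order = 4)
  c(baseline_mean = mean(trend),
    baseline_sd = stats::sd(trend),
    noise_sd = masked_residual_scale(resid, sig$fs) / sqrt(rho))
}
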