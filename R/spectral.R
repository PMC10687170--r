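# Spectral preprocessing of LFP: line-noise notch filtering, complex
# Morlet wavelet spectrograms on a logarithmic 1-200 Hz axis, 100 ms /
# 50 ms window averaging (bins labeled with their end time), and
# per-frequency z-scoring of log power over the whole recording session.

#' Design and apply a zero-phase 60 Hz comb notch filter
#'
#' One biquad IIR notch per harmonic of the fundamental up to Nyquist,
#' with the bandwidth at the -1 dB point set to \code{bandwidth} (3 Hz by
#' default). The zero-phase (forward-backward) response -- the squared
#' magnitude of the designed biquad cascade -- is applied in the
#' frequency domain on a reflection-padded copy of the signal, which
#' realizes the ideal filtfilt response without its edge transients.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate, Hz (> 120).
#' @param fundamental line frequency, Hz (default 60).
#' @param bandwidth -1 dB bandwidth, Hz (default 3).
#' @return filtered signal.
#' @export
notch_filter <- function(x, sample_rate, fundamental = 60, bandwidth = 3) {
  if (sample_rate <= 2 * fundamental)
    stop("sample_rate must exceed twice the fundamental")
  harmonics <- seq(fundamental, sample_rate / 2 - bandwidth,
                   by = fundamental)
  filters <- lapply(harmonics, design_notch, fs = sample_rate,
                    bandwidth = bandwidth)
  n <- length(x)
  pad <- min(n, ceiling(2 * sample_rate / bandwidth))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1]))
  np <- stats::nextn(length(xp))
  xp <- c(xp, numeric(np - length(xp)))
  w <- 2 * pi * (0:(np - 1)) / np
  gain <- rep(1, np)
  for (ba in filters) {
    z <- exp(-1i * w)
    h <- (ba$b[1] + ba$b[2] * z + ba$b[3] * z^2) /
      (ba$a[1] + ba$a[2] * z + ba$a[3] * z^2)
    gain <- gain * Mod(h)^2          # forward-backward: |H|^2, zero phase
  }
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / np
  y[pad + seq_len(n)]
}

# Biquad notch with specified -1 dB bandwidth: pole radius solved so the
# single-pass magnitude at f0 +- bandwidth/2 is exactly -1 dB.
design_notch <- function(f0, fs, bandwidth, db_point = 1) {
  w0 <- 2 * pi * f0 / fs
  target <- 10^(-db_point / 10)
  gain2 <- function(r, w) {
    b0 <- (1 - 2 * r * cos(w0) + r^2) / (2 - 2 * cos(w0))
    z <- exp(1i * w)
    h <- b0 * (1 - 2 * cos(w0) / z + 1 / z^2) /
      (1 - 2 * r * cos(w0) / z + r^2 / z^2)
    Mod(h)^2
  }
  we <- 2 * pi * (f0 + bandwidth / 2) / fs
  r <- stats::uniroot(function(r) gain2(r, we) - target,
                      c(0.5, 1 - 1e-9), tol = 1e-12)$root
  b0 <- (1 - 2 * r * cos(w0) + r^2) / (2 - 2 * cos(w0))
  list(b = b0 * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * r * cos(w0), r^2))
}

#' Logarithmic frequency axis covering a band
#'
#' Log2-spaced bin centers from \code{fmin} to \code{fmax} inclusive, with
#' approximately \code{bins_per_octave} bins per octave (the spacing is
#' adjusted so both endpoints are hit exactly).
#'
#' @param fmin,fmax band edges, Hz.
#' @param bins_per_octave target bin density (default 12, making the
#'   one-octave cluster size filter about 12 bins).
#' @return numeric vector of frequencies, Hz.
#' @export
cwt_freqs <- function(fmin = 1, fmax = 200, bins_per_octave = 12) {
  n <- ceiling(log2(fmax / fmin) * bins_per_octave) + 1
  2^seq(log2(fmin), log2(fmax), length.out = n)
}

#' Complex Morlet continuous wavelet transform (instantaneous power)
#'
#' FFT-based CWT with the analytic Morlet wavelet at default radian
#' frequency \code{omega0 = 6}; scales are mapped to center frequencies by
#' the standard Fourier factor. Wavelets are L2-normalized so white noise
#' yields flat expected power across frequencies. The signal is
#' reflect-padded at both ends to reduce edge effects; samples inside the
#' cone of influence of the padding are still returned (flagged via the
#' \code{"coi"} attribute, the e-folding time per frequency in seconds).
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate, Hz.
#' @param freqs analysis frequencies, Hz (must lie in (0, Nyquist)).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @return matrix (time x frequency) of instantaneous power (squared
#'   modulus of the wavelet coefficients).
#' @export
morlet_cwt <- function(x, sample_rate, freqs = cwt_freqs(), omega0 = 6) {
  if (any(freqs <= 0 | freqs >= sample_rate / 2))
    stop("freqs must lie strictly inside (0, Nyquist)")
  n <- length(x)
  dt <- 1 / sample_rate
  fourier_factor <- (4 * pi) / (omega0 + sqrt(2 + omega0^2))
  scales <- 1 / (fourier_factor * freqs)       # seconds
  pad <- min(n, ceiling(2 * sqrt(2) * max(scales) / dt))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1]))
  np <- stats::nextn(length(xp))
  xp <- c(xp, numeric(np - length(xp)))
  X <- stats::fft(xp)
  k <- 0:(np - 1)
  wk <- 2 * pi * ifelse(k <= np / 2, k, k - np) / (np * dt)
  pow <- matrix(0, n, length(freqs))
  for (j in seq_along(freqs)) {
    s <- scales[j]
    psi <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-((s * wk - omega0)^2) / 2) * (wk > 0)
    w <- stats::fft(X * psi, inverse = TRUE) / np
    w <- w[pad + seq_len(n)]
    pow[, j] <- Mod(w)^2
  }
  colnames(pow) <- signif(freqs, 6)
  attr(pow, "freqs") <- freqs
  attr(pow, "coi") <- sqrt(2) * scales
  pow
}

#' Average power into overlapping time bins
#'
#' Bins of \code{window} seconds every \code{step} seconds; each output
#' bin is the linear mean of the power samples in its window and is
#' labeled with the window's last time index.
#'
#' @param power matrix (time samples x frequency).
#' @param sample_rate sampling rate, Hz.
#' @param window,step window length and hop, seconds (defaults 0.1, 0.05).
#' @return list with \code{power} (bins x frequency) and \code{times}
#'   (bin end-time labels, seconds from recording start).
#' @export
window_average <- function(power, sample_rate, window = 0.1, step = 0.05) {
  win_n <- round(window * sample_rate)
  step_n <- round(step * sample_rate)
  if (win_n < 1) stop("window shorter than one sample")
  n <- nrow(power)
  starts <- seq(1, n - win_n + 1, by = step_n)
  cs <- apply(power, 2, function(col) cumsum(c(0, col)))
  binned <- (cs[starts + win_n, , drop = FALSE] -
               cs[starts, , drop = FALSE]) / win_n
  times <- (starts - 1 + win_n) / sample_rate
  list(power = binned, times = times)
}

#' Z-score natural-log power per frequency bin over the session
#'
#' Equalizes the weight of all frequency bins: for each frequency,
#' \code{z = (ln p - mean) / sd} with mean and sd taken over the entire
#' recording session. Non-positive power is floored at machine epsilon.
#'
#' @param binned matrix (bins x frequency) of linear power.
#' @return list with \code{power_z} and \code{stats} (per-frequency
#'   \code{mean} and \code{sd} of log power, reusable for un-normalizing).
#' @export
normalize_log_z <- function(binned) {
  lp <- log(pmax(binned, .Machine$double.eps))
  mu <- colMeans(lp)
  sd <- apply(lp, 2, stats::sd)
  sd[sd == 0] <- 1
  z <- sweep(sweep(lp, 2, mu), 2, sd, "/")
  list(power_z = z, stats = list(mean = mu, sd = sd))
}

#' Extract epoch-locked trials from a session spectrogram
#'
#' Collects, for every listed trial, the time bins whose end labels fall
#' in \code{window} seconds relative to the trial's onset of the named
#' epoch, producing a trials x times x frequencies array aligned with the
#' behavioral trial table.
#'
#' @param power_z matrix (bins x frequency), session-normalized power.
#' @param times bin end-time labels, seconds.
#' @param events event data frame (columns trial, epoch, onset) as
#'   produced by \code{\link{synthesize_lfp}}.
#' @param epoch epoch name to lock to.
#' @param window c(t0, t1) seconds relative to epoch onset.
#' @param trials_keep trial indices to retain (e.g., completed trials);
#'   default all trials present in \code{events}.
#' @param freqs frequency axis (Hz) carried into the result.
#' @param channel_id carried into the result.
#' @param win_len,step the averaging window length and hop used upstream
#'   (needed to place the first full bin), seconds.
#' @return list of class \code{spectrogram_set}: \code{power_z} (trials x
#'   times x freqs), \code{times} (bin labels relative to onset),
#'   \code{freqs}, \code{epoch}, \code{channel_id}.
#' @export
epoch_lock <- function(power_z, times, events, epoch, window,
                       trials_keep = NULL, freqs = NULL, channel_id = NA,
                       win_len = 0.1, step = 0.05) {
  ev <- events[events$epoch == epoch, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events for epoch ", epoch)
  if (is.null(trials_keep)) trials_keep <- ev$trial
  ev <- ev[ev$trial %in% trials_keep, , drop = FALSE]
  span <- window[2] - window[1]
  if (span >= win_len) {
    # count bins from the realized labels of the first event, so slight
    # rounding of the hop size at awkward sample rates cannot misalign
    count <- sum(times >= ev$onset[1] + window[1] + win_len - 1e-9 &
                   times <= ev$onset[1] + window[2] + 1e-9)
    if (count < 1) stop("epoch window holds no complete time bin")
  } else {
    count <- 1
  }
  idx <- lapply(ev$onset, function(on) {
    if (span >= win_len) {
      i0 <- which(times >= on + window[1] + win_len - 1e-9)[1]
    } else {
      i0 <- which.min(abs(times - (on + window[2])))
    }
    if (is.na(i0) || i0 + count - 1 > length(times))
      stop("epoch window extends outside the recording")
    i0:(i0 + count - 1)
  })
  arr <- array(NA_real_, dim = c(nrow(ev), count, ncol(power_z)))
  for (i in seq_along(idx)) arr[i, , ] <- power_z[idx[[i]], , drop = FALSE]
  rel_times <- times[idx[[1]]] - ev$onset[1]
  structure(list(power_z = arr, times = rel_times, freqs = freqs,
                 epoch = epoch, channel_id = channel_id,
                 trials = ev$trial),
            class = "spectrogram_set")
}

#' Full preprocessing chain for one channel
#'
#' Notch filter, Morlet CWT, window averaging, session-wide log-z
#' normalization, and epoch locking for every epoch in the recording's
#' layout.
#'
#' @param rec an \code{lfp_recording}.
#' @param channel channel id (column of \code{rec$data}).
#' @param freqs analysis frequencies (default \code{cwt_freqs()} clipped
#'   below Nyquist).
#' @param trials_keep trial indices to retain after epoching.
#' @param window,step averaging window and hop, seconds.
#' @param notch apply the line-noise notch (default TRUE).
#' @param omega0 Morlet parameter.
#' @return named list of \code{spectrogram_set}, one per epoch, plus
#'   attribute \code{"session_stats"} (the normalization statistics).
#' @export
preprocess_channel <- function(rec, channel, freqs = NULL,
                               trials_keep = NULL, window = 0.1,
                               step = 0.05, notch = TRUE, omega0 = 6) {
  fs <- rec$sample_rate
  if (is.null(freqs)) {
    f <- cwt_freqs()
    freqs <- f[f < fs / 2 / 1.05]
  }
  x <- rec$data[, channel]
  if (notch) x <- notch_filter(x, fs)
  pow <- morlet_cwt(x, fs, freqs, omega0 = omega0)
  wa <- window_average(pow, fs, window = window, step = step)
  nz <- normalize_log_z(wa$power)
  out <- lapply(names(rec$epoch_layout), function(ep) {
    epoch_lock(nz$power_z, wa$times, rec$events, ep,
               window = c(0, rec$epoch_layout[[ep]]),
               trials_keep = trials_keep, freqs = freqs,
               channel_id = channel, win_len = window, step = step)
  })
  names(out) <- names(rec$epoch_layout)
  attr(out, "session_stats") <- nz$stats
  out
}
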