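# Synthetic multichannel LFP with controlled internal-state encoding.
#
# The generator is minimal-sufficient for the analysis chain: 1/f-colored
# background noise, a 60 Hz line component, and band-limited noise bursts
# in chosen (epoch, time-window, frequency-band) slots whose trial-to-trial
# amplitude is an affine function of a z-scored internal state. No
# biophysical realism beyond that statistical structure is attempted.

#' Specification of a synthetic LFP recording
#'
#' @param channels data frame with columns \code{channel_id},
#'   \code{region}, \code{network}.
#' @param sample_rate sampling rate, Hz (the recording system's 2000 Hz by
#'   default; tests use lower rates).
#' @param epoch_layout named numeric vector of epoch durations in seconds,
#'   names a subset of \code{\link{TASK_EPOCHS}} in task order. Epoch
#'   durations are a task-configuration choice (0.6 s placeholders by
#'   default).
#' @param encoding_targets list of targets; each a list with
#'   \code{region}, \code{epochs} (character), \code{time_window} (c(t0,
#'   t1) seconds within epoch), \code{freq_band} (c(f1, f2) Hz within
#'   [1, 200]), \code{state} ("error" or "perturbed"), \code{gain}
#'   (dimensionless modulation depth), and optionally \code{base_amp}
#'   (burst amplitude at state 0, in background-sd units; default 1).
#' @param one_over_f_exponent spectral exponent of the background.
#' @param line_amp amplitude of the 60 Hz line component (background-sd
#'   units).
#' @return list of class \code{lfp_spec}.
#' @export
lfp_spec <- function(channels, sample_rate = 2000,
                     epoch_layout = stats::setNames(rep(0.6, 8), TASK_EPOCHS),
                     encoding_targets = list(),
                     one_over_f_exponent = 1, line_amp = 1) {
  stopifnot(all(c("channel_id", "region", "network") %in% names(channels)),
            all(names(epoch_layout) %in% TASK_EPOCHS),
            sample_rate > 0)
  for (tg in encoding_targets) {
    stopifnot(all(tg$epochs %in% names(epoch_layout)))
    if (tg$freq_band[1] < 1 || tg$freq_band[2] > 200 ||
        tg$freq_band[2] >= sample_rate / 2)
      stop("encoding band outside analyzable range")
  }
  structure(list(channels = channels, sample_rate = sample_rate,
                 epoch_layout = epoch_layout,
                 encoding_targets = encoding_targets,
                 one_over_f_exponent = one_over_f_exponent,
                 line_amp = line_amp),
            class = "lfp_spec")
}

# 1/f^a colored noise with unit sd, via spectral shaping of white noise.
colored_noise <- function(n, exponent) {
  if (n < 4) return(stats::rnorm(n))
  wh <- stats::fft(stats::rnorm(n))
  k <- c(1, seq_len(n - 1))          # DC handled separately
  f <- pmin(k, n - k)                # symmetric frequency index
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(wh * shape, inverse = TRUE)) / n
  as.vector(scale(x))
}

# Tukey (tapered cosine) window: flat center, cosine ramps of fraction
# a/2 at each end.
tukey_window <- function(n, a = 0.25) {
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < a / 2
  hi <- x > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / a - 1)))
  w
}

# Band-limited unit-sd noise via FFT masking.
band_noise <- function(n, fs, band) {
  wh <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(stats::fft(wh * mask, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

#' Synthesize a multichannel LFP recording for one session
#'
#' Trials are laid out back-to-back; each trial contains the epochs of the
#' spec's layout in task order. Each channel receives 1/f background
#' noise, a 60 Hz line component, and -- for every encoding target whose
#' region matches the channel -- a band-limited burst in the target's
#' time-frequency slot on every completed trial, with amplitude
#' \code{base_amp * (1 + gain * state_z)} (floored at 0) where
#' \code{state_z} is the trial's z-scored target state.
#'
#' @param trials a \code{trial_table} (completed trials define the state
#'   series; incomplete trials still occupy recording time).
#' @param states list with elements \code{error} and \code{perturbed}:
#'   z-scored state values per completed trial (e.g., from
#'   \code{\link{evolve_states}} on the generating parameters).
#' @param spec an \code{lfp_spec}.
#' @param seed integer seed.
#' @return list of class \code{lfp_recording}: \code{data} (samples x
#'   channels matrix), \code{sample_rate}, \code{channels},
#'   \code{events} (data frame: trial, epoch, onset seconds),
#'   \code{trial_duration}.
#' @export
synthesize_lfp <- function(trials, states, spec, seed = 1L) {
  set.seed(seed)
  fs <- spec$sample_rate
  durs <- spec$epoch_layout
  trial_dur <- sum(durs)
  n_trials <- nrow(trials)
  n_per_trial <- round(trial_dur * fs)
  n_total <- n_per_trial * n_trials
  epoch_offsets <- cumsum(c(0, utils::head(durs, -1)))
  names(epoch_offsets) <- names(durs)

  events <- do.call(rbind, lapply(seq_len(n_trials), function(tr) {
    data.frame(trial = tr, epoch = names(durs),
               onset = (tr - 1) * trial_dur + epoch_offsets,
               stringsAsFactors = FALSE)
  }))
  rownames(events) <- NULL

  comp_idx <- which(trials$completed)
  tvec <- (seq_len(n_total) - 1) / fs
  nch <- nrow(spec$channels)
  data <- matrix(0, n_total, nch)
  colnames(data) <- spec$channels$channel_id

  for (ci in seq_len(nch)) {
    # Background is generated independently per trial segment so that
    # trials are exchangeable -- the assumption the downstream permutation
    # test relies on. Session-long 1/f noise would induce across-trial
    # power autocorrelation that real permutation inference must handle
    # by other means (see the vignette's limitations).
    sig <- as.vector(vapply(seq_len(n_trials), function(tr)
      colored_noise(n_per_trial, spec$one_over_f_exponent),
      numeric(n_per_trial)))
    sig <- sig + spec$line_amp * sin(2 * pi * 60 * tvec +
                                       stats::runif(1, 0, 2 * pi))
    for (tg in spec$encoding_targets) {
      if (tg$region != spec$channels$region[ci]) next
      base_amp <- tg$base_amp %||% 1
      z <- switch(tg$state, error = states$error,
                  perturbed = states$perturbed,
                  stop("unknown state name: ", tg$state))
      for (ep in tg$epochs) {
        for (k in seq_along(comp_idx)) {
          tr <- comp_idx[k]
          t0 <- (tr - 1) * trial_dur + epoch_offsets[[ep]] + tg$time_window[1]
          t1 <- (tr - 1) * trial_dur + epoch_offsets[[ep]] + tg$time_window[2]
          i0 <- round(t0 * fs) + 1
          i1 <- min(round(t1 * fs), n_total)
          nb <- i1 - i0 + 1
          if (nb < 4) next
          amp <- max(base_amp * (1 + tg$gain * z[k]), 0)
          taper <- tukey_window(nb, 0.25)
          sig[i0:i1] <- sig[i0:i1] +
            amp * taper * band_noise(nb, fs, tg$freq_band)
        }
      }
    }
    data[, ci] <- sig
  }
  structure(list(data = data, sample_rate = fs,
                 channels = spec$channels, events = events,
                 trial_duration = trial_dur, epoch_layout = durs),
            class = "lfp_recording")
}

#' Write / read an LFP recording as raw binary plus JSON sidecar
#'
#' Samples are stored as little-endian float64 (channels interleaved by
#' column); the sidecar carries sample rate, channel table, epoch layout,
#' and event markers.
#'
#' @param rec an \code{lfp_recording}.
#' @param path base path; writes \code{<path>.dat} and \code{<path>.json}.
#' @export
write_lfp <- function(rec, path) {
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(sample_rate = rec$sample_rate, n_samples = nrow(rec$data),
               channels = rec$channels, events = rec$events,
               trial_duration = rec$trial_duration,
               epoch_layout = as.list(rec$epoch_layout))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_samples * nrow(meta$channels)
  con <- file(paste0(path, ".dat"), "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  data <- matrix(x, nrow = meta$n_samples)
  colnames(data) <- meta$channels$channel_id
  structure(list(data = data, sample_rate = meta$sample_rate,
                 channels = meta$channels, events = meta$events,
                 trial_duration = meta$trial_duration,
                 epoch_layout = unlist(meta$epoch_layout)),
            class = "lfp_recording")
}
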