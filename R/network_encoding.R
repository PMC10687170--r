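# Encoding strength and connectivity strength from cluster-group windows.
#
# A cluster group's trial-wise signal for a channel is the mean normalized
# power over the group's time-frequency window, averaged over the epochs
# it spans. Encoding strength is the subject-level mean over channels of
# the |Spearman| correlation between that signal and the internal state;
# connectivity strength is the |Spearman| correlation between two
# channels' signals, averaged to the subject level and Fisher-averaged to
# the population level.

#' Trial-wise mean power of a cluster-group window for one channel
#'
#' @param spects named list of \code{spectrogram_set} (or arrays) for the
#'   epochs the group spans, all for one channel and aligned on trials.
#' @param mask logical times x freqs matrix (the group's window), or a
#'   list of masks parallel to \code{spects}.
#' @return numeric vector, one value per trial (mean power over the
#'   masked pixels, averaged across the spanned epochs).
#' @export
trial_power_series <- function(spects, mask) {
  masks <- if (is.list(mask)) mask else rep(list(mask), length(spects))
  per_epoch <- mapply(function(sp, m) {
    arr <- spect_array(sp)
    flat <- matrix(arr, nrow = dim(arr)[1])
    rowMeans(flat[, as.vector(m), drop = FALSE])
  }, spects, masks, SIMPLIFY = TRUE)
  rowMeans(as.matrix(per_epoch))
}

#' Encoding strength of a cluster group for one subject
#'
#' Per channel, the magnitude of the Spearman correlation between the
#' channel's trial-wise cluster-window power and the internal state;
#' averaged across the subject's channels. Lies in [0, 1].
#'
#' @param series_by_channel list of per-trial power series (one per
#'   channel).
#' @param state per-trial internal-state values.
#' @return scalar in [0, 1].
#' @export
encoding_strength <- function(series_by_channel, state) {
  if (length(series_by_channel) < 1) stop("need >= 1 channel")
  n <- length(state)
  if (n < 10) stop("need >= 10 trials")
  mags <- vapply(series_by_channel, function(v) {
    if (length(v) != n) stop("trial-length mismatch")
    if (stats::sd(v) == 0) stop("constant power series")
    abs(stats::cor(v, state, method = "spearman"))
  }, numeric(1))
  mean(mags)
}

#' Performance-based selection of encoding regions
#'
#' Correlates a cluster group's per-subject encoding strengths with
#' session performance across subjects. A region is selected when the
#' two-tailed Pearson correlation magnitude exceeds \code{r_thresh} or
#' its p-value is below \code{p_thresh}, and the cohort is represented on
#' both sides of the average performance (at least \code{min_per_side}
#' subject(s) strictly above and strictly below it).
#'
#' @param strengths per-subject encoding strengths.
#' @param performances session performance per subject, percent (0-100).
#' @param mean_performance cohort average performance used for the
#'   representation rule (default: mean of \code{performances}).
#' @param r_thresh,p_thresh selection thresholds (defaults 0.75 and 0.05).
#' @param min_per_side subjects required strictly above and below the
#'   average (default 1; set 2 for the stricter variant).
#' @return list with \code{performance_r}, \code{performance_p},
#'   \code{represented}, \code{selected}, \code{n_subjects}.
#' @export
select_performance_regions <- function(strengths, performances,
                                       mean_performance = NULL,
                                       r_thresh = 0.75, p_thresh = 0.05,
                                       min_per_side = 1) {
  n <- length(strengths)
  if (n < 3) stop("performance selection needs >= 3 subjects")
  if (length(performances) != n) stop("length mismatch")
  mp <- mean_performance %||% mean(performances)
  ct <- stats::cor.test(strengths, performances, method = "pearson")
  represented <- sum(performances > mp) >= min_per_side &&
    sum(performances < mp) >= min_per_side
  list(performance_r = unname(ct$estimate),
       performance_p = ct$p.value,
       represented = represented,
       selected = represented &&
         (abs(ct$estimate) > r_thresh || ct$p.value < p_thresh),
       n_subjects = n)
}

#' Channel-level connectivity: |Spearman| between trial power series
#'
#' @param series_a,series_b lists of per-trial power series (channels of
#'   region A and region B, aligned on trials).
#' @param method "spearman" (default) or "pearson" (zero-lag
#'   cross-correlation).
#' @return matrix of correlation magnitudes, channels of A x channels of
#'   B. Same-channel (autocorrelation) entries are the caller's job to
#'   exclude from averages.
#' @export
channel_connectivity <- function(series_a, series_b,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  na <- unique(vapply(c(series_a, series_b), length, integer(1)))
  if (length(na) != 1) stop("trial-length mismatch between channels")
  A <- do.call(cbind, series_a)
  B <- do.call(cbind, series_b)
  abs(stats::cor(A, B, method = method))
}

#' Subject connectivity strength: mean over unique channel pairs
#'
#' Averages the channel connectivity magnitudes over unique pairs,
#' excluding the diagonal (autocorrelations) when the two channel sets
#' are the same region.
#'
#' @param mat channel connectivity matrix.
#' @param same_region TRUE when rows and columns are the same channel
#'   set, so the diagonal and duplicate (i, j)/(j, i) entries are
#'   excluded.
#' @return scalar in [0, 1].
#' @export
subject_connectivity <- function(mat, same_region = FALSE) {
  if (same_region) {
    if (nrow(mat) < 2) stop("within-region connectivity needs >= 2 channels")
    mean(mat[upper.tri(mat)])
  } else {
    mean(mat)
  }
}

#' Performance connectivity strength for a region pair
#'
#' Pearson correlation across subjects between subject connectivity
#' strength and session performance. Requires at least
#' \code{min_subjects} subjects and representation above and below the
#' average performance; the stored value is always the full correlation,
#' and \code{exported} marks whether it clears the positive-edge
#' truncation threshold used for graph display (> 0.5).
#'
#' @param strengths per-subject connectivity strengths.
#' @param performances session performance per subject, percent.
#' @param mean_performance cohort average for the representation rule.
#' @param min_subjects minimum cohort size (default 3).
#' @param truncation graph-export threshold (default 0.5).
#' @return list with \code{performance_r}, \code{performance_p},
#'   \code{evaluable}, \code{exported}, \code{n_subjects}.
#' @export
performance_connectivity <- function(strengths, performances,
                                     mean_performance = NULL,
                                     min_subjects = 3, truncation = 0.5) {
  n <- length(strengths)
  mp <- mean_performance %||% mean(performances)
  represented <- any(performances > mp) && any(performances < mp)
  if (n < min_subjects || !represented) {
    return(list(performance_r = NA_real_, performance_p = NA_real_,
                evaluable = FALSE, exported = FALSE, n_subjects = n))
  }
  ct <- stats::cor.test(strengths, performances, method = "pearson")
  list(performance_r = unname(ct$estimate), performance_p = ct$p.value,
       evaluable = TRUE,
       exported = unname(ct$estimate) > truncation,
       n_subjects = n)
}

#' Population connectivity strength via Fisher-z averaging
#'
#' Transforms subject connectivity strengths with Fisher's z
#' (\code{atanh}), averages across subjects, and transforms back.
#' Strengths at or above 1 - 1e-7 are clamped before the transform.
#'
#' @param strengths per-subject connectivity strengths in [0, 1].
#' @return scalar in [0, 1).
#' @export
population_connectivity <- function(strengths) {
  if (length(strengths) < 2)
    stop("population connectivity needs >= 2 subjects")
  s <- pmin(pmax(strengths, 0), 1 - 1e-7)
  tanh(mean(atanh(s)))
}
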