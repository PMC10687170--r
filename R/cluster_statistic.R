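# Hierarchical non-parametric cluster statistic: where in time-frequency
# does a region's power covary with an internal state across trials, at
# the population level?
#
# Per channel, each spectrogram pixel gets the t-statistic of the Spearman
# correlation between state and power across trials. Channel maps are
# averaged hierarchically (channels within subject, then subjects).
# Supra-threshold pixels form 4-connected clusters scored by their mass
# (sum of the averaged t); significance comes from a two-tailed
# permutation test that shuffles the state's trial order within each
# subject (identically across that subject's channels) and records the
# maximum absolute cluster mass per permutation.

T_CAP <- 1e6  # sentinel for |rho| = 1

FREQ_BANDS <- data.frame(
  band = c("delta", "theta", "alpha", "beta", "low gamma", "high gamma",
           "hyper gamma"),
  lo = c(1, 4, 8, 15, 30, 60, 100),
  hi = c(4, 8, 15, 30, 60, 100, 200),
  stringsAsFactors = FALSE
)

#' Map a frequency (Hz) to its canonical band label
#' @param f frequency or vector of frequencies, Hz.
#' @return character vector of band names.
#' @export
frequency_band <- function(f) {
  idx <- findInterval(f, c(FREQ_BANDS$lo, Inf), rightmost.closed = FALSE)
  idx[f >= 200] <- nrow(FREQ_BANDS)
  idx[idx < 1] <- 1
  FREQ_BANDS$band[pmin(idx, nrow(FREQ_BANDS))]
}

spect_array <- function(x) if (inherits(x, "spectrogram_set")) x$power_z else x

rho_to_t <- function(rho, n) {
  rho <- pmin(pmax(rho, -1), 1)
  t <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  t[abs(rho) >= 1 - 1e-12] <- sign(rho[abs(rho) >= 1 - 1e-12]) * T_CAP
  pmin(pmax(t, -T_CAP), T_CAP)
}

#' Per-channel t-map of Spearman state-power correlation
#'
#' For every time-frequency pixel, the Spearman correlation across trials
#' between the internal state and normalized power, transformed to the
#' t-statistic \code{t = rho * sqrt((n - 2) / (1 - rho^2))} (perfect
#' correlations are capped at a large finite sentinel).
#'
#' @param spect a \code{spectrogram_set} or a trials x times x freqs array.
#' @param state per-trial state values (z-scored), length = trials.
#' @return times x freqs matrix of t-statistics.
#' @export
channel_t_map <- function(spect, state) {
  arr <- spect_array(spect)
  n <- dim(arr)[1]
  if (n < 10) stop("need >= 10 trials for the correlation map")
  if (length(state) != n) stop("state length must match trial count")
  if (stats::sd(state) == 0) stop("constant state: no ranking possible")
  flat <- matrix(arr, nrow = n)
  rho <- spearman_vec_mat(state, flat)
  matrix(rho_to_t(rho, n), dim(arr)[2], dim(arr)[3])
}

#' Hierarchical average of channel t-maps
#'
#' Mean over channels within each subject, then mean over subjects, so
#' that a subject with many channels still counts as one vote.
#'
#' @param maps_by_subject list (subjects) of lists (channels) of
#'   times x freqs matrices.
#' @return list of class \code{population_t_map}: \code{t_map} (the
#'   two-stage mean), \code{subject_maps} (subjects x pixels matrix),
#'   \code{n_subjects}, \code{dim}.
#' @export
aggregate_hierarchical <- function(maps_by_subject) {
  if (length(maps_by_subject) < 2)
    stop("regions need >= 2 contributing subjects")
  d <- dim(maps_by_subject[[1]][[1]])
  subject_maps <- t(vapply(maps_by_subject, function(chs) {
    as.vector(Reduce(`+`, chs) / length(chs))
  }, numeric(prod(d))))
  structure(list(t_map = matrix(colMeans(subject_maps), d[1], d[2]),
                 subject_maps = subject_maps,
                 n_subjects = length(maps_by_subject), dim = d),
            class = "population_t_map")
}

# 4-connected components of a logical matrix; returns integer label matrix.
connected_components <- function(mask) {
  d <- dim(mask)
  labels <- matrix(0L, d[1], d[2])
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      i <- (p - 1) %% d[1] + 1
      j <- (p - 1) %/% d[1] + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] < 1 || nb[1] > d[1] || nb[2] < 1 || nb[2] > d[2]) next
        q <- (nb[2] - 1) * d[1] + nb[1]
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Find supra-threshold clusters in a population t-map
#'
#' Pixels passing the cluster-forming threshold are split by the sign of
#' the map and grouped into 4-connected components (time and frequency
#' neighbors, no diagonals); each cluster's statistic is its mass, the
#' sum of the averaged t over member pixels.
#'
#' @param pop a \code{population_t_map} (or a plain t-map matrix with
#'   \code{threshold = "absolute"}).
#' @param alpha two-tailed pixel-forming level (default 0.05).
#' @param threshold "subject_t" (default): a pixel is included when the
#'   one-sample t of the subject-level means across subjects exceeds the
#'   two-tailed Student-t critical value with \code{n_subjects - 1}
#'   degrees of freedom -- subjects are the unit of inference.
#'   "absolute": include pixels with |t-map| above \code{t_thresh}.
#' @param t_thresh absolute threshold when \code{threshold = "absolute"}.
#' @return list of clusters; each has \code{pixels} (linear indices),
#'   \code{mask} (logical matrix), \code{sign}, \code{mass},
#'   \code{time_idx}, \code{freq_idx} (bounding box index ranges).
#' @export
find_clusters <- function(pop, alpha = 0.05,
                          threshold = c("subject_t", "absolute"),
                          t_thresh = NULL) {
  threshold <- match.arg(threshold)
  if (inherits(pop, "population_t_map")) {
    tmap <- pop$t_map
    if (threshold == "subject_t") {
      sm <- pop$subject_maps
      s <- pop$n_subjects
      mu <- colMeans(sm)
      se <- apply(sm, 2, stats::sd) / sqrt(s)
      # zero spread across subjects: infinitely consistent if nonzero
      tpix <- ifelse(se > 0, mu / se,
                     ifelse(abs(mu) > 0, sign(mu) * T_CAP, 0))
      crit <- stats::qt(1 - alpha / 2, df = s - 1)
      supra <- matrix(abs(tpix) > crit, nrow(tmap), ncol(tmap))
    } else {
      supra <- abs(tmap) > t_thresh
    }
  } else {
    tmap <- pop
    if (threshold != "absolute" || is.null(t_thresh))
      stop("plain t-map input requires threshold = 'absolute' with t_thresh")
    supra <- abs(tmap) > t_thresh
  }
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- supra & (sign(tmap) == sgn)
    if (!any(mask)) next
    labels <- connected_components(mask)
    for (lab in seq_len(max(labels))) {
      pix <- which(labels == lab)
      m <- matrix(FALSE, nrow(tmap), ncol(tmap))
      m[pix] <- TRUE
      ti <- range(((pix - 1) %% nrow(tmap)) + 1)
      fi <- range(((pix - 1) %/% nrow(tmap)) + 1)
      out[[length(out) + 1]] <- list(pixels = pix, mask = m, sign = sgn,
                                     mass = sum(tmap[pix]),
                                     time_idx = ti, freq_idx = fi)
    }
  }
  out
}

# One pass of the map/cluster pipeline for a permuted (or identity) state
# order. ranks_by_subject: per subject, list of channel standardized-rank
# matrices (trials x pixels); states_by_subject: per subject numeric state.
region_cluster_pass <- function(ranks_by_subject, states_by_subject,
                                perm_by_subject, d, alpha, threshold,
                                t_thresh) {
  maps <- mapply(function(chans, state, perm) {
    st <- state[perm]
    rs <- rank_standardize(matrix(st, ncol = 1))
    lapply(chans, function(R) {
      rho <- as.vector(crossprod(rs, R))
      matrix(rho_to_t(rho, length(st)), d[1], d[2])
    })
  }, ranks_by_subject, states_by_subject, perm_by_subject,
  SIMPLIFY = FALSE)
  pop <- aggregate_hierarchical(maps)
  find_clusters(pop, alpha = alpha, threshold = threshold,
                t_thresh = t_thresh)
}

#' Cluster-permutation test for one region and epoch
#'
#' Runs the full hierarchical map/cluster pipeline on the observed state
#' order, then on \code{n_perm} permutations in which each subject's state
#' trial order is shuffled once (identically across that subject's
#' channels, independently across subjects), recording the maximum
#' absolute cluster mass per permutation. Each observed cluster gets the
#' add-one p-value \code{p = (k + 1) / (n_perm + 1)} where k counts null
#' maxima at or above its absolute mass, with the cluster's correlation
#' direction carried in the sign.
#'
#' @param spect_by_subject list (subjects) of lists (channels) of
#'   \code{spectrogram_set} or trials x times x freqs arrays, all on the
#'   same pixel grid.
#' @param states_by_subject list of per-trial state vectors.
#' @param n_perm number of permutations (default 1000).
#' @param alpha pixel-forming level (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @param threshold,t_thresh see \code{\link{find_clusters}}.
#' @return list with \code{clusters} (each augmented with
#'   \code{p_signed}), \code{null_max} (the permutation distribution),
#'   \code{t_map}, \code{n_subjects}.
#' @export
permutation_test <- function(spect_by_subject, states_by_subject,
                             n_perm = 1000, alpha = 0.05, seed = 1L,
                             threshold = c("subject_t", "absolute"),
                             t_thresh = NULL) {
  threshold <- match.arg(threshold)
  if (n_perm < 1) stop("n_perm must be >= 1")
  arrs <- lapply(spect_by_subject, function(s) lapply(s, spect_array))
  d <- dim(arrs[[1]][[1]])[2:3]
  ranks <- lapply(arrs, function(chans) lapply(chans, function(a) {
    rank_standardize(matrix(a, nrow = dim(a)[1]))
  }))
  ns <- vapply(states_by_subject, length, integer(1))
  ident <- lapply(ns, seq_len)

  obs <- region_cluster_pass(ranks, states_by_subject, ident, d,
                             alpha, threshold, t_thresh)
  pop <- aggregate_hierarchical(mapply(function(chans, state) {
    rs <- rank_standardize(matrix(state, ncol = 1))
    lapply(chans, function(R)
      matrix(rho_to_t(as.vector(crossprod(rs, R)), length(state)),
             d[1], d[2]))
  }, ranks, states_by_subject, SIMPLIFY = FALSE))

  set.seed(seed)
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perms <- lapply(ns, sample.int)
    cl <- region_cluster_pass(ranks, states_by_subject, perms, d,
                              alpha, threshold, t_thresh)
    null_max[i] <- if (length(cl))
      max(vapply(cl, function(x) abs(x$mass), numeric(1))) else 0
  }
  clusters <- lapply(obs, function(cl) {
    k <- sum(null_max >= abs(cl$mass))
    cl$p_signed <- cl$sign * (k + 1) / (n_perm + 1)
    cl
  })
  list(clusters = clusters, null_max = null_max, t_map = pop$t_map,
       n_subjects = pop$n_subjects)
}

#' Cluster size filter: minimum time, frequency, and area extent
#'
#' Keeps a cluster iff its bounding box spans at least \code{min_time}
#' seconds (number of time bins times the bin step), at least
#' \code{min_octaves} octaves (log2 ratio of bounding bin centers), and
#' its pixel count is at least the product of the minimum time and
#' frequency bin counts.
#'
#' @param cluster a cluster from \code{\link{find_clusters}}.
#' @param freqs frequency axis, Hz.
#' @param step time bin step, seconds (default 0.05).
#' @param min_time minimum temporal extent, seconds (default 0.25).
#' @param min_octaves minimum frequency extent, octaves (default 1).
#' @return TRUE if the cluster passes.
#' @export
filter_cluster_size <- function(cluster, freqs, step = 0.05,
                                min_time = 0.25, min_octaves = 1) {
  n_time <- cluster$time_idx[2] - cluster$time_idx[1] + 1
  oct <- log2(freqs[cluster$freq_idx[2]] / freqs[cluster$freq_idx[1]])
  bpo <- 1 / mean(diff(log2(freqs)))
  min_tbins <- ceiling(min_time / step - 1e-9)
  min_fbins <- ceiling(min_octaves * bpo - 1e-9)
  (n_time * step >= min_time - 1e-9) &&
    (oct >= min_octaves - 1e-9) &&
    (length(cluster$pixels) >= min_tbins * min_fbins)
}

#' Benjamini-Hochberg FDR across regions and epochs
#'
#' Corrects the cluster permutation p-values (magnitudes) for multiple
#' comparisons at level \code{q}; survivors keep their signed p.
#'
#' @param p_signed vector of signed cluster p-values.
#' @param q FDR level (default 0.015).
#' @return logical vector: which clusters survive.
#' @export
fdr_correct <- function(p_signed, q = 0.015) {
  if (length(p_signed) == 0) return(logical(0))
  stats::p.adjust(abs(p_signed), method = "BH") <= q
}

#' Group clusters across epochs and label band and temporal pattern
#'
#' Clusters in the same region with overlapping frequency bins are merged
#' across epochs (union-find). Each group is labeled with the canonical
#' frequency band holding the majority of its pixel area, with its
#' temporal pattern -- persistent if its members cover all task epochs,
#' phasic otherwise -- and with the sign of its summed mass.
#'
#' @param cluster_df data frame with one row per surviving cluster:
#'   columns \code{region}, \code{epoch}, \code{mass}, \code{p_signed},
#'   and a list-column \code{freq_bins} of the frequency-bin indices of
#'   each cluster's mask pixels (one entry per pixel, so band majorities
#'   are weighted by pixel area).
#' @param freqs frequency axis, Hz.
#' @param all_epochs character vector of every task epoch (persistence
#'   requires coverage of all of them).
#' @return data frame with one row per group: region, group id, epochs
#'   spanned, band, temporal pattern, direction, total mass, minimum |p|,
#'   and the member freq-bin range.
#' @export
group_and_label <- function(cluster_df, freqs, all_epochs = TASK_EPOCHS) {
  if (nrow(cluster_df) == 0) {
    return(data.frame(region = character(0), group_id = integer(0),
                      epochs = character(0), band = character(0),
                      temporal_pattern = character(0),
                      direction = numeric(0), mass = numeric(0),
                      min_abs_p = numeric(0)))
  }
  n <- nrow(cluster_df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (cluster_df$region[i] != cluster_df$region[j]) next
    if (length(intersect(cluster_df$freq_bins[[i]],
                         cluster_df$freq_bins[[j]])) > 0)
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  rows <- list()
  member_sets <- list()
  for (g in unique(roots)) {
    members <- which(roots == g)
    bins <- unlist(lapply(members, function(i) cluster_df$freq_bins[[i]]))
    band_area <- table(frequency_band(freqs[bins]))
    epochs <- unique(cluster_df$epoch[members])
    rows[[length(rows) + 1]] <- data.frame(
      region = cluster_df$region[members[1]],
      group_id = g,
      epochs = paste(epochs, collapse = ","),
      band = names(band_area)[which.max(band_area)],
      temporal_pattern = if (all(all_epochs %in% epochs))
        "persistent" else "phasic",
      direction = sign(sum(cluster_df$mass[members])),
      mass = sum(cluster_df$mass[members]),
      min_abs_p = min(abs(cluster_df$p_signed[members])),
      stringsAsFactors = FALSE)
    member_sets[[length(member_sets) + 1]] <- members
  }
  out <- do.call(rbind, rows)
  out$members <- member_sets
  rownames(out) <- NULL
  out
}
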