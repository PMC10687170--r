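# Internal numerical helpers shared across the pipeline.

#' Z-score a numeric vector, mapping constant input to zeros
#'
#' Degenerate (constant or length-1) vectors z-score to all zeros rather
#' than NaN, so downstream regressions see a harmless zero column.
#'
#' @param x numeric vector.
#' @return numeric vector with sample mean 0 and sd 1, or zeros.
#' @keywords internal
zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Column-standardized midranks for fast Spearman correlation
#'
#' Returns ranks centered and scaled to unit norm so that crossprod of two
#' standardized rank vectors is the Spearman correlation (midranks handle
#' ties as `stats::cor(method = "spearman")` does).
#'
#' @param m numeric matrix (observations x variables).
#' @return matrix of the same shape.
#' @keywords internal
rank_standardize <- function(m) {
  m <- as.matrix(m)
  r <- apply(m, 2, rank)
  r <- sweep(r, 2, colMeans(r))
  nrm <- sqrt(colSums(r^2))
  nrm[nrm == 0] <- Inf  # constant column -> zero vector -> zero correlation
  sweep(r, 2, nrm, "/")
}

#' Spearman correlations between one vector and the columns of a matrix
#' @param x numeric vector.
#' @param m numeric matrix with nrow(m) == length(x).
#' @return numeric vector of Spearman rho per column.
#' @keywords internal
spearman_vec_mat <- function(x, m) {
  xs <- rank_standardize(matrix(x, ncol = 1))
  ms <- rank_standardize(m)
  as.vector(crossprod(xs, ms))
}

#' Derive a stream of child seeds from one master seed
#' @keywords internal
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
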