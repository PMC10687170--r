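# Fitting the internal-state behavioral model.
#
# Planning:  rt_z = b0 + b_se*x_se_z + b_p*x_p_z + b[speed] + b[direction]
# Execution: se   = c0 + c_se*x_se_z + c_p*x_p_z + c_rt*rt_z + c[speed, pert]
#
# RT is z-scored per subject before modeling; SE is left on its native
# scale. Both equations use the complete one-hot coding (all speed levels,
# all directions, all speed-by-perturbation cells) alongside a constant,
# as listed in the fitted-weight tables; that design is rank-deficient, so
# weights are the minimum-norm least-squares solution and only contrasts
# between levels are identifiable. A reference-coded fit is available for
# inference on identifiable contrasts.

RT_WEIGHT_NAMES <- c("const", "x_se", "x_p",
                     paste0("speed_", SPEED_LEVELS),
                     paste0("dir_", DIRECTION_LEVELS))
SE_WEIGHT_NAMES <- c("const", "x_se", "x_p", "rt",
                     as.vector(outer(SPEED_LEVELS, PERTURBATION_LEVELS,
                                     function(s, p) paste0(s, ".", p))))

# Fixed (condition) part of the planning design: constant + speed one-hot
# + direction one-hot. `states` columns are appended by callers.
rt_condition_design <- function(trials) {
  n <- nrow(trials)
  m <- cbind(const = rep(1, n),
             outer(trials$speed, SPEED_LEVELS, "==") * 1,
             outer(trials$direction, DIRECTION_LEVELS, "==") * 1)
  colnames(m) <- c("const", paste0("speed_", SPEED_LEVELS),
                   paste0("dir_", DIRECTION_LEVELS))
  m
}

# Fixed part of the execution design: constant + rt + speed-by-perturbation
# one-hot (6 cells).
se_condition_design <- function(trials, rt_z) {
  n <- nrow(trials)
  cell <- paste0(trials$speed, ".", trials$perturbation)
  lev <- as.vector(outer(SPEED_LEVELS, PERTURBATION_LEVELS,
                         function(s, p) paste0(s, ".", p)))
  m <- cbind(const = rep(1, n), rt = rt_z, outer(cell, lev, "==") * 1)
  colnames(m) <- c("const", "rt", lev)
  m
}

#' Gaussian maximum-likelihood weights for a (possibly rank-deficient) design
#'
#' Ordinary least squares (the Gaussian-family, identity-link GLM maximum
#' likelihood). A rank-deficient design -- the constant-plus-complete-one-hot
#' coding -- is resolved by the minimum-norm (pseudo-inverse) solution, so a
#' weight exists for every listed level; columns that are identically zero
#' (for example the perturbed state in a perturbation-free session) are
#' flagged as non-identifiable.
#'
#' @param design numeric matrix, rows = completed trials.
#' @param response numeric vector.
#' @param method "pinv" (minimum-norm, default) or "qr"
#'   (\code{lm.fit}; rank-deficient columns get coefficient 0).
#' @return list with \code{weights} (named; attribute
#'   \code{"identifiable"} flags structurally informative columns),
#'   \code{noise_var} (mean squared residual), \code{fitted}.
#' @export
fit_weights <- function(design, response, method = c("pinv", "qr")) {
  method <- match.arg(method)
  design <- as.matrix(design)
  n <- nrow(design)
  if (n <= qr(design)$rank) stop("fewer trials than identifiable parameters")
  if (method == "pinv") {
    w <- as.vector(MASS::ginv(design) %*% response)
  } else {
    f <- lm.fit(design, response)
    w <- f$coefficients
    w[is.na(w)] <- 0
  }
  names(w) <- colnames(design)
  fitted <- as.vector(design %*% w)
  attr(w, "identifiable") <- colSums(design != 0) > 0
  list(weights = w, noise_var = mean((response - fitted)^2), fitted = fitted)
}

#' Point predictions from a fitted behavioral model
#'
#' Evaluates the planning and execution equations (noise excluded) for
#' given trial conditions and z-scored internal states.
#'
#' @param trial single-row \code{trial_table} (conditions used: speed,
#'   direction, perturbation).
#' @param x_se_z,x_p_z z-scored internal states at this trial.
#' @param fit a \code{behavior_fit}.
#' @param rt_z optionally, the observed z-scored RT to feed the execution
#'   equation; defaults to the planning equation's prediction.
#' @return list with \code{rt_z} and \code{se}.
#' @export
predict_behavior <- function(trial, x_se_z, x_p_z, fit, rt_z = NULL) {
  w <- fit$rt_weights
  sp <- paste0("speed_", trial$speed)
  dr <- paste0("dir_", trial$direction)
  if (!all(c(sp, dr) %in% names(w))) stop("missing weight for condition level")
  rt_hat <- unname(w["const"] + w["x_se"] * x_se_z + w["x_p"] * x_p_z +
                     w[sp] + w[dr])
  v <- fit$se_weights
  cell <- paste0(trial$speed, ".", trial$perturbation)
  if (!cell %in% names(v)) stop("missing weight for condition level")
  rt_in <- if (is.null(rt_z)) rt_hat else rt_z
  se_hat <- unname(v["const"] + v["x_se"] * x_se_z + v["x_p"] * x_p_z +
                     v["rt"] * rt_in + v[cell])
  list(rt_z = rt_hat, se = se_hat)
}

# ---- grid-search machinery -------------------------------------------------

# Orthonormal basis of the fixed design's column space plus the pieces
# needed to score every (alpha_se, alpha_p) grid point from sufficient
# statistics: for states residualized against the fixed columns, the
# regression sum of squares is a 2x2 solve per grid point.
grid_scores <- function(Fmat, y, XSE, XP) {
  n <- length(y)
  qrF <- qr(Fmat)
  QF <- qr.Q(qrF)[, seq_len(qrF$rank), drop = FALSE]
  Qy <- as.vector(crossprod(QF, y))
  Q1 <- crossprod(QF, XSE)            # rank x 99
  Q2 <- crossprod(QF, XP)
  a11 <- colSums(XSE^2) - colSums(Q1^2)       # per alpha_se
  a22 <- colSums(XP^2) - colSums(Q2^2)        # per alpha_p
  a12 <- crossprod(XSE, XP) - crossprod(Q1, Q2)  # 99 x 99
  b1 <- as.vector(crossprod(XSE, y)) - as.vector(crossprod(Q1, Qy))
  b2 <- as.vector(crossprod(XP, y)) - as.vector(crossprod(Q2, Qy))
  A11 <- matrix(a11, length(a11), length(a22))
  A22 <- matrix(a22, length(a11), length(a22), byrow = TRUE)
  B1 <- matrix(b1, length(b1), length(b2))
  B2 <- matrix(b2, length(b1), length(b2), byrow = TRUE)
  scale <- A11 + A22
  det <- A11 * A22 - a12^2
  tol <- 1e-10 * pmax(scale^2, 1e-300)
  quad <- matrix(0, nrow(det), ncol(det))
  ok <- det > tol
  quad[ok] <- (A22[ok] * B1[ok]^2 - 2 * a12[ok] * B1[ok] * B2[ok] +
                 A11[ok] * B2[ok]^2) / det[ok]
  r1 <- !ok & (A11 >= A22) & (A11 > 1e-12)
  quad[r1] <- B1[r1]^2 / A11[r1]
  r2 <- !ok & (A22 > A11) & (A22 > 1e-12)
  quad[r2] <- B2[r2]^2 / A22[r2]
  py2 <- sum(Qy^2) + quad                 # ||projection of y||^2
  tss <- sum(y^2) - n * mean(y)^2
  ssr <- pmax(py2 - n * mean(y)^2, 0)
  list(pearson = sqrt(pmin(ssr / tss, 1)),
       rmse = sqrt(pmax(sum(y^2) - py2, 0) / n))
}

#' Fit the internal-state model by grid search over the decay constants
#'
#' Evaluates every (alpha_se, alpha_p) pair on a 0.01-step grid over
#' [0.01, 0.99] (99 x 99 pairs at the default step). For each pair the
#' states are evolved and z-scored, the planning and execution weights are
#' fitted by least squares, and the candidate is scored. The default
#' selection minimizes the summed root-mean-squared error of the two
#' outputs (the model-fitting objective); \code{criterion = "pearson"}
#' instead maximizes the mean of the two outputs' Pearson correlations
#' between observed and estimated outputs, breaking ties by lower summed
#' RMSE. The RMSE default is preferred because averaging per-output
#' correlations gives the noisier execution equation's nearly flat score
#' an equal vote and measurably degrades recovery of the decay constants.
#' One decay pair is shared by both equations; \code{outputs} restricts
#' the score to a single equation for sensitivity analysis.
#'
#' @param trials a \code{trial_table} with >= 20 completed trials.
#' @param grid_step grid spacing for the decay constants (default 0.01).
#' @param criterion "rmse" (default) or "pearson".
#' @param outputs which outputs enter the selection score.
#' @param carry_incomplete passed to \code{\link{evolve_states}}.
#' @return object of class \code{behavior_fit}: \code{params}
#'   (\code{state_params}), \code{rt_weights}, \code{se_weights},
#'   \code{rt_noise_var}, \code{se_noise_var}, \code{states}
#'   (\code{state_trace}), \code{rt_estimate}, \code{se_estimate} (per
#'   completed trial), \code{metrics} (see \code{\link{evaluate_fit}}),
#'   \code{rt_center}, \code{rt_scale} (the z-scoring applied to RT), and
#'   \code{grid} (alpha grid with the score surface).
#' @export
grid_search_fit <- function(trials, grid_step = 0.01,
                            criterion = c("rmse", "pearson"),
                            outputs = c("both", "rt", "se"),
                            carry_incomplete = FALSE) {
  criterion <- match.arg(criterion)
  outputs <- match.arg(outputs)
  comp <- trials[trials$completed, , drop = FALSE]
  if (nrow(comp) < 20) stop("need >= 20 completed trials for grid search")
  alphas <- seq(0.01, 0.99, by = grid_step)
  rt_center <- mean(comp$rt_seconds)
  rt_scale <- stats::sd(comp$rt_seconds)
  if (rt_scale == 0) rt_scale <- 1  # degenerate: constant RT, logged scale 1
  rt_z <- (comp$rt_seconds - rt_center) / rt_scale
  se <- comp$speed_error

  # State traces for every alpha value (z-scored), shared by both equations.
  pulse <- as.numeric(comp$perturbation %in% c("towards", "away"))
  XSE <- vapply(alphas, function(a)
    zscore_or_zero(decay_recursion(se, a, 0)), numeric(nrow(comp)))
  XP <- vapply(alphas, function(a)
    zscore_or_zero(decay_recursion(pulse, a, 0)), numeric(nrow(comp)))

  F_rt <- rt_condition_design(comp)
  F_se <- se_condition_design(comp, rt_z)
  s_rt <- grid_scores(F_rt, rt_z, XSE, XP)
  s_se <- grid_scores(F_se, se, XSE, XP)

  pe <- switch(outputs, both = (s_rt$pearson + s_se$pearson) / 2,
               rt = s_rt$pearson, se = s_se$pearson)
  rm <- switch(outputs, both = s_rt$rmse + s_se$rmse,
               rt = s_rt$rmse, se = s_se$rmse)
  if (criterion == "pearson") {
    best <- which(pe == max(pe))
    if (length(best) > 1) best <- best[which.min(rm[best])]
  } else {
    best <- which.min(rm)
  }
  idx <- arrayInd(best[1], dim(pe))
  params <- state_params(alphas[idx[1]], alphas[idx[2]])

  fit <- finalize_fit(trials, params, criterion = criterion,
                      carry_incomplete = carry_incomplete)
  fit$grid <- list(alphas = alphas, score = pe, rmse = rm,
                   criterion = criterion, outputs = outputs)
  fit
}

# Fit weights and metrics at fixed decay constants.
finalize_fit <- function(trials, params, criterion = "pearson",
                         carry_incomplete = FALSE, include_states = TRUE) {
  comp <- trials[trials$completed, , drop = FALSE]
  rt_center <- mean(comp$rt_seconds)
  rt_scale <- stats::sd(comp$rt_seconds)
  if (rt_scale == 0) rt_scale <- 1
  rt_z <- (comp$rt_seconds - rt_center) / rt_scale
  se <- comp$speed_error
  states <- evolve_states(trials, params, carry_incomplete = carry_incomplete)

  X_rt <- cbind(rt_condition_design(comp)[, 1, drop = FALSE],
                x_se = states$x_se_z, x_p = states$x_p_z,
                rt_condition_design(comp)[, -1])
  X_se <- cbind(const = 1, x_se = states$x_se_z, x_p = states$x_p_z,
                se_condition_design(comp, rt_z)[, -1])
  if (!include_states) {
    X_rt[, c("x_se", "x_p")] <- 0
    X_se[, c("x_se", "x_p")] <- 0
  }
  colnames(X_rt)[1] <- "const"
  f_rt <- fit_weights(X_rt[, RT_WEIGHT_NAMES], rt_z)
  f_se <- fit_weights(X_se[, SE_WEIGHT_NAMES], se)

  fit <- structure(list(
    params = params,
    rt_weights = f_rt$weights, se_weights = f_se$weights,
    rt_noise_var = f_rt$noise_var, se_noise_var = f_se$noise_var,
    states = states,
    rt_estimate = f_rt$fitted, se_estimate = f_se$fitted,
    rt_center = rt_center, rt_scale = rt_scale,
    include_states = include_states,
    subject_id = comp$subject_id[1]
  ), class = "behavior_fit")
  fit$metrics <- evaluate_fit(fit, trials)
  fit
}

#' Conditions-only baseline model
#'
#' The subject-specific linear model with the same design as the
#' internal-state model minus both state columns: RT on speed and
#' direction; SE on RT and the speed-by-perturbation cells. Used for the
#' with/without-states model comparison.
#'
#' @inheritParams grid_search_fit
#' @return a \code{behavior_fit} whose state weights are structurally zero.
#' @export
fit_baseline <- function(trials) {
  finalize_fit(trials, state_params(0.5, 0.5), include_states = FALSE)
}

#' Goodness-of-fit metrics for a behavioral model
#'
#' Pearson correlation between observed and estimated outputs, coefficient
#' of determination (proportion of output variance explained, reported
#' clamped to [0, 1]), Gaussian deviance (residual sum of squares), and a
#' 10-fold cross-validated R^2 in which the internal states are held fixed
#' at the values fitted on all data (states are history-dependent, so they
#' are not re-estimated per fold).
#'
#' @param fit a \code{behavior_fit}.
#' @param trials the \code{trial_table} the fit was computed on.
#' @param cv_folds number of cross-validation folds (default 10).
#' @return list with \code{pearson_rt}, \code{pearson_se}, \code{r2_rt},
#'   \code{r2_se}, \code{deviance_rt}, \code{deviance_se}, \code{cv10_rt},
#'   \code{cv10_se}.
#' @export
evaluate_fit <- function(fit, trials, cv_folds = 10) {
  comp <- trials[trials$completed, , drop = FALSE]
  n <- nrow(comp)
  rt_z <- (comp$rt_seconds - fit$rt_center) / fit$rt_scale
  se <- comp$speed_error
  m <- list()
  for (out in c("rt", "se")) {
    y <- if (out == "rt") rt_z else se
    yhat <- if (out == "rt") fit$rt_estimate else fit$se_estimate
    r <- if (stats::sd(yhat) > 0 && stats::sd(y) > 0)
      stats::cor(y, yhat) else 0
    rss <- sum((y - yhat)^2)
    tss <- sum((y - mean(y))^2)
    m[[paste0("pearson_", out)]] <- r
    m[[paste0("r2_", out)]] <- min(max(1 - rss / tss, 0), 1)
    m[[paste0("deviance_", out)]] <- rss
  }
  if (n < cv_folds) stop("fewer completed trials than CV folds")
  st <- fit$states
  X_rt <- cbind(const = 1, x_se = st$x_se_z, x_p = st$x_p_z,
                rt_condition_design(comp)[, -1])
  X_se <- cbind(const = 1, x_se = st$x_se_z, x_p = st$x_p_z,
                se_condition_design(comp, rt_z)[, -1])
  if (!fit$include_states) {
    X_rt[, c("x_se", "x_p")] <- 0
    X_se[, c("x_se", "x_p")] <- 0
  }
  folds <- rep(seq_len(cv_folds), length.out = n)
  for (out in c("rt", "se")) {
    X <- if (out == "rt") X_rt else X_se
    y <- if (out == "rt") rt_z else se
    pred <- numeric(n)
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      w <- fit_weights(X[tr, , drop = FALSE], y[tr])$weights
      pred[!tr] <- X[!tr, , drop = FALSE] %*% w
    }
    m[[paste0("cv10_", out)]] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  m
}

#' Reference-coded refit for inference on identifiable contrasts
#'
#' Refits both equations at the fit's decay constants using treatment
#' coding (first level of each factor as reference) via \code{lm}, giving
#' standard errors and confidence intervals for the identifiable
#' parameters.
#'
#' @param fit a \code{behavior_fit}.
#' @param trials the \code{trial_table} the fit was computed on.
#' @param level confidence level (default 0.95).
#' @return list with \code{rt} and \code{se} elements, each containing the
#'   \code{lm} fit and its \code{confint} matrix.
#' @export
reference_fit <- function(fit, trials, level = 0.95) {
  comp <- trials[trials$completed, , drop = FALSE]
  rt_z <- (comp$rt_seconds - fit$rt_center) / fit$rt_scale
  st <- fit$states
  d <- data.frame(rt_z = rt_z, se = comp$speed_error,
                  x_se = st$x_se_z, x_p = st$x_p_z,
                  speed = factor(comp$speed, SPEED_LEVELS),
                  direction = factor(comp$direction, DIRECTION_LEVELS),
                  cell = factor(paste0(comp$speed, ".", comp$perturbation),
                                as.vector(outer(SPEED_LEVELS,
                                                PERTURBATION_LEVELS,
                                                paste, sep = "."))))
  d$cell <- droplevels(d$cell)
  m_rt <- stats::lm(rt_z ~ x_se + x_p + speed + direction, data = d)
  m_se <- stats::lm(se ~ x_se + x_p + rt_z + cell, data = d)
  list(rt = list(model = m_rt, ci = stats::confint(m_rt, level = level)),
       se = list(model = m_se, ci = stats::confint(m_se, level = level)))
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat("Internal-state behavioral model fit\n")
  cat(sprintf("  subject: %s   alpha_SE = %.2f   alpha_P = %.2f\n",
              x$subject_id, x$params$alpha_se, x$params$alpha_p))
  cat(sprintf("  Pearson r: RT %.3f, SE %.3f   R2: RT %.3f, SE %.3f\n",
              x$metrics$pearson_rt, x$metrics$pearson_se,
              x$metrics$r2_rt, x$metrics$r2_se))
  invisible(x)
}
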