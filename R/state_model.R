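# Internal-state evolution: two scalar latent states per trial.
#
# The error state accumulates past speed errors and the perturbed state
# accumulates past perturbation pulses, each with its own forgetting
# factor (decay constant) in (0, 1):
#
#   x^SE_t = alpha^SE * x^SE_{t-1} + y^SE_{t-1}
#   x^P_t  = alpha^P  * x^P_{t-1}  + 1{perturbation on trial t-1}
#
# with x^SE_1 = x^P_1 = 0. States are constant within a trial (planning
# and execution see the same value) and only update between trials.

#' Decay constants and initial conditions for the internal states
#'
#' @param alpha_se,alpha_p forgetting factors in [0.01, 0.99]: values near
#'   0 forget the previous trial almost entirely; values near 1 carry
#'   history across many trials.
#' @param x1_se,x1_p initial states (both 0 for the fitting procedure).
#' @return list of class \code{state_params}.
#' @export
state_params <- function(alpha_se, alpha_p, x1_se = 0, x1_p = 0) {
  stopifnot(is.finite(alpha_se), is.finite(alpha_p),
            alpha_se >= 0.01, alpha_se <= 0.99,
            alpha_p >= 0.01, alpha_p <= 0.99)
  structure(list(alpha_se = alpha_se, alpha_p = alpha_p,
                 x1_se = x1_se, x1_p = x1_p),
            class = "state_params")
}

# First-order decay recursion: x[1] = x1; x[t] = alpha*x[t-1] + u[t-1].
# u has one entry per trial; u[n] is unused (it would feed trial n+1).
decay_recursion <- function(u, alpha, x1) {
  n <- length(u)
  x <- numeric(n)
  x[1] <- x1
  if (n > 1) for (t in 2:n) x[t] <- alpha * x[t - 1] + u[t - 1]
  x
}

#' Evolve the error and perturbed states over a session
#'
#' States are evolved over completed trials only (the fitted model's
#' convention): incomplete trials contribute neither a speed-error input
#' nor a perturbation pulse, and the state index runs over completed
#' trials. Set \code{carry_incomplete = TRUE} to instead evolve over all
#' trials with zero speed-error input on incomplete ones (perturbation
#' pulses still fire) and return the states at completed trials.
#'
#' @param trials a \code{trial_table}.
#' @param params a \code{state_params}.
#' @param carry_incomplete see Description.
#' @return list of class \code{state_trace} with per-completed-trial
#'   vectors \code{x_se_raw}, \code{x_p_raw} and z-scored copies
#'   \code{x_se_z}, \code{x_p_z} (a constant raw trace z-scores to zeros).
#' @export
evolve_states <- function(trials, params, carry_incomplete = FALSE) {
  if (nrow(trials) == 0) stop("empty trial list")
  comp <- trials$completed
  if (!any(comp)) stop("no completed trials")
  if (carry_incomplete) {
    y_se <- ifelse(comp, trials$speed_error, 0)
    pulse <- as.numeric(trials$perturbation %in% c("towards", "away"))
    keep <- comp
  } else {
    sub <- trials[comp, , drop = FALSE]
    y_se <- sub$speed_error
    pulse <- as.numeric(sub$perturbation %in% c("towards", "away"))
    keep <- rep(TRUE, nrow(sub))
  }
  if (any(!is.finite(y_se))) stop("non-finite speed_error on a completed trial")
  x_se <- decay_recursion(y_se, params$alpha_se, params$x1_se)
  x_p <- decay_recursion(pulse, params$alpha_p, params$x1_p)
  x_se <- x_se[keep]
  x_p <- x_p[keep]
  structure(list(x_se_raw = x_se, x_p_raw = x_p,
                 x_se_z = zscore_or_zero(x_se),
                 x_p_z = zscore_or_zero(x_p)),
            class = "state_trace")
}

#' Closed-form solution of the first-order state evolution
#'
#' Returns the state at trial \code{t} directly from the input history:
#' the initial state decayed \code{t - 1} times plus the decay-weighted
#' cumulative sum of past inputs,
#' \code{alpha^(t-1) x1 + sum_{i<t} alpha^(t-i-1) u_i}.
#'
#' @param inputs per-trial inputs (speed errors or perturbation pulses).
#' @param alpha forgetting factor in [0, 1].
#' @param x1 initial state.
#' @param t trial index (1-based), \code{t <= length(inputs) + 1}.
#' @return the state value at trial t.
#' @export
closed_form_state <- function(inputs, alpha, x1, t) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  stopifnot(t >= 1, t <= length(inputs) + 1)
  val <- alpha^(t - 1) * x1
  if (t > 1) {
    i <- seq_len(t - 1)
    val <- val + sum(alpha^(t - i - 1) * inputs[i])
  }
  val
}
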