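# Synthetic motor-task sessions: trial-condition sampling and generative
# runs of the internal-state model, used as ground truth for parameter
# recovery and for every downstream neural stage.

#' Specification for a synthetic session
#'
#' Defaults encode the task's condition statistics: equally likely fast or
#' slow instruction, uniform target direction over four locations, 20\%
#' perturbation probability with force uniform on [2.5, 15] N at a uniform
#' random angle. The generative behavioral model is the internal-state
#' model itself run forward with Gaussian noise.
#'
#' @param n_trials number of trials (default 300).
#' @param p_perturb perturbation probability per trial (default 0.20).
#' @param force_range perturbation force range, newtons.
#' @param true_params generating \code{\link{state_params}} (default
#'   alpha_SE = 0.30, alpha_P = 0.70).
#' @param true_rt_weights,true_se_weights named generating weights on the
#'   raw-state scale (see Details).
#' @param noise_sd_rt RT noise sd in z-units (default 0.10: the planning
#'   equation is kept high-signal so the decay constants are sharply
#'   identifiable in parameter-recovery use).
#' @param noise_sd_se SE noise sd (default 0.11, keeping essentially all
#'   mass inside the task's [-0.67, 0.67] range without clipping and
#'   yielding session performance near 50\%).
#' @param rt_mean_s,rt_sd_s affine map from RT z-units to seconds
#'   (defaults 0.80 s and 0.15 s).
#' @param clip_se clip generated SE to [-0.67, 0.67] (default FALSE: a
#'   clipped Gaussian breaks the linear model's assumptions, so the noise
#'   sd is instead chosen to keep mass inside the bounds).
#' @param completion_rate probability a trial is completed (default 1).
#' @param seed integer RNG seed.
#' @details Generation runs the state recursion causally on the raw state
#'   scale (z-scoring is a fitting-stage normalization that requires the
#'   full trace, so a causal generator cannot use it). Because z-scoring
#'   is an affine map absorbed by the intercept, the fitted decay
#'   constants are directly comparable to the generating ones; generating
#'   slope weights map to the fitted (z-scored) scale by multiplying by
#'   the sample sd of the raw state.
#' @return list of class \code{generator_spec}.
#' @export
generator_spec <- function(n_trials = 300, p_perturb = 0.20,
                           force_range = c(2.5, 15),
                           true_params = state_params(0.30, 0.70),
                           true_rt_weights = default_rt_weights(),
                           true_se_weights = default_se_weights(),
                           noise_sd_rt = 0.10, noise_sd_se = 0.11,
                           rt_mean_s = 0.80, rt_sd_s = 0.15,
                           clip_se = FALSE, completion_rate = 1,
                           seed = 1L) {
  stopifnot(n_trials >= 1, p_perturb >= 0, p_perturb <= 1,
            noise_sd_rt >= 0, noise_sd_se >= 0,
            force_range[1] >= 2.5, force_range[2] <= 15)
  structure(as.list(environment()), class = "generator_spec")
}

#' Default generating weights for the planning (RT) equation
#' @return named numeric vector on the raw-state scale.
#' @export
default_rt_weights <- function() {
  c(const = 0, x_se = 3.5, x_p = 1.3,
    speed_fast = -0.15, speed_slow = 0.15,
    dir_down = 0.05, dir_right = -0.05, dir_up = 0.05, dir_left = -0.05)
}

#' Default generating weights for the execution (SE) equation
#' @return named numeric vector on the raw-state scale.
#' @export
default_se_weights <- function() {
  c(const = 0, x_se = 0.25, x_p = 0.08, rt = 0.02,
    fast.unperturbed = -0.04, fast.towards = -0.07, fast.away = -0.10,
    slow.unperturbed = 0.04, slow.towards = 0.07, slow.away = 0.02)
}

#' Classify a perturbation angle as towards or away from the target
#'
#' Towards iff the absolute circular difference between the perturbation
#' angle and the target bearing is strictly less than pi/2; the boundary
#' pi/2 itself classifies as away.
#'
#' @param angle perturbation angle, radians.
#' @param direction target direction ("down", "right", "up", "left").
#' @return "towards" or "away".
#' @export
classify_perturbation <- function(angle, direction) {
  bearing <- unname(c(down = -pi / 2, right = 0, up = pi / 2,
                      left = pi)[direction])
  d <- abs(((angle - bearing + pi) %% (2 * pi)) - pi)
  unname(ifelse(d < pi / 2, "towards", "away"))
}

#' Sample trial conditions for a synthetic session
#'
#' @param spec a \code{generator_spec}.
#' @return data frame with speed, direction, perturbation, perturb_force,
#'   perturb_angle (forces/angles NA on unperturbed trials).
#' @export
sample_conditions <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_trials
  speed <- sample(SPEED_LEVELS, n, replace = TRUE)
  direction <- sample(DIRECTION_LEVELS, n, replace = TRUE)
  perturbed <- stats::runif(n) < spec$p_perturb
  force <- ifelse(perturbed,
                  stats::runif(n, spec$force_range[1], spec$force_range[2]),
                  NA_real_)
  angle <- ifelse(perturbed, stats::runif(n, 0, 2 * pi), NA_real_)
  pert <- rep("unperturbed", n)
  pert[perturbed] <- classify_perturbation(angle[perturbed],
                                           direction[perturbed])
  data.frame(speed = speed, direction = direction, perturbation = pert,
             perturb_force = force, perturb_angle = angle,
             stringsAsFactors = FALSE)
}

#' Simulate one session of the motor task
#'
#' Samples conditions, then runs the internal-state model forward: states
#' evolve causally on the raw scale, the planning equation draws a
#' z-unit RT with Gaussian noise (mapped affinely to seconds), and the
#' execution equation draws the speed error with Gaussian noise.
#'
#' @param spec a \code{generator_spec}.
#' @param subject_id identifier for the generated subject.
#' @return list with \code{trials} (a \code{trial_table}), and
#'   \code{truth} (generating parameters, weights, raw state traces, and
#'   the generated z-unit RT).
#' @export
simulate_session <- function(spec, subject_id = "sim01") {
  cond <- sample_conditions(spec)
  n <- spec$n_trials
  w <- spec$true_rt_weights
  v <- spec$true_se_weights
  a_se <- spec$true_params$alpha_se
  a_p <- spec$true_params$alpha_p
  eps_rt <- stats::rnorm(n, 0, spec$noise_sd_rt)
  eps_se <- stats::rnorm(n, 0, spec$noise_sd_se)
  completed <- stats::runif(n) < spec$completion_rate

  x_se <- x_p <- rt_z <- se <- rep(NA_real_, n)
  cur_se <- spec$true_params$x1_se
  cur_p <- spec$true_params$x1_p
  for (t in seq_len(n)) {
    if (!completed[t]) next  # states evolve over completed trials only
    x_se[t] <- cur_se
    x_p[t] <- cur_p
    rt_z[t] <- w["const"] + w["x_se"] * cur_se + w["x_p"] * cur_p +
      w[paste0("speed_", cond$speed[t])] +
      w[paste0("dir_", cond$direction[t])] + eps_rt[t]
    se[t] <- v["const"] + v["x_se"] * cur_se + v["x_p"] * cur_p +
      v["rt"] * rt_z[t] +
      v[paste0(cond$speed[t], ".", cond$perturbation[t])] + eps_se[t]
    if (spec$clip_se) se[t] <- min(max(se[t], -0.67), 0.67)
    cur_se <- a_se * cur_se + se[t]
    cur_p <- a_p * cur_p +
      as.numeric(cond$perturbation[t] %in% c("towards", "away"))
  }
  rt_s <- pmax(spec$rt_mean_s + spec$rt_sd_s * rt_z, 0.05)
  trials <- trial_table(subject_id = subject_id,
                        speed = cond$speed, direction = cond$direction,
                        perturbation = cond$perturbation,
                        rt_seconds = rt_s, speed_error = se,
                        completed = completed,
                        perturb_force = cond$perturb_force,
                        perturb_angle = cond$perturb_angle)
  list(trials = trials,
       truth = list(params = spec$true_params,
                    rt_weights = w, se_weights = v,
                    x_se_raw = x_se[completed], x_p_raw = x_p[completed],
                    rt_z = rt_z[completed], spec = spec))
}

#' Simulate a multi-subject cohort
#'
#' Subjects differ in execution noise (driving realized session
#' performance above and below the cohort mean) and, optionally, in how
#' strongly their state weights scale with that performance gradient, so
#' recovery and performance-selection analyses have planted structure.
#'
#' @param n_subjects number of subjects.
#' @param spec baseline \code{generator_spec} shared by the cohort.
#' @param performance_gradient multiplier controlling how strongly each
#'   subject's state weights track their (designed) performance rank:
#'   0 gives identical weights for all subjects.
#' @param noise_sd_se_range range of execution noise across subjects
#'   (low noise -> high performance).
#' @param seed integer seed; each subject gets a derived child seed.
#' @return list with \code{sessions} (named list of \code{trial_table}),
#'   \code{truth} (per-subject data frame of generating parameters),
#'   \code{performance} (realized session performance, percent).
#' @export
simulate_cohort <- function(n_subjects, spec = generator_spec(),
                            performance_gradient = 1,
                            noise_sd_se_range = c(0.07, 0.20),
                            seed = 1L) {
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(seed, n_subjects)
  # designed gradient: subject 1 best (low noise), last worst
  g <- if (n_subjects == 1) 0 else seq(1, -1, length.out = n_subjects)
  noise <- seq(noise_sd_se_range[1], noise_sd_se_range[2],
               length.out = n_subjects)
  sessions <- list()
  truth <- NULL
  perf <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    sp <- spec
    sp$seed <- seeds[i]
    sp$noise_sd_se <- noise[i]
    # better-performing (low-noise) subjects get smaller state-weight
    # magnitudes: strong error-state weights perpetuate errors, so large
    # weights co-occur with poor performance in this cohort design
    mult <- 1 - 0.5 * performance_gradient * g[i]
    sp$true_rt_weights[c("x_se", "x_p")] <-
      sp$true_rt_weights[c("x_se", "x_p")] * mult
    sp$true_se_weights[c("x_se", "x_p")] <-
      sp$true_se_weights[c("x_se", "x_p")] * mult
    id <- sprintf("sim%02d", i)
    sim <- simulate_session(sp, subject_id = id)
    sessions[[id]] <- sim$trials
    perf[i] <- session_performance(sim$trials)
    truth <- rbind(truth, data.frame(
      subject_id = id, alpha_se = sp$true_params$alpha_se,
      alpha_p = sp$true_params$alpha_p,
      noise_sd_se = sp$noise_sd_se, weight_mult = mult,
      stringsAsFactors = FALSE))
  }
  names(perf) <- names(sessions)
  list(sessions = sessions, truth = truth, performance = perf)
}
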