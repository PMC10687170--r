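# Trial tables and session-level behavioral quantities for the
# center-out instructed-speed reaching task.
#
# One row per trial: the three trial conditions (speed, direction,
# perturbation), the perturbation parameters when one was applied, and the
# two behavioral outputs -- reaction time (RT, seconds) and speed error
# (SE, unitless in [-0.67, 0.67]).

#' Eight task epochs in presentation order
#'
#' Speed Instruction through Show Outcome, grouped into planning
#' (epochs 1-4), execution (5-6), and feedback (7-8) movement phases.
#' @export
TASK_EPOCHS <- c("speed_instruction", "fixation", "show_target", "go_cue",
                 "movement_onset", "hit_target", "speed_feedback",
                 "show_outcome")

#' Movement phase of each task epoch
#' @export
EPOCH_PHASES <- c(speed_instruction = "planning", fixation = "planning",
                  show_target = "planning", go_cue = "planning",
                  movement_onset = "execution", hit_target = "execution",
                  speed_feedback = "feedback", show_outcome = "feedback")

# Instructed-speed midpoints (fraction of calibration speed) and the
# correctness tolerance on speed error.
SPEED_MID <- c(fast = 0.67, slow = 0.33)
SE_TOLERANCE <- 0.13

#' Construct a trial table
#'
#' Builds and validates the canonical one-row-per-trial data frame used by
#' the behavioral model. Incomplete trials carry NA for rt_seconds,
#' speed_error and correct.
#'
#' @param subject_id character scalar.
#' @param speed character vector in \code{c("fast", "slow")}.
#' @param direction character vector in
#'   \code{c("down", "right", "up", "left")}.
#' @param perturbation character vector in
#'   \code{c("unperturbed", "towards", "away")}.
#' @param rt_seconds reaction time in seconds (NA when incomplete).
#' @param speed_error speed error in [-0.67, 0.67] (NA when incomplete).
#' @param completed logical vector; defaults to all TRUE.
#' @param perturb_force force in newtons (NA when unperturbed).
#' @param perturb_angle angle in radians (NA when unperturbed).
#' @return data frame of class \code{trial_table} with a derived
#'   \code{correct} column (\code{|speed_error| <= 0.13} on completed
#'   trials).
#' @export
trial_table <- function(subject_id, speed, direction, perturbation,
                        rt_seconds = NA_real_, speed_error = NA_real_,
                        completed = TRUE,
                        perturb_force = NA_real_, perturb_angle = NA_real_) {
  n <- length(speed)
  df <- data.frame(
    subject_id = rep_len(as.character(subject_id), n),
    trial_index = seq_len(n),
    speed = as.character(speed),
    direction = as.character(direction),
    perturbation = as.character(perturbation),
    perturb_force = rep_len(as.numeric(perturb_force), n),
    perturb_angle = rep_len(as.numeric(perturb_angle), n),
    rt_seconds = rep_len(as.numeric(rt_seconds), n),
    speed_error = rep_len(as.numeric(speed_error), n),
    completed = rep_len(as.logical(completed), n),
    stringsAsFactors = FALSE
  )
  df$rt_seconds[!df$completed] <- NA_real_
  df$speed_error[!df$completed] <- NA_real_
  df$correct <- df$completed & !is.na(df$speed_error) &
    abs(df$speed_error) <= SE_TOLERANCE
  df$correct[!df$completed] <- NA
  validate_trial_table(df)
  class(df) <- c("trial_table", "data.frame")
  df
}

validate_trial_table <- function(df) {
  if (nrow(df) == 0) stop("trial table is empty")
  stopifnot(all(df$speed %in% SPEED_LEVELS),
            all(df$direction %in% DIRECTION_LEVELS),
            all(df$perturbation %in% PERTURBATION_LEVELS))
  if (any(diff(df$trial_index) <= 0))
    stop("trial_index must be strictly increasing")
  comp <- df$completed
  if (any(comp & (!is.finite(df$rt_seconds) | df$rt_seconds < 0)))
    stop("completed trials need finite nonnegative rt_seconds")
  if (any(comp & !is.finite(df$speed_error)))
    stop("completed trials need finite speed_error")
  pert <- df$perturbation != "unperturbed"
  bad <- pert & (!is.finite(df$perturb_force) |
                   df$perturb_force < 2.5 | df$perturb_force > 15)
  if (any(bad))
    stop("perturbed trials need perturb_force in [2.5, 15] N")
  invisible(df)
}

#' Session performance: percent of completed trials that were correct
#'
#' @param trials a \code{trial_table}.
#' @return percent in [0, 100].
#' @export
session_performance <- function(trials) {
  comp <- trials[trials$completed, , drop = FALSE]
  if (nrow(comp) == 0) stop("no completed trials: performance undefined")
  100 * sum(comp$correct) / nrow(comp)
}

#' Behavioral quantities from trial event timestamps
#'
#' RT is the time from Go Cue to the cursor leaving the center. The trial
#' speed is the center-to-target distance divided by the Go Cue to
#' Hold Target interval, scaled by the subject's calibration speed; speed
#' error is the instructed midpoint (0.67 fast / 0.33 slow) minus the
#' trial speed. A trial is correct when |speed error| <= 0.13.
#'
#' @param t_go_cue,t_leave_center,t_hold_target event times in seconds,
#'   ordered \code{t_go_cue <= t_leave_center <= t_hold_target}.
#' @param center_target_distance distance in pixels.
#' @param calibration_speed subject calibration speed, pixels/second.
#' @param instructed_speed "fast" or "slow".
#' @return list with \code{rt_seconds}, \code{speed_error}, \code{correct}.
#' @export
behavior_metrics <- function(t_go_cue, t_leave_center, t_hold_target,
                             center_target_distance, calibration_speed,
                             instructed_speed) {
  instructed_speed <- match.arg(instructed_speed, SPEED_LEVELS)
  if (t_leave_center < t_go_cue || t_hold_target < t_leave_center)
    stop("event times must be ordered: go cue <= leave center <= hold")
  dur <- t_hold_target - t_go_cue
  if (dur <= 0) stop("non-positive movement duration")
  if (calibration_speed <= 0) stop("calibration_speed must be positive")
  trial_speed <- (center_target_distance / dur) / calibration_speed
  se <- SPEED_MID[[instructed_speed]] - trial_speed
  list(rt_seconds = t_leave_center - t_go_cue,
       speed_error = se,
       correct = abs(se) <= SE_TOLERANCE)
}

#' Read / write trial tables as delimited text
#'
#' @param path file path; format is CSV with the trial_table columns.
#' @return \code{read_trials} returns a \code{trial_table}.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_table(subject_id = df$subject_id, speed = df$speed,
              direction = df$direction, perturbation = df$perturbation,
              rt_seconds = df$rt_seconds, speed_error = df$speed_error,
              completed = df$completed,
              perturb_force = df$perturb_force,
              perturb_angle = df$perturb_angle)
}

#' @rdname read_trials
#' @param trials a \code{trial_table}.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
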