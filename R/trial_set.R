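#' Construct a single cursor trajectory
#'
#' A trajectory is the time-stamped cursor path of one trial during the
#' stimulus phase: time in seconds since stimulus onset and screen position
#' in pixels.
#'
#' @param t numeric vector of timestamps (s), strictly increasing, first
#'   value \eqn{\ge 0}.
#' @param x,y numeric vectors of cursor positions (px), same length as `t`.
#' @return A `trajectory` object (data.frame with columns `t`, `x`, `y`).
#' @export
trajectory <- function(t, x, y) {
  if (length(t) < 2L)
    stop("degenerate trajectory: fewer than 2 samples", call. = FALSE)
  if (length(x) != length(t) || length(y) != length(t))
    stop("t, x, y must have equal length", call. = FALSE)
  if (anyNA(t) || anyNA(x) || anyNA(y))
    stop("trajectory contains missing values", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timestamps not increasing", call. = FALSE)
  if (t[1L] < 0)
    stop("first timestamp is negative", call. = FALSE)
  new_trajectory(as.numeric(t), as.numeric(x), as.numeric(y))
}

# fast constructor for inputs already known to satisfy the invariants
new_trajectory <- function(t, x, y) {
  structure(list(t = t, x = x, y = y),
            class = c("trajectory", "data.frame"),
            row.names = c(NA_integer_, -length(t)))
}

#' Center and mirror a trajectory
#'
#' Shifts the horizontal coordinate so movement starts at `x = 0` and mirrors
#' trajectories of right-side responses to the left, so that all trials share
#' one spatial frame (the chosen response box lies at negative x).  Vertical
#' coordinate and timestamps are untouched.  Idempotent for already-centered
#' left-response trajectories.
#'
#' @param traj a [trajectory()].
#' @param response_side `"left"` or `"right"`.
#' @return The preprocessed `trajectory`.
#' @export
preprocess_trajectory <- function(traj, response_side) {
  stopifnot(inherits(traj, "trajectory"))
  response_side <- match.arg(response_side, c("left", "right"))
  x <- traj$x - traj$x[1L]
  if (response_side == "right") x <- -x
  trajectory(traj$t, x, traj$y)
}

#' Step-wise speed and acceleration of a trajectory
#'
#' Speed is the 2-D Euclidean displacement per inter-sample step divided by
#' the step duration; each step is attributed to the timestamp of its later
#' endpoint.  Acceleration is the finite difference of speed over those
#' timestamps (one fewer value than speed).
#'
#' @param traj a [trajectory()] with at least 2 samples (3 for acceleration).
#' @return A list with `t_mid` (step timestamps), `speed` (px/s) and `accel`
#'   (px/s^2; `numeric(0)` when fewer than 3 samples).
#' @export
kinematics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- diff(traj$t)
  if (any(dt == 0)) stop("duplicate timestamps", call. = FALSE)
  disp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  speed <- disp / dt
  t_mid <- traj$t[-1L]
  accel <- if (length(speed) >= 2L) diff(speed) / diff(t_mid) else numeric(0)
  list(t_mid = t_mid, speed = speed, accel = accel)
}

new_trial_set <- function(trials, trajectories) {
  rownames(trials) <- NULL
  structure(list(trials = trials, trajectories = trajectories),
            class = "trial_set")
}

traj_key <- function(participant, trial) paste(participant, trial, sep = "\r")

#' @export
print.trial_set <- function(x, ...) {
  cat("Trial set:", nrow(x$trials), "trials,",
      length(unique(x$trials$participant)), "participants\n")
  cat("  preprocessed:", isTRUE(attr(x, "preprocessed")), "\n")
  invisible(x)
}

#' Number of trials in a trial set
#' @param x a `trial_set`.
#' @param ... unused.
#' @export
ntrials <- function(x, ...) nrow(x$trials)

#' Load cursor trajectories and a trial table
#'
#' Reads a long-format trajectory CSV (`participant,trial,t,x,y`) and a trial
#' table CSV (`participant,trial,stimulus_side,response_side,accuracy,rt`)
#' and joins them into a `trial_set`.  Trajectories are kept raw; call
#' [preprocess_trials()] before measure extraction.
#'
#' @param trajectory_file,trial_file paths to the two CSV files.
#' @param t_unit `"s"` or `"ms"`: unit of the trajectory `t` column.
#' @param flip_y if `TRUE`, negate y (for raw screen coordinates where y
#'   grows downward; the package convention is y growing toward the response
#'   boxes).
#' @return A `trial_set`.
#' @export
load_trials <- function(trajectory_file, trial_file, t_unit = c("s", "ms"),
                        flip_y = FALSE) {
  t_unit <- match.arg(t_unit)
  for (f in c(trajectory_file, trial_file))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  traj <- read.csv(trajectory_file, stringsAsFactors = FALSE)
  trials <- read.csv(trial_file, stringsAsFactors = FALSE)
  need_traj <- c("participant", "trial", "t", "x", "y")
  need_tr <- c("participant", "trial", "stimulus_side", "response_side",
               "accuracy", "rt")
  for (col in need_traj)
    if (!col %in% names(traj))
      stop("trajectory file missing column '", col, "'", call. = FALSE)
  for (col in need_tr)
    if (!col %in% names(trials))
      stop("trial file missing column '", col, "'", call. = FALSE)
  if (!is.numeric(traj$t))
    stop("trajectory column 't' is not numeric", call. = FALSE)
  keep <- complete.cases(traj[, c("t", "x", "y")])
  traj <- traj[keep, , drop = FALSE]
  if (t_unit == "ms") traj$t <- traj$t / 1000
  if (flip_y) traj$y <- -traj$y
  validate_trial_table(trials)
  key <- traj_key(traj$participant, traj$trial)
  trajs <- split(traj[, c("t", "x", "y")], factor(key, levels = unique(key)))
  wanted <- traj_key(trials$participant, trials$trial)
  missing_traj <- setdiff(wanted, names(trajs))
  if (length(missing_traj) > 0L)
    stop("trial table references trials without trajectory rows: ",
         paste(gsub("\r", "/", utils::head(missing_traj, 5L)), collapse = ", "),
         call. = FALSE)
  trajs <- lapply(trajs[wanted], function(d) trajectory(d$t, d$x, d$y))
  names(trajs) <- wanted
  new_trial_set(trials, trajs)
}

validate_trial_table <- function(trials) {
  ok_side <- c("left", "right")
  if (!all(trials$stimulus_side %in% ok_side) ||
      !all(trials$response_side %in% ok_side))
    stop("stimulus_side/response_side must be 'left' or 'right'", call. = FALSE)
  if (!all(trials$accuracy %in% c(0, 1)))
    stop("accuracy must be 0 or 1", call. = FALSE)
  if (any(trials$accuracy != as.integer(trials$response_side == trials$stimulus_side)))
    stop("accuracy inconsistent with stimulus/response sides", call. = FALSE)
  if (any(trials$rt <= 0))
    stop("non-positive rt", call. = FALSE)
  dup <- duplicated(traj_key(trials$participant, trials$trial))
  if (any(dup))
    stop("duplicated participant/trial index", call. = FALSE)
  invisible(TRUE)
}

#' Preprocess all trajectories of a trial set
#'
#' Applies [preprocess_trajectory()] (x-centering and left-mirroring) to
#' every trial using its recorded response side.
#'
#' @param ts a `trial_set`.
#' @return The `trial_set` with preprocessed trajectories.
#' @export
preprocess_trials <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  key <- traj_key(ts$trials$participant, ts$trials$trial)
  ts$trajectories[key] <- Map(preprocess_trajectory,
                              ts$trajectories[key],
                              ts$trials$response_side)
  attr(ts, "preprocessed") <- TRUE
  ts
}

#' Subset a trial set
#'
#' @param ts a `trial_set`.
#' @param idx logical or integer index into the trial table.
#' @return A `trial_set` containing only the selected trials.
#' @export
subset_trials <- function(ts, idx) {
  trials <- ts$trials[idx, , drop = FALSE]
  key <- traj_key(trials$participant, trials$trial)
  out <- new_trial_set(trials, ts$trajectories[key])
  attr(out, "preprocessed") <- attr(ts, "preprocessed")
  out
}

#' Write a trial set to CSV files
#'
#' Inverse of [load_trials()]: writes the long-format trajectory file and the
#' trial table.
#'
#' @param ts a `trial_set`.
#' @param trajectory_file,trial_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_trials <- function(ts, trajectory_file, trial_file) {
  key <- traj_key(ts$trials$participant, ts$trials$trial)
  rows <- Map(function(k, p, tr) {
    d <- ts$trajectories[[k]]
    data.frame(participant = p, trial = tr, t = d$t, x = d$x, y = d$y)
  }, key, ts$trials$participant, ts$trials$trial)
  traj <- do.call(rbind, rows)
  write.csv(traj, trajectory_file, row.names = FALSE, quote = FALSE)
  write.csv(ts$trials, trial_file, row.names = FALSE, quote = FALSE)
  invisible(c(trajectory_file, trial_file))
}
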