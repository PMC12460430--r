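#' Names of the 18 cursor measures
#' @return Character vector of measure names.
#' @export
measure_names <- function() {
  c("accChanges", "AD", "AUC", "curvature", "MAD", "MADabove", "maxAcc",
    "maxVel", "meanVel", "minVel", "minX", "motorPauses", "motionTime",
    "reversals", "sampleEnX", "timeToPeakAcc", "timeToPeakVel", "xFlips")
}

#' Computation-cost precedence of measures and behavioral variables
#'
#' Ranking used by [correlation_reduce()] to decide which member of a highly
#' correlated pair is discarded: the cheaper (earlier) variable is retained.
#' RT and accuracy head the ranking (they come for free with any response)
#' and are never discarded themselves.  Deviation measures are ordered by the
#' number of computational steps: a single max over deviations (MAD) is
#' cheaper than the one-sided max (MADabove), which is cheaper than the area
#' integral (AUC) and the full average (AD); velocity extrema precede
#' acceleration extrema (one less differentiation); timing-of-peak and
#' complexity measures are the most expensive.
#'
#' @return Character vector, cheapest first.
#' @export
measure_precedence <- function() {
  c("rt", "accuracy",
    "minX", "MAD", "MADabove", "AUC", "AD",
    "maxVel", "minVel", "maxAcc", "meanVel",
    "motionTime", "motorPauses",
    "timeToPeakVel", "timeToPeakAcc",
    "xFlips", "reversals", "accChanges",
    "curvature", "sampleEnX")
}

# signed perpendicular deviation of every point from the chord; positive on
# the non-chosen (right) side under the left-mirrored convention
signed_deviation <- function(traj) {
  n <- nrow(traj)
  dx <- traj$x[n] - traj$x[1L]
  dy <- traj$y[n] - traj$y[1L]
  L <- sqrt(dx^2 + dy^2)
  if (L == 0)
    stop("undefined deviation: trajectory starts and ends at the same point",
         call. = FALSE)
  d <- (dy * (traj$x - traj$x[1L]) - dx * (traj$y - traj$y[1L])) / L
  # arc position: scalar projection onto the chord
  s <- ((traj$x - traj$x[1L]) * dx + (traj$y - traj$y[1L]) * dy) / L
  list(d = d, s = s, chord = L)
}

#' Deviation measures of a preprocessed trajectory
#'
#' The optimal trajectory is the straight segment from the first to the last
#' recorded point.  Signed perpendicular deviation is positive toward the
#' non-chosen (right) response side.
#'
#' @param traj preprocessed [trajectory()] (x-centered, left-mirrored).
#' @return Named list: `AD` mean absolute deviation (px); `AUC` absolute area
#'   between path and chord (px^2, trapezoid over the chord projection);
#'   `MAD` max absolute deviation (px); `MADabove` max deviation toward the
#'   non-chosen side (px, 0 if the path never deviates that way); `minX`
#'   closest horizontal approach to the alternative side, reported as the
#'   largest x attained (px); `curvature` path length / chord length (>= 1).
#' @export
deviation_measures <- function(traj) {
  sd_ <- signed_deviation(traj)
  d <- sd_$d
  path_len <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  auc <- abs(sum(diff(sd_$s) * (head(d, -1L) + tail(d, -1L)) / 2))
  list(AD = mean(abs(d)),
       AUC = auc,
       MAD = max(abs(d)),
       MADabove = max(c(d[d > 0], 0)),
       minX = max(traj$x),
       curvature = path_len / sd_$chord)
}

#' Velocity, acceleration and timing measures
#'
#' @param traj preprocessed [trajectory()] with at least 3 samples.
#' @param kin optional precomputed [kinematics()].
#' @param pause_tol displacement (px) at or below which a step counts as a
#'   motor pause; default 0 (strict).
#' @return Named list: `maxVel`, `minVel` (px/s, step-speed extremes),
#'   `meanVel` (px/s, time-weighted: total path length / total duration),
#'   `maxAcc` (px/s^2), `timeToPeakVel`, `timeToPeakAcc` (s since stimulus
#'   onset, first maximum), `motorPauses` (summed duration of zero-
#'   displacement steps, s), `motionTime` (total duration minus pauses, s).
#' @export
kinematic_measures <- function(traj, kin = kinematics(traj), pause_tol = 0) {
  if (nrow(traj) < 3L) stop("need at least 3 samples", call. = FALSE)
  dt <- diff(traj$t)
  duration <- traj$t[nrow(traj)] - traj$t[1L]
  disp <- kin$speed * dt
  pauses <- sum(dt[disp <= pause_tol])
  t_acc <- kin$t_mid[-1L]   # accel value i spans steps i, i+1
  list(maxVel = max(kin$speed),
       minVel = min(kin$speed),
       meanVel = sum(disp) / duration,
       maxAcc = max(kin$accel),
       timeToPeakVel = kin$t_mid[which.max(kin$speed)],
       timeToPeakAcc = t_acc[which.max(kin$accel)],
       motorPauses = pauses,
       motionTime = duration - pauses)
}

# count sign changes in a sequence after dropping zeros
sign_changes <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Direction-change and midline-crossing counts
#'
#' @param traj preprocessed [trajectory()].
#' @param kin optional precomputed [kinematics()].
#' @return Named list: `xFlips` sign changes of consecutive nonzero
#'   horizontal steps (zero steps skipped); `reversals` crossings of the
#'   vertical start line x = 0 after the first departure, a touch-and-return
#'   counting once; `accChanges` sign changes of consecutive nonzero
#'   acceleration values.
#' @export
count_measures <- function(traj, kin = kinematics(traj)) {
  xflips <- sign_changes(diff(traj$x))
  acc_changes <- sign_changes(kin$accel)
  # reversals: returns to / crossings of the start line x = x[1] after the
  # first departure; a touch-and-return counts once, and a crossing through
  # a sampled zero also counts once
  r <- rle(sign(traj$x - traj$x[1L]))
  v <- r$values
  if (length(v) > 0L && v[1L] == 0) v <- v[-1L]
  rev_count <- 0L
  if (length(v) > 1L) {
    nz <- v[v != 0]
    rev_count <- sum(nz[-1L] != nz[-length(nz)])
    zi <- which(v == 0)
    zi <- zi[zi > 1L]                   # zero-runs after the departure
    if (length(zi) > 0L) {
      nxt <- ifelse(zi < length(v), v[pmin(zi + 1L, length(v))], NA)
      prev <- v[zi - 1L]
      rev_count <- rev_count + sum(is.na(nxt) | nxt == prev)
    }
  }
  list(xFlips = xflips, reversals = as.integer(rev_count),
       accChanges = acc_changes)
}

#' Sample entropy of the differenced horizontal coordinate
#'
#' SampEn(m, r) of the first-differenced x series: the negative log of the
#' ratio of (m+1)-length to m-length template matches within Chebyshev
#' tolerance `r = r_frac * SD(series)`, self-matches excluded.  Larger values
#' indicate a more irregular lateral movement.  Amplitude-invariant because
#' the tolerance scales with the series SD.
#'
#' @param traj a [trajectory()]; entropy is computed on `diff(x)`.
#' @param m embedding dimension (template length), default 2.
#' @param r_frac tolerance as a fraction of the series SD, default 0.2.
#' @return SampEn value (>= 0); 0 when every m-template match extends to an
#'   (m+1)-match; `NA` when no m-template matches exist.
#' @export
sample_entropy_x <- function(traj, m = 2L, r_frac = 0.2) {
  d <- diff(traj$x)
  sample_entropy(d, m = m, r_frac = r_frac)
}

#' Sample entropy of a numeric series
#' @param series numeric vector, length >= m + 2.
#' @param m embedding dimension.
#' @param r_frac tolerance as a fraction of `sd(series)`; for a constant
#'   series the tolerance collapses to 0 but all templates still match
#'   exactly, giving SampEn 0.
#' @return SampEn value, or `NA` when no m-length template matches exist.
#' @export
sample_entropy <- function(series, m = 2L, r_frac = 0.2) {
  if (length(series) < m + 2L)
    stop("series too short for sample entropy (need length >= m + 2)",
         call. = FALSE)
  r <- r_frac * sd(series)
  cnt <- sampen_counts_cpp(as.numeric(series), as.integer(m), r)
  if (cnt$B == 0) return(NA_real_)
  if (cnt$A == 0) return(NA_real_)      # -log(0) undefined; flag as missing
  -log(cnt$A / cnt$B)
}

#' All 18 cursor measures of one trial
#'
#' @param traj preprocessed [trajectory()].
#' @param sampen_m,sampen_r_frac sample-entropy parameters.
#' @param pause_tol motor-pause displacement tolerance (px).
#' @return Named numeric vector with the 18 measures of [measure_names()].
#'   Individual measure failures surface as `NA` cells, never as dropped
#'   trials.
#' @export
trial_measures <- function(traj, sampen_m = 2L, sampen_r_frac = 0.2,
                           pause_tol = 0) {
  kin <- kinematics(traj)
  dev <- tryCatch(deviation_measures(traj),
                  error = function(e) list(AD = NA_real_, AUC = NA_real_,
                                           MAD = NA_real_, MADabove = NA_real_,
                                           minX = max(traj$x),
                                           curvature = NA_real_))
  kinm <- kinematic_measures(traj, kin, pause_tol = pause_tol)
  cnt <- count_measures(traj, kin)
  sen <- tryCatch(sample_entropy_x(traj, sampen_m, sampen_r_frac),
                  error = function(e) NA_real_)
  out <- c(accChanges = cnt$accChanges, AD = dev$AD, AUC = dev$AUC,
           curvature = dev$curvature, MAD = dev$MAD, MADabove = dev$MADabove,
           maxAcc = kinm$maxAcc, maxVel = kinm$maxVel, meanVel = kinm$meanVel,
           minVel = kinm$minVel, minX = dev$minX,
           motorPauses = kinm$motorPauses, motionTime = kinm$motionTime,
           reversals = cnt$reversals, sampleEnX = sen,
           timeToPeakAcc = kinm$timeToPeakAcc,
           timeToPeakVel = kinm$timeToPeakVel, xFlips = cnt$xFlips)
  out[measure_names()]
}

#' Cursor measures for every trial of a trial set
#'
#' @param ts a preprocessed `trial_set` (see [preprocess_trials()]).
#' @param ... passed to [trial_measures()].
#' @return data.frame with participant, trial, rt, accuracy and the 18
#'   measure columns, one row per trial.
#' @export
cursor_measures <- function(ts, ...) {
  stopifnot(inherits(ts, "trial_set"))
  if (!isTRUE(attr(ts, "preprocessed")))
    ts <- preprocess_trials(ts)
  key <- traj_key(ts$trials$participant, ts$trials$trial)
  mm <- t(vapply(ts$trajectories[key], function(tr) trial_measures(tr, ...),
                 numeric(18L)))
  out <- data.frame(participant = ts$trials$participant,
                    trial = ts$trials$trial,
                    rt = ts$trials$rt,
                    accuracy = ts$trials$accuracy)
  cbind(out, as.data.frame(mm, row.names = seq_len(nrow(mm))))
}

#' Participant-level mean measures
#'
#' Arithmetic mean of each cursor measure, RT and accuracy over a
#' participant's retained trials; correct and error trials are both included.
#' All means are taken over the same trial subset.
#'
#' @param trial_table output of [cursor_measures()] (possibly after outlier
#'   filtering).  Trials with any flagged-missing measure cell are excluded
#'   so that every mean is taken over the same trial subset; the retained
#'   count is reported in `n_trials`.
#' @return data.frame with one row per participant: `participant`,
#'   `n_trials`, `rt`, `accuracy` and the 18 measure means.
#' @export
participant_measures <- function(trial_table) {
  cols <- c("rt", "accuracy", measure_names())
  ok <- complete.cases(trial_table[, cols])
  trial_table <- trial_table[ok, , drop = FALSE]
  sp <- split(trial_table, trial_table$participant)
  rows <- lapply(sp, function(d) {
    means <- colMeans(d[, cols, drop = FALSE])
    cbind(data.frame(participant = d$participant[1L], n_trials = nrow(d)),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
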