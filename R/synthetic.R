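#' Configuration of a synthetic cohort
#'
#' Defaults emulate the shape of a 103-participant, 90-trial,
#' two-alternative forced-choice cursor-tracking session: per-participant
#' DDM parameters drawn from a truncated trivariate normal, per-trial
#' choices and response times simulated from the DDM with a 2-s response
#' ceiling, and cursor trajectories generated by a motor model whose
#' kinematics are coupled to the decision process.
#'
#' The motor couplings plant recoverable, sign-correct associations between
#' cursor measures and DDM parameters: lateral movement irregularity
#' (white-vs-oscillatory noise mix) decreases with drift rate
#' (`sampleEnX` vs `v` negative); the single velocity peak sits shortly
#' after the decision event, so its latency grows with threshold separation
#' via the decision time (`timeToPeakVel` vs `a` positive); the ballistic
#' response segment spans the motor share of the non-decision time, so its
#' peak speed falls with `t0` (`maxVel` vs `t0` negative) while speed jitter
#' grows with `t0` (`accChanges` vs `t0` positive).  Each coupling gain can
#' be set to 0 independently for ablation.
#'
#' @param n_participants,n_trials cohort size (defaults 103 x 90).
#' @param param_mean,param_sd,param_cor mean, SD and correlation matrix of
#'   the participant-level (v, a, t0) distribution.
#' @param param_lower,param_upper truncation bounds (rejection sampling).
#' @param fs cursor sampling rate (Hz).
#' @param rt_cap response ceiling (s); slower simulated trials are redrawn.
#' @param dt Euler step of the decision simulator (s).
#' @param ev_logit_gain gain with which the scaled evidence biases the
#'   lateral step direction (the cursor drifts toward the currently favored
#'   side; noisier, slower evidence yields a more erratic x path).
#' @param sine_logit_gain gain of the smooth oscillatory component of the
#'   lateral step-direction logit; its weight is `(1 - omega)`, so
#'   low-drift participants (high `omega`) step near-randomly while
#'   high-drift participants oscillate regularly.
#' @param x_target,y_total response-box lateral offset and vertical travel
#'   (px).
#' @param vy_base baseline pre-decision upward speed (px/s).
#' @param amp_lateral magnitude (px) of the constant-size lateral impulses
#'   of the pre-decision phase.  Lateral impulses switch direction but not
#'   size, so the lateral complexity channel cannot leak into the
#'   acceleration-based measures.
#' @param lat_every lateral impulses occur on every `lat_every`-th sample
#'   (hand wiggles live at a few Hz, well below the sampling rate); the
#'   decimation keeps the lateral contribution to path length small.
#' @param pixel_noise SD (px) of white lateral sensor noise added to the
#'   reported x positions; sub-pixel, so it perturbs direction-flip counts
#'   but stays far below the sample-entropy tolerance.
#' @param entropy_gain,entropy_noise gain of the drift-rate to noise-
#'   whiteness coupling and SD of its participant-level disturbance.
#' @param jitter_base speed-jitter magnitude (fraction of the step
#'   displacement).
#' @param jitter_k0 baseline smoothing window (samples) of the speed-jitter
#'   noise; jerky movers have window 1 (white jitter, many acceleration
#'   sign flips), smooth movers a long window (few flips).
#' @param jitter_gain log-scale gain of the t0 to jitter-smoothness
#'   coupling (slower responders move more jerkily).
#' @param jitter_noise SD of the participant-level disturbance on the
#'   log smoothing window.
#' @param pause_prob per-sample probability of starting a motor pause.
#' @param encode_frac share of the non-decision time spent on pre-decision
#'   encoding (the rest is the post-decision ballistic motor segment).
#' @param ballistic_noise SD of the participant-level log-normal multiplier
#'   on the ballistic segment duration; gives the velocity-peak latency a
#'   variance component independent of the response time.
#' @param peak_sharpness baseline shape parameter of the ballistic velocity
#'   profile (beta-density profile; larger = sharper, higher peak for the
#'   same distance and duration).
#' @param peak_gain log-scale gain of the t0 to sharpness coupling (fast
#'   responders flick, slow responders glide: peak speed falls with t0).
#' @param peak_mode baseline position of the velocity peak within the
#'   ballistic segment (fraction of its duration); the peak sits shortly
#'   after the decision event.
#' @param peak_pos_gain logit-scale gain of the t0 to peak-position
#'   coupling: fast responders flick (early, sharp peak), slow responders
#'   glide (later, flatter peak).
#' @param seed master seed (required for generation).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 103L, n_trials = 90L,
                          param_mean = c(v = 0.65, a = 2.0, t0 = 0.35),
                          param_sd = c(v = 0.35, a = 0.45, t0 = 0.13),
                          param_cor = diag(3),
                          param_lower = c(v = 0.05, a = 0.8, t0 = 0.15),
                          param_upper = c(v = 3.0, a = 3.5, t0 = 0.60),
                          fs = 107, rt_cap = 2.0, dt = 1e-3,
                          ev_logit_gain = 2.0, sine_logit_gain = 6,
                          x_target = 820, y_total = 900,
                          vy_base = 420, amp_lateral = 8, lat_every = 1L,
                          pixel_noise = 0,
                          ballistic_noise = 1.0,
                          peak_sharpness = 2.2, peak_gain = 8,
                          peak_mode = 0.15, peak_pos_gain = 0,
                          entropy_gain = 3.0, entropy_noise = 0.35,
                          jitter_base = 0.3, jitter_k0 = 4,
                          jitter_gain = 7.0, jitter_noise = 0.4,
                          pause_prob = 0.02, encode_frac = 0.6,
                          seed = NULL) {
  cov <- diag(param_sd) %*% param_cor %*% diag(param_sd)
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("parameter covariance is not positive semi-definite", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d participants x %d trials, %g Hz, rt cap %g s\n",
              x$n_participants, x$n_trials, x$fs, x$rt_cap))
  invisible(x)
}

# rejection-sample participant parameter triples from the truncated MVN
draw_participant_params <- function(config) {
  mu <- config$param_mean
  cov <- diag(config$param_sd) %*% config$param_cor %*% diag(config$param_sd)
  n <- config$n_participants
  out <- matrix(NA_real_, 0L, 3L)
  drawn <- 0L
  accepted <- 0L
  while (nrow(out) < n) {
    cand <- MASS::mvrnorm(max(n, 50L), mu, cov)
    ok <- cand[, 1L] >= config$param_lower[1L] & cand[, 1L] <= config$param_upper[1L] &
      cand[, 2L] >= config$param_lower[2L] & cand[, 2L] <= config$param_upper[2L] &
      cand[, 3L] >= config$param_lower[3L] & cand[, 3L] <= config$param_upper[3L]
    drawn <- drawn + nrow(cand)
    accepted <- accepted + sum(ok)
    out <- rbind(out, cand[ok, , drop = FALSE])
    if (drawn >= 100L * n && accepted / drawn < 0.01)
      stop("infeasible truncation: acceptance rate below 1%", call. = FALSE)
  }
  list(params = out[seq_len(n), , drop = FALSE],
       acceptance = accepted / drawn)
}

# smooth oscillatory lateral noise: unit-amplitude sine with random phase
sine_noise <- function(t, freq, phase) sin(2 * pi * freq * t + phase)

#' Generate one cursor trajectory from a decision process
#'
#' Motor model used by [generate_cohort()].  Before the decision event the
#' cursor climbs at the baseline speed while its lateral position tracks the
#' scaled evidence path plus structured noise; after the decision a
#' minimum-jerk ballistic segment moves to the chosen response box with a
#' single velocity peak at its midpoint.  Speed jitter multiplies all step
#' displacements; motor pauses freeze the cursor for geometric-length runs.
#'
#' @param evidence evidence path at `dt` resolution (from
#'   [ddm_simulate_path()]), starting at `zr * a`.
#' @param decision_time decision duration (s, > 0).
#' @param choice 1 = upper boundary (correct side), 0 = lower.
#' @param rt total trial duration (s).
#' @param stimulus_sign -1 for a left stimulus, +1 for right.
#' @param a threshold separation used to scale the evidence.
#' @param motor list of participant motor traits: `omega` (randomness of
#'   the lateral sign process in \[0,1\]), `amp_lat` (lateral step size,
#'   px), `sharp` (ballistic velocity-profile shape), `jitter` (speed
#'   jitter SD as a fraction), `jitter_k` (jitter smoothing window,
#'   samples), `pause_prob`, `vy` (pre-decision upward speed, px/s),
#'   `sine_freq` (Hz), `sine_phase`, `bmult` (ballistic duration
#'   multiplier), `ev_logit_gain`, `sine_logit_gain`, `encode_frac`,
#'   `lat_every`, `pixel_noise`, and the geometry `x_target`, `y_total`.
#' @param fs sampling rate (Hz).
#' @param dt evidence-path resolution (s).
#' @return A [trajectory()] in generator coordinates (x centered on the
#'   screen midline at 960 px, y increasing toward the response boxes).
#' @export
trajectory_from_decision <- function(evidence, decision_time, choice, rt,
                                     stimulus_sign, a, motor, fs = 107,
                                     dt = 1e-3) {
  if (decision_time <= 0) stop("decision_time must be > 0", call. = FALSE)
  t <- seq(0, rt, by = 1 / fs)
  if (length(t) < 4L) t <- seq(0, rt, length.out = 4L)
  n <- length(t)
  # ballistic segment: the motor share of the trial's non-decision time,
  # scaled by a participant-level log-normal multiplier and clamped so
  # that a pre-decision phase of at least 3 samples remains
  t0_trial <- rt - decision_time
  tau_b <- min(max((1 - motor$encode_frac) * t0_trial * motor$bmult, 3 / fs),
               0.8 * rt)
  t_dec <- rt - tau_b
  t_enc <- max(t_dec - decision_time, 0)
  resp_sign <- if (choice == 1L) stimulus_sign else -stimulus_sign
  # evidence drive, scaled to [-1, 1] and oriented toward the stimulus
  # side; the [t_enc, t_dec] window maps linearly onto the evidence path
  ev_scaled <- (evidence / a - 0.5) * 2
  ev_at <- function(tq) {
    frac <- (tq - t_enc) / max(t_dec - t_enc, 1e-9)
    idx <- pmin(pmax(round(frac * (length(ev_scaled) - 1L)), 0),
                length(ev_scaled) - 1L) + 1L
    out <- ev_scaled[idx]
    out[tq < t_enc] <- 0
    out
  }
  pre <- t < t_dec
  x <- numeric(n); y <- numeric(n)
  # pre-decision lateral channel: constant-magnitude steps whose direction
  # is a Bernoulli sign process.  The logit mixes a smooth oscillation
  # (weight 1 - omega) with the scaled evidence, so the cursor drifts
  # toward the currently favored side; for high omega the signs are close
  # to random and the x series is irregular.  Constant step size keeps the
  # pre-decision speed exactly flat, so this channel cannot leak into the
  # acceleration-based measures.
  n_pre <- sum(pre)
  if (n_pre > 1L) {
    # lateral impulses on a decimated clock (every lat_every-th sample):
    # hand wiggles live at a few Hz, far below the sampling rate, and the
    # decimation keeps the lateral path-length contribution small
    L <- if (is.null(motor$lat_every)) 1L else motor$lat_every
    active <- (seq_len(n_pre - 1L) - 1L) %% L == 0L
    n_s <- sum(active)
    ta <- t[pre][-1L][active]
    # step-direction logit: a smooth oscillation (weight 1 - omega) plus
    # the scaled evidence; high-omega participants step near-randomly
    logit <- (1 - motor$omega) * motor$sine_logit_gain *
      sine_noise(ta, motor$sine_freq, motor$sine_phase) +
      motor$ev_logit_gain * stimulus_sign * ev_at(ta)
    sgn <- numeric(n_pre - 1L)
    sgn[active] <- ifelse(runif(n_s) < stats::plogis(logit), 1, -1)
    x[pre] <- c(0, cumsum(motor$amp_lat * sgn))
  }
  y[pre] <- motor$vy * t[pre]
  # ballistic segment to the chosen box: symmetric beta-density velocity
  # profile; sharper profiles reach a higher peak over the same distance
  # and duration (peak speed at the segment midpoint)
  post <- !pre
  if (any(post)) {
    i0 <- max(which(pre))
    x0 <- x[i0]; y0 <- y[i0]
    Tb <- rt - t[i0]
    tau <- pmin((t[post] - t[i0]) / max(Tb, 1e-6), 1)
    pk <- if (is.null(motor$peak_pos)) 0.5 else motor$peak_pos
    s <- stats::pbeta(tau, 1 + 2 * motor$sharp * pk,
                      1 + 2 * motor$sharp * (1 - pk))
    x[post] <- x0 + (resp_sign * motor$x_target - x0) * s
    y[post] <- y0 + (motor$y_total - y0) * s
  }
  dx2 <- diff(x); dy2 <- diff(y)
  # speed jitter: multiplicative noise on step displacements, smoothed over
  # jitter_k samples.  A window of 1 gives white jitter (acceleration flips
  # on most steps); long windows give slowly varying speed (few flips), so
  # the acceleration sign-change count tracks movement jerkiness, not just
  # trial duration.
  k <- motor$jitter_k
  eta <- rnorm(n - 1L + k - 1L)
  if (k > 1L) {
    eta <- as.numeric(stats::filter(eta, rep(1 / k, k), sides = 1L))
    eta <- eta[k:(n - 2L + k)] * sqrt(k)
  }
  mult <- pmax(1 + motor$jitter * eta, 0.05)
  # motor pauses: geometric-length frozen runs, pre-decision only; every
  # trial gets at least one (cursor speed always touches zero somewhere)
  pause <- runif(n - 1L) < motor$pause_prob & t[-n] < t_dec
  pre_idx <- which(t[-n] < t_dec)
  if (length(pre_idx) > 0L && !any(pause))
    pause[pre_idx[sample.int(length(pre_idx), 1L)]] <- TRUE
  run <- which(pause)
  if (length(run) > 0L) {
    extra <- unlist(lapply(run, function(i) i + seq_len(rgeom(1L, 0.4))))
    pause[extra[extra <= n - 1L]] <- TRUE
  }
  mult[pause] <- 0
  # pre-decision lateral steps keep their exact magnitude (jitter acts on
  # the vertical channel there), so the x series carries only the sign
  # process and the pauses; the ballistic segment is jittered as a whole
  mult_x <- mult
  pre_step <- t[-n] < t_dec
  mult_x[pre_step & !pause] <- 1
  x <- c(x[1L], x[1L] + cumsum(dx2 * mult_x))
  y <- c(y[1L], y[1L] + cumsum(dy2 * mult))
  # sub-pixel lateral sensor noise: visible to direction-flip counting but
  # far below the sample-entropy tolerance
  px <- if (is.null(motor$pixel_noise)) 0 else motor$pixel_noise
  if (px > 0) x <- x + rnorm(length(x), 0, px)
  new_trajectory(t, 960 + x, y)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-participant DDM parameters from the truncated trivariate
#' normal, simulates each trial's choice, response time and evidence path
#' with the DDM (redrawing trials that exceed the response ceiling), and
#' renders a cursor trajectory per trial with
#' [trajectory_from_decision()].  Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()]; `seed` must be set.
#' @return List: `trials` (a raw, unpreprocessed `trial_set`), `truth`
#'   (per-participant true parameters and motor traits, per-trial decision
#'   times), `acceptance` (truncation acceptance rate).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(config$seed))
    stop("cohort generation requires an explicit seed", call. = FALSE)
  set.seed(config$seed)
  pd <- draw_participant_params(config)
  pm <- pd$params
  colnames(pm) <- c("v", "a", "t0")
  mu <- config$param_mean
  n_p <- config$n_participants
  traits <- data.frame(
    participant = sprintf("p%03d", seq_len(n_p)),
    v = pm[, "v"], a = pm[, "a"], t0 = pm[, "t0"],
    omega = stats::plogis(config$entropy_gain * (mu[["v"]] - pm[, "v"]) +
                            rnorm(n_p, 0, config$entropy_noise)),
    amp_lat = config$amp_lateral * exp(rnorm(n_p, 0, 0.25)),
    sharp = pmin(pmax(config$peak_sharpness *
                        exp(-config$peak_gain * (pm[, "t0"] - mu[["t0"]]) +
                              rnorm(n_p, 0, 0.2)), 1), 10),
    peak_pos = stats::plogis(stats::qlogis(config$peak_mode) +
                               config$peak_pos_gain * (pm[, "t0"] - mu[["t0"]])),
    jitter = config$jitter_base * exp(rnorm(n_p, 0, 0.2)),
    jitter_k = pmax(1, pmin(15, round(
      config$jitter_k0 * exp(-config$jitter_gain * (pm[, "t0"] - mu[["t0"]]) +
                               rnorm(n_p, 0, config$jitter_noise))))),
    pause_prob = pmin(config$pause_prob * exp(rnorm(n_p, 0, 0.3)), 0.15),
    vy = config$vy_base * exp(rnorm(n_p, 0, 0.25)),
    sine_freq = runif(n_p, 1.2, 2.8),
    bmult = pmin(pmax(exp(rnorm(n_p, 0, config$ballistic_noise)), 0.35), 3.5))
  n_tot <- n_p * config$n_trials
  trajs <- vector("list", n_tot)
  col_participant <- character(n_tot); col_trial <- integer(n_tot)
  col_stim <- character(n_tot); col_resp <- character(n_tot)
  col_acc <- integer(n_tot); col_rt <- numeric(n_tot)
  col_dt <- numeric(n_tot)
  k <- 0L
  for (i in seq_len(n_p)) {
    par_i <- ddm_params(pm[i, "v"], pm[i, "a"], pm[i, "t0"])
    motor <- as.list(traits[i, c("omega", "amp_lat", "sharp", "peak_pos",
                                 "jitter", "jitter_k", "pause_prob", "vy",
                                 "sine_freq", "bmult")])
    motor$ev_logit_gain <- config$ev_logit_gain
    motor$sine_logit_gain <- config$sine_logit_gain
    motor$lat_every <- config$lat_every
    motor$pixel_noise <- config$pixel_noise
    motor$encode_frac <- config$encode_frac
    motor$amp_ev <- config$amp_ev
    motor$x_target <- config$x_target
    motor$y_total <- config$y_total
    for (j in seq_len(config$n_trials)) {
      stim_sign <- if (j %% 2L == 0L) 1 else -1   # balanced sides
      attempts <- 0L
      repeat {
        sim <- ddm_simulate_path(par_i, dt = config$dt)
        rt <- sim$decision_time + pm[i, "t0"]
        attempts <- attempts + 1L
        if (rt < config$rt_cap) break
        if (attempts > 200L)
          stop("trial redraw limit hit: rt cap too strict for parameters",
               call. = FALSE)
      }
      motor$sine_phase <- runif(1L, 0, 2 * pi)
      traj <- trajectory_from_decision(sim$path, sim$decision_time,
                                       sim$choice, rt, stim_sign,
                                       pm[i, "a"], motor,
                                       fs = config$fs, dt = config$dt)
      k <- k + 1L
      stim_side <- if (stim_sign < 0) "left" else "right"
      col_participant[k] <- traits$participant[i]
      col_trial[k] <- j
      col_stim[k] <- stim_side
      col_resp[k] <- if (sim$choice == 1L) stim_side else
        setdiff(c("left", "right"), stim_side)
      col_acc[k] <- sim$choice
      col_rt[k] <- rt
      col_dt[k] <- sim$decision_time
      trajs[[k]] <- traj
    }
  }
  trials <- data.frame(participant = col_participant, trial = col_trial,
                       stimulus_side = col_stim, response_side = col_resp,
                       accuracy = col_acc, rt = col_rt)
  names(trajs) <- traj_key(trials$participant, trials$trial)
  truth_trials <- data.frame(participant = col_participant,
                             trial = col_trial, decision_time = col_dt,
                             choice = col_acc)
  list(trials = new_trial_set(trials, trajs),
       truth = list(participants = traits, trials = truth_trials),
       acceptance = pd$acceptance)
}
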