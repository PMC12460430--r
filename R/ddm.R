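#' Drift diffusion model parameters
#'
#' Container for the three free DDM parameters used throughout the package.
#' The relative start point is fixed at the neutral value `zr = 0.5` and the
#' diffusion coefficient at `s = 1`; inter-trial variability parameters are
#' fixed at 0.
#'
#' @param v drift rate (evidence units per second, s = 1 scale).
#' @param a threshold separation (> 0).
#' @param t0 non-decision time in seconds (>= 0).
#' @return A named numeric vector of class `ddm_params`.
#' @export
ddm_params <- function(v, a, t0) {
  if (!is.finite(v) || !is.finite(a) || !is.finite(t0))
    stop("non-finite DDM parameter", call. = FALSE)
  if (a <= 0) stop("threshold separation a must be > 0", call. = FALSE)
  if (t0 < 0) stop("non-decision time t0 must be >= 0", call. = FALSE)
  structure(c(v = unname(v), a = unname(a), t0 = unname(t0)),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.4f, a = %.4f, t0 = %.4f (zr = 0.5, s = 1)\n",
              x[["v"]], x[["a"]], x[["t0"]]))
  invisible(x)
}

#' Log density of the Wiener first-passage time
#'
#' Log of the defective first-passage density of a drift diffusion process
#' between two absorbing boundaries, evaluated at the observed response time
#' and boundary.  The lower-boundary density uses the dual small-time /
#' large-time series with automatic switching; the upper boundary follows by
#' the reflection `v -> -v`, `zr -> 1 - zr`.
#'
#' @param rt response time(s) in seconds (including non-decision time).
#' @param choice `"upper"`/`"lower"`, or 1/0.
#' @param params a [ddm_params()].
#' @param zr relative start point (fixed 0.5 in the pipeline).
#' @param eps truncation error of the series.
#' @return Vector of log densities; `-Inf` where `rt <= t0`.
#' @export
wiener_logpdf <- function(rt, choice, params, zr = 0.5, eps = 1e-7) {
  up <- choice_to_int(choice)
  if (length(up) == 1L) up <- rep(up, length(rt))
  if (length(up) != length(rt))
    stop("rt and choice lengths differ", call. = FALSE)
  wiener_lpdf_cpp(as.numeric(rt), as.integer(up), params[["v"]],
                  params[["a"]], params[["t0"]], zr, eps)
}

choice_to_int <- function(choice) {
  if (is.character(choice)) {
    if (!all(choice %in% c("upper", "lower")))
      stop("choice must be 'upper' or 'lower'", call. = FALSE)
    as.integer(choice == "upper")
  } else {
    ch <- as.integer(choice)
    if (!all(ch %in% c(0L, 1L)))
      stop("numeric choice must be 0 (lower) or 1 (upper)", call. = FALSE)
    ch
  }
}

#' Closed-form choice probability and mean decision time
#'
#' Analytic first-passage formulas for the two-boundary diffusion: the
#' probability of absorption at the upper boundary and the mean decision
#' time (unconditional, excluding non-decision time).
#'
#' @param params a [ddm_params()].
#' @param zr relative start point.
#' @return List with `p_upper` and `mean_dt` (s).
#' @export
ddm_closed_form <- function(params, zr = 0.5) {
  v <- params[["v"]]; a <- params[["a"]]
  z <- zr * a
  p_up <- if (abs(v) < 1e-12) z / a else
    (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a))
  list(p_upper = p_up, mean_dt = mean_fpt(v, a, z))
}

# unconditional mean first-passage time of a drifted Brownian motion from z
# between 0 and a (s = 1)
mean_fpt <- function(v, a, z) {
  if (abs(v) < 1e-12) return(z * (a - z))
  p_up <- (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a))
  (a * p_up - z) / v
}

#' Simulate choices and response times from the DDM
#'
#' Euler–Maruyama random walk from `zr * a` with increments
#' `v dt + sqrt(dt) N(0,1)` until a boundary crossing; the response time is
#' the crossing time plus the non-decision time.  Reproducible under
#' `set.seed()`.
#'
#' @param params a [ddm_params()].
#' @param n number of trials.
#' @param dt Euler step (s); smaller steps reduce discretization bias at the
#'   cost of runtime.
#' @param zr relative start point.
#' @param max_time walks not absorbed by this time are censored at the
#'   nearer boundary (practically unreachable for sane parameters).
#' @param boundary_correction apply the Broadie–Glasserman–Kou continuity
#'   correction (boundaries pulled inward by `0.5826 * sqrt(dt)`, crossing
#'   attributed to mid-step), which removes the leading-order discretization
#'   bias of the Euler walk.  Default `TRUE`.
#' @return data.frame with `choice` (1 upper / 0 lower) and `rt` (s).
#' @export
ddm_simulate <- function(params, n, dt = 1e-3, zr = 0.5, max_time = 30,
                         boundary_correction = TRUE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  res <- ddm_simulate_cpp(as.integer(n), params[["v"]], params[["a"]],
                          params[["t0"]], zr, dt,
                          as.integer(ceiling(max_time / dt)),
                          isTRUE(boundary_correction))
  data.frame(choice = res$choice, rt = res$rt)
}

#' Simulate one trial and return the evidence path
#'
#' @inheritParams ddm_simulate
#' @return List with `path` (evidence at each Euler step, starting at
#'   `zr * a`, clamped at the crossed boundary), `choice`, `decision_time`.
#' @export
ddm_simulate_path <- function(params, dt = 1e-3, zr = 0.5, max_time = 30) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  ddm_path_cpp(params[["v"]], params[["a"]], zr, dt,
               as.integer(ceiling(max_time / dt)))
}

#' Response-time outlier filtering
#'
#' Two-stage per-participant trimming applied before DDM fitting: first the
#' fastest `ceil(early_frac * n)` trials are discarded, then all trials with
#' RT strictly greater than mean + `sd_mult` * SD of the remaining RTs.
#' The procedure is deliberately not idempotent: a second application trims
#' further, since both rules are relative to the current sample.
#'
#' @param ts a `trial_set` (every participant needs >= 10 trials).
#' @param early_frac fraction of fastest trials to discard (default 0.035).
#' @param sd_mult SD multiplier for the slow-tail cut (default 2).
#' @return List with `trials` (filtered `trial_set`) and `report`
#'   (per-participant data.frame of removal counts, plus totals in
#'   attributes `n_removed` and `pct_removed`).
#' @export
filter_rt_outliers <- function(ts, early_frac = 0.035, sd_mult = 2) {
  stopifnot(inherits(ts, "trial_set"))
  sp <- split(seq_len(nrow(ts$trials)), ts$trials$participant)
  keep_idx <- integer(0)
  rep_rows <- lapply(names(sp), function(p) {
    idx <- sp[[p]]
    n <- length(idx)
    if (n < 10L)
      stop("participant ", p, " has fewer than 10 trials", call. = FALSE)
    rt <- ts$trials$rt[idx]
    n_early <- ceiling(early_frac * n)
    early <- order(rt)[seq_len(n_early)]
    rest <- setdiff(seq_len(n), early)
    thr <- mean(rt[rest]) + sd_mult * sd(rt[rest])
    late <- rest[rt[rest] > thr]
    kept <- setdiff(rest, late)
    if (length(kept) < 2L)
      stop("participant ", p, " left with fewer than 2 trials", call. = FALSE)
    keep_idx <<- c(keep_idx, idx[kept])
    data.frame(participant = p, n = n, n_early = n_early,
               n_late = length(late), n_kept = length(kept))
  })
  report <- do.call(rbind, rep_rows)
  n_removed <- sum(report$n) - sum(report$n_kept)
  attr(report, "n_removed") <- n_removed
  attr(report, "pct_removed") <- 100 * n_removed / sum(report$n)
  list(trials = subset_trials(ts, sort(keep_idx)), report = report)
}

# negative log likelihood for one participant's data
ddm_negll <- function(par, rt, up, eps = 1e-7) {
  if (par[2L] <= 0) return(Inf)
  wiener_negll_cpp(rt, up, par[1L], par[2L], par[3L], 0.5, eps)
}

#' Maximum-likelihood DDM fit for one participant
#'
#' Maximizes the summed log Wiener first-passage density over drift rate,
#' threshold separation and non-decision time (`zr` fixed at 0.5, diffusion
#' at 1) with multi-start box-constrained local optimization.  The upper
#' boundary of the process is the correct response, so `choice` should be
#' coded 1 = correct, 0 = error.
#'
#' @param rt response times (s), at least 10.
#' @param choice 1/0 or `"upper"`/`"lower"`.
#' @param n_starts number of optimizer starts (>= 5 recommended).
#' @param eps density truncation error.
#' @return A `ddm_fit1` list: `params` ([ddm_params()]), `loglik`,
#'   `n_trials`, `fit_index` (mean log-likelihood per trial), `converged`,
#'   `one_choice` warning flag.
#' @export
fit_ddm_trials <- function(rt, choice, n_starts = 8L, eps = 1e-7) {
  up <- choice_to_int(choice)
  rt <- as.numeric(rt)
  if (length(rt) < 10L)
    stop("DDM fitting requires at least 10 trials", call. = FALSE)
  one_choice <- length(unique(up)) == 1L
  t0_max <- min(rt) - 1e-3
  if (t0_max <= 0) t0_max <- min(rt) * 0.5
  lower <- c(-8, 0.2, 1e-4)
  upper_b <- c(8, 6, t0_max)
  acc <- mean(up)
  acc_c <- min(max(acc, 0.02), 0.98)
  starts <- list()
  # heuristic starts: accuracy = logistic(v*a) at zr = 0.5
  for (a0 in c(1, 1.8, 2.6)) {
    v0 <- log(acc_c / (1 - acc_c)) / a0
    starts[[length(starts) + 1L]] <- c(min(max(v0, lower[1]), upper_b[1]), a0,
                                       min(0.9 * t0_max, 0.3))
  }
  grid <- expand.grid(v = c(0.3, 1.5), a = c(1.2, 2.2),
                      t0 = c(0.5, 0.85) * t0_max)
  for (i in seq_len(nrow(grid)))
    starts[[length(starts) + 1L]] <- as.numeric(grid[i, ])
  starts <- starts[seq_len(max(n_starts, 5L))]
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-6), upper_b - 1e-6)
    opt <- tryCatch(
      nlminb(st, ddm_negll, rt = rt, up = up, eps = eps,
             lower = lower, upper = upper_b,
             control = list(iter.max = 500L, eval.max = 800L)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best))
    stop("DDM fit failed from every start", call. = FALSE)
  ll <- -best$objective
  structure(list(params = ddm_params(best$par[1L], best$par[2L], best$par[3L]),
                 loglik = ll, n_trials = length(rt),
                 fit_index = ll / length(rt),
                 converged = best$convergence == 0 && is.finite(ll),
                 one_choice = one_choice),
            class = "ddm_fit1")
}

#' @export
print.ddm_fit1 <- function(x, ...) {
  cat(sprintf("DDM ML fit: v = %.3f, a = %.3f, t0 = %.3f  (logLik %.2f on %d trials)\n",
              x$params[["v"]], x$params[["a"]], x$params[["t0"]],
              x$loglik, x$n_trials))
  if (x$one_choice) cat("  warning: all responses on one boundary\n")
  invisible(x)
}

#' @export
coef.ddm_fit1 <- function(object, ...) unclass(object$params)

#' @export
logLik.ddm_fit1 <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n_trials, class = "logLik")
}

#' Fit the DDM to every participant of a trial set
#'
#' Applies [fit_ddm_trials()] per participant, using `accuracy` as the
#' boundary indicator (correct = upper).  Outlier filtering
#' ([filter_rt_outliers()]) should normally be applied first.
#'
#' @param ts a `trial_set`.
#' @param ... passed to [fit_ddm_trials()].
#' @return A `ddm_fit` object: list with `fits` (per participant) and
#'   `params` (data.frame participant, v, a, t0, loglik, fit_index,
#'   n_trials, converged).
#' @export
fit_ddm <- function(ts, ...) {
  stopifnot(inherits(ts, "trial_set"))
  sp <- split(ts$trials, ts$trials$participant)
  fits <- lapply(sp, function(d) fit_ddm_trials(d$rt, d$accuracy, ...))
  params <- do.call(rbind, lapply(names(fits), function(p) {
    f <- fits[[p]]
    data.frame(participant = p, v = f$params[["v"]], a = f$params[["a"]],
               t0 = f$params[["t0"]], loglik = f$loglik,
               fit_index = f$fit_index, n_trials = f$n_trials,
               converged = f$converged)
  }))
  rownames(params) <- NULL
  structure(list(fits = fits, params = params), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Per-participant DDM ML fits (", nrow(x$params), " participants)\n",
      sep = "")
  print(utils::head(x$params[, c("participant", "v", "a", "t0", "fit_index")],
                    10L), ...)
  if (nrow(x$params) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) {
  m <- as.matrix(object$params[, c("v", "a", "t0")])
  rownames(m) <- object$params$participant
  m
}

#' @export
summary.ddm_fit <- function(object, ...) {
  m <- coef(object)
  out <- rbind(mean = colMeans(m), sd = apply(m, 2L, sd),
               min = apply(m, 2L, min), max = apply(m, 2L, max))
  structure(list(stats = out, n = nrow(m)), class = "summary.ddm_fit")
}

#' @export
print.summary.ddm_fit <- function(x, ...) {
  cat("DDM parameter distribution over", x$n, "participants:\n")
  print(round(x$stats, 4L))
  invisible(x)
}

#' Simulate from fitted DDM parameters
#'
#' @param object a `ddm_fit`.
#' @param nsim trials per participant.
#' @param seed optional seed.
#' @param ... passed to [ddm_simulate()].
#' @return data.frame with participant, choice, rt.
#' @export
simulate.ddm_fit <- function(object, nsim = 90L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(object$params)), function(i) {
    p <- object$params[i, ]
    d <- ddm_simulate(ddm_params(p$v, p$a, p$t0), nsim, ...)
    cbind(participant = p$participant, d)
  })
  do.call(rbind, out)
}

#' Screen empirical DDM fits against synthetic parameter sets
#'
#' Draws `n_sets` parameter triples from a trivariate normal distribution
#' with the mean and covariance of the empirical fits (invalid draws with
#' `a <= 0` or `t0 < 0` rejected), simulates each, keeps only RTs below
#' `rt_cap`, samples `n_trials` data points, refits, and pools the resulting
#' fit indices (mean log-likelihood per trial) into a reference
#' distribution.  Empirical fits with a fit index below its 5% quantile are
#' flagged as bad fits.
#'
#' @param fit a `ddm_fit` for >= 3 participants.
#' @param n_sets number of synthetic parameter sets (>= 2).
#' @param n_trials data points per synthetic set (default 90).
#' @param rt_cap RT ceiling mimicking the task time limit (s).
#' @param quantile_level flagging quantile (default 0.05).
#' @param dt simulator Euler step.
#' @param seed optional seed.
#' @return A `ddm_fit_quality` list: `flags` (data.frame participant,
#'   fit_index, bad_fit), `threshold`, `synthetic_fit_index`.
#' @export
assess_fit_quality <- function(fit, n_sets = 1000L, n_trials = 90L,
                               rt_cap = 2.0, quantile_level = 0.05,
                               dt = 1e-3, seed = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (!is.null(seed)) set.seed(seed)
  if (n_sets < 2L)
    stop("n_sets must be >= 2 (quantile of a single fit is undefined)",
         call. = FALSE)
  m <- coef(fit)
  if (nrow(m) < 3L)
    stop("need >= 3 participants to estimate the parameter covariance",
         call. = FALSE)
  mu <- colMeans(m)
  sig <- stats::cov(m)
  if (any(!is.finite(sig)) || det(sig) <= 0)
    stop("degenerate covariance of fitted parameters", call. = FALSE)
  draws <- matrix(NA_real_, 0L, 3L)
  tries <- 0L
  while (nrow(draws) < n_sets) {
    cand <- MASS::mvrnorm(n_sets, mu, sig)
    cand <- cand[cand[, 2L] > 0.2 & cand[, 3L] >= 0, , drop = FALSE]
    draws <- rbind(draws, cand)
    tries <- tries + 1L
    if (tries > 200L)
      stop("truncated parameter sampling acceptance too low", call. = FALSE)
  }
  draws <- draws[seq_len(n_sets), , drop = FALSE]
  syn_fit_index <- vapply(seq_len(n_sets), function(i) {
    p <- ddm_params(draws[i, 1L], draws[i, 2L], draws[i, 3L])
    keep <- data.frame(choice = integer(0), rt = numeric(0))
    guard <- 0L
    while (nrow(keep) < n_trials && guard < 50L) {
      sim <- ddm_simulate(p, n_trials * 2L, dt = dt)
      keep <- rbind(keep, sim[sim$rt < rt_cap, ])
      guard <- guard + 1L
    }
    if (nrow(keep) < n_trials) return(NA_real_)
    sel <- keep[sample.int(nrow(keep), n_trials), ]
    f <- tryCatch(fit_ddm_trials(sel$rt, sel$choice),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$fit_index
  }, numeric(1L))
  syn_fit_index <- syn_fit_index[is.finite(syn_fit_index)]
  thr <- as.numeric(quantile(syn_fit_index, quantile_level))
  flags <- data.frame(participant = fit$params$participant,
                      fit_index = fit$params$fit_index,
                      bad_fit = fit$params$fit_index < thr)
  structure(list(flags = flags, threshold = thr,
                 synthetic_fit_index = syn_fit_index),
            class = "ddm_fit_quality")
}

#' @export
print.ddm_fit_quality <- function(x, ...) {
  cat(sprintf("Fit-quality screen: %d synthetic sets, 5%% threshold %.4f\n",
              length(x$synthetic_fit_index), x$threshold))
  cat(sprintf("  %d of %d participants flagged as bad fits\n",
              sum(x$flags$bad_fit), nrow(x$flags)))
  invisible(x)
}
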