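#' Predictor sets of the resampling model families
#'
#' @param mapping a `ddm_mapping` (its minimal models define the cursor
#'   predictors per target).
#' @param family `"cursor"`, `"rt_ac"` or `"hybrid"`.
#' @param target `"v"`, `"a"` or `"t0"`.
#' @return Character vector of predictor column names.
#' @export
family_predictors <- function(mapping, family, target) {
  family <- match.arg(family, c("cursor", "rt_ac", "hybrid"))
  cursor <- mapping$models[[target]]$minimal$predictors
  switch(family,
         cursor = cursor,
         rt_ac = c("rt", "accuracy"),
         hybrid = unique(c("rt", "accuracy", cursor)))
}

# derive one RNG stream seed per (size, iteration) from the master seed
stream_seeds <- function(seed, n_sizes, B) {
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max - 1L, n_sizes * B), n_sizes, B)
}

# split trial rows by participant once; returns list of row-index vectors
participant_rows <- function(trial_table) {
  split(seq_len(nrow(trial_table)), trial_table$participant)
}

#' Trial-reduction bootstrap of the cursor-based PLSR models
#'
#' For every trial sample size `s` and bootstrap iteration, draws `s` trials
#' with replacement per participant, averages the predictors over the draw,
#' refits each model family's PLSR against the fixed full-data DDM
#' parameter, and records the LOO-CV R^2.  The DDM parameters stay fixed at
#' their full-data values throughout; only the cursor/behavioral side is
#' resampled.
#'
#' @param trial_table per-trial measure table ([cursor_measures()] output,
#'   after outlier filtering).
#' @param params data.frame `participant`, `v`, `a`, `t0` (full-data fits).
#' @param mapping a `ddm_mapping` defining the minimal cursor predictors.
#' @param sizes increasing trial sample sizes; capped at the smallest
#'   per-participant trial count.
#' @param B bootstrap iterations per size.
#' @param seed master seed; one RNG stream per (size, iteration).
#' @param families subset of `c("cursor", "rt_ac", "hybrid")`.
#' @param targets subset of `c("v", "a", "t0")`.
#' @param draw `"bootstrap"` (with replacement) or `"identity"` (the full
#'   trial set, a degenerate draw used for validation).
#' @return A `resampling_curves` object: data.frame `curves` with columns
#'   family, target, size, mean_r2, ci_lo, ci_hi, n_ok, plus the per-
#'   iteration draws in `r2` (list of arrays).
#' @export
resample_plsr <- function(trial_table, params, mapping, sizes, B = 1000L,
                          seed = 1L,
                          families = c("cursor", "rt_ac", "hybrid"),
                          targets = c("v", "a", "t0"),
                          draw = c("bootstrap", "identity")) {
  draw <- match.arg(draw)
  rows <- participant_rows(trial_table)
  params <- params[match(names(rows), params$participant), ]
  if (anyNA(params$participant))
    stop("params missing participants present in trial table", call. = FALSE)
  max_size <- min(lengths(rows))
  if (any(sizes > max_size))
    stop("sizes exceed the smallest per-participant trial count (",
         max_size, ")", call. = FALSE)
  pred_cols <- unique(c("rt", "accuracy",
                        unlist(lapply(targets, function(tg)
                          family_predictors(mapping, "cursor", tg)))))
  ok_rows <- complete.cases(trial_table[, pred_cols, drop = FALSE])
  if (!all(ok_rows)) {
    trial_table <- trial_table[ok_rows, , drop = FALSE]
    rows <- participant_rows(trial_table)
    max_size <- min(lengths(rows))
  }
  seeds <- stream_seeds(seed, length(sizes), B)
  res <- array(NA_real_,
               dim = c(length(families), length(targets), length(sizes), B),
               dimnames = list(families, targets, sizes, NULL))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    for (b in seq_len(B)) {
      set.seed(seeds[si, b])
      Xp <- t(vapply(rows, function(idx) {
        pick <- if (draw == "identity") idx else
          idx[sample.int(length(idx), s, replace = TRUE)]
        colMeans(as.matrix(trial_table[pick, pred_cols, drop = FALSE]))
      }, numeric(length(pred_cols))))
      colnames(Xp) <- pred_cols
      for (fi in seq_along(families)) {
        for (ti in seq_along(targets)) {
          preds <- family_predictors(mapping, families[fi], targets[ti])
          fit <- tryCatch(
            fit_plsr(Xp[, preds, drop = FALSE], params[[targets[ti]]]),
            error = function(e) NULL)
          if (!is.null(fit)) res[fi, ti, si, b] <- fit$cv_r2
        }
      }
    }
  }
  summarize_curves(res, families, targets, sizes)
}

summarize_curves <- function(res, families, targets, sizes) {
  rows <- list()
  for (fi in seq_along(families)) for (ti in seq_along(targets))
    for (si in seq_along(sizes)) {
      r2 <- res[fi, ti, si, ]
      ok <- r2[is.finite(r2)]
      rows[[length(rows) + 1L]] <- data.frame(
        family = families[fi], target = targets[ti], size = sizes[si],
        mean_r2 = mean(ok), ci_lo = as.numeric(quantile(ok, 0.025)),
        ci_hi = as.numeric(quantile(ok, 0.975)), n_ok = length(ok))
    }
  structure(list(curves = do.call(rbind, rows), r2 = res),
            class = "resampling_curves")
}

#' @export
print.resampling_curves <- function(x, ...) {
  cat("Trial-reduction resampling curves:\n")
  print.data.frame(x$curves, row.names = FALSE, digits = 3L)
  invisible(x)
}

#' @export
plot.resampling_curves <- function(x, target = "t0", ...) {
  d <- x$curves[x$curves$target == target, ]
  fams <- unique(d$family)
  graphics::plot(range(d$size), range(c(d$ci_lo, d$ci_hi)), type = "n",
                 xlab = "trials per participant", ylab = "LOO-CV R2",
                 main = paste("target:", target), ...)
  for (i in seq_along(fams)) {
    di <- d[d$family == fams[i], ]
    graphics::lines(di$size, di$mean_r2, col = i, lwd = 2)
    graphics::lines(di$size, di$ci_lo, col = i, lty = 3)
    graphics::lines(di$size, di$ci_hi, col = i, lty = 3)
  }
  graphics::legend("bottomright", legend = fams, col = seq_along(fams),
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Self-correlation of DDM parameters under trial subsampling
#'
#' For every size and iteration, draws trials with replacement per
#' participant, refits the DDM by maximum likelihood, and squares the
#' Pearson correlation (across participants) between the subsample
#' parameters and the fixed full-data parameters.  Non-convergent fits are
#' dropped from that iteration's correlation and counted.
#'
#' @param ts filtered `trial_set`.
#' @param params full-data parameter data.frame (`participant,v,a,t0`).
#' @param sizes sample sizes, all >= 10 (the ML fitting floor).
#' @param B iterations per size.
#' @param seed master seed.
#' @param n_starts optimizer starts per fit (lower than the full-data
#'   default to keep the bootstrap tractable).
#' @param draw `"bootstrap"` or `"identity"` (validation hook).
#' @return A `resampling_curves` object (family `"ddm_selfcorr"`), with
#'   `n_failed` fit failures per size attached to the curves.
#' @export
resample_ddm_selfcorr <- function(ts, params, sizes, B = 1000L, seed = 1L,
                                  n_starts = 5L,
                                  draw = c("bootstrap", "identity")) {
  draw <- match.arg(draw)
  if (any(sizes < 10L))
    stop("DDM refitting requires sizes >= 10", call. = FALSE)
  rows <- participant_rows(ts$trials)
  params <- params[match(names(rows), params$participant), ]
  max_size <- min(lengths(rows))
  if (any(sizes > max_size))
    stop("sizes exceed the smallest per-participant trial count (",
         max_size, ")", call. = FALSE)
  targets <- c("v", "a", "t0")
  seeds <- stream_seeds(seed, length(sizes), B)
  res <- array(NA_real_, dim = c(1L, 3L, length(sizes), B),
               dimnames = list("ddm_selfcorr", targets, sizes, NULL))
  n_failed <- integer(length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    for (b in seq_len(B)) {
      set.seed(seeds[si, b])
      sub <- matrix(NA_real_, length(rows), 3L)
      for (pi in seq_along(rows)) {
        idx <- rows[[pi]]
        pick <- if (draw == "identity") idx else
          idx[sample.int(length(idx), s, replace = TRUE)]
        f <- tryCatch(fit_ddm_trials(ts$trials$rt[pick],
                                     ts$trials$accuracy[pick],
                                     n_starts = n_starts),
                      error = function(e) NULL)
        if (is.null(f) || !f$converged) {
          n_failed[si] <- n_failed[si] + 1L
        } else {
          sub[pi, ] <- unclass(f$params)
        }
      }
      ok <- complete.cases(sub)
      if (sum(ok) >= 3L) {
        for (ti in 1:3)
          res[1L, ti, si, b] <- cor(sub[ok, ti], params[[targets[ti]]][ok])^2
      }
    }
  }
  out <- summarize_curves(res, "ddm_selfcorr", targets, sizes)
  out$curves$n_failed <- rep(n_failed, times = 3L)
  out$n_failed <- n_failed
  out
}

#' Trial-order control models
#'
#' Deterministic counterpart of the bootstrap: for every trial position `k`,
#' fits the family PLSR models on predictors averaged over the first `k`
#' presentation-ordered trials (accumulated series) and on trial `k` alone
#' (single-trial series).
#'
#' @param trial_table per-trial measure table.
#' @param params full-data parameter data.frame.
#' @param mapping a `ddm_mapping`.
#' @param families model families.
#' @param targets DDM parameters.
#' @return An `order_effect_series`: data.frame with columns series
#'   ("accumulated"/"single"), family, target, k, cv_r2.
#' @export
order_effect_models <- function(trial_table, params, mapping,
                                families = c("cursor", "rt_ac", "hybrid"),
                                targets = c("v", "a", "t0")) {
  trial_table <- trial_table[order(trial_table$participant,
                                   trial_table$trial), ]
  rows <- participant_rows(trial_table)
  params <- params[match(names(rows), params$participant), ]
  K <- min(lengths(rows))
  if (K < 2L) stop("need a common trial count >= 2", call. = FALSE)
  pred_cols <- unique(c("rt", "accuracy",
                        unlist(lapply(targets, function(tg)
                          family_predictors(mapping, "cursor", tg)))))
  trial_table <- trial_table[complete.cases(
    trial_table[, pred_cols, drop = FALSE]), , drop = FALSE]
  out <- list()
  for (k in seq_len(K)) {
    for (series in c("accumulated", "single")) {
      Xp <- t(vapply(rows, function(idx) {
        pick <- if (series == "accumulated") idx[seq_len(k)] else idx[k]
        colMeans(as.matrix(trial_table[pick, pred_cols, drop = FALSE]))
      }, numeric(length(pred_cols))))
      colnames(Xp) <- pred_cols
      for (fam in families) for (tg in targets) {
        preds <- family_predictors(mapping, fam, tg)
        fit <- tryCatch(fit_plsr(Xp[, preds, drop = FALSE], params[[tg]]),
                        error = function(e) NULL)
        out[[length(out) + 1L]] <- data.frame(
          series = series, family = fam, target = tg, k = k,
          cv_r2 = if (is.null(fit)) NA_real_ else fit$cv_r2)
      }
    }
  }
  structure(list(series = do.call(rbind, out)),
            class = "order_effect_series")
}

#' @export
print.order_effect_series <- function(x, ...) {
  cat("Trial-order control series (",
      max(x$series$k), " trial positions)\n", sep = "")
  invisible(x)
}
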