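#' Pairwise correlation report of measures, DDM parameters and behavior
#'
#' Pearson correlations with p-values (t-transform) over participant-level
#' variables.  P-values are reporting aids (display rule p < .05); variable
#' exclusion uses only the correlation magnitude.
#'
#' @param data numeric data.frame (participant-level).
#' @return List with matrices `r` and `p`.
#' @export
correlation_report <- function(data) {
  m <- as.matrix(data)
  r <- suppressWarnings(cor(m))
  n <- nrow(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p, n = n)
}

#' Correlational reduction of the cursor-measure battery
#'
#' Iteratively removes one member of the most strongly correlated measure
#' pair while any pair has `|r| >=` the threshold, keeping the member that is
#' cheaper to compute according to the precedence ranking.  RT and accuracy
#' take part as retained partners (a measure redundant with RT is dropped)
#' but are never discarded themselves and are not part of the returned
#' predictor set.
#'
#' @param participants participant-level data.frame containing `rt`,
#'   `accuracy` and the 18 measure columns.
#' @param threshold correlation magnitude at or above which a pair is
#'   condensed (default 0.9).
#' @param precedence character ranking, cheapest first; must cover every
#'   measure (default [measure_precedence()]).
#' @return List: `retained` (measure names), `discarded` (data.frame measure,
#'   partner, r), `report` ([correlation_report()] of the full variable set).
#' @export
correlation_reduce <- function(participants, threshold = 0.9,
                               precedence = measure_precedence()) {
  meas <- measure_names()
  vars <- c("rt", "accuracy", meas)
  missing_cols <- setdiff(vars, names(participants))
  if (length(missing_cols) > 0L)
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(participants) < 4L)
    stop("need at least 4 participants", call. = FALSE)
  d <- participants[, vars]
  if (anyNA(d)) stop("missing cells in participant table", call. = FALSE)
  miss_rank <- setdiff(vars, precedence)
  if (length(miss_rank) > 0L)
    stop("precedence ranking missing: ", paste(miss_rank, collapse = ", "),
         call. = FALSE)
  protected <- c("rt", "accuracy")
  active <- vars
  discarded <- data.frame(measure = character(0), partner = character(0),
                          r = numeric(0))
  cost <- match(vars, precedence)
  names(cost) <- vars
  repeat {
    r <- suppressWarnings(cor(d[, active]))
    r[is.na(r)] <- 0          # zero-variance columns correlate with nothing
    diag(r) <- 0
    r[abs(r) < threshold] <- 0
    # both-protected pairs can never be condensed
    pp <- outer(active %in% protected, active %in% protected, "&")
    r[pp] <- 0
    if (all(r == 0)) break
    idx <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1L, ]
    pair <- active[idx]
    drop_m <- pair[which.max(cost[pair])]
    keep_m <- setdiff(pair, drop_m)
    discarded <- rbind(discarded,
                       data.frame(measure = drop_m, partner = keep_m,
                                  r = cor(d[[drop_m]], d[[keep_m]])))
    active <- setdiff(active, drop_m)
  }
  list(retained = setdiff(active, protected), discarded = discarded,
       report = correlation_report(d))
}

new_trace <- function() {
  data.frame(step = character(0), removed = character(0),
             cv_r2_before = numeric(0), cv_r2_after = numeric(0),
             rmsep_before = numeric(0), rmsep_after = numeric(0))
}

# a fixed component request cannot exceed the current predictor count
cap_ncomp <- function(ncomp, p) {
  if (identical(ncomp, "auto")) ncomp else min(as.integer(ncomp), p)
}

trace_row <- function(step, removed, before, after) {
  data.frame(step = step, removed = removed,
             cv_r2_before = before$cv_r2, cv_r2_after = after$cv_r2,
             rmsep_before = before$rmsep, rmsep_after = after$rmsep)
}

#' Remove predictors whose regression and correlation signs disagree
#'
#' Iteratively refits the PLSR after discarding, among predictors whose
#' standardized coefficient sign contradicts the sign of their Pearson
#' correlation with the criterion, the one correlating most weakly with the
#' criterion (ties broken by the precedence ranking, later-ranked dropped
#' first).  Such sign-inconsistent predictors act as statistical suppressors
#' and resist psychological interpretation.
#'
#' @param X predictor matrix/data.frame.
#' @param y criterion.
#' @param ncomp passed to [fit_plsr()].
#' @param precedence tie-break ranking.
#' @return List `model` (consistent `plsr_fit`) and `trace` (removal log).
#' @export
sign_consistency_prune <- function(X, y, ncomp = "auto",
                                   precedence = measure_precedence()) {
  X <- as.matrix(X)
  trace <- new_trace()
  repeat {
    if (ncol(X) == 0L)
      stop("all predictors removed during sign-consistency pruning",
           call. = FALSE)
    model <- fit_plsr(X, y, ncomp = cap_ncomp(ncomp, ncol(X)))
    rvec <- apply(X, 2L, cor, y = y)
    mism <- which(sign(model$coefficients) * sign(rvec) < 0)
    if (length(mism) == 0L)
      return(list(model = model, trace = trace))
    cand <- names(mism)[abs(rvec[mism]) == min(abs(rvec[mism]))]
    if (length(cand) > 1L) {
      rank_pos <- match(cand, precedence)
      rank_pos[is.na(rank_pos)] <- length(precedence) + 1L
      cand <- cand[which.max(rank_pos)]
    } else cand <- cand[1L]
    X2 <- X[, setdiff(colnames(X), cand), drop = FALSE]
    if (ncol(X2) == 0L)
      stop("all predictors removed during sign-consistency pruning",
           call. = FALSE)
    model2 <- fit_plsr(X2, y, ncomp = cap_ncomp(ncomp, ncol(X2)))
    trace <- rbind(trace, trace_row("sign-prune", cand, model, model2))
    X <- X2
  }
}

#' VIP-based predictor reduction
#'
#' First discards, in one pass, every predictor with a VIP score below the
#' threshold; then iteratively removes the lowest-VIP predictor below the
#' threshold, keeping each removal only while the LOO RMSEP does not
#' increase.
#'
#' @param model a consistent `plsr_fit` (from [sign_consistency_prune()]).
#' @param vip_threshold default 0.8.
#' @param ncomp passed to [fit_plsr()].
#' @return List `model` and `trace`.
#' @export
vip_reduce <- function(model, vip_threshold = 0.8, ncomp = "auto") {
  trace <- new_trace()
  X <- model$X; y <- model$y
  low <- names(model$vip)[model$vip < vip_threshold]
  if (length(low) > 0L && length(low) < ncol(X)) {
    X2 <- X[, setdiff(colnames(X), low), drop = FALSE]
    model2 <- fit_plsr(X2, y, ncomp = cap_ncomp(ncomp, ncol(X2)))
    trace <- rbind(trace, trace_row("vip-prune",
                                    paste(low, collapse = "+"),
                                    model, model2))
    model <- model2
    X <- X2
  }
  repeat {
    if (ncol(X) <= 1L) break
    low <- model$vip[model$vip < vip_threshold]
    if (length(low) == 0L) break
    cand <- names(low)[which.min(low)]
    X2 <- X[, setdiff(colnames(X), cand), drop = FALSE]
    model2 <- fit_plsr(X2, y, ncomp = cap_ncomp(ncomp, ncol(X2)))
    if (model2$rmsep > model$rmsep) break
    trace <- rbind(trace, trace_row("vip-prune", cand, model, model2))
    model <- model2
    X <- X2
  }
  list(model = model, trace = trace)
}

#' Minimal-model probing
#'
#' Greedily tests dropping each remaining predictor and accepts the removal
#' with the smallest RMSEP increase, provided the explained variance loss
#' and RMSEP rise stay within tolerance; iterates until no further removal
#' qualifies.
#'
#' @param model a `plsr_fit` (normally VIP-reduced).
#' @param max_r2_loss largest tolerated drop in LOO-CV R^2 (default 0.01).
#' @param max_rmsep_rise largest tolerated RMSEP increase (default 0.002).
#' @param ncomp passed to [fit_plsr()].
#' @return List `model` and `trace`.
#' @export
minimal_reduce <- function(model, max_r2_loss = 0.01, max_rmsep_rise = 0.002,
                           ncomp = "auto") {
  trace <- new_trace()
  repeat {
    X <- model$X; y <- model$y
    if (ncol(X) <= 1L) break
    best <- NULL
    for (nm in colnames(X)) {
      X2 <- X[, setdiff(colnames(X), nm), drop = FALSE]
      m2 <- fit_plsr(X2, y, ncomp = cap_ncomp(ncomp, ncol(X2)))
      if (model$cv_r2 - m2$cv_r2 <= max_r2_loss &&
          m2$rmsep - model$rmsep <= max_rmsep_rise) {
        if (is.null(best) || m2$rmsep < best$model$rmsep)
          best <- list(name = nm, model = m2)
      }
    }
    if (is.null(best)) break
    trace <- rbind(trace, trace_row("minimal-prune", best$name, model,
                                    best$model))
    model <- best$model
  }
  list(model = model, trace = trace)
}

#' Map cursor measures onto the DDM parameters
#'
#' The full reduction chain: correlational condensation of the 18 measures,
#' then per DDM parameter a sign-consistent initial PLSR, VIP reduction, and
#' minimal-model probing.  Deterministic given its input.
#'
#' @param participants participant-level table with `rt`, `accuracy`, the 18
#'   measures, and columns `v`, `a`, `t0` (fitted or ground-truth DDM
#'   parameters).
#' @param threshold correlational reduction threshold.
#' @param vip_threshold VIP pruning threshold.
#' @param max_r2_loss,max_rmsep_rise minimal-model tolerances.
#' @param ncomp PLSR component selection (default `"auto"`).
#' @param precedence computation-cost ranking.
#' @return A `ddm_mapping` object: `reduction` (correlational stage), and
#'   per target in `models` the `initial`, `vip` and `minimal` `plsr_fit`s
#'   with their reduction traces.
#' @export
run_mapping <- function(participants, threshold = 0.9, vip_threshold = 0.8,
                        max_r2_loss = 0.01, max_rmsep_rise = 0.002,
                        ncomp = "auto", precedence = measure_precedence()) {
  for (tg in c("v", "a", "t0"))
    if (!tg %in% names(participants))
      stop("missing DDM parameter column '", tg, "'", call. = FALSE)
  red <- correlation_reduce(participants, threshold = threshold,
                            precedence = precedence)
  X_all <- as.matrix(participants[, red$retained, drop = FALSE])
  keep <- apply(X_all, 2L, sd) > 1e-10    # constant measures carry no signal
  X_all <- X_all[, keep, drop = FALSE]
  models <- lapply(c(v = "v", a = "a", t0 = "t0"), function(tg) {
    y <- participants[[tg]]
    init <- sign_consistency_prune(X_all, y, ncomp = ncomp,
                                   precedence = precedence)
    vip <- vip_reduce(init$model, vip_threshold = vip_threshold,
                      ncomp = ncomp)
    minimal <- minimal_reduce(vip$model, max_r2_loss = max_r2_loss,
                              max_rmsep_rise = max_rmsep_rise, ncomp = ncomp)
    list(initial = init$model, vip = vip$model, minimal = minimal$model,
         trace = rbind(init$trace, vip$trace, minimal$trace))
  })
  structure(list(reduction = red, models = models,
                 settings = list(threshold = threshold,
                                 vip_threshold = vip_threshold,
                                 max_r2_loss = max_r2_loss,
                                 max_rmsep_rise = max_rmsep_rise)),
            class = "ddm_mapping")
}

#' @export
print.ddm_mapping <- function(x, ...) {
  cat("Cursor-measure to DDM-parameter mapping\n")
  cat("  retained after correlational reduction:",
      paste(x$reduction$retained, collapse = ", "), "\n")
  for (tg in names(x$models)) {
    m <- x$models[[tg]]
    cat(sprintf("  %-3s initial R^2 = %.3f (%d pred.) -> minimal R^2 = %.3f (%s)\n",
                tg, m$initial$cv_r2, length(m$initial$predictors),
                m$minimal$cv_r2, paste(m$minimal$predictors, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.ddm_mapping <- function(object, ...) {
  rows <- lapply(names(object$models), function(tg) {
    m <- object$models[[tg]]
    data.frame(target = tg,
               stage = c("initial", "vip", "minimal"),
               n_predictors = c(length(m$initial$predictors),
                                length(m$vip$predictors),
                                length(m$minimal$predictors)),
               cv_r2 = c(m$initial$cv_r2, m$vip$cv_r2, m$minimal$cv_r2),
               rmsep = c(m$initial$rmsep, m$vip$rmsep, m$minimal$rmsep))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.ddm_mapping", "data.frame")
  out
}

#' @export
print.summary.ddm_mapping <- function(x, ...) {
  cat("PLSR model stages per DDM parameter:\n")
  print.data.frame(x, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' Coefficient dot chart of the mapping models
#'
#' @param x a `ddm_mapping`.
#' @param stage `"minimal"`, `"vip"` or `"initial"`.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.ddm_mapping <- function(x, stage = c("minimal", "vip", "initial"), ...) {
  stage <- match.arg(stage)
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (tg in names(x$models)) {
    m <- x$models[[tg]][[stage]]
    graphics::dotchart(m$coefficients, labels = m$predictors,
                       main = sprintf("%s (R2 = %.2f)", tg, m$cv_r2),
                       xlab = "standardized coefficient", ...)
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}

#' Replay a reduction trace
#'
#' Refits the model sequence implied by a trace, confirming that the logged
#' removals reproduce the final model.
#'
#' @param X,y the inputs of the initial model (before any pruning).
#' @param trace a trace data.frame from the reduction functions.
#' @param ncomp component selection.
#' @return The `plsr_fit` after applying all logged removals.
#' @export
replay_trace <- function(X, y, trace, ncomp = "auto") {
  X <- as.matrix(X)
  removed <- unlist(strsplit(trace$removed, "+", fixed = TRUE))
  keep <- setdiff(colnames(X), removed)
  fit_plsr(X[, keep, drop = FALSE], y, ncomp = ncomp)
}
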