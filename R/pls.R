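# NIPALS PLS1 on pre-standardized matrices.  Returns weights W, X-loadings
# P, y-loadings q, scores' sums of squares tt, all for 1..ncomp components.
pls1_nipals <- function(Xs, ys, ncomp) {
  p <- ncol(Xs)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  tt <- numeric(ncomp)
  E <- Xs
  f <- ys
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { ncomp <- k - 1L; break }
    w <- w / nw
    t_k <- drop(E %*% w)
    ss <- sum(t_k^2)
    if (ss < 1e-14) { ncomp <- k - 1L; break }
    p_k <- drop(crossprod(E, t_k)) / ss
    q_k <- sum(f * t_k) / ss
    W[, k] <- w; P[, k] <- p_k; q[k] <- q_k; tt[k] <- ss
    E <- E - tcrossprod(t_k, p_k)
    f <- f - q_k * t_k
  }
  list(W = W[, seq_len(ncomp), drop = FALSE],
       P = P[, seq_len(ncomp), drop = FALSE],
       q = q[seq_len(ncomp)], tt = tt[seq_len(ncomp)], ncomp = ncomp)
}

# regression coefficients (standardized scale) for a NIPALS decomposition
pls1_coef <- function(dec) {
  R <- dec$W %*% solve(crossprod(dec$P, dec$W))
  drop(R %*% dec$q)
}

pls1_vip <- function(dec) {
  ssy <- dec$q^2 * dec$tt
  p <- nrow(dec$W)
  wn <- sweep(dec$W, 2L, sqrt(colSums(dec$W^2)), "/")
  vip2 <- p * drop(wn^2 %*% ssy) / sum(ssy)
  sqrt(vip2)
}

std_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  list(mu = mu, sd = ifelse(sdv > 0, sdv, 1))
}

std_apply <- function(X, s) sweep(sweep(X, 2L, s$mu, "-"), 2L, s$sd, "/")

# standardized-scale coefficients for given data and component count
pls1_fit_coef <- function(X, y, ncomp) {
  sx <- std_fit(X); Xs <- std_apply(X, sx)
  my <- mean(y); sy <- sd(y); if (sy == 0) sy <- 1
  ys <- (y - my) / sy
  dec <- pls1_nipals(Xs, ys, ncomp)
  list(dec = dec, coef = pls1_coef(dec), sx = sx, my = my, sy = sy)
}

#' Partial least squares regression of one DDM parameter on cursor measures
#'
#' PLS1 regression via the NIPALS algorithm.  Predictors and criterion are
#' z-standardized before component extraction; coefficients are reported on
#' the standardized scale.  Model performance is evaluated by
#' leave-one-out cross-validation: in each fold the model (including the
#' standardization) is refit without the held-out observation and used to
#' predict it.  `cv_r2 = 1 - PRESS/TSS` and `rmsep = sqrt(PRESS/n)` (on the
#' original criterion scale).
#'
#' @param X numeric matrix or data.frame of predictors (named columns).
#' @param y numeric criterion vector.
#' @param ncomp `"auto"` (component count minimizing the LOO RMSEP over
#'   `1..min(p, n - 2)`) or a fixed integer.
#' @return A `plsr_fit` object.
#' @export
fit_plsr <- function(X, y, ncomp = "auto") {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  if (length(y) != n) stop("X and y sizes differ", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  csd <- apply(X, 2L, sd)
  if (any(csd == 0))
    stop("constant predictor column: ",
         paste(colnames(X)[csd == 0], collapse = ", "), call. = FALSE)
  ncomp_max <- max(1L, min(p, n - 2L))
  # LOO predictions for every candidate component count in one pass
  press_by_k <- matrix(NA_real_, n, ncomp_max)
  for (i in seq_len(n)) {
    ft <- pls1_fit_coef(X[-i, , drop = FALSE], y[-i], ncomp_max)
    xs <- (X[i, ] - ft$sx$mu) / ft$sx$sd
    for (k in seq_len(ft$dec$ncomp)) {
      dk <- list(W = ft$dec$W[, 1:k, drop = FALSE],
                 P = ft$dec$P[, 1:k, drop = FALSE],
                 q = ft$dec$q[1:k], tt = ft$dec$tt[1:k], ncomp = k)
      yhat <- ft$my + ft$sy * sum(xs * pls1_coef(dk))
      press_by_k[i, k] <- (y[i] - yhat)^2
    }
    if (ft$dec$ncomp < ncomp_max)   # rank-deficient fold: reuse last column
      press_by_k[i, (ft$dec$ncomp + 1L):ncomp_max] <- press_by_k[i, ft$dec$ncomp]
  }
  press <- colSums(press_by_k)
  rmsep_k <- sqrt(press / n)
  if (identical(ncomp, "auto")) {
    ncomp_use <- which.min(rmsep_k)
  } else {
    ncomp_use <- as.integer(ncomp)
    if (ncomp_use < 1L || ncomp_use > ncomp_max)
      stop("ncomp out of range 1..", ncomp_max, call. = FALSE)
  }
  ft <- pls1_fit_coef(X, y, ncomp_use)
  if (ft$dec$ncomp < ncomp_use) ncomp_use <- ft$dec$ncomp
  Xs <- std_apply(X, ft$sx)
  fitted_y <- ft$my + ft$sy * drop(Xs %*% ft$coef)
  tss <- sum((y - mean(y))^2)
  structure(list(predictors = colnames(X), target = attr(y, "target"),
                 n = n, ncomp = ncomp_use,
                 weights = ft$dec$W, x_loadings = ft$dec$P,
                 y_loadings = ft$dec$q, score_ss = ft$dec$tt,
                 coefficients = setNames(ft$coef, colnames(X)),
                 vip = setNames(pls1_vip(ft$dec), colnames(X)),
                 cv_r2 = 1 - press[ncomp_use] / tss,
                 rmsep = rmsep_k[ncomp_use],
                 press = press[ncomp_use],
                 rmsep_by_ncomp = rmsep_k,
                 x_center = ft$sx$mu, x_scale = ft$sx$sd,
                 y_center = ft$my, y_scale = ft$sy,
                 fitted.values = fitted_y, residuals = y - fitted_y,
                 y = y, X = X),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR fit: %d predictors, %d component(s), n = %d\n",
              length(x$predictors), x$ncomp, x$n))
  cat(sprintf("  LOO-CV R^2 = %.4f, RMSEP = %.4f\n", x$cv_r2, x$rmsep))
  invisible(x)
}

#' @export
summary.plsr_fit <- function(object, ...) {
  tab <- data.frame(coefficient = object$coefficients, vip = object$vip)
  structure(list(table = tab, cv_r2 = object$cv_r2, rmsep = object$rmsep,
                 ncomp = object$ncomp, n = object$n), class = "summary.plsr_fit")
}

#' @export
print.summary.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR with %d component(s), n = %d: LOO-CV R^2 = %.4f, RMSEP = %.4f\n",
              x$ncomp, x$n, x$cv_r2, x$rmsep))
  cat("Standardized coefficients and VIP scores:\n")
  print(round(x$table, 4L))
  invisible(x)
}

#' @export
coef.plsr_fit <- function(object, ...) object$coefficients

#' @export
fitted.plsr_fit <- function(object, ...) object$fitted.values

#' @export
residuals.plsr_fit <- function(object, ...) object$residuals

#' @export
predict.plsr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, object$x_center, "-"), 2L, object$x_scale, "/")
  object$y_center + object$y_scale * drop(Xs %*% object$coefficients)
}
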