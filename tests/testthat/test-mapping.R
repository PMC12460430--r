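# participant-level table with all expected columns, built around a given
# set of named overriding columns
fake_participants <- function(n = 40L, override = list(), seed = 1L) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * 18L), n, 18L))
  names(d) <- measure_names()
  d$rt <- runif(n, 0.8, 1.5)
  d$accuracy <- runif(n, 0.5, 0.95)
  for (nm in names(override)) d[[nm]] <- override[[nm]]
  d
}

test_that("correlational reduction keeps the cheaper of a redundant pair", {
  d <- fake_participants()
  # duplicated column pair: AD == AUC (r = 1); AUC is cheaper by precedence
  d$AD <- d$AUC
  red <- correlation_reduce(d)
  expect_true("AUC" %in% red$retained)
  expect_false("AD" %in% red$retained)
  expect_true("AD" %in% red$discarded$measure)

  # vacuous threshold discards nothing
  red2 <- correlation_reduce(d, threshold = 1.01)
  expect_length(red2$retained, 18L)

  # missing precedence entry is a configuration error
  expect_error(correlation_reduce(d, precedence = c("rt", "accuracy")),
               "precedence")
})

test_that("planted near-duplicate measures condense as in the cost ranking", {
  d <- fake_participants(seed = 2L)
  # plant corr(timeToPeakAcc, timeToPeakVel) ~ 0.95
  d$timeToPeakAcc <- d$timeToPeakVel + rnorm(nrow(d), 0, 0.32)
  r <- cor(d$timeToPeakAcc, d$timeToPeakVel)
  expect_gt(r, 0.9)
  red <- correlation_reduce(d)
  expect_false("timeToPeakAcc" %in% red$retained)
  expect_true("timeToPeakVel" %in% red$retained)
})

test_that("RT and accuracy serve as partners but are never discarded", {
  d <- fake_participants(seed = 3L)
  d$meanVel <- d$rt + rnorm(nrow(d), 0, 0.02)
  red <- correlation_reduce(d)
  expect_false("meanVel" %in% red$retained)
  expect_true(all(red$discarded$measure != "rt"))
  expect_true(all(red$discarded$measure != "accuracy"))
})

test_that("sign-consistency pruning removes suppressor predictors", {
  set.seed(6)
  n <- 60
  # orthogonal predictors all positively correlated with y: nothing removed
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  y <- drop(X %*% c(1, 1, 1)) + rnorm(n, 0, 0.5)
  out <- sign_consistency_prune(X, y)
  expect_length(out$model$predictors, 3L)
  expect_equal(nrow(out$trace), 0L)

  # classic suppressor: x3 correlates with x1 but not with y; its
  # regression coefficient flips against its (weak) correlation
  x1 <- rnorm(n)
  x3 <- 0.9 * x1 + rnorm(n, 0, 0.4)
  x2 <- rnorm(n)
  ys <- x1 + 0.8 * x2 + rnorm(n, 0, 0.3)
  Xs <- cbind(x1 = x1, x2 = x2, x3 = x3)
  out2 <- sign_consistency_prune(Xs, ys, ncomp = 3)
  expect_false("x3" %in% out2$model$predictors)
  # postcondition: no mismatches remain
  rvec <- apply(out2$model$X, 2, cor, y = ys)
  expect_true(all(sign(out2$model$coefficients) * sign(rvec) >= 0))
})

test_that("VIP reduction drops uninformative predictors and keeps VIP norm", {
  set.seed(7)
  removed <- replicate(20, {
    n <- 50
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, c(paste0("s", 1:5), "noise")))
    y <- drop(X[, 1:5] %*% rep(0.8, 5)) + rnorm(n, 0, 0.6)
    m0 <- fit_plsr(X, y)
    out <- vip_reduce(m0)
    expect_equal(sum(out$model$vip^2), length(out$model$predictors),
                 tolerance = 1e-8)
    !("noise" %in% out$model$predictors)
  })
  expect_gte(mean(removed), 0.9)
})

test_that("minimal reduction removes redundant twins and replays exactly", {
  set.seed(8)
  n <- 50
  base <- rnorm(n)
  X <- cbind(twin1 = base + rnorm(n, 0, 0.05),
             twin2 = base + rnorm(n, 0, 0.05),
             other = rnorm(n))
  y <- base + rnorm(n, 0, 0.4)
  m0 <- fit_plsr(X, y)
  out <- minimal_reduce(m0)
  expect_lt(length(out$model$predictors), 3L)
  # single-predictor model is left untouched
  m1 <- fit_plsr(X[, "twin1", drop = FALSE], y)
  expect_equal(minimal_reduce(m1)$model$predictors, "twin1")
  # trace replay reproduces the final model exactly
  rep_fit <- replay_trace(X, y, out$trace)
  expect_equal(rep_fit$cv_r2, out$model$cv_r2, tolerance = 1e-12)
  expect_setequal(rep_fit$predictors, out$model$predictors)
})

test_that("the mapping chain is deterministic and null-safe", {
  g <- tiny_cohort(seed = 31L, n_participants = 12L, n_trials = 15L)
  pm <- participant_measures(cursor_measures(g$trials))
  tr <- g$truth$participants
  ptab <- cbind(pm, tr[match(pm$participant, tr$participant),
                       c("v", "a", "t0")])
  m1 <- run_mapping(ptab)
  m2 <- run_mapping(ptab)
  expect_equal(summary(m1), summary(m2))

  # a shuffled criterion yields near-zero minimal-model performance
  set.seed(32)
  ptab_null <- ptab
  ptab_null$v <- sample(ptab_null$v)
  ptab_null$a <- sample(ptab_null$a)
  ptab_null$t0 <- sample(ptab_null$t0)
  m_null <- run_mapping(ptab_null)
  r2s <- vapply(m_null$models, function(m) m$minimal$cv_r2, numeric(1))
  expect_lt(max(r2s), 0.5)
})
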