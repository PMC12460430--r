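test_that("closed-form choice probability and mean decision time", {
  p <- ddm_params(1, 2, 0)
  cf <- ddm_closed_form(p)
  expect_equal(cf$p_upper, (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  expect_equal(cf$mean_dt, tanh(1), tolerance = 1e-12)
  # driftless symmetric case: p = zr, E[T] = z(a-z)
  cf0 <- ddm_closed_form(ddm_params(0, 2, 0))
  expect_equal(cf0$p_upper, 0.5)
  expect_equal(cf0$mean_dt, 1)
})

test_that("Wiener density is normalized and integrates to the choice split", {
  p <- ddm_params(1, 2, 0.3)
  fu <- function(t) exp(wiener_logpdf(t, rep(1L, length(t)), p))
  fl <- function(t) exp(wiener_logpdf(t, rep(0L, length(t)), p))
  iu <- integrate(fu, 0.3, 40, rel.tol = 1e-8)$value
  il <- integrate(fl, 0.3, 40, rel.tol = 1e-8)$value
  expect_equal(iu + il, 1, tolerance = 1e-4)
  expect_equal(iu, ddm_closed_form(p)$p_upper, tolerance = 1e-4)
  # density is zero (log -Inf) before the non-decision time
  expect_identical(wiener_logpdf(0.2, 1L, p), -Inf)
})

test_that("simulator agrees with the density (distribution cross-check)", {
  set.seed(31)
  for (pars in list(c(1.2, 1.6, 0.25), c(-0.5, 2.2, 0.4))) {
    p <- ddm_params(pars[1L], pars[2L], pars[3L])
    sim <- ddm_simulate(p, 50000)
    up <- sim$rt[sim$choice == 1L]
    if (length(up) < 5000) up <- sim$rt[sim$choice == 0L]
    ch <- as.integer(length(up) == length(sim$rt[sim$choice == 1L]))
    # CDF of the chosen boundary by quadrature of the density
    f <- function(t) exp(wiener_logpdf(t, rep(ch, length(t)), p))
    mass <- integrate(f, p[["t0"]], 60, rel.tol = 1e-8)$value
    qs <- quantile(up, c(0.1, 0.25, 0.5, 0.75, 0.9))
    cdf <- vapply(qs, function(q)
      integrate(f, p[["t0"]], q, rel.tol = 1e-7)$value / mass, numeric(1L))
    expect_lt(max(abs(cdf - c(0.1, 0.25, 0.5, 0.75, 0.9))), 0.02)
  }
})

test_that("simulator is reproducible and validates inputs", {
  p <- ddm_params(0.8, 1.8, 0.3)
  set.seed(5); a <- ddm_simulate(p, 50)
  set.seed(5); b <- ddm_simulate(p, 50)
  expect_identical(a, b)
  expect_error(ddm_simulate(p, 10, dt = 0), "dt must be")
  expect_error(ddm_simulate(p, 0), "n must be")
  expect_error(ddm_params(1, -1, 0.2), "must be > 0")
})

test_that("RT outlier filter removes the fastest fraction then the slow tail", {
  rts <- c(0.2, 0.21, 0.22, 0.23, rep(1.0, 96))
  trials <- data.frame(participant = "p1", trial = 1:100,
                       stimulus_side = "left", response_side = "left",
                       accuracy = 1L, rt = rts)
  trajs <- replicate(100, straight_traj(), simplify = FALSE)
  names(trajs) <- traj_key(trials$participant, trials$trial)
  ts <- traceddm:::new_trial_set(trials, trajs)
  out <- filter_rt_outliers(ts)
  # ceil(0.035 * 100) = 4 early removals; SD = 0 afterwards, strict > keeps all
  expect_equal(out$report$n_early, 4L)
  expect_equal(out$report$n_late, 0L)
  expect_equal(out$report$n_kept, 96L)
  expect_true(all(out$trials$trials$rt == 1.0))

  # the filter is deliberately not idempotent
  out2 <- filter_rt_outliers(out$trials)
  expect_lt(nrow(out2$trials$trials), nrow(out$trials$trials))

  # too few trials is an error
  expect_error(filter_rt_outliers(subset_trials(ts, 1:5)), "fewer than 10")
})

test_that("ML fit recovers parameters and respects its floor", {
  set.seed(11)
  truth <- ddm_params(1.5, 1.8, 0.35)
  sim <- ddm_simulate(truth, 400)
  fit <- fit_ddm_trials(sim$rt, sim$choice)
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["v"]] - 1.5), 0.4)
  expect_lt(abs(fit$params[["a"]] - 1.8), 0.3)
  expect_lt(abs(fit$params[["t0"]] - 0.35), 0.05)
  # likelihood at the truth cannot beat the fitted optimum
  ll_truth <- sum(wiener_logpdf(sim$rt, sim$choice, truth))
  expect_lte(ll_truth, fit$loglik + 1e-6)
  expect_error(fit_ddm_trials(sim$rt[1:9], sim$choice[1:9]), "at least 10")
  # all-one-choice data fit with a warning flag
  one <- sim[sim$choice == 1L, ][1:20, ]
  f1 <- fit_ddm_trials(one$rt, one$choice)
  expect_true(f1$one_choice)
})

test_that("fitting a zero-drift process yields a small drift estimate", {
  set.seed(13)
  errs <- replicate(6, {
    sim <- ddm_simulate(ddm_params(0, 2, 0.3), 300)
    fit_ddm_trials(sim$rt, sim$choice)$params[["v"]]
  })
  expect_lt(abs(mean(errs)), 0.15)
})

test_that("fit-quality screen rejects degenerate inputs", {
  set.seed(17)
  sim <- ddm_simulate(ddm_params(1, 1.8, 0.3), 60)
  f <- fit_ddm_trials(sim$rt, sim$choice)
  params <- do.call(rbind, lapply(1:3, function(i)
    data.frame(participant = paste0("p", i), v = f$params[["v"]],
               a = f$params[["a"]], t0 = f$params[["t0"]],
               loglik = f$loglik, fit_index = f$fit_index,
               n_trials = f$n_trials, converged = TRUE)))
  fake <- structure(list(fits = list(f, f, f), params = params),
                    class = "ddm_fit")
  expect_error(assess_fit_quality(fake, n_sets = 1), "n_sets")
  # identical participants give a singular covariance
  expect_error(assess_fit_quality(fake, n_sets = 10), "covariance")
})

test_that("a participant with uniform-noise RTs is flagged as a bad fit", {
  set.seed(19)
  fits <- list(); params <- NULL
  for (i in 1:8) {
    sim <- ddm_simulate(ddm_params(0.9 + 0.1 * i, 1.6 + 0.05 * i,
                                   0.25 + 0.01 * i), 90)
    f <- fit_ddm_trials(sim$rt, sim$choice)
    fits[[i]] <- f
    params <- rbind(params,
                    data.frame(participant = paste0("p", i),
                               v = f$params[["v"]], a = f$params[["a"]],
                               t0 = f$params[["t0"]], loglik = f$loglik,
                               fit_index = f$fit_index,
                               n_trials = f$n_trials, converged = TRUE))
  }
  # participant 9: RTs are uniform noise, unrelated to any diffusion
  noise_rt <- runif(90, 0.1, 3.5)
  f9 <- fit_ddm_trials(noise_rt, rbinom(90, 1, 0.5))
  fits[[9]] <- f9
  params <- rbind(params,
                  data.frame(participant = "p9", v = f9$params[["v"]],
                             a = f9$params[["a"]], t0 = f9$params[["t0"]],
                             loglik = f9$loglik, fit_index = f9$fit_index,
                             n_trials = f9$n_trials, converged = TRUE))
  fake <- structure(list(fits = fits, params = params), class = "ddm_fit")
  fq <- assess_fit_quality(fake, n_sets = 60, rt_cap = Inf, seed = 2)
  expect_true(fq$flags$bad_fit[fq$flags$participant == "p9"])
})
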