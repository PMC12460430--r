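# one small fitted cohort shared across the resampling tests
rs_g <- tiny_cohort(seed = 41L, n_participants = 8L, n_trials = 24L)
rs_ts <- preprocess_trials(rs_g$trials)
rs_filt <- filter_rt_outliers(rs_ts)
rs_meas <- cursor_measures(rs_filt$trials)
rs_meas <- rs_meas[complete.cases(rs_meas), ]
rs_fit <- fit_ddm(rs_filt$trials)
rs_map <- run_mapping(merge(participant_measures(rs_meas),
                            rs_fit$params[, c("participant", "v", "a", "t0")],
                            by = "participant"))
rs_trials <- rs_filt$trials

test_that("family predictor sets derive from the minimal models", {
  expect_identical(family_predictors(rs_map, "rt_ac", "v"),
                   c("rt", "accuracy"))
  cursor <- family_predictors(rs_map, "cursor", "t0")
  hybrid <- family_predictors(rs_map, "hybrid", "t0")
  expect_true(all(cursor %in% hybrid))
  expect_true(all(c("rt", "accuracy") %in% hybrid))
})

test_that("an identity draw at full size reproduces the full-data model", {
  full_size <- min(table(rs_meas$participant))
  rc <- resample_plsr(rs_meas, rs_fit$params, rs_map, sizes = full_size,
                      B = 1L, seed = 1L, families = "rt_ac",
                      targets = "t0", draw = "identity")
  pm_full <- participant_measures(rs_meas)
  ref <- fit_plsr(pm_full[, c("rt", "accuracy")],
                  rs_fit$params$t0[match(pm_full$participant,
                                         rs_fit$params$participant)])
  expect_equal(rc$curves$mean_r2, ref$cv_r2, tolerance = 1e-10)
})

test_that("bootstrap curves are reproducible and internally consistent", {
  sizes <- c(4L, 12L)
  r1 <- resample_plsr(rs_meas, rs_fit$params, rs_map, sizes = sizes,
                      B = 8L, seed = 7L)
  r2 <- resample_plsr(rs_meas, rs_fit$params, rs_map, sizes = sizes,
                      B = 8L, seed = 7L)
  expect_identical(r1$curves, r2$curves)
  # the mean lies inside its own interval, for every family and size
  expect_true(all(r1$curves$ci_lo <= r1$curves$mean_r2 + 1e-12))
  expect_true(all(r1$curves$mean_r2 <= r1$curves$ci_hi + 1e-12))
  # total iteration count: |sizes| x B per (family, target)
  expect_equal(sum(r1$curves$n_ok), length(sizes) * 8L * 3L * 3L)
  # uncertainty shrinks with the trial sample size
  w <- with(r1$curves, tapply(ci_hi - ci_lo, size, mean))
  expect_gt(w[["4"]], w[["12"]])
  # sizes beyond the common trial count are refused
  expect_error(resample_plsr(rs_meas, rs_fit$params, rs_map, sizes = 1000L,
                             B = 2L, seed = 1L), "exceed")
})

test_that("DDM self-correlation under identity draw is exactly 1", {
  full_size <- min(table(rs_trials$trials$participant))
  sc <- resample_ddm_selfcorr(rs_trials, rs_fit$params, sizes = full_size,
                              B = 1L, seed = 1L, draw = "identity")
  expect_equal(sc$curves$mean_r2, rep(1, 3), tolerance = 1e-9)
  expect_error(resample_ddm_selfcorr(rs_trials, rs_fit$params, sizes = 5L,
                                     B = 1L, seed = 1L), "sizes >= 10")
})

test_that("DDM self-correlation bootstrap is reproducible", {
  s1 <- resample_ddm_selfcorr(rs_trials, rs_fit$params, sizes = 10L,
                              B = 2L, seed = 3L)
  s2 <- resample_ddm_selfcorr(rs_trials, rs_fit$params, sizes = 10L,
                              B = 2L, seed = 3L)
  expect_identical(s1$curves, s2$curves)
  expect_true(all(s1$curves$mean_r2 >= 0 & s1$curves$mean_r2 <= 1))
})

test_that("trial-order series end at the full-data model", {
  # equalize trial counts so the accumulated series can reach the full data
  K <- min(table(rs_meas$participant))
  sub <- do.call(rbind, lapply(split(rs_meas, rs_meas$participant),
                               utils::head, K))
  oe <- order_effect_models(sub, rs_fit$params, rs_map,
                            families = "hybrid", targets = "t0")
  expect_setequal(unique(oe$series$series), c("accumulated", "single"))
  expect_equal(sort(unique(oe$series$k)), seq_len(K))
  acc_last <- oe$series$cv_r2[oe$series$series == "accumulated" &
                                oe$series$k == K]
  pm_full <- participant_measures(sub)
  preds <- family_predictors(rs_map, "hybrid", "t0")
  ref <- fit_plsr(pm_full[, preds],
                  rs_fit$params$t0[match(pm_full$participant,
                                         rs_fit$params$participant)])
  expect_equal(acc_last, ref$cv_r2, tolerance = 1e-10)
})
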