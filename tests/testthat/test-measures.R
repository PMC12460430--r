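test_that("straight path has zero deviation and unit curvature", {
  tr <- straight_traj()
  d <- deviation_measures(tr)
  expect_equal(d$AD, 0, tolerance = 1e-10)
  expect_equal(d$AUC, 0, tolerance = 1e-8)
  expect_equal(d$MAD, 0, tolerance = 1e-10)
  expect_equal(d$MADabove, 0, tolerance = 1e-10)
  expect_equal(d$curvature, 1, tolerance = 1e-12)
  cm <- count_measures(tr)
  expect_equal(cm$xFlips, 0L)
  expect_equal(cm$reversals, 0L)
})

test_that("right-angle toy path matches hand-computed deviations", {
  tr <- trajectory(c(0, 0.1, 0.2), c(0, 0, -100), c(0, 100, 100))
  d <- deviation_measures(tr)
  expect_equal(d$curvature, 200 / sqrt(2 * 100^2), tolerance = 1e-9)
  expect_equal(d$MAD, 100 / sqrt(2), tolerance = 1e-9)
  expect_equal(d$MADabove, 100 / sqrt(2), tolerance = 1e-9)
  # all deviation on the chosen (left) side -> MADabove is 0
  tr2 <- trajectory(c(0, 0.1, 0.2), c(0, -100, -100), c(0, 0, 100))
  d2 <- deviation_measures(tr2)
  expect_equal(d2$MADabove, 0)
  expect_gt(d2$MAD, 0)
  # start == end has no defined optimal trajectory
  loop <- trajectory(c(0, 0.1, 0.2), c(0, 5, 0), c(0, 5, 0))
  expect_error(deviation_measures(loop), "undefined deviation")
})

test_that("kinematic measures follow the first-maximum and pause rules", {
  # speeds 10,30,30,20 px/s over exact 1/8-s steps -> first max at t = 1/4
  d <- c(0, cumsum(c(10, 30, 30, 20) / 8))
  tr <- trajectory((0:4) / 8, d, rep(0, 5))
  km <- kinematic_measures(tr)
  expect_equal(km$maxVel, 30)
  expect_equal(km$timeToPeakVel, 0.25)
  expect_equal(km$motorPauses, 0)
  expect_equal(km$motionTime, 0.5)

  # frozen 0.2 s gap
  tr2 <- trajectory(c(0, 0.1, 0.3, 0.4), c(0, 10, 10, 20), c(0, 0, 0, 0))
  km2 <- kinematic_measures(tr2)
  expect_equal(km2$motorPauses, 0.2)
  expect_equal(km2$motionTime, 0.2)

  # constant speed: peak attributed to the first step's end
  km3 <- kinematic_measures(straight_traj())
  expect_equal(km3$timeToPeakVel, straight_traj()$t[2L])
  expect_equal(km3$meanVel, km3$maxVel, tolerance = 1e-9)
})

test_that("direction flips and midline reversals count as specified", {
  tr <- trajectory(0:4 / 10, c(0, -1, -2, -1, -3), 0:4)
  expect_equal(count_measures(tr)$xFlips, 2L)
  tr2 <- trajectory(0:3 / 10, c(0, -5, 3, -2), 0:3)
  expect_equal(count_measures(tr2)$reversals, 2L)
  # touch-and-return counts once
  tr3 <- trajectory(0:3 / 10, c(0, -5, 0, -3), 0:3)
  expect_equal(count_measures(tr3)$reversals, 1L)
  # monotone x at constant speed
  cm <- count_measures(straight_traj())
  expect_equal(cm$xFlips, 0L)
  expect_equal(cm$accChanges, 0L)
})

test_that("sample entropy matches the exhaustive brute-force oracle", {
  # constant series: all templates match, entropy 0
  expect_equal(sample_entropy(rep(2, 10)), 0)
  # toy alternating diff series
  toy <- c(1, 2, 1, 2, 1, 2, 1, 2)
  expect_equal(sample_entropy(toy, m = 2L, r_frac = 0.5),
               sampen_brute(toy, m = 2L, r_frac = 0.5))
  set.seed(99)
  for (i in 1:40) {
    n <- sample(8:30, 1L)
    x <- switch(sample(3, 1L),
                rnorm(n),
                round(rnorm(n), 1),
                sin(seq_len(n) / 2) + rnorm(n, 0, 0.2))
    got <- sample_entropy(x)
    want <- sampen_brute(x)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
  expect_error(sample_entropy(c(1, 2, 3), m = 2L), "too short")
})

test_that("white noise is more entropic than a sine of the same length", {
  set.seed(7)
  diffs <- replicate(60, {
    wn <- cumsum(rnorm(80))
    sn <- cumsum(2 * sin(seq_len(80) / 3))
    t <- seq(0, 1, length.out = 80)
    sample_entropy_x(trajectory(t, wn, t)) -
      sample_entropy_x(trajectory(t, sn, t))
  })
  expect_gt(median(diffs, na.rm = TRUE), 0)
})

test_that("measure invariants hold on random-walk trajectories", {
  set.seed(3)
  for (i in 1:200) {
    tr <- random_walk_traj(sample(10:60, 1L))
    d <- deviation_measures(tr)
    expect_gte(d$curvature, 1)
    expect_lte(d$MADabove, d$MAD + 1e-12)
    expect_gte(d$AUC, 0)
    km <- kinematic_measures(tr)
    dur <- tr$t[nrow(tr)] - tr$t[1L]
    expect_equal(km$motorPauses + km$motionTime, dur, tolerance = 1e-9)
    expect_lte(km$minVel, km$meanVel + 1e-9)
    expect_lte(km$meanVel, km$maxVel + 1e-9)
  }
})

test_that("all 18 measures are invariant to x-mirroring after preprocessing", {
  set.seed(8)
  for (i in 1:20) {
    tr <- random_walk_traj(40L)
    left <- preprocess_trajectory(tr, "left")
    right <- preprocess_trajectory(trajectory(tr$t, -tr$x, tr$y), "right")
    expect_equal(trial_measures(left), trial_measures(right),
                 tolerance = 1e-9)
  }
})

test_that("aggregation averages over the same retained trials", {
  g <- tiny_cohort(seed = 21L, n_participants = 3L, n_trials = 10L)
  meas <- cursor_measures(g$trials)
  expect_named(meas, c("participant", "trial", "rt", "accuracy",
                       measure_names()), ignore.order = TRUE)
  # single-trial participant: mean equals the trial's vector
  one <- participant_measures(meas[meas$participant == meas$participant[1L] &
                                     meas$trial == 1L, ])
  expect_equal(unlist(one[, measure_names()]),
               unlist(meas[1L, measure_names()]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two identical trials: mean equals either
  two <- participant_measures(rbind(meas[1:1, ], meas[1:1, ]))
  expect_equal(unlist(two[, measure_names()]),
               unlist(meas[1L, measure_names()]), tolerance = 1e-12,
               ignore_attr = TRUE)
  pm <- participant_measures(meas)
  expect_false(anyNA(pm))
})
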