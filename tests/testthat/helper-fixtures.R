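# shared fixtures, built in code

# straight diagonal path: constant speed in exact binary arithmetic
# (1/8-second steps, integer displacements), so speed ties are exact
straight_traj <- function(n = 11L) {
  i <- 0:(n - 1L)
  trajectory(i / 8, -10 * i, 10 * i)
}

# small synthetic cohort for I/O and pipeline tests
tiny_cohort <- function(seed = 5L, n_participants = 4L, n_trials = 12L) {
  generate_cohort(cohort_config(n_participants = n_participants,
                                n_trials = n_trials, seed = seed))
}

# exhaustive O(n^2) template-counting sample-entropy oracle, independent of
# the package implementation
sampen_brute <- function(x, m = 2L, r_frac = 0.2) {
  r <- r_frac * sd(x)
  n <- length(x)
  A <- 0L; B <- 0L
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j == i) next
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r &&
            max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r)
          A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# random-walk trajectory generator for property tests
random_walk_traj <- function(n = 40L) {
  trajectory(cumsum(runif(n, 0.005, 0.02)),
             cumsum(rnorm(n, -1, 4)),
             cumsum(abs(rnorm(n, 3, 1))))
}
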