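#' Run the full analysis pipeline
#'
#' Chains the stages end to end: obtain data (synthetic cohort or CSV
#' files), preprocess trajectories, extract per-trial cursor measures,
#' filter RT outliers, aggregate to participant means, fit the DDM per
#' participant, map measures onto the fitted parameters, and (optionally)
#' run the trial-reduction bootstrap.  Every output file is re-derivable
#' from the inputs plus the configuration; all randomness flows from the
#' explicit seed.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; required, no wall-clock fallback.
#' @param cohort a [cohort_config()] for synthetic data, or `NULL` when
#'   loading from files.
#' @param trajectory_file,trial_file input CSVs (used when `cohort` is
#'   `NULL`).
#' @param resample_sizes trial sample sizes for the bootstrap stage, or
#'   `NULL` to skip it.
#' @param B bootstrap iterations.
#' @param assess_fit if `TRUE`, run the synthetic-parameter fit screen.
#' @param n_sets synthetic parameter sets for the fit screen.
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with all stage objects (`trials`, `measures`,
#'   `participants`, `ddm`, `mapping`, `curves`, `fit_quality`).
#' @export
run_pipeline <- function(out_dir, seed, cohort = NULL,
                         trajectory_file = NULL, trial_file = NULL,
                         resample_sizes = NULL, B = 100L,
                         assess_fit = FALSE, n_sets = 200L,
                         verbose = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required", call. = FALSE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(cohort)) {
    cohort$seed <- seed
    say("simulate: ", cohort$n_participants, " participants x ",
        cohort$n_trials, " trials")
    gen <- stage("simulate", generate_cohort(cohort))
    ts <- gen$trials
  } else {
    if (is.null(trajectory_file) || is.null(trial_file))
      stop("either a cohort config or both input files are required",
           call. = FALSE)
    say("load: ", trajectory_file)
    ts <- stage("load", load_trials(trajectory_file, trial_file))
    gen <- NULL
  }
  ts <- stage("preprocess", preprocess_trials(ts))
  say("measures: ", ntrials(ts), " trials")
  meas <- stage("measures", cursor_measures(ts))
  filt <- stage("filter", filter_rt_outliers(ts))
  say("filter: removed ", attr(filt$report, "n_removed"), " trials (",
      sprintf("%.2f%%", attr(filt$report, "pct_removed")), ")")
  kept <- traj_key(filt$trials$trials$participant, filt$trials$trials$trial)
  meas_kept <- meas[traj_key(meas$participant, meas$trial) %in% kept, ]
  pm <- stage("aggregate", participant_measures(meas_kept))
  say("fit-ddm: ", nrow(pm), " participants")
  fit <- stage("fit-ddm", fit_ddm(filt$trials))
  fq <- NULL
  if (assess_fit) {
    say("assess-fit: ", n_sets, " synthetic sets")
    fq <- stage("assess-fit",
                assess_fit_quality(fit, n_sets = n_sets, seed = seed + 1L))
  }
  ptab <- merge(pm, fit$params[, c("participant", "v", "a", "t0")],
                by = "participant")
  say("map: correlational reduction + PLSR chain")
  mapping <- stage("map", run_mapping(ptab))
  curves <- NULL
  if (!is.null(resample_sizes)) {
    say("resample: sizes ", paste(resample_sizes, collapse = ","),
        " x B = ", B)
    curves <- stage("resample",
                    resample_plsr(meas_kept, fit$params, mapping,
                                  sizes = resample_sizes, B = B,
                                  seed = seed + 2L))
  }
  write.csv(meas, file.path(out_dir, "measures.csv"), row.names = FALSE)
  write.csv(ptab, file.path(out_dir, "participants.csv"), row.names = FALSE)
  write.csv(fit$params, file.path(out_dir, "params.csv"), row.names = FALSE)
  stages <- summary(mapping)
  write.csv(stages, file.path(out_dir, "mapping.csv"), row.names = FALSE)
  if (!is.null(curves))
    write.csv(curves$curves, file.path(out_dir, "curves.csv"),
              row.names = FALSE)
  say("done: ", out_dir)
  invisible(list(trials = ts, truth = if (!is.null(gen)) gen$truth,
                 measures = meas, participants = ptab, ddm = fit,
                 fit_quality = fq, mapping = mapping, curves = curves))
}
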