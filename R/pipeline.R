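# End-to-end orchestration: simulate -> segment -> QC -> fit -> stats.

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

run_group_pipeline <- function(cohort, seg_params, min_trials,
                               same_response_threshold) {
  segments <- segment_cohort(cohort, seg_params)
  qc <- apply_trial_exclusions(cohort, segments, seg_params)
  pexcl <- apply_participant_exclusions(qc$trials, min_trials,
                                        same_response_threshold)
  fits <- fit_cohort_psychometrics(pexcl$trials,
                                   cohort$design$comparison_intensities)
  # a degenerate fit (too few informative trials / all-identical responses)
  # leaves that participant without a usable cell, mirroring the
  # participant-level exclusion rule; non-converged-but-finite ridge
  # estimates are retained and stay flagged in the fits table
  bad_fit <- unique(fits$participant[!fits$valid])
  fits_ok <- fits[!fits$participant %in% bad_fit, ]
  pct <- phase_percent_times(pexcl$trials)
  norm <- normalize_pses(fits_ok, pct)
  list(cohort = cohort, segments = segments, qc = qc$report,
       trials_retained = pexcl$trials, participant_exclusions = pexcl$excluded,
       nonconverged_participants = bad_fit, fits = fits, norm = norm)
}

stage_counts <- function(stage) {
  tibble::tibble(
    n_trials_total = nrow(stage$cohort$trials),
    n_trials_rejected = stage$qc$n_rejected,
    n_trials_retained_pre_participant = stage$qc$n_total - stage$qc$n_rejected,
    n_trials_retained = nrow(stage$trials_retained),
    n_participants_in = nrow(stage$cohort$participants),
    n_participants_retained = length(unique(stage$norm$participant))
  )
}

#' Run the Experiment-1 layout end to end
#'
#' Simulates one self-touch cohort, segments and quality-controls it, fits
#' the psychometric functions, and runs the inference layer: normalized
#' PSEs, the one-way repeated-measures ANOVA over the five reaching trial
#' types, the seven planned pairwise comparisons, and the per-participant
#' attenuation-slope analysis over both spans.
#'
#' @param n_participants Cohort size.
#' @param design A [design_config()].
#' @param population A [population_params()] (Experiment-1 self-touch by
#'   default).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param kinematics `"landmark"` (fast, closed-form landmarks) or `"full"`
#'   (sampled 240 Hz traces through the full segmentation chain).
#' @param seg_params A [segmentation_params()].
#' @param min_trials,same_response_threshold Participant-exclusion settings.
#' @return A `run_report` list: stage outputs (`cohort`, `segments`, `qc`,
#'   `fits`, `norm`), `anova`, `comparisons`, `slopes` /
#'   `slopes_within`, `counts`, and `provenance`.
#' @export
run_experiment1 <- function(n_participants = 29,
                            design = design_config(),
                            population = population_params("exp1", "self_touch"),
                            seed = 1,
                            kinematics = c("landmark", "full"),
                            seg_params = segmentation_params(),
                            min_trials = 10,
                            same_response_threshold = 0.95) {
  kinematics <- match.arg(kinematics)
  cfg <- list(n_participants = n_participants, design = design,
              population = population, seed = seed, kinematics = kinematics,
              seg_params = seg_params, min_trials = min_trials,
              same_response_threshold = same_response_threshold)
  cohort <- simulate_cohort(n_participants, design, population, seed = seed,
                            kinematics = kinematics)
  st <- run_group_pipeline(cohort, seg_params, min_trials,
                           same_response_threshold)
  anova <- rm_anova(st$norm)
  comparisons <- planned_comparisons(st$norm)
  slopes <- fit_participant_slopes(st$norm, span = "early_target")
  slopes_within <- fit_participant_slopes(st$norm, span = "early_late")
  means <- tapply(st$norm$pse_norm, st$norm$trial_type, mean)
  structure(c(st, list(
    anova = anova, comparisons = comparisons,
    slopes = slopes, slopes_within = slopes_within,
    type_means = means,
    counts = stage_counts(st),
    provenance = list(seed = seed, config_hash = config_hash(cfg),
                      package_version = as.character(utils::packageVersion("somatten")))
  )), class = "run_report")
}

#' Run the Experiment-2 layout end to end
#'
#' Simulates a self-touch group (sloped attenuation profile) and a
#' no-self-touch group (flat profile), runs the per-group pipelines, then
#' the between-group inference: mixed ANOVA (group x trial type), the five
#' between-group planned contrasts, per-group slope tests, the
#' between-group slope contrast, and the one-sided Bayes factor for the
#' no-self-touch group's slope.
#'
#' @param n_self,n_noself Group sizes.
#' @param design A [design_config()].
#' @param population_self,population_noself Group populations.
#' @param seed Integer seed.
#' @inheritParams run_experiment1
#' @return A `run_report` list with per-group stages (`self`, `noself`),
#'   `norm` (combined, with `group`), `anova`, `comparisons`, `slopes`,
#'   `slopes_within`, `bayes_noself_slope`, `counts`, `provenance`.
#' @export
run_experiment2 <- function(n_self = 29, n_noself = 27,
                            design = design_config(),
                            population_self = population_params("exp2", "self_touch"),
                            population_noself = population_params("exp2", "no_self_touch"),
                            seed = 1,
                            kinematics = c("landmark", "full"),
                            seg_params = segmentation_params(),
                            min_trials = 10,
                            same_response_threshold = 0.95) {
  kinematics <- match.arg(kinematics)
  cfg <- list(n_self = n_self, n_noself = n_noself, design = design,
              population_self = population_self,
              population_noself = population_noself, seed = seed,
              kinematics = kinematics, seg_params = seg_params,
              min_trials = min_trials,
              same_response_threshold = same_response_threshold)
  seeds <- child_seeds(seed, 2)
  co_self <- simulate_cohort(n_self, design, population_self, seed = seeds[1],
                             kinematics = kinematics, id_prefix = "S")
  co_noself <- simulate_cohort(n_noself, design, population_noself,
                               seed = seeds[2], kinematics = kinematics,
                               id_prefix = "N")
  st_self <- run_group_pipeline(co_self, seg_params, min_trials,
                                same_response_threshold)
  st_noself <- run_group_pipeline(co_noself, seg_params, min_trials,
                                  same_response_threshold)
  st_self$norm$group <- "self_touch"
  st_noself$norm$group <- "no_self_touch"
  norm <- dplyr::bind_rows(st_self$norm, st_noself$norm)
  anova <- mixed_anova(norm)
  comparisons <- between_group_comparisons(norm)
  slopes <- fit_participant_slopes(norm, span = "early_target")
  slopes_within <- fit_participant_slopes(norm, span = "early_late")
  bf <- bayes_factor_one_sided(
    slopes$slopes$slope[slopes$slopes$group == "no_self_touch"],
    direction = "less")
  structure(list(
    self = st_self, noself = st_noself, norm = norm,
    anova = anova, comparisons = comparisons,
    slopes = slopes, slopes_within = slopes_within,
    bayes_noself_slope = bf,
    type_means = tapply(norm$pse_norm, list(norm$group, norm$trial_type), mean),
    counts = dplyr::bind_rows(self_touch = stage_counts(st_self),
                              no_self_touch = stage_counts(st_noself),
                              .id = "group"),
    provenance = list(seed = seed, config_hash = config_hash(cfg),
                      package_version = as.character(utils::packageVersion("somatten")))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$counts)) {
    print(x$counts)
  }
  if (!is.null(x$anova)) {
    cat("ANOVA:\n")
    print(as.data.frame(x$anova), digits = 4)
  }
  if (!is.null(x$slopes)) {
    for (g in names(x$slopes$group_tests)) {
      s <- x$slopes$slopes$slope[x$slopes$slopes$group == g]
      cat(sprintf("slope [%s]: mean %.4g N/%% (p = %.4g, %s)\n", g, mean(s),
                  x$slopes$group_tests[[g]]$p_raw,
                  x$slopes$group_tests[[g]]$test_used))
    }
  }
  invisible(x)
}
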