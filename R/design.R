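#' Experimental design configuration
#'
#' Describes the force-discrimination trial schedule and stimulus timing: the
#' comparison-force ladder, repetition counts, the five reaching trial types,
#' and the scheduled / hardware-triggered test-force times. Defaults encode
#' the canonical design: seven comparison intensities (1-3 N) tested 16 times
#' per reaching type and 8 times at baseline (560 + 56 = 616 trials), a 2 N /
#' 100 ms test force, a comparison force 1200 ms after the test force,
#' scheduled test forces at 250/370/550 ms after the go-cue (shifted +100 ms
#' in Experiment 2), a ~35 ms hardware delay for tap-triggered forces, and a
#' 300 ms post-reach offset.
#'
#' @param comparison_intensities Comparison-force ladder in newtons, strictly
#'   increasing, containing `test_force`.
#' @param reps_per_reaching_type Repetitions of each intensity within each
#'   reaching trial type.
#' @param reps_baseline Repetitions of each intensity in the baseline block.
#' @param test_force Test-force amplitude (N).
#' @param test_duration Test-force duration (ms).
#' @param comparison_delay Test-to-comparison interval (ms).
#' @param scheduled_force_times Go-cue-locked test-force times (ms) for the
#'   three time-scheduled trial types.
#' @param post_reach_offset Tap-to-test interval for post-reach trials (ms).
#' @param system_delay Hardware delay between tap/trigger and the
#'   tap-triggered test force (ms).
#' @param experiment2_shift Added to `scheduled_force_times` in Experiment 2
#'   layouts (ms).
#' @return A `design_config` list.
#' @export
#' @examples
#' d <- design_config()
#' n_trials_per_participant(d) # 616
design_config <- function(comparison_intensities = c(1, 1.5, 1.75, 2, 2.25, 2.5, 3),
                          reps_per_reaching_type = 16L,
                          reps_baseline = 8L,
                          test_force = 2,
                          test_duration = 100,
                          comparison_delay = 1200,
                          scheduled_force_times = c(t250 = 250, t370 = 370, t550 = 550),
                          post_reach_offset = 300,
                          system_delay = 35,
                          experiment2_shift = 100) {
  assert_that(length(comparison_intensities) >= 1,
              "comparison_intensities must be non-empty")
  assert_that(all(diff(comparison_intensities) > 0),
              "comparison_intensities must be strictly increasing")
  assert_that(test_force %in% comparison_intensities,
              "test_force must be a member of comparison_intensities")
  assert_that(reps_per_reaching_type >= 1 && reps_baseline >= 1,
              "repetition counts must be >= 1")
  assert_that(length(scheduled_force_times) == 3 &&
                all(scheduled_force_times >= 0),
              "scheduled_force_times must be three non-negative times")
  assert_that(all(c(test_duration, comparison_delay, post_reach_offset,
                    system_delay, experiment2_shift) >= 0),
              "all delays must be >= 0")
  structure(list(
    comparison_intensities = as.numeric(comparison_intensities),
    reps_per_reaching_type = as.integer(reps_per_reaching_type),
    reps_baseline = as.integer(reps_baseline),
    reaching_types = c("t250", "t370", "t550", "target", "post_reach"),
    test_force = test_force,
    test_duration = test_duration,
    comparison_delay = comparison_delay,
    scheduled_force_times = scheduled_force_times,
    post_reach_offset = post_reach_offset,
    system_delay = system_delay,
    experiment2_shift = experiment2_shift
  ), class = "design_config")
}

#' Trials per participant implied by a design
#'
#' @param design A [design_config()].
#' @return Named integer vector with `reaching`, `baseline` and `total`.
#' @export
n_trials_per_participant <- function(design) {
  k <- length(design$comparison_intensities)
  reaching <- k * design$reps_per_reaching_type * length(design$reaching_types)
  baseline <- k * design$reps_baseline
  c(reaching = reaching, baseline = baseline, total = reaching + baseline)
}

#' Attenuation profile of the simulated observer
#'
#' The generative stand-in for how the perceived test-force intensity (the
#' PSE shift relative to baseline) evolves over the reach. Within the reach,
#' attenuation at `p` percent of the movement is
#' `slope_per_percent * 100 * (p / 100) ^ curvature`: zero at movement
#' onset, reaching `slope_per_percent * 100` at the moment of self-touch,
#' with `curvature > 1` concentrating the buildup late in the reach (the
#' prediction of self-touch sharpens as the movement progresses, so
#' attenuation accumulates faster near contact; `curvature = 1` gives a
#' straight line with gradient `slope_per_percent`). Target trials receive
#' `slope_per_percent * 100 + target_extra_dip` (the predicted self-touch
#' moment counts as 100% regardless of the hardware delay), and post-reach
#' trials carry only `post_reach_residual`.
#'
#' @param slope_per_percent Mean attenuation gradient over the full reach
#'   (N per % of reach duration; negative = progressive attenuation).
#' @param target_extra_dip Extra PSE shift at self-touch beyond the
#'   within-reach trend (N).
#' @param post_reach_residual PSE shift 300 ms after the tap (N).
#' @param curvature Exponent of the within-reach buildup (>= 1).
#' @return An `attenuation_profile` list.
#' @export
attenuation_profile <- function(slope_per_percent = -2.3e-3,
                                target_extra_dip = -0.08,
                                post_reach_residual = -0.08,
                                curvature = 1.5) {
  assert_that(curvature >= 1, "curvature must be >= 1")
  structure(list(slope_per_percent = slope_per_percent,
                 target_extra_dip = target_extra_dip,
                 post_reach_residual = post_reach_residual,
                 curvature = curvature),
            class = "attenuation_profile")
}

#' Flat (null) attenuation profile
#'
#' Used for the no-self-touch condition, in which the reaching movement has
#' no somatosensory consequences for the static hand.
#' @return An `attenuation_profile` with all components zero.
#' @export
flat_profile <- function() attenuation_profile(0, 0, 0)

#' Evaluate an attenuation profile for one or more trials
#'
#' @param profile An [attenuation_profile()].
#' @param percent Test-force time as % of reach duration (used for scheduled
#'   trial types; clamped to `[0, 100]`).
#' @param type Scheduled trial type (`t250`/`t370`/`t550`/`target`/
#'   `post_reach`/`baseline`), recycled against `percent`.
#' @return PSE shift in newtons (<= 0 for attenuation).
#' @export
evaluate_attenuation <- function(profile, percent, type) {
  n <- max(length(percent), length(type))
  percent <- rep_len(percent, n)
  type <- rep_len(type, n)
  out <- numeric(n)
  k <- profile$curvature %||% 1
  sched <- type %in% c("t250", "t370", "t550")
  p01 <- pmin(pmax(percent[sched], 0), 100) / 100
  out[sched] <- profile$slope_per_percent * 100 * p01^k
  out[type == "target"] <- profile$slope_per_percent * 100 + profile$target_extra_dip
  out[type == "post_reach"] <- profile$post_reach_residual
  out[type == "baseline"] <- 0
  out
}

#' Per-participant simulation parameters
#'
#' Kinematic and psychophysical parameters for one simulated participant.
#' Reaction time is defined as the latency from go-cue to the *detected*
#' movement onset (velocity > 5 cm/s), and movement duration as detected
#' onset to tap, matching how these quantities are measured from data.
#'
#' @param reaction_time_mean,reaction_time_sd Go-cue to detected onset (ms).
#' @param movement_duration_mean Detected onset to tap (ms).
#' @param movement_duration_within_sd Trial-to-trial duration SD (ms).
#' @param reach_amplitude Start-to-target distance (cm).
#' @param sampling_rate Motion-capture rate (Hz).
#' @param kinematic_noise_sd Isotropic positional noise per sample (cm).
#' @param baseline_pse Resting-state PSE (N).
#' @param baseline_jnd Resting-state JND (N), > 0.
#' @param profile An [attenuation_profile()].
#' @param condition `"self_touch"` or `"no_self_touch"`.
#' @return A `participant_params` list.
#' @export
participant_params <- function(reaction_time_mean = 220,
                               reaction_time_sd = 42,
                               movement_duration_mean = 542,
                               movement_duration_within_sd = 77,
                               reach_amplitude = 25,
                               sampling_rate = 240,
                               kinematic_noise_sd = 0.01,
                               baseline_pse = 2,
                               baseline_jnd = 0.17,
                               profile = attenuation_profile(),
                               condition = c("self_touch", "no_self_touch")) {
  condition <- match.arg(condition)
  assert_that(sampling_rate > 0, "sampling_rate must be > 0")
  assert_that(reaction_time_sd >= 0 && movement_duration_within_sd >= 0 &&
                kinematic_noise_sd >= 0, "SDs must be >= 0")
  assert_that(baseline_jnd > 0, "baseline_jnd must be > 0")
  assert_that(reach_amplitude > 0, "reach_amplitude must be > 0")
  assert_that(movement_duration_mean > 0, "movement duration must be > 0")
  if (condition == "no_self_touch") profile <- flat_profile()
  structure(list(reaction_time_mean = reaction_time_mean,
                 reaction_time_sd = reaction_time_sd,
                 movement_duration_mean = movement_duration_mean,
                 movement_duration_within_sd = movement_duration_within_sd,
                 reach_amplitude = reach_amplitude,
                 sampling_rate = sampling_rate,
                 kinematic_noise_sd = kinematic_noise_sd,
                 baseline_pse = baseline_pse,
                 baseline_jnd = baseline_jnd,
                 profile = profile,
                 condition = condition),
            class = "participant_params")
}

#' Population-level generator parameters
#'
#' Distributions from which per-participant parameters are drawn by
#' [simulate_cohort()]. Defaults follow the study conditions: Experiment-1
#' reaction times 220 +/- 42 ms, reach durations 542 ms with 46 ms
#' between-participant and 77 +/- 20 ms within-participant SD, a 25 cm reach.
#' Experiment-2 cohorts react faster (171 +/- 38 ms) and their
#' scheduled test forces are shifted 100 ms later; both Experiment-2 groups
#' share the same reaching kinematics (the paper reports comparable
#' durations and probe times across groups), and differ only in the
#' attenuation profile (default sloped for self-touch, flat for
#' no-self-touch).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param condition `"self_touch"` or `"no_self_touch"`.
#' @param profile Mean attenuation profile for the group; `NULL` picks the
#'   per-experiment default (flat for `no_self_touch`).
#' @param slope_between_sd Between-participant SD of the attenuation slope
#'   (N/%).
#' @param rt_mean,rt_within_sd,rt_between_sd Reaction-time population mean,
#'   within- and between-participant SD (ms); `NULL` picks defaults.
#' @param duration_mean,duration_between_sd Reach-duration population mean
#'   and between-participant SD (ms).
#' @param duration_within_mean,duration_within_sd Mean and spread of the
#'   per-participant within-SD of duration (ms).
#' @param pse_mean,pse_between_sd Baseline-PSE population parameters (N).
#' @param jnd_mean,jnd_between_sd Baseline-JND population parameters (N).
#' @param reach_amplitude Reach amplitude (cm).
#' @param kinematic_noise_sd Positional noise SD (cm).
#' @param force_noise_sd Actuator noise on measured forces (N).
#' @return A `population_params` list.
#' @export
population_params <- function(experiment = c("exp1", "exp2"),
                              condition = c("self_touch", "no_self_touch"),
                              profile = NULL,
                              slope_between_sd = 1.0e-3,
                              rt_mean = NULL, rt_within_sd = NULL,
                              rt_between_sd = 25,
                              duration_mean = 542, duration_between_sd = 46,
                              duration_within_mean = 77, duration_within_sd = 20,
                              pse_mean = 2, pse_between_sd = 0.1,
                              jnd_mean = 0.17, jnd_between_sd = 0.03,
                              reach_amplitude = 25,
                              kinematic_noise_sd = 0.01,
                              force_noise_sd = 0.03) {
  experiment <- match.arg(experiment)
  condition <- match.arg(condition)
  if (is.null(rt_mean)) rt_mean <- if (experiment == "exp1") 220 else 171
  if (is.null(rt_within_sd)) rt_within_sd <- if (experiment == "exp1") 42 else 38
  if (is.null(profile)) {
    profile <- if (condition == "no_self_touch") flat_profile()
    else attenuation_profile()
  }
  if (condition == "no_self_touch") slope_between_sd <- 0
  structure(list(experiment = experiment, condition = condition,
                 profile = profile, slope_between_sd = slope_between_sd,
                 rt_mean = rt_mean, rt_within_sd = rt_within_sd,
                 rt_between_sd = rt_between_sd,
                 duration_mean = duration_mean,
                 duration_between_sd = duration_between_sd,
                 duration_within_mean = duration_within_mean,
                 duration_within_sd = duration_within_sd,
                 pse_mean = pse_mean, pse_between_sd = pse_between_sd,
                 jnd_mean = jnd_mean, jnd_between_sd = jnd_between_sd,
                 reach_amplitude = reach_amplitude,
                 kinematic_noise_sd = kinematic_noise_sd,
                 force_noise_sd = force_noise_sd),
            class = "population_params")
}

#' Draw per-participant parameters from a population
#'
#' @param population A [population_params()].
#' @return A [participant_params()] with the participant's attenuation
#'   profile attached.
#' @export
draw_participant <- function(population) {
  p <- population
  slope <- p$profile$slope_per_percent +
    if (p$slope_between_sd > 0) rnorm(1, 0, p$slope_between_sd) else 0
  prof <- attenuation_profile(slope_per_percent = slope,
                              target_extra_dip = p$profile$target_extra_dip,
                              post_reach_residual = p$profile$post_reach_residual,
                              curvature = p$profile$curvature %||% 1)
  participant_params(
    reaction_time_mean = rtruncnorm_pos(1, p$rt_mean, p$rt_between_sd, 50),
    reaction_time_sd = p$rt_within_sd,
    movement_duration_mean = rtruncnorm_pos(1, p$duration_mean, p$duration_between_sd, 200),
    movement_duration_within_sd = rtruncnorm_pos(1, p$duration_within_mean, p$duration_within_sd, 5),
    reach_amplitude = p$reach_amplitude,
    kinematic_noise_sd = p$kinematic_noise_sd,
    baseline_pse = rnorm(1, p$pse_mean, p$pse_between_sd),
    baseline_jnd = rtruncnorm_pos(1, p$jnd_mean, p$jnd_between_sd, 0.05),
    profile = prof,
    condition = p$condition
  )
}
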