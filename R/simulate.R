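#' Simulate a single reaching trace
#'
#' Builds a 240 Hz kinematic record for one reaching trial: the hand rests at
#' the start position until movement start, follows a minimum-jerk trajectory
#' of the given amplitude and duration along the reach axis, then rests at
#' the target. Isotropic Gaussian positional noise is added per sample. For
#' the self-touch condition a tap-force pulse (rising well above the 0.3 N
#' detection threshold) is emitted at movement end; for the no-self-touch
#' condition the distance-trigger time is recorded instead.
#'
#' @param params A [participant_params()].
#' @param trial One-row trial stub (needs `scheduled_type`); may carry
#'   `test_time` / `comparison_time` event markers.
#' @param rt,duration Detected-onset latency and onset-to-tap duration (ms);
#'   drawn from `params` when `NULL`.
#' @param seed Optional seed.
#' @return A `kin_trace`: list with `time` (ms), `pos` (n x 3 cm),
#'   `tap_force` (N), `distance_trigger_time`, `distortion` flags, TTL
#'   `events`, and the designated `start_x`.
#' @export
simulate_reach_trace <- function(params, trial = NULL, rt = NULL,
                                 duration = NULL, seed = NULL) {
  assert_that(params$movement_duration_mean > 0 && params$reach_amplitude > 0,
              "duration and amplitude must be > 0")
  with_seed(seed, {
    if (is.null(rt)) {
      rt <- rtruncnorm_pos(1, params$reaction_time_mean,
                           params$reaction_time_sd, 50)
    }
    if (is.null(duration)) {
      duration <- rtruncnorm_pos(1, params$movement_duration_mean,
                                 params$movement_duration_within_sd, 100)
    }
    assert_that(duration > 0, "duration must be > 0")
    lmk <- minjerk_landmarks(rt, duration, params$reach_amplitude,
                             condition = params$condition)
    test_time <- trial$test_time %||% NA_real_
    comparison_time <- trial$comparison_time %||% NA_real_
    # the trace needs to cover the segmentation window (offset + distortion
    # margin); force events beyond it live in the trial record / TTL markers
    t_end <- lmk$offset + 500
    dt <- 1000 / params$sampling_rate
    time <- seq(0, t_end, by = dt)
    n <- length(time)
    tau <- (time - lmk$movement_start) / lmk$t_total
    x <- minjerk_position(tau, params$reach_amplitude)
    pos <- cbind(x = x, y = numeric(n), z = numeric(n))
    if (params$kinematic_noise_sd > 0) {
      pos <- pos + matrix(rnorm(3 * n, 0, params$kinematic_noise_sd), n, 3)
    }
    tap_force <- numeric(n)
    trigger <- NA_real_
    if (params$condition == "self_touch") {
      # fast ramp to 2 N at contact, ~130 ms press, release
      rel <- time - lmk$offset
      tap_force <- 2 * pmin(pmax(rel / 10, 0), 1) *
        pmin(pmax((140 - rel) / 30, 0), 1)
    } else {
      trigger <- lmk$offset
    }
    structure(list(
      time = time,
      pos = pos,
      tap_force = tap_force,
      distance_trigger_time = trigger,
      distortion = logical(n),
      events = c(go_cue = 0, test_force = test_time,
                 comparison_force = comparison_time),
      condition = params$condition,
      start_x = 0,
      sampling_rate = params$sampling_rate
    ), class = "kin_trace")
  })
}

#' Simulate observer responses for a force-discrimination trial
#'
#' The observer compares the comparison force against the perceived test
#' intensity through a logistic psychometric function:
#' `P(comparison stronger) = plogis((comparison - perceived_pse) * log(3) / jnd)`,
#' so that the probability is 0.5 at the perceived PSE and 0.75 one JND above
#' it. Vectorised over trials.
#'
#' @param comparison Comparison-force intensity (N).
#' @param perceived_pse Perceived test intensity, i.e. baseline PSE plus the
#'   attenuation-profile shift for the trial's phase (N).
#' @param jnd Discrimination threshold (N), > 0.
#' @param seed Optional seed.
#' @return Character vector, `"comparison_stronger"` or `"test_stronger"`.
#' @export
simulate_observer_response <- function(comparison, perceived_pse, jnd,
                                       seed = NULL) {
  assert_that(all(jnd > 0), "jnd must be > 0")
  with_seed(seed, {
    p <- plogis((comparison - perceived_pse) * log(3) / jnd)
    ifelse(rbinom(length(p), 1, p) == 1, "comparison_stronger", "test_stronger")
  })
}

#' Probability that the comparison force is judged stronger
#' @inheritParams simulate_observer_response
#' @return Numeric vector of probabilities.
#' @export
observer_probability <- function(comparison, perceived_pse, jnd) {
  assert_that(all(jnd > 0), "jnd must be > 0")
  plogis((comparison - perceived_pse) * log(3) / jnd)
}

simulate_participant <- function(pid, params, design, experiment, force_noise_sd,
                                 kinematics = "landmark") {
  sched <- make_trial_schedule(design,
                               seed = sample.int(.Machine$integer.max - 1L, 1))
  sched$participant <- pid
  reaching <- sched$block == "reaching"
  nr <- sum(reaching)

  rt <- rtruncnorm_pos(nr, params$reaction_time_mean, params$reaction_time_sd, 50)
  dur <- rtruncnorm_pos(nr, params$movement_duration_mean,
                        params$movement_duration_within_sd, 100)
  lmk <- minjerk_landmarks(rt, dur, params$reach_amplitude,
                           condition = params$condition)
  shift <- if (experiment == "exp2") design$experiment2_shift else 0
  sched_times <- design$scheduled_force_times + shift
  type <- sched$scheduled_type[reaching]
  test_time <- rep(NA_real_, nr)
  for (tt in names(sched_times)) test_time[type == tt] <- sched_times[[tt]]
  test_time[type == "target"] <- lmk$offset[type == "target"] + design$system_delay
  test_time[type == "post_reach"] <- lmk$offset[type == "post_reach"] +
    design$post_reach_offset

  percent <- (test_time - lmk$onset) / (lmk$offset - lmk$onset) * 100
  shift_n <- evaluate_attenuation(params$profile, percent, type)

  trials <- sched
  trials$test_time <- NA_real_
  trials$comparison_time <- NA_real_
  trials$test_time[reaching] <- test_time
  trials$test_time[!reaching] <- 100
  trials$comparison_time <- trials$test_time + design$comparison_delay
  trials$test_intensity_measured <- trials$test_intensity_commanded +
    rnorm(nrow(trials), 0, force_noise_sd)
  trials$comparison_intensity_measured <- trials$comparison_intensity_commanded +
    rnorm(nrow(trials), 0, force_noise_sd)

  perceived <- rep(params$baseline_pse, nrow(trials))
  perceived[reaching] <- perceived[reaching] + shift_n
  trials$response <- simulate_observer_response(
    trials$comparison_intensity_measured, perceived, params$baseline_jnd)
  trials$corruption <- NA_character_

  segments_truth <- tibble::tibble(
    participant = pid,
    trial_id = sched$trial_id[reaching],
    onset = lmk$onset,
    offset = lmk$offset,
    movement_duration = lmk$movement_duration,
    peak_time = lmk$peak_time,
    peak_speed = lmk$peak_speed,
    ascend85 = lmk$ascend85,
    descend85 = lmk$descend85,
    start_displacement = 0,
    landmarks_ok = TRUE,
    distortion_overlap = FALSE
  )

  traces <- NULL
  if (kinematics == "full") {
    traces <- vector("list", nr)
    idx <- which(reaching)
    for (i in seq_len(nr)) {
      traces[[i]] <- simulate_reach_trace(params, trials[idx[i], ],
                                          rt = rt[i], duration = dur[i])
    }
    names(traces) <- paste(pid, sched$trial_id[reaching], sep = "_")
  }

  list(trials = trials, segments_truth = segments_truth, traces = traces)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant parameters from the population, builds each
#' participant's 616-trial schedule, simulates reaching kinematics and
#' observer responses, and assembles a reproducible cohort dataset.
#'
#' Two kinematic representations are available. `"full"` materialises a
#' 240 Hz `kin_trace` per reaching trial, to be processed by
#' [segment_cohort()]. `"landmark"` skips the sampled traces and stores the
#' generator's closed-form minimum-jerk landmarks directly as the
#' segmentation table; this is the representation used for large simulation
#' batteries, and is distributionally identical to segmenting noise-free
#' traces with interpolated crossings.
#'
#' @param n_participants Number of participants (>= 1).
#' @param design A [design_config()].
#' @param population A [population_params()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param kinematics `"landmark"` or `"full"`.
#' @param id_prefix Participant-identifier prefix.
#' @return A `cohort` object: list with `trials`, `participants`,
#'   `segments_truth`, `traces` (full mode), `design`, `population`, and a
#'   `manifest` recording seed and generation mode.
#' @export
#' @examples
#' co <- simulate_cohort(2, design_config(), population_params(), seed = 1)
#' nrow(co$trials) # 1232
simulate_cohort <- function(n_participants, design = design_config(),
                            population = population_params(), seed = NULL,
                            kinematics = c("landmark", "full"),
                            id_prefix = "P") {
  assert_that(n_participants >= 1, "n_participants must be >= 1")
  kinematics <- match.arg(kinematics)
  with_seed(seed, {
    pids <- sprintf("%s%02d", id_prefix, seq_len(n_participants))
    # one independent stream per participant: trial-level draws are then
    # identical between the landmark and full kinematic representations
    seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
    out <- vector("list", n_participants)
    pars <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      with_seed(seeds[i], {
        pars[[i]] <- draw_participant(population)
        out[[i]] <- simulate_participant(pids[i], pars[[i]], design,
                                         population$experiment,
                                         population$force_noise_sd, kinematics)
      })
    }
    participants <- tibble::tibble(
      participant = pids,
      condition = population$condition,
      reaction_time_mean = vapply(pars, `[[`, 0, "reaction_time_mean"),
      movement_duration_mean = vapply(pars, `[[`, 0, "movement_duration_mean"),
      movement_duration_within_sd = vapply(pars, `[[`, 0, "movement_duration_within_sd"),
      baseline_pse = vapply(pars, `[[`, 0, "baseline_pse"),
      baseline_jnd = vapply(pars, `[[`, 0, "baseline_jnd"),
      slope_per_percent = vapply(pars, function(p) p$profile$slope_per_percent, 0)
    )
    traces <- NULL
    if (kinematics == "full") {
      traces <- do.call(c, lapply(out, `[[`, "traces"))
    }
    structure(list(
      trials = dplyr::bind_rows(lapply(out, `[[`, "trials")),
      participants = participants,
      params = pars,
      segments_truth = dplyr::bind_rows(lapply(out, `[[`, "segments_truth")),
      traces = traces,
      design = design,
      population = population,
      manifest = list(seed = seed, n_participants = n_participants,
                      kinematics = kinematics,
                      experiment = population$experiment,
                      condition = population$condition)
    ), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d trials (%s, %s, %s kinematics)\n",
              nrow(x$participants), nrow(x$trials),
              x$manifest$experiment %||% "exp1",
              x$manifest$condition %||% "self_touch",
              x$manifest$kinematics %||% "landmark"))
  invisible(x)
}
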