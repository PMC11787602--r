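#' Segmentation parameters
#'
#' Tunable constants of the kinematic preprocessing and segmentation:
#' a 5-sample (~21 ms at 240 Hz) moving-average position filter, movement
#' onset at the first sustained crossing of 5 cm/s (held for 100 ms), reach
#' offset at the first 0.3 N tap-force crossing, peak-velocity search
#' restricted to the first 67% of the movement, and phase boundaries at 85%
#' of peak speed.
#'
#' @param smooth_span Moving-average span in samples (odd, >= 1).
#' @param onset_speed_threshold Onset speed threshold (cm/s).
#' @param onset_hold Time the speed must stay above threshold (ms).
#' @param tap_force_threshold Tap detection threshold (N).
#' @param peak_window_fraction Fraction of the movement within which the
#'   peak-velocity search is constrained.
#' @param phase_velocity_fraction Fraction of peak speed defining the
#'   ascending/descending phase boundaries.
#' @param sampling_rate Sampling rate (Hz).
#' @param interpolate Use linear sub-sample interpolation for threshold
#'   crossings (`TRUE`, default) or snap to sample times (`FALSE`).
#' @param distortion_window Pre-onset / post-offset margins (ms) within which
#'   a distortion flag invalidates the trial (exclusion criterion `f`).
#' @param start_displacement_limit Maximum tolerated displacement of the
#'   start position along the reach axis (cm, criterion `c`).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smooth_span = 5,
                                onset_speed_threshold = 5,
                                onset_hold = 100,
                                tap_force_threshold = 0.3,
                                peak_window_fraction = 0.67,
                                phase_velocity_fraction = 0.85,
                                sampling_rate = 240,
                                interpolate = TRUE,
                                distortion_window = c(before = 50, after = 350),
                                start_displacement_limit = 5) {
  assert_that(smooth_span >= 1 && smooth_span %% 2 == 1,
              "smooth_span must be odd and >= 1")
  assert_that(peak_window_fraction > 0 && peak_window_fraction < 1 &&
                phase_velocity_fraction > 0 && phase_velocity_fraction < 1,
              "fractions must lie in (0, 1)")
  assert_that(onset_speed_threshold > 0 && tap_force_threshold > 0 &&
                onset_hold > 0 && sampling_rate > 0,
              "thresholds, hold and sampling rate must be > 0")
  structure(list(smooth_span = as.integer(smooth_span),
                 onset_speed_threshold = onset_speed_threshold,
                 onset_hold = onset_hold,
                 tap_force_threshold = tap_force_threshold,
                 peak_window_fraction = peak_window_fraction,
                 phase_velocity_fraction = phase_velocity_fraction,
                 sampling_rate = sampling_rate,
                 interpolate = isTRUE(interpolate),
                 distortion_window = distortion_window,
                 start_displacement_limit = start_displacement_limit),
            class = "segmentation_params")
}

#' Smooth a position matrix with a centred moving average
#'
#' Applies the moving-average filter per coordinate. Edges use a shrinking
#' centred window so that output length equals input length.
#'
#' @param pos Numeric vector or n x d matrix of positions.
#' @param span Window span in samples (odd); or a [segmentation_params()].
#' @return Smoothed positions, same shape as the input.
#' @export
smooth_positions <- function(pos, span = 5) {
  if (inherits(span, "segmentation_params")) span <- span$smooth_span
  vec <- is.null(dim(pos))
  if (vec) pos <- matrix(pos, ncol = 1)
  n <- nrow(pos)
  assert_that(n >= span, "trace shorter than the smoothing span")
  half <- (span - 1) %/% 2
  out <- pos
  if (half > 0) {
    for (j in seq_len(ncol(pos))) {
      sm <- stats::filter(pos[, j], rep(1 / span, span), sides = 2)
      out[, j] <- as.numeric(sm)
      for (i in seq_len(half)) {
        k <- i - 1L
        out[i, j] <- mean(pos[seq_len(2 * k + 1), j])
        out[n - k, j] <- mean(pos[(n - 2 * k):n, j])
      }
    }
  }
  if (vec) out[, 1] else out
}

#' Compute 3D speed from a position series
#'
#' Differentiates each coordinate (central differences on interior samples,
#' one-sided at the edges) and returns the Euclidean norm, i.e. the
#' tangential speed, on the same timebase.
#'
#' @param pos n x d position matrix (cm) or vector.
#' @param time Timestamps in ms, strictly increasing and uniform.
#' @return Speed in cm/s, length n.
#' @export
compute_speed <- function(pos, time) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1)
  n <- nrow(pos)
  assert_that(n >= 2, "need at least two samples")
  dtv <- diff(time)
  assert_that(all(abs(dtv - dtv[1]) < 1e-6 * dtv[1] + 1e-9),
              "timestamps must be uniform")
  dt_s <- dtv[1] / 1000
  vel <- apply(pos, 2, function(x) {
    c(x[2] - x[1],
      (x[3:n] - x[1:(n - 2)]) / 2,
      x[n] - x[n - 1]) / dt_s
  })
  if (is.null(dim(vel))) vel <- matrix(vel, ncol = 1)
  sqrt(rowSums(vel^2))
}

# Interpolated upward-crossing time of `series` through `threshold` between
# samples k-1 and k (series[k] is the first sample above).
interp_crossing <- function(time, series, k, threshold, interpolate) {
  if (!interpolate || k == 1 || series[k - 1] > threshold) return(time[k])
  s0 <- series[k - 1]; s1 <- series[k]
  if (s1 == s0) return(time[k])
  time[k - 1] + (threshold - s0) / (s1 - s0) * (time[k] - time[k - 1])
}

#' Detect movement onset from a speed series
#'
#' Finds the first time at which the speed exceeds the onset threshold and
#' stays above it for the full hold period (100 ms = 24 consecutive samples
#' at 240 Hz). The search starts at `after` (the go-cue by default).
#'
#' @param speed Speed series (cm/s).
#' @param time Timestamps (ms).
#' @param params A [segmentation_params()].
#' @param after Earliest time considered (ms).
#' @return Onset time in ms (sub-sample interpolated unless
#'   `params$interpolate` is `FALSE`), or `NA_real_` if no qualifying run
#'   exists (the trial is later rejected under criterion `b`).
#' @export
detect_movement_onset <- function(speed, time, params = segmentation_params(),
                                  after = 0) {
  dt <- 1000 / params$sampling_rate
  hold <- as.integer(ceiling(params$onset_hold / dt))
  ok <- speed > params$onset_speed_threshold & time >= after
  n <- length(ok)
  if (n < hold) return(NA_real_)
  # run-length scan: first index starting a run of >= hold TRUEs
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= hold)
  if (length(cand) == 0) return(NA_real_)
  k <- starts[cand[1]]
  interp_crossing(time, speed, k, params$onset_speed_threshold,
                  params$interpolate && time[k] > after)
}

#' Detect the reach offset (end of movement)
#'
#' Self-touch: first upward crossing of the tap-force threshold after
#' movement onset. No-self-touch: the recorded distance-trigger time.
#'
#' @param trace A `kin_trace`, or a list with `time`, `tap_force`,
#'   `distance_trigger_time` and `condition`.
#' @param onset Movement-onset time (ms).
#' @param params A [segmentation_params()].
#' @return Offset time (ms), or `NA_real_` if the tap/trigger is missing.
#' @export
detect_reach_offset <- function(trace, onset, params = segmentation_params()) {
  if (identical(trace$condition, "no_self_touch")) {
    trig <- trace$distance_trigger_time
    return(if (is.null(trig) || !is.finite(trig)) NA_real_ else trig)
  }
  f <- trace$tap_force
  idx <- which(f > params$tap_force_threshold & trace$time > onset)
  if (length(idx) == 0 || !is.finite(onset)) return(NA_real_)
  interp_crossing(trace$time, f, idx[1], params$tap_force_threshold,
                  params$interpolate)
}

#' Constrained peak-velocity search
#'
#' Returns the maximum speed within the first `peak_window_fraction` (67%)
#' of the movement, so that the tap's own velocity transient at the end of
#' the reach is never mistaken for the transport peak. Ties break to the
#' earliest sample.
#'
#' @param speed,time Speed series and timestamps.
#' @param onset,offset Movement onset and offset times (ms).
#' @param params A [segmentation_params()].
#' @return List with `peak_time` and `peak_speed`.
#' @export
find_peak_velocity <- function(speed, time, onset, offset,
                               params = segmentation_params()) {
  assert_that(onset < offset, "onset must precede offset")
  hi <- onset + params$peak_window_fraction * (offset - onset)
  win <- which(time >= onset & time <= hi)
  assert_that(length(win) > 0, "empty peak-search window")
  k <- win[which.max(speed[win])]
  list(peak_time = time[k], peak_speed = speed[k])
}

#' Phase-boundary crossings at 85% of peak speed
#'
#' `ascend85` is the first time in `[onset, peak]` at which the speed
#' reaches `phase_velocity_fraction` of the peak; `descend85` the first time
#' after the peak at which it drops below that fraction (the offset if no
#' such drop occurs before it).
#'
#' @inheritParams find_peak_velocity
#' @param peak_time,peak_speed Output of [find_peak_velocity()].
#' @return List with `ascend85` and `descend85` times (ms).
#' @export
compute_phase_crossings <- function(speed, time, onset, offset, peak_time,
                                    peak_speed,
                                    params = segmentation_params()) {
  thr <- params$phase_velocity_fraction * peak_speed
  asc_idx <- which(time >= onset & time <= peak_time & speed >= thr)
  ascend85 <- if (length(asc_idx) == 0) {
    peak_time
  } else {
    interp_crossing(time, speed, asc_idx[1], thr,
                    params$interpolate && time[asc_idx[1]] > onset)
  }
  desc_idx <- which(time > peak_time & time <= offset & speed < thr)
  descend85 <- if (length(desc_idx) == 0) {
    offset
  } else if (params$interpolate) {
    k <- desc_idx[1]
    s0 <- speed[k - 1]; s1 <- speed[k]
    if (s0 >= thr && s1 < thr && s0 != s1) {
      time[k - 1] + (s0 - thr) / (s0 - s1) * (time[k] - time[k - 1])
    } else {
      time[k]
    }
  } else {
    time[desc_idx[1]]
  }
  ascend85 <- max(min(ascend85, peak_time), onset)
  descend85 <- min(max(descend85, peak_time), offset)
  list(ascend85 = ascend85, descend85 = descend85)
}

#' Bin a trial into its reach phase
#'
#' Hardware-triggered trials keep their provenance labels (`target`,
#' `post_reach`). Time-scheduled trials are labelled by when the test force
#' fell relative to the movement landmarks: `early` in `[onset, ascend85)`,
#' `mid` in `[ascend85, descend85)`, `late` in `[descend85, offset)`. A test
#' force before onset or at/after the offset is invalid (exclusion criterion
#' `e`); missing landmarks are invalid under criterion `b`.
#'
#' @param scheduled_type Trial provenance
#'   (`t250`/`t370`/`t550`/`target`/`post_reach`).
#' @param test_time Test-force time (ms after go-cue).
#' @param onset,ascend85,descend85,offset Movement landmarks (ms).
#' @return List with `phase_label` and `invalid_reason` (`NA` if valid).
#' @export
bin_trial <- function(scheduled_type, test_time, onset, ascend85, descend85,
                      offset) {
  if (scheduled_type %in% c("target", "post_reach")) {
    if (!is.finite(offset)) {
      return(list(phase_label = "invalid", invalid_reason = "b"))
    }
    return(list(phase_label = scheduled_type, invalid_reason = NA_character_))
  }
  if (!all(is.finite(c(onset, ascend85, descend85, offset, test_time)))) {
    return(list(phase_label = "invalid", invalid_reason = "b"))
  }
  if (test_time < onset || test_time >= offset) {
    return(list(phase_label = "invalid", invalid_reason = "e"))
  }
  label <- if (test_time < ascend85) "early"
  else if (test_time < descend85) "mid"
  else "late"
  list(phase_label = label, invalid_reason = NA_character_)
}

#' Segment one reaching trace
#'
#' Runs the full preprocessing and segmentation chain on a `kin_trace`:
#' smoothing, 3D speed, onset/offset detection, constrained peak-velocity
#' search, 85% phase crossings, and the start-displacement and distortion
#' checks used by the exclusion filters.
#'
#' @param trace A `kin_trace`.
#' @param params A [segmentation_params()].
#' @return One-row tibble of landmarks
#'   (`onset`, `offset`, `movement_duration`, `peak_time`, `peak_speed`,
#'   `ascend85`, `descend85`, `start_displacement`, `landmarks_ok`,
#'   `distortion_overlap`).
#' @export
segment_trial <- function(trace, params = segmentation_params()) {
  tibble::as_tibble(segment_trial_core(trace, params))
}

segment_trial_core <- function(trace, params = segmentation_params()) {
  pos <- smooth_positions(trace$pos, params$smooth_span)
  speed <- compute_speed(pos, trace$time)
  onset <- detect_movement_onset(speed, trace$time, params, after = 0)
  offset <- if (is.finite(onset)) detect_reach_offset(trace, onset, params) else NA_real_
  peak_time <- peak_speed <- ascend85 <- descend85 <- NA_real_
  ok <- is.finite(onset) && is.finite(offset) && onset < offset
  if (ok) {
    pk <- find_peak_velocity(speed, trace$time, onset, offset, params)
    peak_time <- pk$peak_time
    peak_speed <- pk$peak_speed
    cr <- compute_phase_crossings(speed, trace$time, onset, offset,
                                  peak_time, peak_speed, params)
    ascend85 <- cr$ascend85
    descend85 <- cr$descend85
  }
  start_disp <- abs(trace$pos[1, 1] - (trace$start_x %||% trace$pos[1, 1]))
  distortion_overlap <- FALSE
  if (ok && any(trace$distortion)) {
    w <- trace$time >= onset - params$distortion_window[["before"]] &
      trace$time <= offset + params$distortion_window[["after"]]
    distortion_overlap <- any(trace$distortion & w)
  }
  list(onset = onset, offset = offset,
       movement_duration = offset - onset,
       peak_time = peak_time, peak_speed = peak_speed,
       ascend85 = ascend85, descend85 = descend85,
       start_displacement = start_disp,
       landmarks_ok = ok,
       distortion_overlap = distortion_overlap)
}

#' Segment every reaching trial of a cohort
#'
#' For full-kinematics cohorts, runs [segment_trial()] on every stored
#' trace; for landmark cohorts the generator's closed-form landmarks are the
#' segmentation table already and are returned as is.
#'
#' @param cohort A `cohort`.
#' @param params A [segmentation_params()].
#' @return Segmentation tibble, one row per reaching trial.
#' @export
segment_cohort <- function(cohort, params = segmentation_params()) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$traces)) return(cohort$segments_truth)
  keys <- names(cohort$traces)
  segs <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    segs[[i]] <- segment_trial_core(cohort$traces[[i]], params)
  }
  cols <- names(segs[[1]])
  out <- tibble::as_tibble(lapply(setNames(cols, cols), function(cl) {
    unlist(lapply(segs, function(s) {
      v <- s[[cl]]
      if (length(v) == 0) NA else v
    }), use.names = FALSE)
  }))
  id <- do.call(rbind, strsplit(keys, "_(?=[0-9]+$)", perl = TRUE))
  out$participant <- id[, 1]
  out$trial_id <- as.integer(id[, 2])
  dplyr::relocate(out, "participant", "trial_id")
}

#' Attach phase labels to a cohort's trials
#'
#' Joins the segmentation table to the trial table and applies
#' [bin_trial()] per reaching trial; also computes each trial's test-force
#' time as a percentage of the reach duration.
#'
#' @param trials Trial tibble.
#' @param segments Segmentation tibble from [segment_cohort()].
#' @return `trials` with `phase_label`, `invalid_reason` and `percent_time`.
#' @export
label_phases <- function(trials, segments) {
  out <- dplyr::left_join(trials, segments, by = c("participant", "trial_id"))
  n <- nrow(out)
  # vectorised application of the bin_trial() rules
  lab <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  base <- out$block != "reaching"
  lab[base] <- "baseline"
  hw <- !base & out$scheduled_type %in% c("target", "post_reach")
  hw_ok <- hw & is.finite(out$offset)
  lab[hw_ok] <- out$scheduled_type[hw_ok]
  lab[hw & !hw_ok] <- "invalid"
  reason[hw & !hw_ok] <- "b"
  sc <- !base & !hw
  fin <- sc & is.finite(out$onset) & is.finite(out$ascend85) &
    is.finite(out$descend85) & is.finite(out$offset) & is.finite(out$test_time)
  lab[sc & !fin] <- "invalid"
  reason[sc & !fin] <- "b"
  oob <- fin & (out$test_time < out$onset | out$test_time >= out$offset)
  lab[oob] <- "invalid"
  reason[oob] <- "e"
  ok <- fin & !oob
  lab[ok & out$test_time < out$ascend85] <- "early"
  lab[ok & out$test_time >= out$ascend85 & out$test_time < out$descend85] <- "mid"
  lab[ok & out$test_time >= out$descend85] <- "late"
  out$phase_label <- lab
  out$invalid_reason <- reason
  out$percent_time <- ifelse(
    out$block == "reaching" & is.finite(out$onset) & is.finite(out$offset),
    (out$test_time - out$onset) / (out$offset - out$onset) * 100, NA_real_)
  out
}
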