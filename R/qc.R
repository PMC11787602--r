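#' Trial-level exclusion criteria
#'
#' Applies the six exclusion criteria to every trial, independently (a trial
#' can carry several tags):
#' * `a` - measured test force outside the tolerance window (default
#'   1.85-2.15 N), or missing response;
#' * `b` - missing/failed kinematic landmarks (no tap or trigger, no onset);
#' * `c` - movement started before the go-cue, or the start position was
#'   displaced more than 5 cm along the reach axis;
#' * `d` - comparison force delivered before the movement offset (while
#'   moving);
#' * `e` - time-scheduled test force delivered before movement onset or
#'   after the tap;
#' * `f` - motion-tracker distortion overlapping the segmentation window.
#'
#' @param cohort A `cohort`.
#' @param segments Segmentation table from [segment_cohort()] (computed if
#'   `NULL`).
#' @param params A [segmentation_params()] (supplies the start-displacement
#'   limit and distortion window).
#' @param test_force_window Acceptance window for the measured test force (N).
#' @return List with `report` (a `qc_report`) and `trials` (labelled trial
#'   table with rejected trials removed).
#' @export
apply_trial_exclusions <- function(cohort, segments = NULL,
                                   params = segmentation_params(),
                                   test_force_window = c(1.85, 2.15)) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(segments)) segments <- segment_cohort(cohort, params)
  labeled <- label_phases(cohort$trials, segments)
  n <- nrow(labeled)
  reaching <- labeled$block == "reaching"
  has_row <- !reaching | !is.na(labeled$landmarks_ok)
  ok <- reaching & has_row & labeled$landmarks_ok %in% TRUE

  tag_a <- labeled$test_intensity_measured < test_force_window[1] |
    labeled$test_intensity_measured > test_force_window[2] |
    is.na(labeled$response)
  tag_b <- reaching & (!has_row | !(labeled$landmarks_ok %in% TRUE))
  tag_c <- ok & (labeled$onset < 0 |
                   labeled$start_displacement > params$start_displacement_limit)
  tag_d <- ok & !is.na(labeled$comparison_time) &
    labeled$comparison_time < labeled$offset
  tag_e <- reaching & labeled$invalid_reason %in% "e"
  tag_f <- ok & labeled$distortion_overlap %in% TRUE

  tags <- cbind(a = tag_a, b = tag_b, c = tag_c, d = tag_d, e = tag_e, f = tag_f)
  tags[is.na(tags)] <- FALSE
  rejected <- rowSums(tags) > 0
  tag_str <- apply(tags, 1, function(r) paste(colnames(tags)[r], collapse = ","))

  decisions <- tibble::tibble(
    participant = labeled$participant,
    trial_id = labeled$trial_id,
    block = labeled$block,
    phase_label = labeled$phase_label,
    rejected = rejected,
    tags = ifelse(rejected, tag_str, NA_character_)
  )
  kept <- labeled[!rejected, , drop = FALSE]
  retained_by_type <- table(kept$phase_label[kept$block == "reaching"])
  report <- structure(list(
    decisions = decisions,
    n_total = n,
    n_rejected = sum(rejected),
    rejection_fraction = sum(rejected) / n,
    rejected_by_tag = colSums(tags),
    retained_by_type = retained_by_type
  ), class = "qc_report")
  list(report = report, trials = kept)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> rejected %d / %d trials (%.1f%%)\n",
              x$n_rejected, x$n_total, 100 * x$rejection_fraction))
  cat("  by tag:", paste(sprintf("%s=%d", names(x$rejected_by_tag),
                                 x$rejected_by_tag), collapse = " "), "\n")
  invisible(x)
}

#' Participant-level exclusions
#'
#' Drops a participant if any reaching-trial phase has fewer than
#' `min_trials` retained trials, or if at least `same_response_threshold` of
#' the responses in any trial type are identical (an unreliable psychometric
#' fit), or if the participant has no kinematic data at all.
#'
#' @param trials Labelled, trial-QC-filtered trial table (from
#'   [apply_trial_exclusions()]).
#' @param min_trials Minimum retained trials per reaching phase.
#' @param same_response_threshold Proportion of identical responses at or
#'   above which a trial type is considered degenerate.
#' @return List with `trials` (retained participants only) and `excluded`
#'   (tibble of `participant`, `reason`).
#' @export
apply_participant_exclusions <- function(trials, min_trials = 10,
                                         same_response_threshold = 0.95) {
  phases <- c("early", "mid", "late", "target", "post_reach")
  excluded <- list()
  for (pid in unique(trials$participant)) {
    tp <- trials[trials$participant == pid, ]
    reach <- tp[tp$block == "reaching", ]
    if (nrow(reach) == 0 || all(is.na(reach$onset))) {
      excluded[[pid]] <- "missing_kinematics"
      next
    }
    counts <- table(factor(reach$phase_label, levels = phases))
    if (any(counts < min_trials)) {
      excluded[[pid]] <- sprintf("too_few_%s_trials",
                                 names(counts)[which.min(counts)])
      next
    }
    degen <- FALSE
    for (ph in c(phases, "baseline")) {
      resp <- tp$response[tp$phase_label == ph]
      resp <- resp[!is.na(resp)]
      if (length(resp) > 0 &&
          max(table(resp)) / length(resp) >= same_response_threshold) {
        degen <- TRUE
        excluded[[pid]] <- sprintf("same_response_%s", ph)
        break
      }
    }
  }
  excl <- if (length(excluded)) {
    tibble::tibble(participant = names(excluded),
                   reason = unlist(excluded, use.names = FALSE))
  } else {
    tibble::tibble(participant = character(), reason = character())
  }
  list(trials = trials[!trials$participant %in% excl$participant, ],
       excluded = excl)
}
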