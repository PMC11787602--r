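#' Inject controlled artifacts into a cohort
#'
#' Corrupts a fraction of trials so that exactly one named exclusion
#' criterion fires per corrupted trial, and returns the ground-truth ledger.
#' Used to validate the quality-control filters by round-trip: on an
#' otherwise clean (noise-free) cohort the QC rejection set must equal the
#' ledger tag-for-tag.
#'
#' Criterion-specific alterations:
#' * `a` - measured test force set to 1.7 N (outside the 1.85-2.15 N window);
#' * `b` - the tap-force pulse is erased (or the distance trigger dropped),
#'   so no movement offset can be found;
#' * `c` - the whole trajectory is displaced 10 cm toward the target, so the
#'   start position violates the 5 cm start-displacement limit;
#' * `d` - the comparison force is rescheduled to 50 ms before the movement
#'   offset ("while moving");
#' * `e` - the scheduled test force is moved to 50 ms before movement onset
#'   (only `t250`/`t370`/`t550` trials are eligible);
#' * `f` - distortion flags are raised around the time of peak velocity.
#'
#' @param cohort A [simulate_cohort()] result (either kinematic mode).
#' @param rates Named numeric vector of corruption rates in `[0, 1]`; names
#'   drawn from `a`-`f`.
#' @param seed Optional seed for trial selection.
#' @return The cohort with a `ledger` tibble (`participant`, `trial_id`,
#'   `criterion`) attached; corrupted trials also carry the criterion in
#'   `trials$corruption`.
#' @export
inject_artifacts <- function(cohort, rates, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  known <- c("a", "b", "c", "d", "e", "f")
  if (length(rates) == 0) {
    cohort$ledger <- tibble::tibble(participant = character(),
                                    trial_id = integer(),
                                    criterion = character())
    return(cohort)
  }
  assert_that(!is.null(names(rates)) && all(names(rates) %in% known),
              "unknown criterion name in rates (use a-f)")
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")

  trials <- cohort$trials
  truth <- cohort$segments_truth
  full <- !is.null(cohort$traces)
  key <- paste(trials$participant, trials$trial_id, sep = "_")
  reaching <- trials$block == "reaching"
  scheduled <- trials$scheduled_type %in% c("t250", "t370", "t550")
  taken <- rep(FALSE, nrow(trials))
  ledger <- list()

  with_seed(seed, {
    for (crit in intersect(known, names(rates))) {
      rate <- rates[[crit]]
      if (rate <= 0) next
      eligible <- which(!taken & (if (crit == "a") rep(TRUE, nrow(trials))
                                  else if (crit == "e") scheduled
                                  else reaching))
      pick <- eligible[runif(length(eligible)) < rate]
      if (length(pick) == 0) next
      taken[pick] <- TRUE
      trials$corruption[pick] <- crit
      tkey <- key[pick]
      trow <- match(paste(trials$participant[pick], trials$trial_id[pick], sep = "_"),
                    paste(truth$participant, truth$trial_id, sep = "_"))
      if (crit == "a") {
        trials$test_intensity_measured[pick] <- 1.7
      } else if (crit == "b") {
        if (full) {
          for (k in tkey) {
            tr <- cohort$traces[[k]]
            tr$tap_force[] <- 0
            tr$distance_trigger_time <- NA_real_
            cohort$traces[[k]] <- tr
          }
        }
        truth$offset[trow] <- NA_real_
        truth$landmarks_ok[trow] <- FALSE
      } else if (crit == "c") {
        if (full) {
          for (k in tkey) {
            tr <- cohort$traces[[k]]
            tr$pos[, 1] <- tr$pos[, 1] + 10
            cohort$traces[[k]] <- tr
          }
        }
        truth$start_displacement[trow] <- 10
      } else if (crit == "d") {
        trials$comparison_time[pick] <- truth$offset[trow] - 50
      } else if (crit == "e") {
        trials$test_time[pick] <- truth$onset[trow] - 50
        trials$comparison_time[pick] <- trials$test_time[pick] +
          cohort$design$comparison_delay
        if (full) {
          for (j in seq_along(pick)) {
            tr <- cohort$traces[[tkey[j]]]
            tr$events["test_force"] <- trials$test_time[pick[j]]
            tr$events["comparison_force"] <- trials$comparison_time[pick[j]]
            cohort$traces[[tkey[j]]] <- tr
          }
        }
      } else if (crit == "f") {
        if (full) {
          for (j in seq_along(pick)) {
            tr <- cohort$traces[[tkey[j]]]
            win <- abs(tr$time - truth$peak_time[trow[j]]) <= 20
            tr$distortion[win] <- TRUE
            cohort$traces[[tkey[j]]] <- tr
          }
        }
        truth$distortion_overlap[trow] <- TRUE
      }
      ledger[[crit]] <- tibble::tibble(participant = trials$participant[pick],
                                       trial_id = trials$trial_id[pick],
                                       criterion = crit)
    }
  })

  cohort$trials <- trials
  cohort$segments_truth <- truth
  cohort$ledger <- if (length(ledger)) {
    led <- dplyr::bind_rows(ledger)
    led[order(led$participant, led$trial_id), ]
  } else {
    tibble::tibble(participant = character(), trial_id = integer(),
                   criterion = character())
  }
  cohort
}
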