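# On-disk cohort dialect: trials.csv + segments.csv + manifest.json
# (+ optional traces.csv in long format). All plain text.

#' Write a cohort to a directory
#'
#' Serializes the trial table, the segmentation/landmark table, a JSON
#' manifest (seed, design, generation mode, corruption ledger) and,
#' optionally, the full kinematic traces in long format.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @param include_traces Also write `traces.csv` (large; full-kinematics
#'   cohorts only).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, include_traces = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$trials, file.path(dir, "trials.csv"), progress = FALSE)
  readr::write_csv(cohort$segments_truth, file.path(dir, "segments.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"),
                   progress = FALSE)
  manifest <- c(cohort$manifest,
                list(design = unclass(cohort$design),
                     schema_version = "1",
                     ledger = if (!is.null(cohort$ledger)) cohort$ledger))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (include_traces && !is.null(cohort$traces)) {
    long <- lapply(names(cohort$traces), function(k) {
      tr <- cohort$traces[[k]]
      tibble::tibble(key = k, time = tr$time,
                     x = tr$pos[, 1], y = tr$pos[, 2], z = tr$pos[, 3],
                     tap_force = tr$tap_force,
                     distortion = tr$distortion)
    })
    readr::write_csv(dplyr::bind_rows(long), file.path(dir, "traces.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory containing `trials.csv`, `segments.csv`,
#'   `manifest.json`.
#' @return A `cohort` (landmark representation; traces are not
#'   round-tripped).
#' @export
read_cohort <- function(dir) {
  trials <- readr::read_csv(file.path(dir, "trials.csv"),
                            show_col_types = FALSE, progress = FALSE)
  segments <- readr::read_csv(file.path(dir, "segments.csv"),
                              show_col_types = FALSE, progress = FALSE)
  participants <- if (file.exists(file.path(dir, "participants.csv"))) {
    readr::read_csv(file.path(dir, "participants.csv"),
                    show_col_types = FALSE, progress = FALSE)
  }
  if ("corruption" %in% names(trials)) {
    trials$corruption <- as.character(trials$corruption)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  design <- do.call(design_config, manifest$design[
    setdiff(names(manifest$design), "reaching_types")])
  structure(list(trials = tibble::as_tibble(trials),
                 participants = participants,
                 segments_truth = tibble::as_tibble(segments),
                 traces = NULL,
                 design = design,
                 manifest = manifest[setdiff(names(manifest), "design")]),
            class = "cohort")
}

trial_schema <- function() {
  list(
    participant = "character", trial_id = "numeric", block = "character",
    scheduled_type = "character",
    test_intensity_commanded = "numeric", test_intensity_measured = "numeric",
    comparison_intensity_commanded = "numeric",
    comparison_intensity_measured = "numeric",
    test_time = "numeric", comparison_time = "numeric", response = "character"
  )
}

#' Ingest an externally supplied trial table
#'
#' Reads a trial CSV in the documented dialect, validates it row by row
#' (reporting line numbers for violations and loading the remaining rows),
#' and assembles a cohort. If a segmentation table is supplied the kinematic
#' stages can be skipped; if the trial table already carries `phase_label`
#' the pipeline can resume directly at the psychometric stage.
#'
#' @param trials_file Path to the trial CSV.
#' @param segments_file Optional path to a segmentation CSV.
#' @param design A [design_config()] describing the schedule.
#' @param schema_version Dialect version (only `"1"` is defined).
#' @return List with `cohort` and `errors` (tibble `line`, `message`).
#' @export
ingest_external <- function(trials_file, segments_file = NULL,
                            design = design_config(), schema_version = "1") {
  assert_that(identical(schema_version, "1"), "unknown schema version")
  raw <- readr::read_csv(trials_file, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  schema <- trial_schema()
  missing_cols <- setdiff(names(schema), names(raw))
  assert_that(length(missing_cols) == 0, "missing required columns: %s",
              paste(missing_cols, collapse = ", "))
  errors <- list()
  note <- function(line, msg) {
    errors[[length(errors) + 1]] <<- tibble::tibble(line = line, message = msg)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    participant = raw$participant,
    trial_id = num_or_na(raw$trial_id),
    block = raw$block,
    scheduled_type = raw$scheduled_type,
    test_intensity_commanded = num_or_na(raw$test_intensity_commanded),
    test_intensity_measured = num_or_na(raw$test_intensity_measured),
    comparison_intensity_commanded = num_or_na(raw$comparison_intensity_commanded),
    comparison_intensity_measured = num_or_na(raw$comparison_intensity_measured),
    test_time = num_or_na(raw$test_time),
    comparison_time = num_or_na(raw$comparison_time),
    response = raw$response
  )
  if ("phase_label" %in% names(raw)) out$phase_label <- raw$phase_label
  bad <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    line <- i + 1L # header is line 1
    if (!out$block[i] %in% c("reaching", "baseline")) {
      note(line, sprintf("invalid block '%s'", out$block[i]))
      bad[i] <- TRUE
    }
    if (!out$scheduled_type[i] %in% c("t250", "t370", "t550", "target",
                                      "post_reach", "baseline")) {
      note(line, sprintf("invalid scheduled_type '%s'", out$scheduled_type[i]))
      bad[i] <- TRUE
    }
    if (is.na(out$comparison_intensity_measured[i]) ||
        out$comparison_intensity_measured[i] <= 0) {
      note(line, "malformed comparison intensity")
      bad[i] <- TRUE
    }
    if (!is.na(out$response[i]) &&
        !out$response[i] %in% c("comparison_stronger", "test_stronger")) {
      note(line, sprintf("invalid response '%s'", out$response[i]))
      bad[i] <- TRUE
    }
  }
  out$corruption <- NA_character_
  segments <- if (!is.null(segments_file)) {
    tibble::as_tibble(readr::read_csv(segments_file, show_col_types = FALSE,
                                      progress = FALSE))
  } else {
    tibble::tibble(participant = character(), trial_id = numeric(),
                   onset = numeric(), offset = numeric(),
                   movement_duration = numeric(), peak_time = numeric(),
                   peak_speed = numeric(), ascend85 = numeric(),
                   descend85 = numeric(), start_displacement = numeric(),
                   landmarks_ok = logical(), distortion_overlap = logical())
  }
  cohort <- structure(list(trials = out[!bad, ],
                           participants = NULL,
                           segments_truth = segments,
                           traces = NULL,
                           design = design,
                           manifest = list(source = trials_file,
                                           schema_version = schema_version,
                                           kinematics = "external")),
                      class = "cohort")
  list(cohort = cohort,
       errors = if (length(errors)) dplyr::bind_rows(errors)
       else tibble::tibble(line = integer(), message = character()))
}
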