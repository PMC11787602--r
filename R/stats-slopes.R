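#' Per-participant mean test-force times as % of reach duration
#'
#' For each participant and each binned phase (`early`, `mid`, `late`), the
#' mean of `(test_time - onset) / (offset - onset) * 100` over retained
#' trials. Target trials are pinned at 100% (the predicted self-touch
#' moment); post-reach trials have no within-reach percent.
#'
#' @param trials Labelled, QC-filtered trial table (with `percent_time`).
#' @return Tibble `participant`, `trial_type`, `percent`.
#' @export
phase_percent_times <- function(trials) {
  phases <- c("early", "mid", "late")
  sub <- trials[trials$phase_label %in% phases & is.finite(trials$percent_time), ]
  agg <- stats::aggregate(percent_time ~ participant + phase_label, data = sub,
                          FUN = mean)
  out <- tibble::tibble(participant = agg$participant,
                        trial_type = agg$phase_label,
                        percent = agg$percent_time)
  pins <- expand.grid(participant = unique(trials$participant),
                      trial_type = c("target", "post_reach"),
                      stringsAsFactors = FALSE)
  pins$percent <- ifelse(pins$trial_type == "target", 100, NA_real_)
  dplyr::bind_rows(out, tibble::as_tibble(pins))
}

#' Normalize reaching PSEs to the baseline PSE
#'
#' Subtracts each participant's baseline PSE from their PSE in every
#' reaching trial type, and attaches the per-participant mean percent-time
#' of test-force delivery (the x-axis of the slope analysis). Participants
#' missing the baseline fit or any reaching cell are dropped and listed in
#' the `dropped` attribute.
#'
#' @param fits Fits table from [fit_cohort_psychometrics()].
#' @param percent_times Optional [phase_percent_times()] output.
#' @param group Optional group label for the cohort (recycled), or a tibble
#'   `participant`, `group`.
#' @return Long tibble `participant`, `trial_type`, `pse_norm`, `percent`
#'   (and `group`), complete rows only.
#' @export
normalize_pses <- function(fits, percent_times = NULL, group = NULL) {
  types <- c("early", "mid", "late", "target", "post_reach")
  ok_fit <- fits[fits$valid %in% TRUE, ]
  base <- ok_fit[as.character(ok_fit$trial_type) == "baseline",
                 c("participant", "pse")]
  names(base)[2] <- "pse_baseline"
  reach <- ok_fit[as.character(ok_fit$trial_type) %in% types, ]
  out <- dplyr::left_join(reach, base, by = "participant")
  dropped_base <- unique(out$participant[is.na(out$pse_baseline)])
  out <- out[!is.na(out$pse_baseline), ]
  out$pse_norm <- out$pse - out$pse_baseline
  counts <- table(out$participant)
  incomplete <- names(counts)[counts < length(types)]
  out <- out[!out$participant %in% incomplete, ]
  res <- tibble::tibble(participant = out$participant,
                        trial_type = factor(as.character(out$trial_type),
                                            levels = types),
                        pse_norm = out$pse_norm)
  if (!is.null(percent_times)) {
    res <- dplyr::left_join(res,
                            dplyr::mutate(percent_times,
                                          trial_type = factor(trial_type,
                                                              levels = types)),
                            by = c("participant", "trial_type"))
  }
  if (!is.null(group)) {
    if (is.data.frame(group)) {
      res <- dplyr::left_join(res, group, by = "participant")
    } else {
      res$group <- group
    }
  }
  attr(res, "dropped") <- unique(c(dropped_base, incomplete))
  res
}

#' Per-participant linear attenuation slopes
#'
#' Fits an ordinary least-squares line to each participant's normalized
#' PSEs against the percent of reach duration at which the test force was
#' delivered, over either the full reach (`early`-`target`, target pinned
#' at 100%) or the within-reach span (`early`-`late`). The group of slopes
#' is tested against zero through the normality-gated one-sample path, and
#' contrasted between groups (when two are present) through the
#' normality-gated independent path.
#'
#' @param norm Normalized-PSE table with `percent` (see [normalize_pses()]).
#' @param span `"early_target"` or `"early_late"`.
#' @param alpha_normality Normality-gate level.
#' @return List with `slopes` (tibble `participant`, `slope`, `group`),
#'   `group_tests` (one gated test vs 0 per group), `between_test`
#'   (`NULL` for one group), `span`, and `dropped`.
#' @export
fit_participant_slopes <- function(norm, span = c("early_target", "early_late"),
                                   alpha_normality = 0.05) {
  span <- match.arg(span)
  types <- if (span == "early_target") c("early", "mid", "late", "target")
  else c("early", "mid", "late")
  sub <- norm[as.character(norm$trial_type) %in% types &
                is.finite(norm$percent) & is.finite(norm$pse_norm), ]
  has_group <- "group" %in% names(sub)
  dropped <- character()
  rows <- lapply(split(sub, sub$participant), function(g) {
    if (nrow(g) < 3) {
      dropped <<- c(dropped, g$participant[1])
      return(NULL)
    }
    slope <- unname(coef(lm(pse_norm ~ percent, data = g))[2])
    tibble::tibble(participant = g$participant[1], slope = slope,
                   group = if (has_group) as.character(g$group[1]) else "all")
  })
  slopes <- dplyr::bind_rows(rows)
  assert_that(nrow(slopes) >= 3, "fewer than three participants with slopes")
  group_tests <- lapply(split(slopes$slope, slopes$group), function(s) {
    gated_one_sample_test(s, mu = 0, alpha_normality = alpha_normality)
  })
  groups <- names(group_tests)
  between <- NULL
  if (length(groups) == 2) {
    between <- gated_independent_test(
      slopes$slope[slopes$group == groups[1]],
      slopes$slope[slopes$group == groups[2]], alpha_normality)
    between$pair <- sprintf("slope:%s_vs_%s", groups[1], groups[2])
  }
  list(slopes = slopes, group_tests = group_tests, between_test = between,
       span = span, dropped = dropped)
}
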