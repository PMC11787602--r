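#' Build a participant's trial schedule
#'
#' Expands the design into trial stubs: every comparison intensity appears
#' `reps_per_reaching_type` times in each of the five reaching trial types
#' (randomly interleaved, equal probability) and `reps_baseline` times in a
#' separate baseline block.
#'
#' @param design A [design_config()].
#' @param seed Integer seed for the reaching-block permutation.
#' @return A tibble of trial stubs with `trial_id`, `block`,
#'   `scheduled_type`, and commanded intensities.
#' @export
#' @examples
#' nrow(make_trial_schedule(design_config(), seed = 1)) # 616
make_trial_schedule <- function(design, seed = NULL) {
  assert_that(inherits(design, "design_config"), "design must be a design_config")
  reaching <- expand.grid(
    comparison_intensity_commanded = design$comparison_intensities,
    rep = seq_len(design$reps_per_reaching_type),
    scheduled_type = design$reaching_types,
    stringsAsFactors = FALSE
  )
  baseline <- expand.grid(
    comparison_intensity_commanded = design$comparison_intensities,
    rep = seq_len(design$reps_baseline),
    stringsAsFactors = FALSE
  )
  perm <- with_seed(seed, {
    list(reaching = sample.int(nrow(reaching)),
         baseline = sample.int(nrow(baseline)))
  })
  reaching <- reaching[perm$reaching, , drop = FALSE]
  baseline <- baseline[perm$baseline, , drop = FALSE]
  tibble::tibble(
    trial_id = seq_len(nrow(reaching) + nrow(baseline)),
    block = c(rep("reaching", nrow(reaching)), rep("baseline", nrow(baseline))),
    scheduled_type = c(reaching$scheduled_type, rep("baseline", nrow(baseline))),
    test_intensity_commanded = design$test_force,
    comparison_intensity_commanded = c(reaching$comparison_intensity_commanded,
                                       baseline$comparison_intensity_commanded)
  )
}
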