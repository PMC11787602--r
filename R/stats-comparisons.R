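# Normality-gated pairwise tests with matched effect sizes.
#
# Each contrast is tested parametrically (t) when the Shapiro-Wilk test does
# not reject normality of the paired differences (or of both groups), and
# with the matching rank test otherwise. Effect sizes follow the test
# family: Cohen's d for t-tests, rank-biserial correlation for Wilcoxon
# tests; 95% CIs are the standard t interval or the Hodges-Lehmann interval.

shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(0) # degenerate -> rank path
  shapiro.test(x)$p.value
}

#' Normality-gated one-sample / paired comparison
#'
#' Tests whether `x` (typically a vector of paired differences or
#' per-participant coefficients) differs from `mu`. Shapiro-Wilk at
#' `alpha_normality` selects a one-sample t-test or a Wilcoxon signed-rank
#' test. The rank-biserial correlation is `2V/S - 1` with `S = n'(n'+1)/2`
#' over the non-zero observations.
#'
#' @param x Numeric vector.
#' @param mu Null value.
#' @param alpha_normality Normality-gate level.
#' @return One-row tibble: `test_used`, `statistic`, `df`, `p_raw`,
#'   `ci_lo`, `ci_hi`, `effect_size_type`, `effect_size`, `n`.
#' @export
gated_one_sample_test <- function(x, mu = 0, alpha_normality = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  assert_that(n >= 3, "need at least three observations")
  d <- x - mu
  if (all(d == 0)) {
    return(tibble::tibble(test_used = "wilcoxon_signed_rank",
                          statistic = NA_real_, df = NA_real_, p_raw = 1,
                          ci_lo = mu, ci_hi = mu,
                          effect_size_type = "rank_biserial", effect_size = 0,
                          n = n))
  }
  if (shapiro_p(d) >= alpha_normality) {
    tt <- t.test(x, mu = mu)
    tibble::tibble(test_used = "paired_t",
                   statistic = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                   effect_size_type = "cohens_d",
                   effect_size = mean(d) / stats::sd(d), n = n)
  } else {
    wt <- suppressWarnings(wilcox.test(d, conf.int = TRUE))
    dn <- d[d != 0]
    S <- length(dn) * (length(dn) + 1) / 2
    tibble::tibble(test_used = "wilcoxon_signed_rank",
                   statistic = unname(wt$statistic), df = NA_real_,
                   p_raw = wt$p.value,
                   ci_lo = wt$conf.int[1] + mu, ci_hi = wt$conf.int[2] + mu,
                   effect_size_type = "rank_biserial",
                   effect_size = 2 * unname(wt$statistic) / S - 1, n = n)
  }
}

#' Normality-gated independent-samples comparison
#'
#' Welch t-test when both groups pass the Shapiro-Wilk gate, Wilcoxon
#' rank-sum otherwise. Cohen's d uses the pooled SD; the rank-biserial
#' correlation is `2U/(n1 n2) - 1`.
#'
#' @param x,y Numeric vectors (group 1, group 2); the difference reported is
#'   `x - y`.
#' @param alpha_normality Normality-gate level.
#' @return One-row tibble as in [gated_one_sample_test()], plus `n2`.
#' @export
gated_independent_test <- function(x, y, alpha_normality = 0.05) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  assert_that(n1 >= 3 && n2 >= 3, "need at least three observations per group")
  if (min(shapiro_p(x), shapiro_p(y)) >= alpha_normality) {
    tt <- t.test(x, y, var.equal = FALSE)
    sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
    tibble::tibble(test_used = "welch_t",
                   statistic = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                   effect_size_type = "cohens_d",
                   effect_size = (mean(x) - mean(y)) / sp, n = n1, n2 = n2)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE))
    tibble::tibble(test_used = "rank_sum",
                   statistic = unname(wt$statistic), df = NA_real_,
                   p_raw = wt$p.value,
                   ci_lo = wt$conf.int[1], ci_hi = wt$conf.int[2],
                   effect_size_type = "rank_biserial",
                   effect_size = 2 * unname(wt$statistic) / (n1 * n2) - 1,
                   n = n1, n2 = n2)
  }
}

#' Default within-subject comparison plan
#'
#' The seven hypothesis-driven pairs: serial time dependence during reaching
#' and recovery afterwards.
#' @return List of type pairs; each comparison is `first - second`.
#' @export
default_within_plan <- function() {
  list(c("early", "mid"), c("early", "late"), c("early", "target"),
       c("mid", "late"), c("mid", "target"), c("late", "target"),
       c("target", "post_reach"))
}

#' Planned within-subject comparisons with FDR correction
#'
#' Runs the normality-gated paired path for every pair in the plan and
#' applies Benjamini-Hochberg FDR across the plan.
#'
#' @param norm A normalized-PSE table ([normalize_pses()]) or any long tibble
#'   with `participant`, `trial_type`, and the column named in `dv`.
#' @param plan List of type pairs (default [default_within_plan()]).
#' @param dv Response column.
#' @param alpha_normality Normality-gate level.
#' @return Comparison tibble with `pair`, the gated-test columns, and
#'   `p_fdr`.
#' @export
planned_comparisons <- function(norm, plan = default_within_plan(),
                                dv = "pse_norm", alpha_normality = 0.05) {
  wide <- tapply(norm[[dv]], list(norm$participant, as.character(norm$trial_type)),
                 mean)
  rows <- lapply(plan, function(pr) {
    keep <- stats::complete.cases(wide[, pr])
    assert_that(sum(keep) >= 3, "fewer than three complete pairs for %s-%s",
                pr[1], pr[2])
    d <- wide[keep, pr[1]] - wide[keep, pr[2]]
    out <- gated_one_sample_test(d, mu = 0, alpha_normality = alpha_normality)
    out$pair <- paste(pr, collapse = "_vs_")
    out
  })
  out <- dplyr::relocate(dplyr::bind_rows(rows), "pair")
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out
}

#' Between-group planned contrasts with FDR correction
#'
#' One normality-gated independent comparison per trial type
#' (group 1 minus group 2), FDR-corrected across types.
#'
#' @param norm Normalized-PSE table with a `group` column (two levels).
#' @param types Trial types to contrast.
#' @param dv Response column.
#' @param alpha_normality Normality-gate level.
#' @return Comparison tibble with `pair` (`<type>:<g1>_vs_<g2>`) and `p_fdr`.
#' @export
between_group_comparisons <- function(norm,
                                      types = c("early", "mid", "late",
                                                "target", "post_reach"),
                                      dv = "pse_norm", alpha_normality = 0.05) {
  groups <- unique(as.character(norm$group))
  assert_that(length(groups) == 2, "exactly two groups are required")
  rows <- lapply(types, function(tt) {
    sub <- norm[as.character(norm$trial_type) == tt, ]
    x <- sub[[dv]][sub$group == groups[1]]
    y <- sub[[dv]][sub$group == groups[2]]
    out <- gated_independent_test(x, y, alpha_normality)
    out$pair <- sprintf("%s:%s_vs_%s", tt, groups[1], groups[2])
    out
  })
  out <- dplyr::relocate(dplyr::bind_rows(rows), "pair")
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out
}
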