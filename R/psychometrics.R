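#' Rebin measured comparison forces to the canonical ladder
#'
#' Maps each measured comparison intensity to the nearest canonical value;
#' exact midpoints break upward.
#'
#' @param x Measured intensities (N).
#' @param canonical Canonical intensity set (strictly increasing).
#' @return Canonical intensities, same length as `x`.
#' @export
#' @examples
#' rebin_comparison(c(1.9, 1.625), c(1, 1.5, 1.75, 2, 2.25, 2.5, 3)) # 2, 1.75
rebin_comparison <- function(x, canonical = c(1, 1.5, 1.75, 2, 2.25, 2.5, 3)) {
  assert_that(length(canonical) >= 1, "canonical set must be non-empty")
  canonical <- sort(canonical)
  if (length(canonical) == 1) return(rep(canonical, length(x)))
  mids <- canonical[-length(canonical)] + diff(canonical) / 2
  # findInterval(x, mids) counts midpoints <= x, so exact midpoints round up
  canonical[findInterval(x, mids) + 1L]
}

#' Tabulate responses per comparison intensity
#'
#' @param comparison Measured comparison intensities (rebinned internally).
#' @param response Response vector (`"comparison_stronger"` /
#'   `"test_stronger"`).
#' @param canonical Canonical intensity ladder.
#' @return Tibble with `intensity`, `n_trials`, `n_comparison_stronger`.
#' @export
response_table <- function(comparison, response,
                           canonical = c(1, 1.5, 1.75, 2, 2.25, 2.5, 3)) {
  keep <- !is.na(response)
  x <- rebin_comparison(comparison[keep], canonical)
  resp <- response[keep] == "comparison_stronger"
  idx <- match(x, sort(canonical))
  k <- length(canonical)
  tibble::new_tibble(list(
    intensity = sort(canonical),
    n_trials = tabulate(idx, k),
    n_comparison_stronger = tabulate(idx[resp], k)
  ), nrow = k)
}

#' Derive PSE and JND from logistic coefficients
#'
#' For the two-parameter logistic psychometric function
#' `p = plogis(b0 + b1 x)`: the point of subjective equality is
#' `PSE = -b0 / b1` (p = 0.5) and the just-noticeable difference is
#' `JND = log(3) / b1` (distance from p = 0.5 to p = 0.75).
#'
#' @param beta0,beta1 Intercept and slope (per N); `beta1` must be non-zero.
#' @return List with `pse` and `jnd`.
#' @export
#' @examples
#' derive_pse_jnd(-4, 2) # pse 2, jnd log(3)/2
derive_pse_jnd <- function(beta0, beta1) {
  assert_that(all(beta1 != 0), "beta1 must be non-zero")
  list(pse = -beta0 / beta1, jnd = log(3) / beta1)
}

#' McFadden's pseudo-R2 for a binomial logistic fit
#'
#' `1 - LL(model) / LL(intercept-only)`, computed on grouped Bernoulli
#' counts.
#'
#' @param table A [response_table()].
#' @param beta0,beta1 Fitted coefficients.
#' @return McFadden pseudo-R2 in `[0, 1]`.
#' @export
mcfadden_r2 <- function(table, beta0, beta1) {
  tab <- table[table$n_trials > 0, ]
  k <- tab$n_comparison_stronger
  n <- tab$n_trials
  eps <- 1e-12
  p_model <- pmin(pmax(plogis(beta0 + beta1 * tab$intensity), eps), 1 - eps)
  p0 <- sum(k) / sum(n)
  assert_that(p0 > 0 && p0 < 1,
              "intercept-only likelihood degenerate (all responses identical)")
  ll <- function(p) sum(k * log(p) + (n - k) * log(1 - p))
  1 - ll(p_model) / ll(rep(p0, nrow(tab)))
}

# Bernoulli log-likelihood of grouped data under (b0, b1)
psy_loglik <- function(beta0, beta1, table) {
  tab <- table[table$n_trials > 0, ]
  eps <- 1e-12
  p <- pmin(pmax(plogis(beta0 + beta1 * tab$intensity), eps), 1 - eps)
  sum(tab$n_comparison_stronger * log(p) +
        (tab$n_trials - tab$n_comparison_stronger) * log(1 - p))
}

#' Fit the logistic psychometric function
#'
#' Maximum-likelihood Bernoulli-logistic fit of
#' `P(comparison stronger | intensity)` on a grouped response table, via
#' [stats::glm()]. Under (quasi-)complete separation or non-convergence the
#' fit is repeated with a weak ridge penalty (1e-6 on both coefficients) and
#' flagged `converged = FALSE`; degenerate tables (fewer than two informative
#' intensities, or all responses identical) are flagged rather than silently
#' fitted.
#'
#' @param table A [response_table()].
#' @return A `psych_fit`: tibble row with `beta0`, `beta1`, `pse`, `jnd`,
#'   `mcfadden_r2`, `n_trials`, `converged`, `valid`.
#' @export
fit_psychometric <- function(table) {
  tibble::as_tibble(fit_psychometric_core(table))
}

fit_psychometric_core <- function(table) {
  tab <- table[table$n_trials > 0, ]
  n_tot <- sum(tab$n_trials)
  k_tot <- sum(tab$n_comparison_stronger)
  degenerate <- nrow(tab) < 2 || k_tot == 0 || k_tot == n_tot
  beta0 <- beta1 <- pse <- jnd <- r2 <- NA_real_
  converged <- FALSE
  if (!degenerate) {
    fit <- suppressWarnings(stats::glm.fit(
      x = cbind(1, tab$intensity), y = tab$n_comparison_stronger / tab$n_trials,
      weights = tab$n_trials, family = binomial(),
      control = list(epsilon = 1e-8, maxit = 100)))
    beta0 <- unname(fit$coefficients[1])
    beta1 <- unname(fit$coefficients[2])
    separated <- any(fit$fitted.values > 1 - 1e-8) &&
      any(fit$fitted.values < 1e-8) && abs(beta1) > 50
    converged <- isTRUE(fit$converged) && !separated && is.finite(beta1)
    if (!converged) {
      # ridge-penalised refit keeps the estimate finite; flag propagates to QC
      pen <- function(b) -psy_loglik(b[1], b[2], tab) + 1e-6 * sum(b^2)
      opt <- optim(c(0, 1), pen, method = "BFGS")
      beta0 <- opt$par[1]
      beta1 <- opt$par[2]
    }
    if (is.finite(beta1) && beta1 != 0) {
      pj <- derive_pse_jnd(beta0, beta1)
      pse <- pj$pse
      jnd <- pj$jnd
      r2 <- mcfadden_r2(table, beta0, beta1)
    } else if (is.finite(beta1)) {
      # exactly slope-free data: the model collapses to intercept-only
      # (McFadden R2 = 0) and the PSE is undefined
      r2 <- mcfadden_r2(table, beta0, 0)
    }
  }
  list(beta0 = beta0, beta1 = beta1, pse = pse, jnd = jnd,
       mcfadden_r2 = r2, n_trials = n_tot,
       converged = converged, valid = !degenerate && is.finite(pse))
}

#' Fit psychometric functions for every participant and trial type
#'
#' @param trials Labelled, QC-filtered trial table (needs `participant`,
#'   `phase_label`, `comparison_intensity_measured`, `response`).
#' @param canonical Canonical comparison ladder.
#' @return Fits tibble: one row per participant x trial type with the
#'   [fit_psychometric()] columns.
#' @export
fit_cohort_psychometrics <- function(trials,
                                     canonical = c(1, 1.5, 1.75, 2, 2.25, 2.5, 3)) {
  types <- c("early", "mid", "late", "target", "post_reach", "baseline")
  keep <- trials$phase_label %in% types
  trials <- trials[keep, ]
  key <- paste(trials$participant, trials$phase_label, sep = "\r")
  grp <- split(seq_len(nrow(trials)), key)
  comp <- trials$comparison_intensity_measured
  resp <- trials$response
  rows <- lapply(names(grp), function(k) {
    idx <- grp[[k]]
    tab <- response_table(comp[idx], resp[idx], canonical)
    out <- fit_psychometric_core(tab)
    id <- strsplit(k, "\r", fixed = TRUE)[[1]]
    out$participant <- id[1]
    out$trial_type <- id[2]
    out
  })
  cols <- names(rows[[1]])
  out <- tibble::as_tibble(lapply(setNames(cols, cols), function(cl) {
    unlist(lapply(rows, `[[`, cl), use.names = FALSE)
  }))
  out$trial_type <- factor(out$trial_type, levels = types)
  dplyr::arrange(dplyr::relocate(out, "participant", "trial_type"),
                 participant, trial_type)
}
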