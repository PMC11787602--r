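#' Greenhouse-Geisser epsilon
#'
#' Sphericity estimate from the double-centred covariance of the
#' within-subject measurements: `eps = tr(S)^2 / ((k-1) * sum(S^2))` with
#' `S = C Sigma C`, `C = I - J/k`. Bounded by `1/(k-1)` below and 1 above.
#'
#' @param y n x k matrix of within-subject measurements (one column per
#'   level), or a covariance matrix with `is_cov = TRUE`.
#' @param is_cov Interpret `y` as a covariance matrix.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(y, is_cov = FALSE) {
  S <- if (is_cov) y else stats::cov(y)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  min(max(eps, 1 / (k - 1)), 1)
}

# wide participant x level matrix from a long table; errors on missing cells
wide_matrix <- function(data, id, within, dv) {
  tab <- tapply(data[[dv]], list(data[[id]], data[[within]]), mean)
  if (anyNA(tab)) {
    miss <- which(is.na(tab), arr.ind = TRUE)
    stop_config("incomplete within-subject design; missing cells: %s",
                paste(sprintf("%s:%s", rownames(tab)[miss[, 1]],
                              colnames(tab)[miss[, 2]]), collapse = ", "))
  }
  tab
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject decomposition (via [stats::aov()] with an
#' `Error(id/within)` stratum), with partial eta-squared and
#' Greenhouse-Geisser-corrected degrees of freedom and p-value. The
#' corrected values are reported whenever the epsilon estimate is below 1.
#'
#' @param data Long-format data frame.
#' @param dv,within,id Column names of the response, within-subject factor
#'   and subject identifier.
#' @return An `anova_report` tibble: `effect`, `df1`, `df2`, `F`, `p`,
#'   `pes` (partial eta-squared), `epsilon`, `df1_gg`, `df2_gg`, `p_gg`.
#' @export
rm_anova <- function(data, dv = "pse_norm", within = "trial_type", id = "participant") {
  mat <- wide_matrix(data, id, within, dv)
  k <- ncol(mat)
  n <- nrow(mat)
  assert_that(k >= 2, "need at least two within-subject levels")
  assert_that(n >= 3, "need at least three participants")
  df <- data.frame(y = as.vector(mat),
                   type = factor(rep(colnames(mat), each = n)),
                   idf = factor(rep(rownames(mat), k)))
  fit <- aov(y ~ type + Error(idf / type), data = df)
  s <- summary(fit)[["Error: idf:type"]][[1]]
  rownames(s) <- trimws(rownames(s))
  ss_eff <- s["type", "Sum Sq"]
  ss_err <- s["Residuals", "Sum Sq"]
  Fv <- s["type", "F value"]
  if (ss_eff < 1e-12 * max(ss_err, 1)) Fv <- 0 # no effect variance at all
  eps <- gg_epsilon(mat)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  pv <- s["type", "Pr(>F)"]
  if (identical(Fv, 0) && !is.finite(pv)) pv <- 1
  tibble::tibble(
    effect = within,
    df1 = df1, df2 = df2, F = Fv,
    p = pv,
    pes = ss_eff / (ss_eff + ss_err),
    epsilon = eps,
    df1_gg = eps * df1, df2_gg = eps * df2,
    p_gg = pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  ) -> out
  class(out) <- c("anova_report", class(out))
  out
}

#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' Between-subjects group factor crossed with a within-subjects factor.
#' Sums of squares come from [stats::aov()] with an `Error(id/within)`
#' specification; epsilon is estimated from the pooled within-group
#' covariance and applied to the within-subject effects (the group main
#' effect is not sphericity-dependent).
#'
#' @param data Long-format data frame.
#' @param dv,within,between,id Column names.
#' @return An `anova_report` tibble with one row per effect (`between`,
#'   `within`, `interaction`).
#' @export
mixed_anova <- function(data, dv = "pse_norm", within = "trial_type",
                        between = "group", id = "participant") {
  groups <- unique(data[[between]])
  assert_that(length(groups) == 2, "exactly two groups are required")
  for (g in groups) {
    assert_that(sum(data[[between]] == g) > 0, "one group is empty")
  }
  gmap <- unique(data[, c(id, between)])
  assert_that(!any(duplicated(gmap[[id]])),
              "each participant must belong to one group")
  mat <- wide_matrix(data, id, within, dv)
  k <- ncol(mat)
  n <- nrow(mat)
  grp <- gmap[[between]][match(rownames(mat), gmap[[id]])]
  df <- data.frame(y = as.vector(mat),
                   type = factor(rep(colnames(mat), each = n)),
                   grp = factor(rep(grp, k)),
                   idf = factor(rep(rownames(mat), k)))
  fit <- aov(y ~ grp * type + Error(idf / type), data = df)
  s_b <- summary(fit)[["Error: idf"]][[1]]
  s_w <- summary(fit)[["Error: idf:type"]][[1]]
  rownames(s_b) <- trimws(rownames(s_b))
  rownames(s_w) <- trimws(rownames(s_w))
  # pooled within-group covariance for epsilon
  covs <- lapply(split(as.data.frame(mat), grp), function(m) {
    (nrow(m) - 1) * stats::cov(as.matrix(m))
  })
  S_pool <- Reduce(`+`, covs) / (n - length(groups))
  eps <- gg_epsilon(S_pool, is_cov = TRUE)
  ng <- length(groups)
  row_of <- function(tab, name, err_row, df1, df2, epsv) {
    ss_eff <- tab[name, "Sum Sq"]
    ss_err <- tab[err_row, "Sum Sq"]
    Fv <- tab[name, "F value"]
    if (ss_eff < 1e-12 * max(ss_err, 1)) Fv <- 0
    pv <- tab[name, "Pr(>F)"]
    if (identical(Fv, 0) && !is.finite(pv)) pv <- 1
    tibble::tibble(df1 = df1, df2 = df2, F = Fv, p = pv,
                   pes = ss_eff / (ss_eff + ss_err), epsilon = epsv,
                   df1_gg = epsv * df1, df2_gg = epsv * df2,
                   p_gg = pf(Fv, epsv * df1, epsv * df2, lower.tail = FALSE))
  }
  out <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(effect = between),
                     row_of(s_b, "grp", "Residuals", ng - 1, n - ng, 1)),
    dplyr::bind_cols(tibble::tibble(effect = within),
                     row_of(s_w, "type", "Residuals", k - 1, (n - ng) * (k - 1), eps)),
    dplyr::bind_cols(tibble::tibble(effect = "interaction"),
                     row_of(s_w, "grp:type", "Residuals", (ng - 1) * (k - 1),
                            (n - ng) * (k - 1), eps))
  )
  class(out) <- c("anova_report", class(out))
  out
}
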