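# Shared fixtures and brute-force oracles. Oracles are deliberately dumb
# scans/enumerations, independent of the package's detection code paths.

small_design <- function() {
  design_config(comparison_intensities = c(1.5, 2, 2.5),
                reps_per_reaching_type = 2L, reps_baseline = 2L)
}

# population with all variability switched off: every trial is identical and
# every QC criterion is silent, so any rejection after inject_artifacts()
# is attributable to the injection
clean_population <- function(condition = "self_touch") {
  population_params(
    "exp1", condition,
    profile = flat_profile(), slope_between_sd = 0,
    rt_mean = 220, rt_within_sd = 0, rt_between_sd = 0,
    duration_mean = 542, duration_between_sd = 0,
    duration_within_mean = 60, duration_within_sd = 0,
    pse_between_sd = 0, jnd_between_sd = 0,
    kinematic_noise_sd = 0, force_noise_sd = 0
  )
}

snapped_params <- function(...) segmentation_params(interpolate = FALSE, ...)

# exhaustive onset scan: first sample index starting `hold` consecutive
# samples strictly above the threshold
oracle_onset_index <- function(speed, threshold, hold) {
  n <- length(speed)
  for (i in seq_len(n - hold + 1)) {
    ok <- TRUE
    for (j in i:(i + hold - 1)) {
      if (speed[j] <= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(i)
  }
  NA_integer_
}

# exhaustive first-upward-crossing scan after a time point
oracle_crossing_index <- function(series, threshold, time, after) {
  for (i in seq_along(series)) {
    if (time[i] > after && series[i] > threshold) return(i)
  }
  NA_integer_
}

# random single-peaked speed profile on a uniform timebase
random_single_peak <- function(n = 120, rate = 240) {
  peak_at <- sample(seq(20, n - 20), 1)
  up <- sort(runif(peak_at, 0, 100))
  down <- sort(runif(n - peak_at, 0, max(up) * 0.999), decreasing = TRUE)
  list(time = (seq_len(n) - 1) * 1000 / rate, speed = c(up, down))
}

# Bernoulli log-likelihood of a grouped response table (test-local copy)
table_loglik <- function(beta0, beta1, tab) {
  p <- pmin(pmax(plogis(beta0 + beta1 * tab$intensity), 1e-12), 1 - 1e-12)
  sum(tab$n_comparison_stronger * log(p) +
        (tab$n_trials - tab$n_comparison_stronger) * log(1 - p))
}

# dense 2-D grid-search ML oracle for the logistic psychometric fit
oracle_grid_fit <- function(tab, pse_range = c(1.2, 2.8), jnd_range = c(0.05, 0.8),
                            pse_step = 5e-4, jnd_step = 2e-3) {
  pse <- seq(pse_range[1], pse_range[2], by = pse_step)
  jnd <- seq(jnd_range[1], jnd_range[2], by = jnd_step)
  grid <- expand.grid(pse = pse, jnd = jnd)
  b1 <- log(3) / grid$jnd
  b0 <- -grid$pse * b1
  ll <- numeric(nrow(grid))
  tt <- tab[tab$n_trials > 0, ]
  for (r in seq_len(nrow(tt))) {
    p <- pmin(pmax(plogis(b0 + b1 * tt$intensity[r]), 1e-12), 1 - 1e-12)
    ll <- ll + tt$n_comparison_stronger[r] * log(p) +
      (tt$n_trials[r] - tt$n_comparison_stronger[r]) * log(1 - p)
  }
  grid[which.max(ll), ]
}

# simulate a grouped response table from the logistic observer
simulate_table <- function(beta0, beta1, n_per,
                           intensities = c(1, 1.5, 1.75, 2, 2.25, 2.5, 3)) {
  p <- plogis(beta0 + beta1 * intensities)
  k <- rbinom(length(p), n_per, p)
  tibble::tibble(intensity = intensities, n_trials = n_per,
                 n_comparison_stronger = k)
}

long_from_matrix <- function(mat, grp = NULL) {
  df <- data.frame(
    participant = rep(rownames(mat), ncol(mat)),
    trial_type = rep(colnames(mat), each = nrow(mat)),
    pse_norm = as.vector(mat)
  )
  if (!is.null(grp)) df$group <- rep(grp, ncol(mat))
  df
}

# textbook sums-of-squares one-way repeated-measures decomposition
oracle_rm_anova <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  gm <- mean(mat)
  ss_type <- n * sum((colMeans(mat) - gm)^2)
  ss_subj <- k * sum((rowMeans(mat) - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_err <- ss_tot - ss_type - ss_subj
  F <- (ss_type / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = F, df1 = k - 1, df2 = (k - 1) * (n - 1),
       pes = ss_type / (ss_type + ss_err))
}

# textbook split-plot (one between, one within) decomposition
oracle_mixed_anova <- function(mat, grp) {
  n <- nrow(mat)
  k <- ncol(mat)
  g <- length(unique(grp))
  gm <- mean(mat)
  subj_means <- rowMeans(mat)
  ss_between_subj <- k * sum((subj_means - gm)^2)
  ss_group <- 0
  for (lev in unique(grp)) {
    ng <- sum(grp == lev)
    ss_group <- ss_group + ng * k * (mean(mat[grp == lev, , drop = FALSE]) - gm)^2
  }
  ss_subj_within <- ss_between_subj - ss_group
  ss_type <- n * sum((colMeans(mat) - gm)^2)
  ss_cells <- 0
  for (lev in unique(grp)) {
    sub <- mat[grp == lev, , drop = FALSE]
    ss_cells <- ss_cells + nrow(sub) * sum((colMeans(sub) - gm)^2)
  }
  ss_inter <- ss_cells - ss_type - ss_group
  ss_tot <- sum((mat - gm)^2)
  ss_err_within <- ss_tot - ss_between_subj - ss_type - ss_inter
  df_err_b <- n - g
  df_err_w <- (n - g) * (k - 1)
  list(
    F_group = (ss_group / (g - 1)) / (ss_subj_within / df_err_b),
    F_type = (ss_type / (k - 1)) / (ss_err_within / df_err_w),
    F_inter = (ss_inter / ((g - 1) * (k - 1))) / (ss_err_within / df_err_w),
    pes_group = ss_group / (ss_group + ss_subj_within),
    pes_type = ss_type / (ss_type + ss_err_within),
    pes_inter = ss_inter / (ss_inter + ss_err_within)
  )
}

# Benjamini-Hochberg step-up closed form
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
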