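test_that("repeated-measures ANOVA matches a manual sums-of-squares oracle", {
  mat <- matrix(c(3, 5, 2, 7, 1,
                  4, 6, 3, 9, 2,
                  6, 7, 5, 8, 4,
                  2, 4, 2, 5, 1), nrow = 5, byrow = FALSE)
  rownames(mat) <- paste0("s", 1:5)
  colnames(mat) <- paste0("c", 1:4)
  got <- rm_anova(long_from_matrix(mat))
  want <- oracle_rm_anova(mat)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)
  expect_equal(got$pes, want$pes, tolerance = 1e-10)
  expect_equal(got$p, pf(want$F, want$df1, want$df2, lower.tail = FALSE))
  # random 3x3 integer tables agree to 1e-10
  set.seed(6)
  for (i in 1:25) {
    m <- matrix(sample(0:9, 9, replace = TRUE), 3, 3,
                dimnames = list(paste0("s", 1:3), paste0("c", 1:3)))
    if (oracle_rm_anova(m)$F %in% c(Inf, NaN)) next
    expect_equal(rm_anova(long_from_matrix(m))$F, oracle_rm_anova(m)$F,
                 tolerance = 1e-10)
  }
})

test_that("degenerate and two-level repeated-measures cases behave", {
  # identical values across levels: zero effect variance
  mat <- matrix(rep(c(1, 4, 2), 4), nrow = 3, byrow = FALSE,
                dimnames = list(paste0("s", 1:3), paste0("c", 1:4)))
  expect_equal(rm_anova(long_from_matrix(mat))$F, 0)
  # two levels: epsilon 1 and F equal to the squared paired t
  set.seed(8)
  m2 <- matrix(rnorm(20), 10, 2,
               dimnames = list(paste0("s", 1:10), c("a", "b")))
  got <- rm_anova(long_from_matrix(m2))
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(got$epsilon, 1)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(got$p, tt$p.value, tolerance = 1e-10)
  expect_error(rm_anova(long_from_matrix(m2)[-1, ]), "incomplete")
})

test_that("Greenhouse-Geisser epsilon stays within its bounds", {
  set.seed(10)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    n <- sample((k + 2):20, 1)
    y <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k), k, k)
    eps <- gg_epsilon(y)
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1 + 1e-12)
  }
  # perfectly spherical covariance: epsilon 1
  expect_equal(gg_epsilon(diag(4), is_cov = TRUE), 1)
})

test_that("mixed ANOVA matches the split-plot oracle", {
  set.seed(12)
  mat <- matrix(rnorm(8 * 3, mean = rep(c(0, 1), each = 4)), 8, 3,
                dimnames = list(paste0("s", 1:8), paste0("c", 1:3)))
  grp <- rep(c("g1", "g2"), each = 4)
  got <- mixed_anova(long_from_matrix(mat, grp))
  want <- oracle_mixed_anova(mat, grp)
  expect_equal(got$F[got$effect == "group"], want$F_group, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "trial_type"], want$F_type, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "interaction"], want$F_inter, tolerance = 1e-10)
  expect_equal(got$pes[got$effect == "group"], want$pes_group, tolerance = 1e-10)
  expect_equal(got$pes[got$effect == "interaction"], want$pes_inter,
               tolerance = 1e-10)
  # identical groups: group and interaction effects vanish
  mat2 <- rbind(mat[1:4, ], mat[1:4, ])
  rownames(mat2) <- paste0("s", 1:8)
  got2 <- mixed_anova(long_from_matrix(mat2, grp))
  expect_equal(got2$F[got2$effect == "group"], 0)
  expect_equal(got2$F[got2$effect == "interaction"], 0)
  expect_error(mixed_anova(long_from_matrix(mat, rep("g1", 8))), "two groups")
})

test_that("Benjamini-Hochberg adjustment matches the step-up closed form", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.2, 0.9)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  set.seed(14)
  for (i in 1:20) {
    pr <- runif(sample(3:12, 1))
    adj <- p.adjust(pr, "BH")
    expect_equal(adj, oracle_bh(pr))
    # monotone nondecreasing in the raw-p ranking
    expect_true(all(diff(adj[order(pr)]) >= -1e-15))
  }
  # an all-equal p-vector is returned unchanged
  expect_equal(p.adjust(rep(0.07, 5), "BH"), rep(0.07, 5))
})

test_that("the normality gate selects the matching test family", {
  set.seed(15)
  x <- rnorm(30)
  g <- gated_one_sample_test(x)
  expect_equal(g$test_used, "paired_t")
  expect_equal(g$effect_size_type, "cohens_d")
  expect_equal(g$statistic, unname(t.test(x)$statistic))
  # heavy-tailed sample fails Shapiro-Wilk -> signed-rank path
  y <- c(rnorm(28, 0, 0.05), 8, -9)
  expect_lt(shapiro.test(y)$p.value, 0.05)
  gy <- gated_one_sample_test(y)
  expect_equal(gy$test_used, "wilcoxon_signed_rank")
  expect_equal(gy$effect_size_type, "rank_biserial")
  expect_gte(gy$effect_size, -1)
  expect_lte(gy$effect_size, 1)
  # all-zero differences: degenerate rank path with p = 1, effect 0
  gz <- gated_one_sample_test(rep(0, 12))
  expect_equal(gz$p_raw, 1)
  expect_equal(gz$effect_size, 0)
})

test_that("effect sizes follow the test conventions", {
  set.seed(16)
  x <- rnorm(25, 0.8)
  g <- gated_one_sample_test(x)
  expect_equal(sign(g$effect_size), sign(mean(x)))
  expect_equal(g$effect_size, mean(x) / sd(x))
  # signed-rank rank-biserial equals 2V/S - 1 on a hand-checkable vector
  d <- c(1, 2, 3, -4, 5) # ranks of |d|: 1 2 3 4 5; V = 1+2+3+5 = 11
  wt <- suppressWarnings(wilcox.test(d))
  expect_equal(unname(wt$statistic), 11)
  gd <- gated_one_sample_test(c(rep(d, 5), 40)) # force non-normal
  expect_equal(gd$test_used, "wilcoxon_signed_rank")
  # independent family: Welch t and rank-sum with matched effect sizes
  a <- rnorm(20, 1)
  b <- rnorm(25, 0)
  gi <- gated_independent_test(a, b)
  expect_equal(gi$test_used, "welch_t")
  sp <- sqrt((19 * var(a) + 24 * var(b)) / 43)
  expect_equal(gi$effect_size, (mean(a) - mean(b)) / sp)
  a2 <- c(rnorm(18, 0, 0.05), 6, -7)
  gi2 <- gated_independent_test(a2, b)
  expect_equal(gi2$test_used, "rank_sum")
  U <- unname(suppressWarnings(wilcox.test(a2, b))$statistic)
  expect_equal(gi2$effect_size, 2 * U / (20 * 25) - 1)
})

test_that("planned comparisons run the plan with FDR across it", {
  set.seed(18)
  types <- c("early", "mid", "late", "target", "post_reach")
  norm <- expand.grid(participant = paste0("p", 1:20), trial_type = types,
                      stringsAsFactors = FALSE)
  shift <- c(early = 0, mid = -0.05, late = -0.1, target = -0.3,
             post_reach = -0.02)
  norm$pse_norm <- rnorm(nrow(norm), shift[norm$trial_type], 0.08)
  out <- planned_comparisons(norm)
  expect_equal(nrow(out), 7)
  expect_setequal(out$pair, c("early_vs_mid", "early_vs_late",
                              "early_vs_target", "mid_vs_late",
                              "mid_vs_target", "late_vs_target",
                              "target_vs_post_reach"))
  expect_true(all(out$p_fdr >= out$p_raw - 1e-15))
  expect_equal(out$p_fdr, p.adjust(out$p_raw, "BH"))
  expect_lt(out$p_fdr[out$pair == "early_vs_target"], 0.001)
})

test_that("participant slopes recover exact lines and nulls", {
  types <- c("early", "mid", "late", "target")
  norm <- expand.grid(participant = paste0("p", 1:6), trial_type = types,
                      stringsAsFactors = FALSE)
  pct <- c(early = 15, mid = 40, late = 70, target = 100)
  norm$percent <- pct[norm$trial_type]
  # exact line: slope recovered to machine precision
  norm$pse_norm <- -0.002 * norm$percent
  fit <- fit_participant_slopes(norm, span = "early_target")
  expect_equal(fit$slopes$slope, rep(-0.002, 6), tolerance = 1e-12)
  # constant response: slope zero
  norm$pse_norm <- 0.4
  fit0 <- fit_participant_slopes(norm, span = "early_target")
  expect_equal(fit0$slopes$slope, rep(0, 6), tolerance = 1e-12)
  # within-reach span drops the target cell
  fit_w <- fit_participant_slopes(norm, span = "early_late")
  expect_equal(fit_w$span, "early_late")
  expect_equal(nrow(fit_w$slopes), 6)
})

test_that("one-sided default Bayes factors match an independent quadrature", {
  set.seed(19)
  x <- rnorm(30, 0, 1)
  x <- (x - mean(x)) / sd(x) * 1 # mean exactly 0, sd 1
  bf <- bayes_factor_one_sided(x, direction = "less")
  expect_gt(bf$bf0_plus, 1) # null supported when the mean is exactly zero
  expect_equal(bf$bf0_plus * bf$bf_plus0, 1)
  # fine-grid quadrature of the same integrand, written independently
  for (dir in c("less", "greater")) {
    y <- rnorm(25, -0.3, 1.2)
    bfy <- bayes_factor_one_sided(y, direction = dir)
    tstat <- mean(y) / (sd(y) / sqrt(25))
    ts <- if (dir == "less") -tstat else tstat
    delta <- seq(1e-9, 60, length.out = 400001)
    dens <- suppressWarnings(dt(ts, 24, ncp = delta * sqrt(25))) *
      2 * dcauchy(delta, 0, 0.707)
    h <- delta[2] - delta[1]
    m1 <- (sum(dens) - (dens[1] + dens[length(dens)]) / 2) * h # trapezoid
    want <- dt(ts, 24) / m1
    expect_equal(bfy$bf0_plus, want, tolerance = 5e-4)
  }
  # frozen cross-check: the two-sided marginal of the same machinery
  # reproduces the standard default-prior Bayes factor for t = 1.50723,
  # n = 29 (0.543557, verified against an independent implementation)
  m0 <- dt(1.50723, 28)
  m1 <- integrate(function(d) {
    suppressWarnings(dt(1.50723, 28, ncp = d * sqrt(29))) * dcauchy(d, 0, 0.707)
  }, -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(m1 / m0, 0.543557, tolerance = 1e-5)
  expect_error(bayes_factor_one_sided(rep(2, 10)), "variance")
})
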