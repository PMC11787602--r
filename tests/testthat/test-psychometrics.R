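test_that("comparison forces rebin to the nearest canonical intensity", {
  canon <- c(1, 1.5, 1.75, 2, 2.25, 2.5, 3)
  expect_equal(rebin_comparison(2.0, canon), 2.0)
  expect_equal(rebin_comparison(1.9, canon), 2.0) # midpoint 1.875 < 1.9
  expect_equal(rebin_comparison(1.625, canon), 1.75) # exact midpoint: upward
  expect_equal(rebin_comparison(c(0.2, 5), canon), c(1, 3))
  expect_error(rebin_comparison(2, numeric()), "non-empty")
  # random values always map to a true nearest neighbour
  set.seed(2)
  x <- runif(500, 0.8, 3.2)
  got <- rebin_comparison(x, canon)
  for (i in seq_along(x)) {
    expect_lte(abs(got[i] - x[i]), min(abs(canon - x[i])) + 1e-12)
  }
})

test_that("PSE and JND derive from the logistic coefficients", {
  pj <- derive_pse_jnd(-4, 2)
  expect_equal(pj$pse, 2)
  expect_equal(pj$jnd, log(3) / 2)
  expect_equal(derive_pse_jnd(0, 1)$pse, 0)
  expect_equal(derive_pse_jnd(0, 1)$jnd, log(3))
  expect_error(derive_pse_jnd(1, 0), "non-zero")
  # logistic(pse + jnd) = 0.75 identically
  for (b in list(c(-4, 2), c(-11.7, 5.85), c(3, 1.2))) {
    pj <- derive_pse_jnd(b[1], b[2])
    expect_equal(plogis(b[1] + b[2] * (pj$pse + pj$jnd)), 0.75)
  }
})

test_that("the generative observer is recovered by the fit", {
  set.seed(5)
  tab <- simulate_table(-11.7, 5.85, 200) # pse 2, jnd log(3)/5.85
  fit <- fit_psychometric(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$pse - 2), 0.02)
  expect_lt(abs(fit$jnd - log(3) / 5.85), 0.03)
})

test_that("a response table symmetric about 2 N yields PSE exactly 2", {
  tab <- tibble::tibble(intensity = c(1, 1.5, 1.75, 2, 2.25, 2.5, 3),
                        n_trials = rep(20L, 7),
                        n_comparison_stronger = c(1L, 4L, 7L, 10L, 13L, 16L, 19L))
  fit <- fit_psychometric(tab)
  expect_equal(fit$pse, 2, tolerance = 1e-8)
  g <- oracle_grid_fit(tab, pse_range = c(1.8, 2.2))
  expect_equal(g$pse, 2, tolerance = 6e-4)
})

test_that("the ML fit matches a dense grid-search oracle", {
  set.seed(9)
  for (i in 1:10) {
    jnd_true <- runif(1, 0.12, 0.45)
    pse_true <- runif(1, 1.7, 2.3)
    b1 <- log(3) / jnd_true
    tab <- simulate_table(-pse_true * b1, b1, sample(c(8L, 16L, 24L), 1))
    fit <- fit_psychometric(tab)
    g <- oracle_grid_fit(tab)
    expect_lt(abs(fit$pse - g$pse), 1e-3)
    expect_lt(abs(fit$jnd - g$jnd), 5e-3)
    # fitted coefficients beat every grid point in log-likelihood
    expect_gte(table_loglik(fit$beta0, fit$beta1, tab) + 1e-9,
               table_loglik(-g$pse * log(3) / g$jnd, log(3) / g$jnd, tab))
  }
})

test_that("McFadden pseudo-R2 measures the likelihood improvement", {
  # slope-free data: model collapses to the intercept-only fit
  flat <- tibble::tibble(intensity = c(1, 2, 3), n_trials = c(40L, 40L, 40L),
                         n_comparison_stronger = c(20L, 20L, 20L))
  expect_equal(mcfadden_r2(flat, 0, 0), 0)
  fitf <- fit_psychometric(flat)
  expect_lt(fitf$mcfadden_r2, 1e-6)
  expect_false(fitf$valid) # PSE undefined without a slope
  # a steep transition leaves entropy only at its midpoint
  steep <- tibble::tibble(intensity = c(1, 2, 3), n_trials = c(50L, 50L, 50L),
                          n_comparison_stronger = c(0L, 25L, 50L))
  expect_gt(mcfadden_r2(steep, -40, 20), 0.6)
  # near-deterministic data with a matching model approach 1
  det <- tibble::tibble(intensity = c(1, 3), n_trials = c(50L, 50L),
                        n_comparison_stronger = c(0L, 50L))
  expect_gt(mcfadden_r2(det, -80, 40), 0.999)
  # hand-computed small table
  tab <- tibble::tibble(intensity = c(1.5, 2, 2.5), n_trials = c(10L, 10L, 10L),
                        n_comparison_stronger = c(2L, 5L, 9L))
  b0 <- -5; b1 <- 2.5
  p <- plogis(b0 + b1 * tab$intensity)
  ll_m <- sum(tab$n_comparison_stronger * log(p) +
                (tab$n_trials - tab$n_comparison_stronger) * log(1 - p))
  p0 <- 16 / 30
  ll_0 <- sum(tab$n_comparison_stronger * log(p0) +
                (tab$n_trials - tab$n_comparison_stronger) * log(1 - p0))
  expect_equal(mcfadden_r2(tab, b0, b1), 1 - ll_m / ll_0)
  expect_error(mcfadden_r2(tibble::tibble(intensity = 2, n_trials = 10L,
                                          n_comparison_stronger = 10L), 0, 1),
               "degenerate")
})

test_that("fitted curves are monotone and shift-equivariant", {
  set.seed(3)
  tab <- simulate_table(-11.7, 5.85, 30)
  fit <- fit_psychometric(tab)
  x <- seq(1, 3, by = 0.01)
  expect_true(all(diff(plogis(fit$beta0 + fit$beta1 * x)) > 0))
  # adding c to every intensity shifts the PSE by c, JND unchanged
  for (cc in c(-0.4, 0.7)) {
    tab2 <- tab
    tab2$intensity <- tab$intensity + cc
    fit2 <- fit_psychometric(tab2)
    expect_equal(fit2$pse, fit$pse + cc, tolerance = 1e-6)
    expect_equal(fit2$jnd, fit$jnd, tolerance = 1e-6)
  }
})

test_that("PSE estimates converge as trials accumulate", {
  set.seed(17)
  rmse <- vapply(c(8L, 16L, 64L, 256L), function(n_per) {
    err <- replicate(60, {
      fit_psychometric(simulate_table(-11.7, 5.85, n_per))$pse - 2
    })
    sqrt(mean(err^2))
  }, 0)
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[4], 0.03)
})

test_that("degenerate tables are flagged, never silently fitted", {
  one_int <- tibble::tibble(intensity = 2, n_trials = 50L,
                            n_comparison_stronger = 25L)
  f1 <- fit_psychometric(one_int)
  expect_false(f1$valid)
  all_same <- tibble::tibble(intensity = c(1, 2, 3), n_trials = c(10L, 10L, 10L),
                             n_comparison_stronger = c(10L, 10L, 10L))
  f2 <- fit_psychometric(all_same)
  expect_false(f2$valid)
  expect_false(f2$converged)
  # complete separation: ridge fallback keeps a finite flagged estimate
  sep <- tibble::tibble(intensity = c(1, 1.5, 2.5, 3),
                        n_trials = rep(25L, 4),
                        n_comparison_stronger = c(0L, 0L, 25L, 25L))
  f3 <- fit_psychometric(sep)
  expect_false(f3$converged)
  expect_true(is.finite(f3$pse))
  expect_gt(f3$pse, 1.5)
  expect_lt(f3$pse, 2.5)
})

test_that("clean simulated cohorts produce good fits throughout", {
  co <- simulate_cohort(8, design_config(), population_params(), seed = 23)
  qc <- apply_trial_exclusions(co)
  keep <- apply_participant_exclusions(qc$trials)
  fits <- fit_cohort_psychometrics(keep$trials)
  expect_gte(mean(fits$mcfadden_r2 > 0.4, na.rm = TRUE), 0.95)
  expect_true(all(fits$valid))
})
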