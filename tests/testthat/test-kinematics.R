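test_that("moving-average smoothing behaves like a box filter", {
  n <- 50
  const <- matrix(2.5, n, 3)
  expect_equal(smooth_positions(const), const)
  # unit impulse spreads into five samples of 1/5
  imp <- numeric(n)
  imp[25] <- 1
  sm <- smooth_positions(imp)
  expect_equal(sm[23:27], rep(0.2, 5))
  expect_equal(sum(sm), 1)
  # affine signals are preserved on interior samples
  ramp <- seq(0, 10, length.out = n)
  expect_equal(smooth_positions(ramp)[3:(n - 2)], ramp[3:(n - 2)])
  expect_error(smooth_positions(ramp[1:3], span = 5), "span")
})

test_that("speed is the norm of the numerical derivative", {
  dt <- 1000 / 240
  time <- seq(0, 1000, by = dt)
  n <- length(time)
  expect_equal(compute_speed(matrix(1, n, 3), time), rep(0, n))
  # uniform motion at 10 cm/s along one axis
  pos <- cbind(10 * time / 1000, numeric(n), numeric(n))
  expect_equal(compute_speed(pos, time)[2:(n - 1)], rep(10, n - 2))
  # planar circular motion: speed = r * omega
  r <- 5
  omega <- 2 * pi # rad/s
  pos2 <- cbind(r * cos(omega * time / 1000), r * sin(omega * time / 1000),
                numeric(n))
  sp <- compute_speed(pos2, time)
  expect_equal(sp[3:(n - 2)], rep(r * omega, n - 4), tolerance = 1e-3)
  expect_error(compute_speed(pos, time^1.3), "uniform")
})

test_that("movement onset requires the full 100 ms hold", {
  p <- snapped_params()
  dt <- 1000 / 240
  time <- (0:199) * dt
  expect_true(is.na(detect_movement_onset(numeric(200), time, p)))
  # a 12-sample (50 ms) excursion above 5 cm/s does not qualify
  sp <- numeric(200)
  sp[50:61] <- 10
  expect_true(is.na(detect_movement_onset(sp, time, p)))
  sp[100:140] <- 10 # 41 samples > 24-sample hold
  expect_equal(detect_movement_onset(sp, time, p), time[100])
})

test_that("onset detection equals a brute-force run scan", {
  p <- snapped_params()
  dt <- 1000 / 240
  set.seed(11)
  for (i in 1:300) {
    n <- 150
    time <- (0:(n - 1)) * dt
    # piecewise-constant random speeds hovering around the threshold
    sp <- abs(rep(runif(15, 0, 12), each = 10)) + runif(n, -0.5, 0.5)
    got <- detect_movement_onset(sp, time, p)
    want <- oracle_onset_index(sp, p$onset_speed_threshold, 24L)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, time[want])
  }
})

test_that("reach offset is the first tap crossing (or the trigger)", {
  p <- snapped_params()
  dt <- 1000 / 240
  time <- (0:199) * dt
  f <- numeric(200)
  f[120:200] <- 1
  trace <- list(time = time, tap_force = f, condition = "self_touch")
  expect_equal(detect_reach_offset(trace, onset = 100, p), time[120])
  expect_true(is.na(detect_reach_offset(
    list(time = time, tap_force = rep(0.2, 200), condition = "self_touch"),
    onset = 100, p)))
  # bounce: crossings at 120 and 160; first one after onset wins
  f2 <- numeric(200)
  f2[120:130] <- 1
  f2[160:170] <- 1
  tr2 <- list(time = time, tap_force = f2, condition = "self_touch")
  want <- oracle_crossing_index(f2, 0.3, time, 100)
  expect_equal(detect_reach_offset(tr2, onset = 100, p), time[want])
  # crossings before onset are ignored
  expect_equal(detect_reach_offset(tr2, onset = time[140], p), time[160])
  # no-self-touch: recorded trigger time is returned as is
  tr3 <- list(time = time, condition = "no_self_touch",
              distance_trigger_time = 432.1)
  expect_equal(detect_reach_offset(tr3, onset = 100, p), 432.1)
})

test_that("peak-velocity search is constrained to 67% of the movement", {
  p <- snapped_params()
  time <- 0:999
  # bimodal: global max sits after the 67% boundary and must be ignored
  sp <- exp(-((time - 250) / 80)^2) * 50 + exp(-((time - 900) / 40)^2) * 80
  pk <- find_peak_velocity(sp, time, onset = 0, offset = 1000, p)
  win <- time <= 670
  expect_equal(pk$peak_time, time[win][which.max(sp[win])])
  expect_lt(pk$peak_time, 670)
  expect_false(pk$peak_speed == max(sp)) # unrestricted argmax differs
  # symmetric single peak: midpoint
  sp2 <- minjerk_speed(time / 1000, 25, 1)
  pk2 <- find_peak_velocity(sp2, time, 0, 1000, p)
  expect_equal(pk2$peak_time, 500)
  # monotone increasing in-window: last in-window sample
  pk3 <- find_peak_velocity(time * 0.1, time, 0, 1000, p)
  expect_equal(pk3$peak_time, max(time[win]))
  # ties break to the earliest sample
  sp4 <- rep(c(1, 5, 5, 1), each = 250)
  pk4 <- find_peak_velocity(sp4, time, 0, 1000, p)
  expect_equal(pk4$peak_time, 250)
})

test_that("85% crossings match geometry and brute-force scans", {
  # triangular profile rising 0 -> 100 over [0, 400], falling to 0 at 1000:
  # interpolated crossings sit exactly at the 85% points
  p <- segmentation_params() # interpolating
  time <- seq(0, 1000, by = 1000 / 240)
  sp <- ifelse(time <= 400, time / 4, (1000 - time) / 6)
  pk <- find_peak_velocity(sp, time, 0, 1000, p)
  cr <- compute_phase_crossings(sp, time, 0, 1000, pk$peak_time, pk$peak_speed, p)
  expect_equal(cr$ascend85, 0.85 * pk$peak_speed * 4, tolerance = 1e-6)
  expect_equal(cr$descend85, 1000 - 6 * 0.85 * pk$peak_speed, tolerance = 1e-6)
  # flat-top plateau: first sample at >= 85%, first sample below after it
  ps <- snapped_params()
  sp2 <- c(seq(0, 100, length.out = 50), rep(100, 40),
           seq(100, 0, length.out = 50))
  t2 <- seq_along(sp2) * 1000 / 240
  pk2 <- find_peak_velocity(sp2, t2, t2[1], max(t2), ps)
  cr2 <- compute_phase_crossings(sp2, t2, t2[1], max(t2),
                                 pk2$peak_time, pk2$peak_speed, ps)
  expect_equal(cr2$ascend85, t2[min(which(sp2 >= 85))])
  after <- which(t2 > pk2$peak_time & sp2 < 85)
  expect_equal(cr2$descend85, t2[min(after)])
  # random single-peak profiles vs exhaustive scans (snapped mode)
  set.seed(5)
  for (i in 1:200) {
    rsp <- random_single_peak()
    pk3 <- find_peak_velocity(rsp$speed, rsp$time, rsp$time[1], max(rsp$time), ps)
    cr3 <- compute_phase_crossings(rsp$speed, rsp$time, rsp$time[1],
                                   max(rsp$time), pk3$peak_time,
                                   pk3$peak_speed, ps)
    thr <- 0.85 * pk3$peak_speed
    asc <- min(which(rsp$speed >= thr))
    expect_equal(cr3$ascend85, rsp$time[asc])
    desc <- which(rsp$time > pk3$peak_time & rsp$speed < thr)
    want <- if (length(desc)) rsp$time[min(desc)] else max(rsp$time)
    expect_equal(cr3$descend85, want)
  }
})

test_that("phase binning follows the landmark intervals", {
  lm <- list(onset = 100, ascend85 = 180, descend85 = 350, offset = 600)
  bin <- function(type, tt) bin_trial(type, tt, lm$onset, lm$ascend85,
                                      lm$descend85, lm$offset)
  expect_equal(bin("t250", 150)$phase_label, "early")
  expect_equal(bin("t370", 180)$phase_label, "mid")   # boundary closed below
  expect_equal(bin("t370", 349.9)$phase_label, "mid")
  expect_equal(bin("t550", 350)$phase_label, "late")
  expect_equal(bin("t250", 50)$phase_label, "invalid")
  expect_equal(bin("t250", 50)$invalid_reason, "e")
  expect_equal(bin("t550", 600)$invalid_reason, "e")
  expect_equal(bin("target", 640)$phase_label, "target")
  expect_equal(bin("post_reach", 900)$phase_label, "post_reach")
  expect_equal(bin_trial("t250", 150, NA, NA, NA, NA)$invalid_reason, "b")
  # test force exactly at peak time is always mid (inside the 85% band)
  expect_equal(bin("t370", 250)$phase_label, "mid")
  # random trials vs an independent interval-membership check
  set.seed(13)
  for (i in 1:1000) {
    tt <- runif(1, 0, 700)
    got <- bin("t370", tt)
    want <- if (tt < lm$onset || tt >= lm$offset) "invalid"
    else if (tt < lm$ascend85) "early"
    else if (tt < lm$descend85) "mid"
    else "late"
    expect_equal(got$phase_label, want)
  }
})

test_that("early/mid/late intervals partition the movement", {
  # simulator landmarks: [onset, offset) is covered with no gaps/overlaps
  co <- simulate_cohort(3, design_config(), population_params(), seed = 31)
  s <- co$segments_truth
  expect_true(all(s$onset < s$ascend85))
  expect_true(all(s$ascend85 <= s$peak_time))
  expect_true(all(s$peak_time <= s$descend85))
  expect_true(all(s$descend85 < s$offset))
  # membership is exclusive and exhaustive on a probe grid
  row <- s[17, ]
  probes <- seq(row$onset, row$offset - 1e-9, length.out = 97)
  labs <- vapply(probes, function(tt) {
    bin_trial("t370", tt, row$onset, row$ascend85, row$descend85,
              row$offset)$phase_label
  }, "")
  expect_true(all(labs %in% c("early", "mid", "late")))
  expect_equal(labs[1], "early")
  expect_equal(labs[length(labs)], "late")
  expect_true(all(diff(match(labs, c("early", "mid", "late"))) >= 0))
})

test_that("landmarks are shift-equivariant and scale-covariant", {
  p <- segmentation_params()
  rsp <- local({
    set.seed(8)
    random_single_peak(n = 200)
  })
  sp <- rsp$speed
  time <- rsp$time
  onset <- detect_movement_onset(sp, time, p)
  pk <- find_peak_velocity(sp, time, onset, max(time), p)
  cr <- compute_phase_crossings(sp, time, onset, max(time),
                                pk$peak_time, pk$peak_speed, p)
  # time translation by delta shifts every landmark by exactly delta
  delta <- 173.25
  onset2 <- detect_movement_onset(sp, time + delta, p, after = delta)
  pk2 <- find_peak_velocity(sp, time + delta, onset2, max(time) + delta, p)
  cr2 <- compute_phase_crossings(sp, time + delta, onset2, max(time) + delta,
                                 pk2$peak_time, pk2$peak_speed, p)
  expect_equal(onset2, onset + delta)
  expect_equal(pk2$peak_time, pk$peak_time + delta)
  expect_equal(cr2$ascend85, cr$ascend85 + delta)
  expect_equal(cr2$descend85, cr$descend85 + delta)
  # scaling speeds leaves the 85%-crossing times unchanged (relative rule)
  for (cc in c(0.5, 3, 10)) {
    pk3 <- find_peak_velocity(sp * cc, time, onset, max(time), p)
    cr3 <- compute_phase_crossings(sp * cc, time, onset, max(time),
                                   pk3$peak_time, pk3$peak_speed, p)
    expect_equal(pk3$peak_time, pk$peak_time)
    expect_equal(cr3$ascend85, cr$ascend85)
    expect_equal(cr3$descend85, cr$descend85)
  }
})

test_that("mean test-force phases are ordered within the reach", {
  co <- simulate_cohort(8, design_config(), population_params(), seed = 41)
  qc <- apply_trial_exclusions(co)
  pct <- phase_percent_times(qc$trials)
  m <- tapply(pct$percent, pct$trial_type, mean, na.rm = TRUE)
  expect_true(m[["early"]] < m[["mid"]])
  expect_true(m[["mid"]] < m[["late"]])
  expect_true(all(m[c("early", "mid", "late")] > 0))
  expect_true(all(m[c("early", "mid", "late")] < 100))
})
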