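test_that("segmentation centres, truncates at the earliest depth maximum, and flags short trials", {
  s <- data.frame(t_ms = c(0, 100, 200, 300, 400),
                  x1_m = c(0, 0.3, 0.55, 0.54, 0.55), x2_m = 1, x3_m = -2)
  seg <- center_and_segment(s)
  expect_equal(seg$t, c(0, 100, 200))       # earliest attainment of the max
  expect_equal(seg$x1[1], 0)
  expect_equal(seg$x2[1], 0)                # centred to (0, 0, 0)

  ramp <- data.frame(t_ms = 0:5 * 100, x1_m = 0:5 * 0.1, x2_m = 0, x3_m = 0)
  expect_length(center_and_segment(ramp)$t, 6)   # max at the last sample

  still <- data.frame(t_ms = 0:5 * 100, x1_m = 0, x2_m = 0, x3_m = 0)
  seg0 <- center_and_segment(still)
  expect_length(seg0$t, 6)                  # degenerate: keep the full trial
  expect_equal(max(seg0$x1), 0)

  short <- data.frame(t_ms = c(0, 10), x1_m = c(0, 1), x2_m = 0, x3_m = 0)
  expect_false(center_and_segment(short)$usable)
})

test_that("segmentation equals a brute-force scan on random integer depth sequences", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    x1 <- sample(0:8, n, replace = TRUE)
    s <- data.frame(t_ms = seq_len(n) * 10, x1_m = x1, x2_m = 0, x3_m = 0)
    seg <- center_and_segment(s)
    expect_length(seg$t, oracle_segment_end(x1 - x1[1]))
  }
})

test_that("initiation detection interpolates the threshold crossing", {
  still <- center_and_segment(
    data.frame(t_ms = 0:5 * 100, x1_m = 0, x2_m = 0, x3_m = 0))
  it <- detect_initiation(still)
  expect_true(is.na(it))
  expect_equal(attr(it, "flag"), "no_movement")

  lin <- center_and_segment(linear_trial(speed = 1))
  expect_equal(detect_initiation(lin, threshold = 0.01), 10,
               tolerance = 1e-6)   # 0.01 m at 1 m/s

  # minimum-jerk trial: analytic threshold-crossing lag
  D <- 0.6; T_ms <- 1000; it_true <- 200
  tr <- minjerk_trial(D = D, T_ms = T_ms, it = it_true, arcs = FALSE)
  seg <- center_and_segment(tr$samples)
  tau_cross <- uniroot(function(tau) D * (10 * tau^3 - 15 * tau^4 +
                                            6 * tau^5) - 0.01,
                       c(1e-6, 0.5))$root
  expected <- it_true + tau_cross * T_ms
  expect_lt(abs(detect_initiation(seg) - expected), 1000 / 120)
})

test_that("differentiation is exact on linear motion and bounded on sinusoids", {
  lin <- center_and_segment(linear_trial(speed = 2))
  ser <- kinematic_series(lin)
  # interior: the shrinking boundary windows perturb the first/last two
  # smoothed positions, hence the first/last four derivative samples
  i <- 5:(nrow(ser) - 4)
  expect_equal(ser$speed[i], rep(2, length(i)), tolerance = 1e-9)
  expect_equal(ser$accel[i], rep(0, length(i)), tolerance = 1e-9)

  # x1 = A sin(w t): peak speed A w within the central-difference bound
  A <- 0.3; w <- 2 * pi * 0.8; dt <- 1 / 120
  t <- seq(0, 300, by = 1000 / 120)
  s <- data.frame(t_ms = t, x1_m = A * sin(w * t / 1000), x2_m = 0, x3_m = 0)
  seg <- structure(list(t = t, x1 = s$x1_m, x2 = s$x2_m, x3 = s$x3_m,
                        usable = TRUE, reason = ""),
                   class = "segmented_trial")
  ser2 <- kinematic_series(seg, smoothing = 1)
  bound <- (w^2 * dt^2 / 6) * A * w + 1e-9
  expect_lt(max(ser2$speed) - A * w, bound)
  expect_gt(max(ser2$speed), A * w - A * w * (w^2 * dt^2 / 6) - 0.02)
})

test_that("minimum-jerk peaks survive smoothing and discretisation", {
  tr <- minjerk_trial(D = 0.6, T_ms = 1000)
  seg <- center_and_segment(tr$samples)
  ser <- kinematic_series(seg, smoothing = 5)
  expect_lt(abs(max(ser$speed) - 1.125) / 1.125, 0.01)
  expect_lt(abs(max(ser$accel) - 3.4641) / 3.4641, 0.02)
})

test_that("stop-trial parameters follow their definitions", {
  # constructed trial: depth 0.40 m at stop onset (600 ms), max 0.45 m at 850
  t <- seq(0, 900, by = 50)
  x1 <- approx(c(0, 600, 850, 900), c(0, 0.40, 0.45, 0.45), xout = t)$y
  seg <- center_and_segment(data.frame(t_ms = t, x1_m = x1, x2_m = 0,
                                       x3_m = 0))
  ser <- kinematic_series(seg)
  par <- extract_parameters(seg, ser, stop_onset = 600, object_depth = 0.5705)
  expect_equal(par$tts, 250)
  expect_equal(par$bd, 0.05, tolerance = 1e-9)
  expect_true(par$acc)       # 0.45 < 0.5705 - 0.02
  expect_error(extract_parameters(seg, ser, stop_onset = NA,
                                  trial_type = "stop"),
               "stop_signal_onset")
})

test_that("time standardisation preserves endpoints and analytic shape", {
  two <- center_and_segment(
    data.frame(t_ms = c(0, 100, 200), x1_m = c(0, 0.1, 0.2), x2_m = 0,
               x3_m = 0))
  rs <- time_standardize(two, n_steps = 21)
  expect_equal(rs$x1_m, seq(0, 0.2, length.out = 21), tolerance = 1e-12)

  tr <- minjerk_trial(D = 0.6, T_ms = 1000, arcs = FALSE)
  seg <- center_and_segment(tr$samples)
  # identity when resampling at the native grid size on uniform sampling
  rs_id <- time_standardize(seg, n_steps = length(seg$t))
  expect_equal(rs_id$x1_m, seg$x1, tolerance = 1e-9)

  rs2 <- time_standardize(seg, n_steps = 101)
  mj <- function(t) {
    tau <- pmin(pmax((t - 200) / 1000, 0), 1)
    0.6 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  }
  expect_lt(max(abs(rs2$x1_m - mj(rs2$t_ms))), 5e-4)   # < 0.5 mm
})

test_that("outlier filtering reproduces hand-worked cases and a brute-force oracle", {
  rec <- data.frame(participant_id = "p1", category = "chocolate",
                    trial_type = "go",
                    pv = c(rep(10, 9), 60))
  out <- filter_and_aggregate(rec, vars = "pv", min_trials = 1)
  expect_equal(out$mean, 10)                 # z(60) = 2.85 > 2.5 removed
  expect_equal(out$n_used, 9)

  rec2 <- data.frame(participant_id = "p1", category = "chocolate",
                     trial_type = "go", pv = c(10, 10, 10, 10, 100))
  out2 <- filter_and_aggregate(rec2, vars = "pv", min_trials = 1)
  expect_equal(out2$mean, 28)                # z(100) = 1.79: kept
  expect_equal(out2$n_used, 5)

  rec3 <- data.frame(participant_id = "p1", category = "neutral",
                     trial_type = "stop", pv = rep(7, 6))
  out3 <- filter_and_aggregate(rec3, vars = "pv")
  expect_equal(out3$mean, 7)                 # SD = 0: remove nothing

  set.seed(5)
  big <- data.frame(
    participant_id = sample(c("a", "b"), 200, TRUE),
    category = sample(c("chocolate", "neutral"), 200, TRUE),
    trial_type = sample(c("go", "stop"), 200, TRUE),
    pv = rnorm(200), tts = rnorm(200, 250, 50))
  got <- filter_and_aggregate(big, vars = c("pv", "tts"))
  for (i in seq_len(nrow(got))) {
    cell <- big[big$participant_id == got$participant_id[i] &
                  big$category == got$category[i] &
                  big$trial_type == got$trial_type[i], ]
    expect_equal(got$mean[i], oracle_filtered_mean(cell[[got$variable[i]]]),
                 tolerance = 1e-12)
  }
})

test_that("peak velocity is robust to millimetre positional noise", {
  set.seed(8)
  # study-typical reach: PV = 1.875 * D / T = 2.11 m/s
  cfg <- study_config(position_noise_sd = 0.001)
  reach <- 1875 * cfg$object_depth / 2.11
  pvs <- replicate(60, {
    tr <- generate_vr_trial(NULL, "neutral", "go", cfg, it = 250,
                            reach_ms = reach)
    seg <- center_and_segment(tr$samples)
    max(kinematic_series(seg)$speed)
  })
  expect_lt(abs(mean(pvs) - 2.11) / 2.11, 0.02)
})

test_that("full-table extraction keeps keys and recovers truth on clean trials", {
  cfg <- study_config(n_participants = 2, n_vr_trials = 16,
                      position_noise_sd = 0, rng_seed = 21)
  coh <- generate_cohort(cfg)
  kin <- extract_kinematics(coh$trials, object_depth = cfg$object_depth)
  expect_equal(nrow(kin), 32)
  truth <- coh$ground_truth$trials
  m <- merge(kin, truth, by = c("participant_id", "trial_index"))
  go <- m[m$trial_type.x == "go", ]
  # completed reaches attain the full object depth
  expect_equal(go$maxz, rep(cfg$object_depth, nrow(go)), tolerance = 1e-6)
  st <- m[m$trial_type.x == "stop" & m$success_true %in% TRUE, ]
  if (nrow(st) > 0) {
    expect_lt(max(abs(st$maxz - st$maxz_true)), 1e-3)
    expect_true(all(st$acc))
  }
})
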