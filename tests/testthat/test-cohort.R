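test_that("screening enforces the inclusion rules with a strict craving threshold", {
  cand <- data.frame(
    id = paste0("c", 1:6),
    age = c(25, 25, 17, 36, 25, 25),
    bmi = c(22, 22, 22, 22, 30.5, 22),
    handedness_score = c(80, 80, 80, 80, 80, 40),
    fcq_trait = c(37, 38, 50, 50, 50, 50))
  kept <- screen_participants(cand)
  expect_equal(kept$id, "c2")          # threshold is strictly > 37
  log <- attr(kept, "screen_log")
  expect_setequal(log$id, c("c1", "c3", "c4", "c5", "c6"))
  expect_match(log$reason[log$id == "c1"], "fcq")
  expect_match(log$reason[log$id == "c6"], "handed")
})

test_that("screening matches a brute-force filter and rejects missing fields", {
  set.seed(11)
  cand <- data.frame(id = 1:100,
                     age = 25, bmi = 22, handedness_score = 80,
                     fcq_trait = sample(30:45, 100, replace = TRUE))
  kept <- screen_participants(cand)
  expect_equal(nrow(kept), sum(cand$fcq_trait >= 38))
  expect_equal(kept$id, cand$id[cand$fcq_trait >= 38])  # order preserved

  cand$bmi[3] <- NA
  kept2 <- screen_participants(cand)
  expect_false(3 %in% kept2$id)
  expect_match(attr(kept2, "screen_log")$reason[
    attr(kept2, "screen_log")$id == 3], "missing")
})

test_that("config validation rejects unbalanceable designs", {
  expect_error(study_config(n_vr_trials = 20, stop_fraction = 0.25),
               "split evenly")
  expect_error(study_config(n_vr_trials = 401), "integer")
  expect_error(study_config(sample_rate = 0))
  expect_silent(study_config(n_participants = 4))
})

test_that("noise-free minimum-jerk trials attain the closed-form peaks", {
  tr <- minjerk_trial(D = 0.6, T_ms = 1000, arcs = FALSE)
  seg <- center_and_segment(tr$samples)
  ser <- kinematic_series(seg)
  par <- extract_parameters(seg, ser, object_depth = 0.6)
  expect_lt(abs(par$pv - 1.125) / 1.125, 0.01)          # 1.875 * D / T
  expect_lt(abs(par$pa - 10 / sqrt(3) * 0.6) / (10 / sqrt(3) * 0.6), 0.02)
  expect_equal(par$maxz, 0.6, tolerance = 1e-9)
  # peak velocity occurs mid-reach
  expect_lt(abs(par$ttpv - (200 + 500)), 10)
})

test_that("an immediate stop halts the hand at the stop-signal depth", {
  cfg <- study_config(position_noise_sd = 0)
  tr <- generate_vr_trial(NULL, "neutral", "stop", cfg, ssd = 150,
                          it = 200, reach_ms = 600, stop_latency = 0)
  expect_true(tr$truth$success)
  expect_equal(tr$truth$bd, 0)
  d_on <- 0.5705 * (10 * (150 / 600)^3 - 15 * (150 / 600)^4 +
                      6 * (150 / 600)^5)
  expect_equal(tr$truth$maxz, d_on, tolerance = 1e-9)
  expect_equal(max(tr$samples$x1_m), d_on, tolerance = 1e-9)
})

test_that("non-positive reach durations are rejected", {
  cfg <- study_config()
  expect_error(generate_vr_trial(NULL, "neutral", "go", cfg, reach_ms = 0),
               "reach duration")
})

test_that("the trial schedule is balanced at the reference design", {
  cfg <- study_config()
  set.seed(1)
  sched <- stopreach:::vr_schedule(cfg)
  tab <- table(sched$category, sched$trial_type)
  expect_equal(sum(sched$trial_type == "stop"), 100)
  expect_equal(sum(sched$trial_type == "go"), 300)
  expect_equal(unname(tab["chocolate", "stop"]), 50)
  expect_equal(unname(tab["neutral", "go"]), 150)
})

test_that("the generator is reproducible and responsive to the intake model", {
  cfg <- study_config(n_participants = 2, n_vr_trials = 8, rng_seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$participants, b$participants)
  expect_identical(a$sst_trials, b$sst_trials)

  # zero noise and a single nonzero weight: intake is an exact linear
  # function of that feature
  cfg2 <- study_config(n_participants = 40, rng_seed = 2,
                       intake_model = list(intercept = 529,
                                           true_weights = c(fcq_trait = 60),
                                           noise_sd = 0))
  ft <- generate_feature_table(cfg2, measurement_noise = FALSE)
  expect_gt(cor(ft$features$fcq_trait, ft$features$intake_kcal), 0.999)
  expect_true(all(ft$features$intake_kcal >= 0))
})

test_that("cohort-level stop success sits in the observed band", {
  cfg <- study_config(n_participants = 8, rng_seed = 4)
  coh <- generate_cohort(cfg)
  st <- coh$ground_truth$trials[coh$ground_truth$trials$trial_type == "stop", ]
  rate <- mean(st$success_true)
  expect_gt(rate, 0.519)
  expect_lte(rate, 1)
  # SSD stays inside the staircase bounds
  expect_true(all(st$participant_id %in% coh$participants$id))
  ssd <- coh$trials$ssd_ms[coh$trials$trial_type == "stop"]
  expect_true(all(ssd >= cfg$vr_staircase$min & ssd <= cfg$vr_staircase$max))
})

test_that("feature tables carry the full predictor set and ground truth", {
  ft <- generate_feature_table(study_config(n_participants = 10,
                                            rng_seed = 3))
  expect_true(all(predictor_set() %in% names(ft$features)))
  expect_equal(nrow(ft$features), 10)
  expect_true(all(c("intake_expected", "pa_choc") %in% names(ft$truth)))
  # cell means: 2 categories x 2 trial types per participant
  expect_equal(nrow(ft$cell_means), 40)
  # chocolate reaches are slower on average (configured category effect)
  cm <- ft$cell_means
  expect_lt(mean(cm$pv[cm$category == "chocolate"]),
            mean(cm$pv[cm$category == "neutral"]))
})
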