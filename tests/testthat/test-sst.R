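test_that("the integration method reproduces the hand-worked example", {
  s <- sst_table(go_rt = c(400, 450, 500, 550, 600),
                 stop_responded = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                 ssd = rep(200, 5), stop_rt = c(420, 430, NA, NA, NA))
  r <- estimate_ssrt(s)
  expect_equal(r$p_respond_stop, 0.4)
  expect_equal(r$ssrt, 250)                  # 2nd of 5 go RTs - 200
  expect_true(r$valid)

  # degenerate go distribution: SSRT = R - S
  s2 <- sst_table(go_rt = rep(480, 6),
                  stop_responded = c(TRUE, FALSE, TRUE, FALSE),
                  ssd = rep(150, 4), stop_rt = c(400, NA, 410, NA))
  expect_equal(estimate_ssrt(s2)$ssrt, 330)
})

test_that("validity gates withhold the estimate", {
  s <- sst_table(go_rt = seq(400, 600, by = 50),
                 stop_responded = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                 ssd = rep(200, 5), stop_rt = c(410, 420, 430, 440, NA))
  r <- estimate_ssrt(s)                      # p = 0.8 out of band
  expect_false(r$valid)
  expect_equal(r$invalid_reason, "stop_prob_out_of_band")
  expect_true(is.na(r$ssrt))

  # signal-respond RT slower than go RT violates the race assumption
  s2 <- sst_table(go_rt = c(400, 420, 440, 460),
                  stop_responded = c(TRUE, TRUE, FALSE, FALSE),
                  ssd = rep(150, 4), stop_rt = c(700, 720, NA, NA))
  r2 <- estimate_ssrt(s2)
  expect_false(r2$valid)
  expect_equal(r2$invalid_reason, "race_violation")

  expect_error(estimate_ssrt(sst_table(go_rt = 500, stop_responded =
                                         logical(0), ssd = numeric(0))),
               "no stop trials")
})

test_that("omission replacement never decreases the selected go quantile", {
  set.seed(17)
  for (i in 1:30) {
    n_go <- sample(10:60, 1)
    go_rt <- round(rnorm(n_go, 600, 120))
    n_om <- sample(1:5, 1)
    responded <- rep(TRUE, n_go); responded[sample(n_go, n_om)] <- FALSE
    stop_resp <- sample(rep(c(TRUE, FALSE), 6))   # p = 0.5, inside the band
    with_om <- sst_table(go_rt, responded, stop_resp, ssd = rep(180, 12),
                         stop_rt = ifelse(stop_resp, 450, NA))
    no_om <- with_om[!(with_om$trial_type == "go" & !with_om$responded), ]
    r1 <- estimate_ssrt(with_om)
    r2 <- estimate_ssrt(no_om)
    expect_gte(r1$ssrt, r2$ssrt)
  }
})

test_that("race-model sessions are scored per category with sane summaries", {
  set.seed(2)
  cfg <- study_config()
  ses <- generate_sst_session(NULL, cfg)
  ses <- cbind(participant_id = "p1", ses)
  res <- score_sst(ses)
  expect_equal(nrow(res), 1)
  expect_true(all(c("ssrt_choc", "ssrt_neut", "rt_go", "ssd_mean",
                    "fa_rate") %in% names(res)))
  expect_gt(res$fa_rate, 0.25)
  expect_lt(res$fa_rate, 0.75)
  # tracking keeps both category estimates near the generating latency
  expect_lt(abs(res$ssrt_choc - 326), 80)
  expect_lt(abs(res$ssrt_neut - 320), 80)
})
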