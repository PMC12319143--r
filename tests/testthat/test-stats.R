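test_that("paired t and Cohen's d follow the dependent-sample definitions", {
  x <- c(3, 5, 7, 9)
  r0 <- paired_t(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect_size, 0)
  expect_equal(r0$p, 1)

  r <- paired_t(c(2, 3, 4), c(1, 1, 1))      # differences 1, 2, 3
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$effect_size, 2, tolerance = 1e-10)
  expect_equal(r$df, 2)

  # constant nonzero difference: flagged, p ~ 0
  rc <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(rc$flag, "zero_variance")
  expect_equal(rc$p, 0)

  # pairwise deletion of missing pairs
  rp <- paired_t(c(1, 2, NA, 4), c(0, NA, 2, 3))
  expect_equal(rp$n, 2)
})

test_that("partial eta squared converts F ratios", {
  expect_equal(partial_eta_sq(0, 1, 73), 0)
  expect_equal(partial_eta_sq(114.71, 1, 73), 0.61, tolerance = 0.005)
  expect_equal(partial_eta_sq(233.20, 1, 73), 0.76, tolerance = 0.005)
  expect_equal(partial_eta_sq(3, 2, 10), 6 / 16)
})

test_that("the 2x2 within-subject ANOVA equals the paired-contrast oracle", {
  set.seed(14)
  for (i in 1:5) {
    n <- 20
    d <- expand.grid(participant_id = seq_len(n),
                     category = c("choc", "neutral"),
                     trial_type = c("go", "stop"))
    d$value <- rnorm(nrow(d)) + rep(rnorm(n), 4) +
      0.4 * (d$category == "choc")
    an <- rm_anova_2x2(d, value = "value")
    # oracle: squared paired t on the per-participant contrast means
    contrast_t <- function(keys) {
      m <- tapply(d$value, list(d$participant_id, keys), mean)
      unname(t.test(m[, 1], m[, 2], paired = TRUE)$statistic)
    }
    t_cat <- contrast_t(d$category)
    t_tt <- contrast_t(d$trial_type)
    expect_equal(an$F[an$effect == "category"], t_cat^2, tolerance = 1e-8)
    expect_equal(an$F[an$effect == "trial_type"], t_tt^2, tolerance = 1e-8)
    inter <- tapply(d$value, list(d$participant_id,
                                  interaction(d$category, d$trial_type)),
                    mean)
    t_int <- unname(t.test(inter[, 1] - inter[, 3],
                           inter[, 2] - inter[, 4],
                           paired = TRUE)$statistic)
    expect_equal(an$F[an$effect == "category:trial_type"], t_int^2,
                 tolerance = 1e-8)
    expect_equal(an$eta_p2,
                 an$F * an$df_num / (an$F * an$df_num + an$df_den))
  }
})

test_that("all-identical cells give zero F ratios", {
  d <- expand.grid(participant_id = 1:8, category = c("a", "b"),
                   trial_type = c("g", "s"))
  d$value <- rep(rnorm(8), 4)                # participant offsets only
  an <- rm_anova_2x2(d, value = "value")
  expect_equal(an$F, rep(0, 3), tolerance = 1e-10)
  expect_error(rm_anova_2x2(d[d$participant_id < 3, ], value = "value"),
               "at least 3")
})

test_that("the generator's category effect on peak velocity is detectable at the study size", {
  detections <- vapply(1:12, function(sd) {
    ft <- generate_feature_table(study_config(rng_seed = 400 + sd))
    an <- rm_anova_2x2(ft$cell_means, value = "pv")
    an$p[an$effect == "category"] < 0.05
  }, logical(1))
  expect_gte(mean(detections), 0.9)
})

test_that("Pearson correlation handles the canonical cases", {
  expect_equal(pearson_r(1:10, 1:10)$statistic, 1)
  expect_equal(pearson_r(1:10, -(1:10))$statistic, -1)
  r <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$statistic, 0.6, tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(pearson_r(c(1, 2, NA, 4, 5), c(2, 1, 4, 3, NA))$n, 3)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_equal(pearson_r(rep(1, 5), rnorm(5))$flag, "zero_variance")
})
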