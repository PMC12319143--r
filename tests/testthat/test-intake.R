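test_that("standardization is exact, drops constants, and supports fold scalers", {
  set.seed(20)
  tab <- data.frame(a = rnorm(30, 5, 2), b = runif(30), c = 1)
  expect_warning(sc <- standardize_features(tab), "zero-variance")
  expect_equal(sc$dropped, "c")
  expect_lt(max(abs(colMeans(sc$data[c("a", "b")]))), 1e-10)
  expect_equal(unname(vapply(sc$data[c("a", "b")], sd, numeric(1))),
               c(1, 1), tolerance = 1e-12)

  # train-fold scaler applied to a test fold, checked by hand on 4 rows
  toy <- data.frame(x = c(2, 4, 6, 8))
  train <- toy[1:2, , drop = FALSE]          # mean 3, sd sqrt(2)
  sc_tr <- standardize_features(train)
  te <- standardize_features(toy[3:4, , drop = FALSE],
                             center = sc_tr$center, scale = sc_tr$scale)
  expect_equal(te$data$x, c((6 - 3) / sqrt(2), (8 - 3) / sqrt(2)))
})

test_that("a noiseless sparse signal is fit exactly and selected by the Lasso", {
  set.seed(4)
  n <- 60
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                   x4 = rnorm(n))
  df$intake_kcal <- 400 + 2 * (df$x1 - mean(df$x1)) / sd(df$x1)
  fit <- intake_fit(df, predictors = paste0("x", 1:4), seed = 2)
  expect_lt(fit$models$ols$mae_in, 1e-8)
  expect_equal(fit$models$lasso$selected, "x1")
  expect_gt(fit$models$lasso$weights[["x1"]], 1)
  # weight reported on the standardized scale
  expect_equal(fit$models$ols$weights[["x1"]], 2, tolerance = 1e-6)
})

test_that("elastic-net weights converge to OLS as the penalty vanishes", {
  set.seed(9)
  n <- 200
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 100 + 30 * x$x1 - 20 * x$x2 + rnorm(n, 0, 5)
  z <- standardize_features(x)
  xm <- as.matrix(z$data)
  ols <- lm.fit(cbind(1, xm), y)$coefficients[-1]
  en <- glmnet::glmnet(xm, y, alpha = 0.5, lambda = c(1, 1e-6),
                       standardize = FALSE, thresh = 1e-12)
  w <- as.numeric(coef(en, s = 1e-6))[-1]
  expect_lt(max(abs(w - ols)), 1e-4)
})

test_that("the Lasso path is monotone in sparsity and honest about noise", {
  set.seed(10)
  n <- 50
  x <- matrix(rnorm(n * 6), n, 6)
  y <- 500 + 40 * x[, 1] + 25 * x[, 2] + rnorm(n, 0, 20)
  fit <- glmnet::glmnet(x, y, alpha = 1, standardize = FALSE)
  # lambda decreases along the path: the active set only grows on this toy
  nz <- fit$df[order(fit$lambda, decreasing = TRUE)]
  expect_true(all(diff(nz) >= 0))

  # all-noise predictors: Lasso collapses towards the intercept-only model
  noise <- data.frame(matrix(rnorm(60 * 5), 60, 5))
  names(noise) <- paste0("x", 1:5)
  noise$intake_kcal <- rnorm(60, 500, 100)
  f2 <- intake_fit(noise, predictors = paste0("x", 1:5), seed = 3)
  expect_lte(length(f2$models$lasso$selected), 2)
  mad0 <- mean(abs(noise$intake_kcal - mean(noise$intake_kcal)))
  expect_lt(abs(f2$models$lasso$mae_out - mad0) / mad0, 0.35)
})

test_that("predict() reproduces fitted values and methods print cleanly", {
  set.seed(30)
  df <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  df$intake_kcal <- 450 + 60 * df$x1 + rnorm(40, 0, 15)
  fit <- intake_fit(df, predictors = c("x1", "x2"), seed = 1)
  pr <- predict(fit, df, model = "ols")
  expect_equal(mean(abs(df$intake_kcal - pr)), fit$models$ols$mae_in,
               tolerance = 1e-8)
  expect_equal(dim(coef(fit)), c(2L, 3L))
  expect_output(print(fit), "out-of-sample")
  expect_output(summary(fit), "Lasso-selected")
})

test_that("the true support is recovered exactly in the noiseless limit", {
  cfg <- study_config(rng_seed = 101,
                      intake_model = list(
                        intercept = 529,
                        true_weights = c(fcq_trait = 60, ssrt_choc = -60,
                                         dwell_total_choc = 60),
                        noise_sd = 0))
  ft <- generate_feature_table(cfg, measurement_noise = FALSE)
  fit <- intake_fit(ft$features, seed = 5)
  expect_true(all(names(cfg$intake_model$true_weights) %in%
                    fit$models$lasso$selected))
  expect_lt(fit$models$ols$mae_in, 1e-6)
})
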