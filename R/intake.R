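# Intake prediction from the standardized predictor set: ordinary least
# squares, elastic net over a mixing-parameter grid, and Lasso, selected by
# K-fold cross-validated mean absolute error. Predictors are standardized
# with training-fold statistics only when cross-validating; the outcome
# stays in kcal so MAE is interpretable.

#' Standardize a feature table
#'
#' Centres and scales each predictor to mean 0, SD 1. Zero-variance
#' predictors are dropped with a warning. When `center`/`scale` are
#' supplied (e.g. training-fold statistics), they are applied instead of
#' the table's own.
#'
#' @param table data.frame of numeric predictors.
#' @param predictors columns to standardize (default: all numeric columns).
#' @param center,scale optional named vectors of pre-computed statistics.
#' @return list: `data` (standardized data.frame), `center`, `scale`,
#'   `dropped` (names of zero-variance predictors).
#' @export
standardize_features <- function(table, predictors = NULL, center = NULL,
                                 scale = NULL) {
  if (is.null(predictors))
    predictors <- names(table)[vapply(table, is.numeric, logical(1))]
  if (nrow(table) < 2L && is.null(center))
    stop("need at least 2 rows to estimate scaling")
  dropped <- character(0)
  if (is.null(center)) {
    center <- vapply(table[predictors], mean, numeric(1))
    scale <- vapply(table[predictors], sd_sample, numeric(1))
    dropped <- predictors[is.na(scale) | scale == 0]
    if (length(dropped)) {
      warning("dropping zero-variance predictor(s): ",
              paste(dropped, collapse = ", "))
      predictors <- setdiff(predictors, dropped)
      center <- center[predictors]; scale <- scale[predictors]
    }
  } else {
    predictors <- names(center)
  }
  out <- table
  for (nm in predictors)
    out[[nm]] <- (table[[nm]] - center[[nm]]) / scale[[nm]]
  out <- out[, c(setdiff(names(table), dropped)), drop = FALSE]
  list(data = out, center = center, scale = scale, dropped = dropped)
}

mae <- function(obs, pred) mean(abs(obs - pred))

# Deterministic fold assignment for n observations.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# Elastic-net CV over (alpha, lambda): for each alpha the lambda path comes
# from the full-data glmnet fit; each fold re-standardizes with its own
# training statistics; the CV curve is averaged over repeated fold
# assignments to stabilise the hyperparameter choice; the (alpha, lambda)
# pair minimising mean held-out MAE wins.
cv_glmnet_mae <- function(x, y, alpha_grid, fold_reps, nlambda,
                          lambda_min_ratio) {
  best <- list(cvm = Inf)
  zfull <- standardize_features(x)
  xz <- as.matrix(zfull$data[, names(zfull$center), drop = FALSE])
  for (alpha in alpha_grid) {
    full <- glmnet::glmnet(xz, y, alpha = alpha,
                           nlambda = nlambda,
                           lambda.min.ratio = lambda_min_ratio,
                           standardize = FALSE)
    lam <- full$lambda
    err <- NULL
    for (folds in fold_reps) {
      for (f in seq_len(max(folds))) {
        tr <- folds != f
        sc <- standardize_features(x[tr, , drop = FALSE])
        xte <- standardize_features(x[!tr, , drop = FALSE],
                                    center = sc$center,
                                    scale = sc$scale)$data
        fit <- glmnet::glmnet(as.matrix(sc$data), y[tr], alpha = alpha,
                              lambda = lam, standardize = FALSE)
        pred <- stats::predict(fit,
                               newx = as.matrix(xte[, names(sc$center)]))
        row <- rep(NA_real_, length(lam))
        row[seq_len(ncol(pred))] <- apply(pred, 2, function(p)
          mae(y[!tr], p))
        err <- rbind(err, row)
      }
    }
    cvm <- colMeans(err)
    i <- which.min(cvm)
    if (cvm[i] < best$cvm)
      best <- list(alpha = alpha, lambda = lam[i], cvm = cvm[i], path = full)
  }
  best
}

#' Fit the intake prediction models
#'
#' Fits ordinary least squares, elastic net (mixing parameter selected over
#' `alpha_grid`) and Lasso (mixing 1) to predict the outcome (kcal) from the
#' standardized predictor set. Penalty strength is chosen by K-fold
#' cross-validated mean absolute error with fold-wise standardization; the
#' reported out-of-sample MAE is the mean held-out MAE at the selected
#' hyperparameters, the in-sample MAE is measured on the full training
#' data. Weights are reported on the standardized scale (kcal per SD).
#'
#' @param features data.frame holding the predictors and the outcome;
#'   incomplete rows are removed (complete-case analysis).
#' @param outcome outcome column name (kept in kcal).
#' @param predictors predictor column names (default [predictor_set()]
#'   intersected with the table).
#' @param alpha_grid elastic-net mixing grid.
#' @param nfolds number of CV folds.
#' @param cv_repeats number of repeated fold assignments over which the CV
#'   error curve is averaged before selecting hyperparameters (stabilises
#'   the penalty choice at small n).
#' @param seed integer seed fixing the fold assignments.
#' @param nlambda,lambda_min_ratio geometry of the penalty path (log-spaced
#'   from the null-model penalty down by `lambda_min_ratio`).
#' @return object of class `intake_fit` with elements `models` (named list
#'   `ols`, `elastic_net`, `lasso`; each with `weights`, `intercept`,
#'   `selected`, `mae_in`, `mae_out`, `alpha`, `lambda`), `scaler`, `n`,
#'   `predictors`, `outcome`, `folds`, `seed`.
#' @examples
#' set.seed(1)
#' df <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
#' df$intake_kcal <- 500 + 100 * df$x1 + rnorm(40, 0, 10)
#' fit <- intake_fit(df, predictors = c("x1", "x2"), seed = 1)
#' coef(fit)
#' @export
intake_fit <- function(features, outcome = "intake_kcal",
                       predictors = NULL,
                       alpha_grid = seq(0.1, 0.9, by = 0.1),
                       nfolds = 5L, cv_repeats = 1L, seed = 1L,
                       nlambda = 50L, lambda_min_ratio = 1e-4) {
  if (is.null(predictors))
    predictors <- intersect(predictor_set(), names(features))
  if (!length(predictors)) stop("no predictors found in the feature table")
  dat <- features[, c(predictors, outcome)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= nfolds) stop("need more complete cases than folds")
  y <- dat[[outcome]]
  xraw <- dat[, predictors, drop = FALSE]
  sc <- standardize_features(xraw)
  predictors <- names(sc$center)
  x <- as.matrix(sc$data[, predictors, drop = FALSE])
  fold_reps <- lapply(seq_len(cv_repeats), function(r)
    make_folds(n, nfolds, seed + (r - 1L)))
  folds <- fold_reps[[1L]]

  models <- list()

  # --- ordinary least squares ------------------------------------------
  ols <- stats::lm.fit(cbind(1, x), y)
  cf_ols <- ols$coefficients
  cf_ols[is.na(cf_ols)] <- 0                # aliased (collinear) columns
  w_ols <- stats::setNames(cf_ols[-1], predictors)
  mae_in_ols <- mae(y, cbind(1, x) %*% cf_ols)
  cv_ols <- vapply(seq_len(nfolds), function(f) {
    tr <- folds != f                        # first fold assignment
    sctr <- standardize_features(xraw[tr, , drop = FALSE])
    xtr <- as.matrix(sctr$data[, names(sctr$center), drop = FALSE])
    xte <- as.matrix(standardize_features(
      xraw[!tr, , drop = FALSE], center = sctr$center,
      scale = sctr$scale)$data[, names(sctr$center), drop = FALSE])
    b <- stats::lm.fit(cbind(1, xtr), y[tr])$coefficients
    b[is.na(b)] <- 0                        # aliased columns predict nothing
    mae(y[!tr], cbind(1, xte) %*% b)
  }, numeric(1))
  models$ols <- list(weights = w_ols, intercept = ols$coefficients[1],
                     selected = predictors, mae_in = mae_in_ols,
                     mae_out = mean(cv_ols), alpha = NA_real_,
                     lambda = 0)

  # --- elastic net and Lasso -------------------------------------------
  for (spec in list(list(name = "elastic_net", grid = alpha_grid),
                    list(name = "lasso", grid = 1))) {
    best <- cv_glmnet_mae(xraw, y, spec$grid, fold_reps, nlambda,
                          lambda_min_ratio)
    fit <- glmnet::glmnet(x, y, alpha = best$alpha, standardize = FALSE,
                          nlambda = nlambda,
                          lambda.min.ratio = lambda_min_ratio)
    cf <- as.numeric(stats::predict(fit, s = best$lambda, type = "coef",
                                    exact = TRUE, x = x, y = y))
    w <- stats::setNames(cf[-1], predictors)
    pred_in <- as.numeric(stats::predict(fit, newx = x, s = best$lambda,
                                         exact = TRUE, x = x, y = y))
    models[[spec$name]] <- list(weights = w, intercept = cf[1],
                                selected = predictors[w != 0],
                                mae_in = mae(y, pred_in),
                                mae_out = best$cvm,
                                alpha = best$alpha, lambda = best$lambda)
  }

  structure(list(models = models, scaler = sc[c("center", "scale")],
                 n = n, predictors = predictors, outcome = outcome,
                 folds = folds, nfolds = nfolds, seed = seed),
            class = "intake_fit")
}

#' @exportS3Method base::print
print.intake_fit <- function(x, ...) {
  cat(sprintf("Intake prediction fits (n = %d, %d predictors, %d-fold CV)\n",
              x$n, length(x$predictors), x$nfolds))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-11s in-sample MAE %6.1f kcal, out-of-sample %6.1f kcal, %d feature(s)%s\n",
                nm, m$mae_in, m$mae_out, length(m$selected),
                if (!is.na(m$alpha))
                  sprintf(" (alpha = %.1f, lambda = %.3g)", m$alpha,
                          m$lambda)
                else ""))
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.intake_fit <- function(object, ...) {
  w <- coef(object)
  sel <- object$models$lasso$selected
  cat(sprintf("Standardized weights (kcal per SD), n = %d\n", object$n))
  print(round(w, 2))
  cat("Lasso-selected features:",
      if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n")
  invisible(w)
}

#' @exportS3Method
coef.intake_fit <- function(object, ...) {
  sapply(object$models, function(m) m$weights[object$predictors])
}

#' Predict intake for new participants
#'
#' @param object an `intake_fit`.
#' @param newdata data.frame containing the predictor columns on their
#'   original scales.
#' @param model which fitted model to use.
#' @param ... unused.
#' @return numeric vector of predicted intake in kcal.
#' @exportS3Method
predict.intake_fit <- function(object, newdata,
                               model = c("lasso", "elastic_net", "ols"),
                               ...) {
  model <- match.arg(model)
  m <- object$models[[model]]
  z <- standardize_features(newdata[, object$predictors, drop = FALSE],
                            center = object$scaler$center,
                            scale = object$scaler$scale)$data
  as.numeric(as.matrix(z[, object$predictors, drop = FALSE]) %*%
               m$weights + m$intercept)
}

#' Weight profile plot of the fitted intake models
#'
#' Grouped bar chart of the standardized weights of the linear, elastic-net
#' and Lasso fits, one group per predictor.
#'
#' @param x an `intake_fit`.
#' @param ... passed to [graphics::barplot()].
#' @exportS3Method
plot.intake_fit <- function(x, ...) {
  w <- t(coef(x))
  graphics::barplot(w, beside = TRUE, las = 2,
                    legend.text = rownames(w),
                    ylab = sprintf("standardized weight (kcal per SD of %s)",
                                   x$outcome),
                    args.legend = list(x = "topright", bty = "n"), ...)
  invisible(x)
}
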