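# Group-level inferential statistics: paired t-tests with Cohen's d
# (d = t / sqrt(n), i.e. mean difference over the SD of differences),
# 2x2 repeated-measures ANOVA with partial eta squared, and Pearson
# correlations. All tests two-sided at the conventional alpha = 0.05; no
# multiplicity correction is applied.

#' Paired (dependent-sample) t-test with Cohen's d
#'
#' Pairs with a missing value in either member are deleted pairwise.
#' Cohen's d for the paired design is `t / sqrt(n)`.
#'
#' @param x,y numeric vectors of per-participant values under the two
#'   conditions (equal length).
#' @return list of class `test_report`: `statistic`, `df`, `p`,
#'   `effect_size` (d), `n`, `flag`.
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1))   # differences 1, 2, 3 -> t = 3.46, d = 2
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  sdd <- sd_sample(d)
  flag <- ""
  if (sdd == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0; flag <- "zero_variance"
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(statistic = t_stat, df = n - 1L, p = p,
                 effect_size = if (is.finite(t_stat)) t_stat / sqrt(n)
                               else sign(t_stat) * Inf,
                 n = n, flag = flag),
            class = "test_report")
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = (F * df_num) / (F * df_num + df_den)`.
#'
#' @param f F statistic (>= 0).
#' @param df_num,df_den numerator and denominator degrees of freedom.
#' @return partial eta squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(114.71, 1, 73)   # 0.61
#' @export
partial_eta_sq <- function(f, df_num = 1, df_den) {
  stopifnot(all(f >= 0), df_num >= 1, all(df_den >= 1))
  (f * df_num) / (f * df_num + df_den)
}

#' 2x2 repeated-measures ANOVA with partial eta squared
#'
#' Within-subject ANOVA over two crossed two-level factors. Participants
#' without all four cells are removed listwise; multiple values per cell
#' are averaged first. In the 2x2 case each effect's F equals the squared
#' paired t on the corresponding difference contrast.
#'
#' @param data data.frame in long format.
#' @param id,a,b,value column names of the participant identifier, the two
#'   factors, and the response.
#' @return data.frame with one row per effect (`a`, `b`, `a:b`): `effect`,
#'   `F`, `df_num`, `df_den`, `p`, `eta_p2`, `n`.
#' @export
rm_anova_2x2 <- function(data, id = "participant_id", a = "category",
                         b = "trial_type", value = "value") {
  d <- data.frame(id = factor(data[[id]]), a = factor(data[[a]]),
                  b = factor(data[[b]]), y = data[[value]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$a)) != 2L || nlevels(droplevels(d$b)) != 2L)
    stop("both factors must have exactly 2 observed levels")
  d <- stats::aggregate(y ~ id + a + b, data = d, FUN = mean)
  counts <- table(d$id)
  keep <- names(counts)[counts == 4L]
  d <- d[d$id %in% keep, , drop = FALSE]
  d$id <- droplevels(d$id)
  n <- nlevels(d$id)
  if (n < 3L) stop("need at least 3 participants with complete 2x2 cells")
  fit <- stats::aov(y ~ a * b + Error(id / (a * b)), data = d)
  sm <- summary(fit)
  ss_total <- stats::var(d$y) * (nrow(d) - 1)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    out <- data.frame(F = tab[i, "F value"], df_num = tab[i, "Df"],
                      df_den = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
    # an effect with no sum of squares is a null effect even when the
    # error stratum is also empty (0/0 otherwise)
    if (tab[i, "Sum Sq"] <= 1e-10 * max(ss_total, 1e-12)) {
      out$F <- 0; out$p <- 1
    }
    out
  }
  out <- rbind(cbind(effect = a, pick("Error: id:a", "a")),
               cbind(effect = b, pick("Error: id:b", "b")),
               cbind(effect = paste(a, b, sep = ":"),
                     pick("Error: id:a:b", "a:b")))
  out$eta_p2 <- partial_eta_sq(out$F, out$df_num, out$df_den)
  out$n <- n
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Pairwise-complete observations; two-sided p with `df = n - 2`.
#'
#' @param x,y numeric vectors.
#' @return list of class `test_report`: `statistic` (r), `df`, `p`, `n`,
#'   `flag` (`"zero_variance"` when undefined).
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd_sample(x) == 0 || sd_sample(y) == 0) {
    return(structure(list(statistic = NA_real_, df = n - 2L, p = NA_real_,
                          effect_size = NA_real_, n = n,
                          flag = "zero_variance"), class = "test_report"))
  }
  ct <- stats::cor.test(x, y)
  structure(list(statistic = unname(ct$estimate), df = n - 2L,
                 p = ct$p.value, effect_size = unname(ct$estimate), n = n,
                 flag = ""), class = "test_report")
}

#' @exportS3Method base::print
print.test_report <- function(x, ...) {
  cat(sprintf("statistic = %.3f, df = %d, p = %.4g, effect = %.3f, n = %d%s\n",
              x$statistic, x$df, x$p, x$effect_size, x$n,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Condition-level results table for the biometric parameters
#'
#' For every variable in a wide cell-summary table, reports the chocolate
#' and neutral condition means (SD), the 2x2 ANOVA category effect (or a
#' paired t where only one trial type carries the variable), and the
#' Pearson correlation of the chocolate-trial and neutral-trial values with
#' intake.
#'
#' @param cells wide per-cell table (see [summary_wide()]): one row per
#'   participant x category x trial_type with parameter columns.
#' @param intake data.frame with `participant_id`, `intake_kcal`.
#' @param vars parameter columns to report.
#' @return data.frame with one row per parameter x trial-type slice:
#'   condition means/SDs, `F`, `p`, `eta_p2`, `r_choc`, `r_neutral`.
#' @export
group_statistics <- function(cells, intake,
                             vars = setdiff(names(cells),
                                            c("participant_id", "category",
                                              "trial_type"))) {
  rows <- list()
  for (v in vars) {
    for (tt in unique(cells$trial_type)) {
      sl <- cells[cells$trial_type == tt, c("participant_id", "category", v)]
      sl <- sl[!is.na(sl[[v]]), , drop = FALSE]
      if (nrow(sl) == 0L) next
      w <- stats::reshape(sl, idvar = "participant_id",
                          timevar = "category", direction = "wide")
      ch <- w[[paste0(v, ".chocolate")]]
      ne <- w[[paste0(v, ".neutral")]]
      if (is.null(ch) || is.null(ne) || sum(!is.na(ch) & !is.na(ne)) < 3)
        next
      tst <- paired_t(ch, ne)
      ik <- intake$intake_kcal[match(w$participant_id,
                                     intake$participant_id)]
      r_ch <- tryCatch(pearson_r(ch, ik)$statistic, error = function(e) NA)
      r_ne <- tryCatch(pearson_r(ne, ik)$statistic, error = function(e) NA)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = v, trial_type = tt,
        m_choc = mean(ch, na.rm = TRUE), sd_choc = sd_sample(ch),
        m_neutral = mean(ne, na.rm = TRUE), sd_neutral = sd_sample(ne),
        t = tst$statistic, df = tst$df, p = tst$p, d = tst$effect_size,
        F_equiv = tst$statistic^2,
        r_choc = r_ch, r_neutral = r_ne, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(parameter = character(0), trial_type = character(0),
                      m_choc = numeric(0), sd_choc = numeric(0),
                      m_neutral = numeric(0), sd_neutral = numeric(0),
                      t = numeric(0), df = integer(0), p = numeric(0),
                      d = numeric(0), F_equiv = numeric(0),
                      r_choc = numeric(0), r_neutral = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
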