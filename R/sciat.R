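# Single-category IAT D-scoring, following the improved-algorithm
# conventions: trials above 10 s dropped; participants with more than 10%
# of trials under 300 ms or with low overall accuracy rejected; error-trial
# RTs replaced by the block mean of correct RTs plus a 600 ms penalty; the
# D-score is the incompatible-minus-compatible mean difference divided by
# the pooled SD of all (correct + penalised) RTs across both blocks.
# Negative D means the avoidance pairing was answered faster.

#' Scoring rules for the SC-IAT D-score
#'
#' @param rt_max trials with RT above this are dropped (ms).
#' @param fast_rt,max_fast_prop participant rejected when more than
#'   `max_fast_prop` of trials are faster than `fast_rt` ms.
#' @param min_accuracy participant rejected below this overall accuracy.
#' @param error_penalty added to the block correct-RT mean for error trials
#'   (ms).
#' @param phase which phase to score (`"test"`; set `NULL` to use every
#'   trial, e.g. for sessions recorded without a practice phase).
#' @return list of class `sciat_rules`.
#' @export
sciat_rules <- function(rt_max = 10000, fast_rt = 300, max_fast_prop = 0.10,
                        min_accuracy = 0.70, error_penalty = 600,
                        phase = "test") {
  structure(list(rt_max = rt_max, fast_rt = fast_rt,
                 max_fast_prop = max_fast_prop, min_accuracy = min_accuracy,
                 error_penalty = error_penalty, phase = phase),
            class = "sciat_rules")
}

#' Compute the SC-IAT D-score for one session
#'
#' @param session data.frame with `block` (`"compatible"`/`"incompatible"`),
#'   `rt_ms`, `correct`, and optionally `phase`.
#' @param rules a [sciat_rules()] object.
#' @return list of class `sciat_result`: `d`, `mean_compatible`,
#'   `mean_incompatible`, `pooled_sd`, `valid`, `invalid_reason`.
#' @examples
#' s <- data.frame(block = rep(c("compatible", "incompatible"), each = 2),
#'                 rt_ms = c(500, 600, 700, 800), correct = TRUE)
#' compute_dscore(s)$d   # 200 / 129.10 = 1.549
#' @export
compute_dscore <- function(session, rules = sciat_rules()) {
  s <- session
  if (!is.null(rules$phase) && "phase" %in% names(s))
    s <- s[s$phase == rules$phase, , drop = FALSE]
  if (!all(c("compatible", "incompatible") %in% s$block))
    return(invalid_sciat("block_missing"))
  s <- s[s$rt_ms <= rules$rt_max, , drop = FALSE]
  if (nrow(s) == 0L) return(invalid_sciat("empty_block"))
  fast_prop <- mean(s$rt_ms < rules$fast_rt)
  accuracy <- mean(s$correct %in% TRUE)
  if (fast_prop > rules$max_fast_prop)
    return(invalid_sciat("too_many_fast_trials"))
  if (accuracy < rules$min_accuracy)
    return(invalid_sciat("low_accuracy"))

  block_vals <- lapply(c("compatible", "incompatible"), function(b) {
    bl <- s[s$block == b, , drop = FALSE]
    ok <- bl$correct %in% TRUE
    if (!any(ok)) return(NULL)
    rt <- bl$rt_ms
    rt[!ok] <- mean(bl$rt_ms[ok]) + rules$error_penalty
    rt
  })
  if (any(vapply(block_vals, is.null, logical(1))))
    return(invalid_sciat("empty_block"))
  m_comp <- mean(block_vals[[1]])
  m_inc <- mean(block_vals[[2]])
  pooled <- sd_sample(c(block_vals[[1]], block_vals[[2]]))
  if (is.na(pooled) || pooled == 0) return(invalid_sciat("zero_variance"))
  structure(list(d = (m_inc - m_comp) / pooled,
                 mean_compatible = m_comp, mean_incompatible = m_inc,
                 pooled_sd = pooled, valid = TRUE, invalid_reason = "none"),
            class = "sciat_result")
}

invalid_sciat <- function(reason) {
  structure(list(d = NA_real_, mean_compatible = NA_real_,
                 mean_incompatible = NA_real_, pooled_sd = NA_real_,
                 valid = FALSE, invalid_reason = reason),
            class = "sciat_result")
}

#' @exportS3Method base::print
print.sciat_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("D = %.3f (compatible %.0f ms, incompatible %.0f ms)\n",
                x$d, x$mean_compatible, x$mean_incompatible))
  else cat(sprintf("D-score withheld: %s\n", x$invalid_reason))
  invisible(x)
}

#' Score a multi-participant SC-IAT trial table
#'
#' @param sessions data.frame with `participant_id` plus the columns of
#'   [compute_dscore()].
#' @param rules a [sciat_rules()] object.
#' @return data.frame, one row per participant: `d_score`, `valid`,
#'   `invalid_reason`.
#' @export
score_sciat <- function(sessions, rules = sciat_rules()) {
  ids <- unique(sessions$participant_id)
  rows <- lapply(ids, function(id) {
    r <- compute_dscore(sessions[sessions$participant_id == id, ,
                                 drop = FALSE], rules)
    data.frame(participant_id = id, d_score = r$d, valid = r$valid,
               invalid_reason = r$invalid_reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
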