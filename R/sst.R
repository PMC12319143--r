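# Stop-signal session scoring: go/stop summaries and SSRT by the
# integration method with replacement of response omissions, with the
# standard validity gates (stop probability within 0.25-0.75 and
# signal-respond RT not exceeding go RT, as the race model requires).

#' Estimate SSRT with the integration method
#'
#' Go omissions are replaced by the maximum observed go RT; go RTs are
#' sorted ascending; the stop latency is the `n`th go RT minus the mean SSD,
#' with `n = ceiling(p_respond_stop * N_go)` clamped to `[1, N_go]`. The
#' estimate is withheld (result invalid) when the stop probability falls
#' outside `p_band` or when the mean signal-respond RT exceeds the mean go
#' RT (race-model violation).
#'
#' @param session data.frame of trials for one participant with columns
#'   `trial_type` (`"go"`/`"stop"`), `rt_ms`, `responded`, `ssd_ms`, and
#'   optionally `category` and `correct`.
#' @param category optional category label to score (`NULL` scores all
#'   trials together).
#' @param p_band admissible stop-respond probability band.
#' @param exclude_choice_errors drop go trials with `correct == FALSE`
#'   before scoring (default keeps them with their RTs).
#' @return list of class `sst_result`: `ssrt`, `go_rt_mean`, `ssd_mean`,
#'   `p_respond_stop`, `n_go`, `n_stop`, `valid`, `invalid_reason` (one of
#'   `"none"`, `"stop_prob_out_of_band"`, `"race_violation"`).
#' @examples
#' s <- data.frame(trial_type = c(rep("go", 5), rep("stop", 5)),
#'                 rt_ms = c(400, 450, 500, 550, 600, 420, 430, NA, NA, NA),
#'                 responded = c(rep(TRUE, 7), FALSE, FALSE, FALSE),
#'                 ssd_ms = c(rep(NA, 5), rep(200, 5)))
#' estimate_ssrt(s)$ssrt   # 2nd of 5 sorted go RTs - 200 = 250 ms
#' @export
estimate_ssrt <- function(session, category = NULL,
                          p_band = c(0.25, 0.75),
                          exclude_choice_errors = FALSE) {
  s <- session
  if (!is.null(category) && "category" %in% names(s))
    s <- s[s$category == category, , drop = FALSE]
  go <- s[s$trial_type == "go", , drop = FALSE]
  stp <- s[s$trial_type == "stop", , drop = FALSE]
  if (nrow(stp) == 0L) stop("no stop trials in session")
  if (nrow(go) == 0L) stop("no go trials in session")
  if (exclude_choice_errors && "correct" %in% names(go))
    go <- go[is.na(go$correct) | go$correct, , drop = FALSE]

  observed <- go$rt_ms[go$responded %in% TRUE & !is.na(go$rt_ms)]
  if (length(observed) == 0L) stop("no responded go trials")
  go_rts <- go$rt_ms
  go_rts[!(go$responded %in% TRUE) | is.na(go_rts)] <- max(observed)
  go_rts <- sort(go_rts)
  n_go <- length(go_rts)

  p <- mean(stp$responded %in% TRUE)
  ssd_mean <- mean(stp$ssd_ms, na.rm = TRUE)
  sr_rt <- stp$rt_ms[stp$responded %in% TRUE & !is.na(stp$rt_ms)]
  go_mean <- mean(observed)

  reason <- "none"
  valid <- TRUE
  if (p < p_band[1] || p > p_band[2]) {
    valid <- FALSE; reason <- "stop_prob_out_of_band"
  } else if (length(sr_rt) > 0 && mean(sr_rt) > go_mean) {
    valid <- FALSE; reason <- "race_violation"
  }
  nth <- min(max(ceiling(p * n_go), 1L), n_go)
  ssrt <- if (valid) go_rts[nth] - ssd_mean else NA_real_
  structure(list(ssrt = ssrt, go_rt_mean = go_mean, ssd_mean = ssd_mean,
                 p_respond_stop = p, n_go = n_go, n_stop = nrow(stp),
                 valid = valid, invalid_reason = reason),
            class = "sst_result")
}

#' @exportS3Method base::print
print.sst_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("SSRT = %.1f ms (go RT %.0f, mean SSD %.0f, p(respond|stop) = %.2f)\n",
                x$ssrt, x$go_rt_mean, x$ssd_mean, x$p_respond_stop))
  else
    cat(sprintf("SSRT withheld: %s (p(respond|stop) = %.2f)\n",
                x$invalid_reason, x$p_respond_stop))
  invisible(x)
}

#' Score a multi-participant stop-signal trial table
#'
#' Computes per-participant, per-category SSRT results plus overall go RT,
#' mean SSD and false-alarm (stop-respond) rate.
#'
#' @param sessions data.frame with `participant_id` plus the columns of
#'   [estimate_ssrt()].
#' @param categories category labels to score separately.
#' @return data.frame, one row per participant: `ssrt_<category>` per
#'   category with validity columns, `rt_go`, `ssd_mean`, `fa_rate`,
#'   `valid`.
#' @export
score_sst <- function(sessions, categories = c("chocolate", "neutral")) {
  ids <- unique(sessions$participant_id)
  rows <- lapply(ids, function(id) {
    s <- sessions[sessions$participant_id == id, , drop = FALSE]
    row <- data.frame(participant_id = id, stringsAsFactors = FALSE)
    all_valid <- TRUE
    for (cat in categories) {
      r <- estimate_ssrt(s, category = cat)
      suffix <- substr(cat, 1, 4)
      row[[paste0("ssrt_", suffix)]] <- r$ssrt
      row[[paste0("p_respond_", suffix)]] <- r$p_respond_stop
      all_valid <- all_valid && r$valid
    }
    go <- s[s$trial_type == "go" & s$responded %in% TRUE, , drop = FALSE]
    stp <- s[s$trial_type == "stop", , drop = FALSE]
    row$rt_go <- mean(go$rt_ms, na.rm = TRUE)
    row$ssd_mean <- mean(stp$ssd_ms, na.rm = TRUE)
    row$fa_rate <- mean(stp$responded %in% TRUE)
    row$valid <- all_valid
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
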