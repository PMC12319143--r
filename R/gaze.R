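# Dwell-time analysis of per-sample gaze-on-stimulus collision streams.

#' Dwell times from a boolean gaze-collision stream
#'
#' Computes the initial dwell time (duration of the first contiguous
#' gaze-on-stimulus run, ending at the first detachment) and the total dwell
#' time (summed duration of all runs in the trial). Short tracker dropouts
#' are bridged: miss-runs of at most `dropout_tolerance` samples flanked by
#' hits count as part of the surrounding fixation.
#'
#' @param gaze_hits logical vector, one element per sample.
#' @param sample_rate sampling rate in Hz (default 120).
#' @param dropout_tolerance maximum bridged gap in samples (default 1).
#' @param from_onset_only when `TRUE`, the first dwell must start at the
#'   first sample (stimulus onset); otherwise the first hit-run anywhere in
#'   the trial counts as the initial fixation (default).
#' @return list of class `gaze_summary`: `dwell_first` (ms), `dwell_total`
#'   (ms), `n_fixation_bouts`, `flag` (`"no_gaze_contact"` for all-miss
#'   streams).
#' @examples
#' compute_dwell(c(rep(TRUE, 12), FALSE, rep(TRUE, 11)))  # bridged: 200 ms
#' @export
compute_dwell <- function(gaze_hits, sample_rate = 120,
                          dropout_tolerance = 1L, from_onset_only = FALSE) {
  stopifnot(dropout_tolerance >= 0, sample_rate > 0)
  hits <- as.logical(gaze_hits)
  period <- 1000 / sample_rate
  if (!any(hits)) {
    return(structure(list(dwell_first = 0, dwell_total = 0,
                          n_fixation_bouts = 0L, flag = "no_gaze_contact"),
                     class = "gaze_summary"))
  }
  bridged <- bridge_gaps(hits, dropout_tolerance)
  r <- rle(bridged)
  run_len <- r$lengths[r$values]
  first_run <- run_len[1]
  if (from_onset_only && !bridged[1]) first_run <- 0
  structure(list(dwell_first = first_run * period,
                 dwell_total = sum(run_len) * period,
                 n_fixation_bouts = length(run_len), flag = ""),
            class = "gaze_summary")
}

# Turn miss-runs of length <= tol that are flanked by hits into hits.
bridge_gaps <- function(hits, tol) {
  if (tol < 1L) return(hits)
  r <- rle(hits)
  n <- length(r$lengths)
  for (i in seq_len(n)) {
    if (!r$values[i] && r$lengths[i] <= tol && i > 1L && i < n)
      r$values[i] <- TRUE
  }
  inverse.rle(r)
}

#' @exportS3Method base::print
print.gaze_summary <- function(x, ...) {
  cat(sprintf("dwell_first = %.1f ms, dwell_total = %.1f ms (%d bouts)%s\n",
              x$dwell_first, x$dwell_total, x$n_fixation_bouts,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Per-trial dwell times from a long-format trial table
#'
#' @param trials long-format sample table with `participant_id`,
#'   `trial_index`, `category`, `trial_type`, `gaze_hit` and `t_ms`.
#' @param sample_rate sampling rate in Hz.
#' @param dropout_tolerance see [compute_dwell()].
#' @return data.frame with one row per trial: keys plus `dwell_first`,
#'   `dwell_total`, `n_fixation_bouts`.
#' @export
extract_gaze <- function(trials, sample_rate = 120, dropout_tolerance = 1L) {
  key <- paste(trials$participant_id, trials$trial_index, sep = "\r")
  idx <- split(seq_len(nrow(trials)), key)
  rows <- lapply(idx, function(i) {
    tr <- trials[i, , drop = FALSE]
    g <- compute_dwell(tr$gaze_hit, sample_rate, dropout_tolerance)
    data.frame(participant_id = tr$participant_id[1],
               trial_index = tr$trial_index[1],
               category = tr$category[1], trial_type = tr$trial_type[1],
               dwell_first = g$dwell_first, dwell_total = g$dwell_total,
               n_fixation_bouts = g$n_fixation_bouts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$trial_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
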