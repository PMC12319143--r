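# Trajectory preprocessing and biometric parameter extraction.
#
# Per-trial chain: centre to the first sample, segment from stimulus onset
# to the earliest attainment of the maximal depth displacement, detect
# movement initiation by a 3D displacement threshold, differentiate the
# smoothed path for speed/acceleration, and read off the per-trial
# parameters (PV, PA, TTPV, TTPA, maxZ, RT; TTS/BD/ACC on stop trials).
# Kinematic peaks are always computed on the unstandardised trajectory;
# time standardisation is provided separately for plotting and averaging.

#' Centre and segment a raw trial
#'
#' Translates all samples so the first one is the origin and truncates the
#' trial after the first attainment of the maximal depth (`x1`)
#' displacement; ties are broken by the earliest sample.
#'
#' @param samples data.frame with `t_ms`, `x1_m`, `x2_m`, `x3_m` (strictly
#'   increasing `t_ms`, first sample at stimulus onset).
#' @return list of class `segmented_trial`: `t`, `x1`, `x2`, `x3`,
#'   `usable`, `reason`. Trials with fewer than 3 samples are flagged
#'   unusable.
#' @examples
#' s <- data.frame(t_ms = c(0, 100, 200, 300, 400),
#'                 x1_m = c(0, 0.3, 0.55, 0.54, 0.55),
#'                 x2_m = 0, x3_m = 0)
#' center_and_segment(s)$t   # ends at 200 ms (earliest max)
#' @export
center_and_segment <- function(samples) {
  if (nrow(samples) < 3L)
    return(structure(list(t = samples$t_ms, x1 = NULL, x2 = NULL, x3 = NULL,
                          usable = FALSE, reason = "fewer_than_3_samples"),
                     class = "segmented_trial"))
  if (any(diff(samples$t_ms) <= 0))
    stop("timestamps must be strictly increasing")
  x1 <- samples$x1_m - samples$x1_m[1]
  x2 <- samples$x2_m - samples$x2_m[1]
  x3 <- samples$x3_m - samples$x3_m[1]
  k <- which.max(x1)                      # which.max takes the earliest tie
  if (x1[k] <= x1[1]) k <- length(x1)     # no forward displacement: keep all
  k <- max(k, 2L)                         # keep at least two samples
  idx <- seq_len(k)
  structure(list(t = samples$t_ms[idx], x1 = x1[idx], x2 = x2[idx],
                 x3 = x3[idx], usable = TRUE, reason = ""),
            class = "segmented_trial")
}

#' Detect movement initiation time
#'
#' Returns the linearly interpolated time at which the 3D displacement from
#' the origin first exceeds `threshold` (the dynamic-starting-line
#' convention).
#'
#' @param seg a `segmented_trial`.
#' @param threshold displacement threshold in metres (default 1 cm).
#' @return time in ms, or `NA` with attribute `flag = "no_movement"` when
#'   the threshold is never exceeded.
#' @export
detect_initiation <- function(seg, threshold = 0.01) {
  stopifnot(threshold > 0)
  if (!isTRUE(seg$usable)) return(NA_real_)
  disp <- sqrt(seg$x1^2 + seg$x2^2 + seg$x3^2)
  k <- which(disp > threshold)[1]
  if (is.na(k)) {
    out <- NA_real_
    attr(out, "flag") <- "no_movement"
    return(out)
  }
  if (k == 1L) return(seg$t[1])
  # interpolate the crossing between samples k-1 and k
  seg$t[k - 1] + (threshold - disp[k - 1]) / (disp[k] - disp[k - 1]) *
    (seg$t[k] - seg$t[k - 1])
}

#' Speed and acceleration series of a segmented trial
#'
#' Coordinates are smoothed with a centred moving average, then speed is the
#' magnitude of the central-difference velocity vector (one-sided at the
#' boundaries) and acceleration is the derivative of the speed series
#' (change in speed, a scalar).
#'
#' @param seg a `segmented_trial`.
#' @param smoothing moving-average window in samples (odd; default 5).
#' @return data.frame `t_ms`, `speed` (m/s), `accel` (m/s^2); attribute
#'   `flag` is set to `"sampling_gap"` when a gap exceeds 3 nominal
#'   periods.
#' @export
kinematic_series <- function(seg, smoothing = 5L) {
  if (!isTRUE(seg$usable) || length(seg$t) < 3L)
    stop("trial not usable for kinematics (need >= 3 samples)")
  ts <- seg$t / 1000                           # seconds
  x1 <- moving_average(seg$x1, smoothing)
  x2 <- moving_average(seg$x2, smoothing)
  x3 <- moving_average(seg$x3, smoothing)
  v1 <- finite_diff(x1, ts); v2 <- finite_diff(x2, ts)
  v3 <- finite_diff(x3, ts)
  speed <- sqrt(v1^2 + v2^2 + v3^2)
  accel <- finite_diff(speed, ts)
  out <- data.frame(t_ms = seg$t, speed = speed, accel = accel)
  gaps <- diff(seg$t)
  if (any(gaps > 3 * stats::median(gaps))) attr(out, "flag") <- "sampling_gap"
  out
}

#' Extract the per-trial biometric parameters
#'
#' @param seg a `segmented_trial`.
#' @param series output of [kinematic_series()] for the same trial.
#' @param stop_onset stop-signal onset in ms (stop trials), or `NA`.
#' @param trial_type `"go"` or `"stop"`.
#' @param object_depth,collision_radius geometry defining stop success: the
#'   stop counts as successful (`acc = TRUE`) when the hand never came
#'   within `collision_radius` of the object depth.
#' @param init_threshold displacement threshold for initiation detection, m.
#' @return one-row data.frame: `it`, `pv`, `ttpv`, `pa`, `ttpa`, `maxz`,
#'   `rt`, `tts`, `bd`, `acc` (times in ms relative to stimulus onset,
#'   lengths in m, speeds in m/s).
#' @export
extract_parameters <- function(seg, series, stop_onset = NA_real_,
                               trial_type = if (is.na(stop_onset)) "go"
                                            else "stop",
                               object_depth = 0.5705,
                               collision_radius = 0.02,
                               init_threshold = 0.01) {
  if (!isTRUE(seg$usable)) {
    return(data.frame(it = NA_real_, pv = NA_real_, ttpv = NA_real_,
                      pa = NA_real_, ttpa = NA_real_, maxz = NA_real_,
                      rt = NA_real_, tts = NA_real_, bd = NA_real_,
                      acc = NA))
  }
  if (trial_type == "stop" && is.na(stop_onset))
    stop("stop trial without stop_signal_onset")
  ipv <- which.max(series$speed)
  ipa <- which.max(series$accel)
  n <- length(seg$t)
  maxz <- seg$x1[n]                 # segmentation ends at the depth maximum
  out <- data.frame(
    it = as.numeric(detect_initiation(seg, init_threshold)),
    pv = series$speed[ipv], ttpv = series$t_ms[ipv],
    pa = series$accel[ipa], ttpa = series$t_ms[ipa],
    maxz = maxz, rt = seg$t[n],
    tts = NA_real_, bd = NA_real_, acc = NA)
  if (trial_type == "stop") {
    out$tts <- seg$t[n] - stop_onset
    out$bd <- maxz - interp_at(seg$t, seg$x1, stop_onset)
    out$acc <- maxz < object_depth - collision_radius
  }
  out
}

#' Time-standardise a segmented trial
#'
#' Linear interpolation of each coordinate at `n_steps` equally spaced time
#' fractions of the segment; the first and last points are preserved
#' exactly. Used for averaging/plotting trajectories of different duration;
#' kinematic peaks are computed on the unstandardised data.
#'
#' @param seg a `segmented_trial`.
#' @param n_steps number of resampled points (default 101).
#' @return data.frame `frac`, `t_ms`, `x1_m`, `x2_m`, `x3_m`.
#' @export
time_standardize <- function(seg, n_steps = 101L) {
  stopifnot(n_steps >= 2L)
  if (!isTRUE(seg$usable)) stop("trial not usable")
  tt <- seq(seg$t[1], seg$t[length(seg$t)], length.out = n_steps)
  data.frame(frac = seq(0, 1, length.out = n_steps), t_ms = tt,
             x1_m = interp_at(seg$t, seg$x1, tt),
             x2_m = interp_at(seg$t, seg$x2, tt),
             x3_m = interp_at(seg$t, seg$x3, tt))
}

#' Extract per-trial parameters from a long-format trial table
#'
#' Runs the full per-trial chain (centre/segment, initiation detection,
#' smoothing and differentiation, parameter read-off) for every trial in a
#' long-format sample table, as written by [generate_cohort()] or
#' equivalently formatted exports.
#'
#' @param trials long-format data.frame with `participant_id`,
#'   `trial_index`, `category`, `trial_type`, `t_ms`, `x1_m`, `x2_m`,
#'   `x3_m`, `stop_onset_ms`, `ssd_ms`.
#' @param object_depth,collision_radius,init_threshold,smoothing see
#'   [extract_parameters()] and [kinematic_series()].
#' @return data.frame with one row per trial: keys plus `it`, `pv`, `ttpv`,
#'   `pa`, `ttpa`, `maxz`, `rt`, `tts`, `bd`, `acc`, `ssd`, `usable`.
#' @export
extract_kinematics <- function(trials, object_depth = 0.5705,
                               collision_radius = 0.02,
                               init_threshold = 0.01, smoothing = 5L) {
  key <- paste(trials$participant_id, trials$trial_index, sep = "\r")
  idx <- split(seq_len(nrow(trials)), key)
  rows <- lapply(idx, function(i) {
    tr <- trials[i, , drop = FALSE]
    meta <- data.frame(participant_id = tr$participant_id[1],
                       trial_index = tr$trial_index[1],
                       category = tr$category[1],
                       trial_type = tr$trial_type[1],
                       ssd = tr$ssd_ms[1], stringsAsFactors = FALSE)
    seg <- center_and_segment(tr)
    if (!isTRUE(seg$usable))
      return(cbind(meta, extract_parameters(seg, NULL), usable = FALSE))
    ser <- kinematic_series(seg, smoothing)
    par <- extract_parameters(seg, ser, stop_onset = tr$stop_onset_ms[1],
                              trial_type = tr$trial_type[1],
                              object_depth = object_depth,
                              collision_radius = collision_radius,
                              init_threshold = init_threshold)
    cbind(meta, par, usable = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$trial_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Outlier-filter and aggregate per-trial parameters to cell means
#'
#' Within each participant x category x trial-type cell and separately per
#' variable, removes values farther than `z_cut` sample standard deviations
#' from the cell mean (single pass; nothing is removed when the SD is zero
#' or the cell has fewer than 3 values), then averages the survivors.
#' `tts` and `bd` are aggregated over successful stop trials only.
#'
#' @param records per-trial parameter table from [extract_kinematics()] (or
#'   any table with the grouping keys and numeric parameter columns).
#' @param vars parameter columns to aggregate.
#' @param z_cut outlier threshold in SD units (default 2.5).
#' @param min_trials cells with fewer usable trials are flagged.
#' @return long data.frame: `participant_id`, `category`, `trial_type`,
#'   `variable`, `mean`, `n_used`, `n_total`, `flagged`.
#' @export
filter_and_aggregate <- function(records,
                                 vars = c("it", "pv", "ttpv", "pa", "ttpa",
                                          "maxz", "rt", "tts", "bd"),
                                 z_cut = 2.5, min_trials = 5L) {
  stopifnot(z_cut > 0)
  vars <- intersect(vars, names(records))
  key <- interaction(records$participant_id, records$category,
                     records$trial_type, drop = TRUE)
  out <- list()
  for (cell in levels(key)) {
    rec <- records[key == cell, , drop = FALSE]
    for (v in vars) {
      x <- rec[[v]]
      if (v %in% c("tts", "bd") && "acc" %in% names(rec))
        x <- x[rec$acc %in% TRUE]
      x <- x[!is.na(x)]
      n_total <- length(x)
      kept <- zfilter(x, z_cut)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = rec$participant_id[1],
        category = rec$category[1], trial_type = rec$trial_type[1],
        variable = v,
        mean = if (length(kept)) mean(kept) else NA_real_,
        n_used = length(kept), n_total = n_total,
        flagged = length(kept) < min_trials, stringsAsFactors = FALSE)
    }
    if ("acc" %in% names(rec) && rec$trial_type[1] == "stop") {
      a <- rec$acc[!is.na(rec$acc)]
      out[[length(out) + 1L]] <- data.frame(
        participant_id = rec$participant_id[1],
        category = rec$category[1], trial_type = rec$trial_type[1],
        variable = "acc", mean = mean(a), n_used = length(a),
        n_total = length(a), flagged = length(a) < min_trials,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Single-pass z filter: keep values with |x - mean| <= z_cut * sample SD.
zfilter <- function(x, z_cut) {
  if (length(x) < 3L) return(x)
  s <- sd_sample(x)
  if (is.na(s) || s == 0) return(x)
  x[abs(x - mean(x)) <= z_cut * s]
}

#' Pivot a long cell summary to one row per cell
#'
#' @param summary_long output of [filter_and_aggregate()].
#' @return data.frame with one row per participant x category x trial-type
#'   and one column per variable.
#' @export
summary_wide <- function(summary_long) {
  out <- stats::reshape(
    summary_long[, c("participant_id", "category", "trial_type",
                     "variable", "mean")],
    idvar = c("participant_id", "category", "trial_type"),
    timevar = "variable", direction = "wide")
  names(out) <- sub("^mean\\.", "", names(out))
  rownames(out) <- NULL
  out
}
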