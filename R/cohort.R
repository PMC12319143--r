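# Synthetic study generator: participants, VR reach/stop trials with gaze,
# web-based stop-signal and single-category IAT sessions, and ad-libitum
# intake produced by a known sparse linear model over the predictor set.
#
# The generator's defaults encode the study conditions the analysis stages
# are meant for: 400 VR trials per participant with a 25% stop fraction and
# balanced chocolate/neutral categories, 120 Hz sampling, target object at
# 0.5705 m depth, minimum-jerk reaches, and an adaptive stop-signal-delay
# staircase (50 ms steps from 200 ms) bounded so that cohort-level stopping
# success lands near the 70-76% range typical of dynamic-starting-line VR
# stopping tasks rather than the 50% of classical key-press tasks.

#' Study configuration for the synthetic cohort generator
#'
#' Collects every tunable of the simulated study. Defaults describe the
#' reference design: `n_vr_trials = 400` reaches per participant of which
#' `stop_fraction = 0.25` receive a stop signal after movement onset,
#' balanced over the two stimulus categories; hand position sampled at
#' 120 Hz; target object centred `object_depth` metres from the start.
#'
#' @param n_participants number of screened participants to generate.
#' @param n_vr_trials VR trials per participant; `n_vr_trials * stop_fraction`
#'   must be a whole, even number so stop trials split evenly over categories.
#' @param stop_fraction proportion of VR trials carrying a stop signal.
#' @param sample_rate hand/gaze sampling rate in Hz.
#' @param object_depth depth of the target object from the start position, m.
#' @param collision_radius radius around the object within which a stop trial
#'   counts as failed, m.
#' @param rng_seed integer seed; identical config + seed reproduces the
#'   dataset exactly.
#' @param category_effects named list of additive chocolate-minus-neutral
#'   shifts: `pv` (m/s, applied to reach speed), `pa` (m/s^2, implied shift
#'   used by the feature-level generator), `tts` (ms, applied to the stop
#'   latency), `dwell_first` and `dwell_total` (ms, applied to gaze dwell).
#' @param intake_model list with `intercept` (kcal), `true_weights` (named
#'   kcal-per-SD weights over the predictor set, zero for unnamed
#'   predictors), and `noise_sd` (kcal).
#' @param position_noise_sd Gaussian positional noise per axis and sample, m.
#' @param lateral_amp,height_amp amplitude of the smooth lateral arc and of
#'   the net height rise of the reach, m.
#' @param vr_staircase,sst_staircase lists with `start`, `step`, `min`,
#'   `max` (ms) for the adaptive stop-signal-delay staircases of the VR task
#'   and the web task.
#' @param n_sst_trials,sst_stop_fraction web stop-signal task design.
#' @param n_iat_practice,n_iat_test SC-IAT trials per block and phase.
#' @param hold_ms recording continued after the reach ends, ms.
#' @return an object of class `study_config` (a validated list).
#' @examples
#' cfg <- study_config(n_participants = 4, rng_seed = 7)
#' cfg$n_vr_trials
#' @export
study_config <- function(n_participants = 72,
                         n_vr_trials = 400,
                         stop_fraction = 0.25,
                         sample_rate = 120,
                         object_depth = 0.5705,
                         collision_radius = 0.02,
                         rng_seed = 1L,
                         category_effects = list(pv = -0.02, pa = -0.03,
                                                 tts = -13,
                                                 dwell_first = 107,
                                                 dwell_total = 216),
                         intake_model = list(
                           intercept = 529,
                           true_weights = c(fcq_trait = 60,
                                            ssrt_choc = -60,
                                            dwell_total_choc = 60),
                           noise_sd = 206),
                         position_noise_sd = 0.001,
                         lateral_amp = 0.02,
                         height_amp = 0.04,
                         vr_staircase = list(start = 200, step = 50,
                                             min = 50, max = 260),
                         sst_staircase = list(start = 200, step = 50,
                                              min = 50, max = 900),
                         n_sst_trials = 400,
                         sst_stop_fraction = 0.25,
                         n_iat_practice = 24,
                         n_iat_test = 72,
                         hold_ms = 150) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_vr_trials = as.integer(n_vr_trials),
              stop_fraction = stop_fraction,
              categories = c("chocolate", "neutral"),
              sample_rate = sample_rate,
              object_depth = object_depth,
              collision_radius = collision_radius,
              rng_seed = as.integer(rng_seed),
              category_effects = category_effects,
              intake_model = intake_model,
              position_noise_sd = position_noise_sd,
              lateral_amp = lateral_amp,
              height_amp = height_amp,
              vr_staircase = vr_staircase,
              sst_staircase = sst_staircase,
              n_sst_trials = as.integer(n_sst_trials),
              sst_stop_fraction = sst_stop_fraction,
              n_iat_practice = as.integer(n_iat_practice),
              n_iat_test = as.integer(n_iat_test),
              hold_ms = hold_ms)
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1,
            cfg$sample_rate > 0,
            cfg$object_depth > 0,
            cfg$stop_fraction > 0, cfg$stop_fraction < 1,
            cfg$height_amp <= 0.05)
  n_stop <- cfg$n_vr_trials * cfg$stop_fraction
  if (abs(n_stop - round(n_stop)) > 1e-9)
    stop("n_vr_trials * stop_fraction must be an integer")
  if (round(n_stop) %% 2 != 0 || (cfg$n_vr_trials - round(n_stop)) %% 2 != 0)
    stop("stop and go trial counts must split evenly over the two categories")
  ns <- cfg$n_sst_trials * cfg$sst_stop_fraction
  if (abs(ns - round(ns)) > 1e-9 || round(ns) %% 2 != 0)
    stop("n_sst_trials * sst_stop_fraction must be an even integer")
  invisible(cfg)
}

#' @exportS3Method base::print
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  participants: %d, VR trials: %d (%.0f%% stop), %g Hz\n",
              x$n_participants, x$n_vr_trials, 100 * x$stop_fraction,
              x$sample_rate))
  cat(sprintf("  object depth: %.4f m, seed: %d\n", x$object_depth,
              x$rng_seed))
  invisible(x)
}

# Population constants of the latent participant model (see the methods
# vignette for their provenance). Between-participant means/SDs.
.pop <- list(
  age = c(22.85, 3.73), bmi = c(22.55, 2.66),
  fcq_trait = c(58.74, 9.93), fcq_state = c(51.21, 12.18),
  bis15 = c(25.2, 5.9),
  pv_neutral = c(2.11, 0.28),           # m/s, go reaches to neutral cues
  it = c(300, 40),                      # ms, movement initiation
  stop_lat_neutral = c(260, 62),        # ms, VR stopping latency
  dwell_first_neutral = c(289, 100),    # ms
  dwell_extra_neutral = c(172, 120),    # ms beyond first dwell
  go_rt_neutral = c(659, 145),          # ms, web task
  go_rt_choc_shift = 34,                # ms
  ssrt_neutral = c(320, 65),            # ms, web task
  ssrt_choc_shift = 6,                  # ms
  iat_base_rt = c(606, 200), iat_d = c(-0.137, 0.22),
  # between-participant SD of the category effects themselves
  eff_sd = c(pv = 0.04, tts = 40, dwell = 75),
  # trial-level SDs
  it_trial_sd = 40, reach_trial_sd = 25, stop_lat_trial_sd = 40,
  dwell_trial_sd = 60, go_rt_trial_sd = 130, ssrt_trial_sd = 30,
  iat_rt_trial_sd = 150,
  go_omission_p = 0.02, iat_error_p = 0.07)

#' Simulate an unscreened candidate pool
#'
#' Draws candidates from a broader population than the eligible one so that
#' [screen_participants()] has work to do: trait-craving scores, BMI, age and
#' handedness all extend beyond the inclusion windows.
#'
#' @param n number of candidates.
#' @return data.frame with `id`, `age`, `bmi`, `handedness_score`,
#'   `fcq_trait`, `fcq_state`, `bis15`.
#' @export
simulate_candidates <- function(n) {
  data.frame(
    id = sprintf("cand%04d", seq_len(n)),
    age = round(rtnorm(n, 24, 5, 16, 45)),
    bmi = round(rtnorm(n, 23, 3.5, 15, 40), 1),
    handedness_score = round(rtnorm(n, 75, 40, -100, 100)),
    fcq_trait = round(rtnorm(n, 48, 15, 15, 90)),
    fcq_state = round(rtnorm(n, .pop$fcq_state[1], .pop$fcq_state[2], 15, 90)),
    bis15 = round(rtnorm(n, .pop$bis15[1], .pop$bis15[2], 15, 60)),
    stringsAsFactors = FALSE)
}

#' Apply the study's screening rules to a candidate table
#'
#' Keeps candidates with trait chocolate craving strictly above the
#' population-median threshold (37), BMI within 18.5-29.9 kg/m^2, age within
#' 18-35 years, and a right-handedness score strictly above 50. Candidates
#' with missing screening fields are rejected with a logged reason. Row order
#' is preserved.
#'
#' @param candidates data.frame with at least `age`, `bmi`,
#'   `handedness_score`, `fcq_trait`.
#' @param thresholds list overriding `fcq_min` (exclusive), `bmi_range`,
#'   `age_range`, `handedness_min` (exclusive).
#' @return the included rows; attribute `"screen_log"` holds a data.frame of
#'   rejected ids and reasons.
#' @examples
#' cand <- data.frame(id = 1:3, age = c(25, 40, 25), bmi = c(22, 22, 31),
#'                    handedness_score = c(80, 80, 80),
#'                    fcq_trait = c(38, 50, 50))
#' screen_participants(cand)
#' @export
screen_participants <- function(candidates,
                                thresholds = list(fcq_min = 37,
                                                  bmi_range = c(18.5, 29.9),
                                                  age_range = c(18, 35),
                                                  handedness_min = 50)) {
  th <- utils::modifyList(list(fcq_min = 37, bmi_range = c(18.5, 29.9),
                               age_range = c(18, 35), handedness_min = 50),
                          thresholds)
  need <- c("age", "bmi", "handedness_score", "fcq_trait")
  miss_col <- setdiff(need, names(candidates))
  if (length(miss_col))
    stop("candidate table lacks columns: ", paste(miss_col, collapse = ", "))
  reasons <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, ]
    why <- character(0)
    if (anyNA(r[need])) {
      why <- paste("missing", paste(need[is.na(unlist(r[need]))],
                                    collapse = "+"))
    } else {
      if (r$fcq_trait <= th$fcq_min) why <- c(why, "fcq_trait_at_or_below_threshold")
      if (r$bmi < th$bmi_range[1] || r$bmi > th$bmi_range[2])
        why <- c(why, "bmi_out_of_range")
      if (r$age < th$age_range[1] || r$age > th$age_range[2])
        why <- c(why, "age_out_of_range")
      if (r$handedness_score <= th$handedness_min)
        why <- c(why, "not_right_handed")
    }
    reasons[i] <- paste(why, collapse = ";")
  }
  keep <- reasons == ""
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- data.frame(id = candidates$id[!keep], reason = reasons[!keep],
                    stringsAsFactors = FALSE)
  attr(out, "screen_log") <- log
  out
}

# Latent per-participant parameters driving every task. One row per
# participant; downstream analysis never sees this table directly.
participant_latents <- function(participants, cfg) {
  n <- nrow(participants)
  eff <- cfg$category_effects
  pv_neutral <- rtnorm(n, .pop$pv_neutral[1], .pop$pv_neutral[2], 1.4, 2.9)
  # category effects vary across participants around the configured means
  pv_choc <- pv_neutral + rtnorm(n, eff$pv, .pop$eff_sd["pv"], eff$pv - 0.12,
                                 eff$pv + 0.12)
  d <- cfg$object_depth
  latents <- data.frame(
    participant_id = participants$id,
    pv_neutral = pv_neutral, pv_choc = pv_choc,
    # minimum-jerk: PV = 1.875 * D / T  =>  T (ms) = 1875 * D / PV
    reach_ms_neutral = 1875 * d / pv_neutral,
    reach_ms_choc = 1875 * d / pv_choc,
    it_mean = rtnorm(n, .pop$it[1], .pop$it[2], 180, 450),
    stop_lat_neutral = rtnorm(n, .pop$stop_lat_neutral[1],
                              .pop$stop_lat_neutral[2], 150, 420),
    dwell_first_neutral = rtnorm(n, .pop$dwell_first_neutral[1],
                                 .pop$dwell_first_neutral[2], 80, 650),
    dwell_extra_neutral = rtnorm(n, .pop$dwell_extra_neutral[1],
                                 .pop$dwell_extra_neutral[2], 0, 600),
    go_rt_neutral = rtnorm(n, .pop$go_rt_neutral[1], .pop$go_rt_neutral[2],
                           400, 1100),
    ssrt_neutral = rtnorm(n, .pop$ssrt_neutral[1], .pop$ssrt_neutral[2],
                          180, 520),
    iat_base_rt = rtnorm(n, .pop$iat_base_rt[1], .pop$iat_base_rt[2],
                         350, 1000),
    iat_d = rtnorm(n, .pop$iat_d[1], .pop$iat_d[2], -0.9, 0.7),
    stringsAsFactors = FALSE)
  latents$stop_lat_choc <- pmax(latents$stop_lat_neutral +
                                  rtnorm(n, eff$tts, .pop$eff_sd["tts"],
                                         eff$tts - 60, eff$tts + 60), 60)
  latents$dwell_first_choc <- latents$dwell_first_neutral +
    rtnorm(n, eff$dwell_first, .pop$eff_sd["dwell"],
           eff$dwell_first - 150, eff$dwell_first + 150)
  latents$dwell_extra_choc <- pmax(
    latents$dwell_extra_neutral + (eff$dwell_total - eff$dwell_first) +
      rtnorm(n, 0, .pop$eff_sd["dwell"], -150, 150), 0)
  latents$go_rt_choc <- latents$go_rt_neutral + .pop$go_rt_choc_shift
  latents$ssrt_choc <- latents$ssrt_neutral + .pop$ssrt_choc_shift
  latents
}

# The 16-predictor true feature vector per participant, derived from the
# latent model. Column order matches predictor_set().
true_features <- function(participants, latents, cfg) {
  d <- cfg$object_depth
  t_choc_s <- latents$reach_ms_choc / 1000
  data.frame(
    participant_id = participants$id,
    fcq_trait = participants$fcq_trait,
    fcq_state = participants$fcq_state,
    bis15 = participants$bis15,
    ssrt_choc = latents$ssrt_choc,
    rt_go = (latents$go_rt_neutral + latents$go_rt_choc) / 2,
    # staircase equilibrium: SSD tracks mean go RT minus stop latency, with
    # per-participant tracking wobble around the equilibrium
    ssd_mean = pmax((latents$go_rt_neutral + latents$go_rt_choc) / 2 -
                      (latents$ssrt_neutral + latents$ssrt_choc) / 2 +
                      stats::rnorm(nrow(latents), 0, 15), 50),
    fa_rate = rtnorm(nrow(latents), 0.465, 0.04, 0.3, 0.65),
    d_score = latents$iat_d,
    pv_choc = latents$pv_choc,
    # minimum-jerk: PA = (10 / sqrt(3)) * D / T^2
    pa_choc = (10 / sqrt(3)) * d / t_choc_s^2,
    tts_choc = latents$stop_lat_choc,
    bd_choc = 0.95 * latents$pv_choc * latents$stop_lat_choc / 2000,
    maxz_choc = rtnorm(nrow(latents), 0.546, 0.031, 0.45, d),
    it_choc = latents$it_mean,
    dwell_first_choc = latents$dwell_first_choc,
    dwell_total_choc = latents$dwell_first_choc + latents$dwell_extra_choc,
    stringsAsFactors = FALSE)
}

#' The fixed predictor set of the intake model
#' @return character vector of the 16 predictor names.
#' @export
predictor_set <- function() {
  c("fcq_trait", "fcq_state", "bis15", "ssrt_choc", "rt_go", "ssd_mean",
    "fa_rate", "d_score", "pv_choc", "pa_choc", "tts_choc", "bd_choc",
    "maxz_choc", "it_choc", "dwell_first_choc", "dwell_total_choc")
}

# intake = intercept + sum(w_j * z(true feature_j)) + N(0, noise_sd), >= 0
intake_from_features <- function(truth, cfg) {
  im <- cfg$intake_model
  w <- im$true_weights
  mu <- rep(im$intercept, nrow(truth))
  for (nm in names(w)) {
    if (!nm %in% names(truth)) stop("unknown predictor in true_weights: ", nm)
    x <- truth[[nm]]
    s <- sd_sample(x)
    z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    mu <- mu + w[[nm]] * z
  }
  kcal <- mu + stats::rnorm(nrow(truth), 0, im$noise_sd)
  list(expected = mu, observed = pmax(kcal, 0))
}

# Minimum-jerk position/velocity on tau in [0, 1] (dimensionless profiles).
minjerk_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
minjerk_vel <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4

#' Generate one VR reach trial with ground truth
#'
#' Simulates the hand path of a single go or stop trial: a minimum-jerk
#' depth reach of distance `object_depth` starting after a sampled
#' initiation time, with a smooth lateral arc and net height rise, Gaussian
#' positional noise, and a per-sample gaze-collision stream. In stop trials
#' the stop signal is scheduled at initiation time + SSD; the depth velocity
#' then decays linearly to zero over the trial's stop latency. The stop
#' succeeds when the hand halts outside the object's collision radius,
#' otherwise the reach completes (failed stop).
#'
#' @param participant one row of the latent parameter table, or `NULL` to
#'   use population-mean latents.
#' @param category `"chocolate"` or `"neutral"`.
#' @param trial_type `"go"` or `"stop"`.
#' @param config a [study_config()].
#' @param ssd stop-signal delay in ms (stop trials; default the staircase
#'   start value).
#' @param it,reach_ms,stop_latency optional deterministic overrides (ms) for
#'   the initiation time, reach duration, and stop latency; sampled from the
#'   participant's latents when `NULL`.
#' @return list with `samples` (data.frame `t_ms`, `x1_m`, `x2_m`, `x3_m`,
#'   `gaze_hit`), `category`, `trial_type`, `ssd_ms`, `stop_onset_ms`, and
#'   `truth` (initiation time, reach duration, stop latency, braking
#'   distance, halt depth, stop success).
#' @examples
#' cfg <- study_config(n_participants = 1, position_noise_sd = 0)
#' set.seed(1)
#' tr <- generate_vr_trial(NULL, "neutral", "go", cfg, it = 200, reach_ms = 1000)
#' max(tr$samples$x1_m)
#' @export
generate_vr_trial <- function(participant, category, trial_type, config,
                              ssd = NULL, it = NULL, reach_ms = NULL,
                              stop_latency = NULL) {
  stopifnot(category %in% config$categories, trial_type %in% c("go", "stop"))
  cfg <- config
  lat <- participant
  choc <- category == "chocolate"
  if (is.null(it)) {
    it_mean <- if (is.null(lat)) .pop$it[1] else lat$it_mean
    it <- rtnorm(1, it_mean, .pop$it_trial_sd, 100, 700)
  }
  if (is.null(reach_ms)) {
    rm_mean <- if (is.null(lat)) 1875 * cfg$object_depth / .pop$pv_neutral[1]
               else if (choc) lat$reach_ms_choc else lat$reach_ms_neutral
    reach_ms <- rtnorm(1, rm_mean, .pop$reach_trial_sd, 250, 1400)
  }
  if (reach_ms <= 0) stop("non-positive reach duration")
  d <- cfg$object_depth
  dt <- 1000 / cfg$sample_rate
  stop_onset <- NA_real_
  success <- NA
  halt <- d
  v0 <- NA_real_
  bd_true <- NA_real_

  if (trial_type == "stop") {
    if (is.null(ssd)) ssd <- cfg$vr_staircase$start
    stop_onset <- it + ssd
    if (is.null(stop_latency)) {
      sl_mean <- if (is.null(lat)) .pop$stop_lat_neutral[1] +
                   (if (choc) cfg$category_effects$tts else 0)
                 else if (choc) lat$stop_lat_choc else lat$stop_lat_neutral
      stop_latency <- rtnorm(1, sl_mean, .pop$stop_lat_trial_sd, 30, 650)
    }
    if (stop_onset < it + reach_ms) {
      tau0 <- (stop_onset - it) / reach_ms
      v0 <- (d / reach_ms) * minjerk_vel(tau0)     # m per ms
      halt <- d * minjerk_pos(tau0) + v0 * stop_latency / 2
      success <- halt < d - cfg$collision_radius
      bd_true <- v0 * stop_latency / 2
    } else {
      success <- FALSE                              # reach done before signal
    }
    if (!isTRUE(success)) halt <- d
  } else {
    ssd <- NA_real_
  }

  end_ms <- if (isTRUE(success)) stop_onset + stop_latency + cfg$hold_ms
            else it + reach_ms + cfg$hold_ms
  t <- seq(0, ceiling(end_ms / dt) * dt, by = dt)

  x1 <- numeric(length(t))
  moving <- t > it & t < it + reach_ms
  x1[moving] <- d * minjerk_pos((t[moving] - it) / reach_ms)
  x1[t >= it + reach_ms] <- d
  if (isTRUE(success)) {
    tau0 <- (stop_onset - it) / reach_ms
    x_on <- d * minjerk_pos(tau0)
    dec <- t > stop_onset & t <= stop_onset + stop_latency
    dtm <- t[dec] - stop_onset
    x1[dec] <- x_on + v0 * dtm - v0 * dtm^2 / (2 * stop_latency)
    x1[t > stop_onset + stop_latency] <- halt
    # before the signal the minimum-jerk profile applies unchanged
    pre <- t <= stop_onset & t > it
    x1[pre] <- d * minjerk_pos((t[pre] - it) / reach_ms)
  }
  s <- x1 / d
  x2 <- cfg$lateral_amp * sin(pi * s)
  x3 <- cfg$height_amp * s
  if (cfg$position_noise_sd > 0) {
    x1 <- x1 + stats::rnorm(length(t), 0, cfg$position_noise_sd)
    x2 <- x2 + stats::rnorm(length(t), 0, cfg$position_noise_sd)
    x3 <- x3 + stats::rnorm(length(t), 0, cfg$position_noise_sd)
  }

  gaze <- simulate_gaze_stream(length(t), dt, lat, choc, cfg)

  list(samples = data.frame(t_ms = t, x1_m = x1, x2_m = x2, x3_m = x3,
                            gaze_hit = gaze),
       category = category, trial_type = trial_type,
       ssd_ms = ssd, stop_onset_ms = stop_onset,
       truth = list(it = it, reach_ms = reach_ms,
                    stop_latency = if (trial_type == "stop") stop_latency
                                   else NA_real_,
                    tts = if (isTRUE(success)) stop_latency else NA_real_,
                    bd = if (isTRUE(success)) bd_true else NA_real_,
                    maxz = halt, success = success))
}

# Boolean gaze-on-stimulus stream: an initial fixation from frame 1, a
# detachment gap, then shorter re-fixation bouts until the target total
# dwell is reached.
simulate_gaze_stream <- function(n, dt, lat, choc, cfg) {
  d1_mean <- if (is.null(lat)) .pop$dwell_first_neutral[1] +
               (if (choc) cfg$category_effects$dwell_first else 0)
             else if (choc) lat$dwell_first_choc else lat$dwell_first_neutral
  ex_mean <- if (is.null(lat)) .pop$dwell_extra_neutral[1] +
               (if (choc) cfg$category_effects$dwell_total -
                  cfg$category_effects$dwell_first else 0)
             else if (choc) lat$dwell_extra_choc else lat$dwell_extra_neutral
  d1 <- rtnorm(1, d1_mean, .pop$dwell_trial_sd, 40, n * dt)
  extra <- rtnorm(1, ex_mean, .pop$dwell_trial_sd, 0, n * dt)
  hits <- rep(FALSE, n)
  n1 <- min(max(round(d1 / dt), 1), n)
  hits[seq_len(n1)] <- TRUE
  pos <- n1 + 1 + round(stats::runif(1, 4, 16))   # detachment gap
  left <- round(extra / dt)
  while (left > 0 && pos <= n) {
    bout <- min(max(round(stats::runif(1, 6, 24)), 1), left, n - pos + 1)
    hits[pos:(pos + bout - 1)] <- TRUE
    left <- left - bout
    pos <- pos + bout + round(stats::runif(1, 6, 18))
  }
  hits
}

# Balanced, randomly ordered VR trial schedule for one participant.
vr_schedule <- function(cfg) {
  n_stop <- round(cfg$n_vr_trials * cfg$stop_fraction)
  n_go <- cfg$n_vr_trials - n_stop
  sched <- data.frame(
    category = c(rep(cfg$categories, each = n_go / 2),
                 rep(cfg$categories, each = n_stop / 2)),
    trial_type = c(rep("go", n_go), rep("stop", n_stop)),
    stringsAsFactors = FALSE)
  sched[sample.int(nrow(sched)), , drop = FALSE]
}

# All VR trials for one participant; single adaptive SSD staircase shared
# across categories (category differences in stopping therefore survive the
# tracking). Returns long-format samples plus per-trial ground truth.
generate_participant_vr <- function(lat, cfg) {
  sched <- vr_schedule(cfg)
  st <- cfg$vr_staircase
  ssd <- st$start
  samples <- vector("list", nrow(sched))
  truth <- vector("list", nrow(sched))
  for (k in seq_len(nrow(sched))) {
    tt <- sched$trial_type[k]
    tr <- generate_vr_trial(lat, sched$category[k], tt, cfg,
                            ssd = if (tt == "stop") ssd else NULL)
    if (tt == "stop") {
      ssd <- if (isTRUE(tr$truth$success)) min(ssd + st$step, st$max)
             else max(ssd - st$step, st$min)
    }
    ns <- nrow(tr$samples)
    samples[[k]] <- cbind(
      data.frame(participant_id = lat$participant_id, trial_index = k,
                 category = tr$category, trial_type = tr$trial_type,
                 stringsAsFactors = FALSE),
      tr$samples,
      data.frame(ssd_ms = rep(tr$ssd_ms, ns),
                 stop_onset_ms = rep(tr$stop_onset_ms, ns)))
    truth[[k]] <- data.frame(
      participant_id = lat$participant_id, trial_index = k,
      category = tr$category, trial_type = tr$trial_type,
      it_true = tr$truth$it, reach_ms_true = tr$truth$reach_ms,
      stop_latency_true = tr$truth$stop_latency,
      tts_true = tr$truth$tts, bd_true = tr$truth$bd,
      maxz_true = tr$truth$maxz,
      success_true = tr$truth$success, stringsAsFactors = FALSE)
  }
  list(samples = do.call(rbind, samples), truth = do.call(rbind, truth))
}

#' Generate one web-based stop-signal session under the race model
#'
#' Go and stop finish times race independently; a response is emitted on a
#' stop trial when the go process finishes before SSD + stop latency. The
#' SSD follows an adaptive staircase per category targeting 50% stopping.
#'
#' @param participant latent row or `NULL` for population means.
#' @param config a [study_config()].
#' @return data.frame with one row per trial: `trial_index`, `category`,
#'   `trial_type`, `rt_ms`, `responded`, `ssd_ms`, `correct`.
#' @export
generate_sst_session <- function(participant, config) {
  cfg <- config
  lat <- participant
  n_stop <- round(cfg$n_sst_trials * cfg$sst_stop_fraction)
  n_go <- cfg$n_sst_trials - n_stop
  sched <- data.frame(
    category = c(rep(cfg$categories, each = n_go / 2),
                 rep(cfg$categories, each = n_stop / 2)),
    trial_type = c(rep("go", n_go), rep("stop", n_stop)),
    stringsAsFactors = FALSE)
  sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
  st <- cfg$sst_staircase
  ssd <- stats::setNames(rep(st$start, 2), cfg$categories)
  out <- data.frame(trial_index = seq_len(nrow(sched)),
                    category = sched$category,
                    trial_type = sched$trial_type,
                    rt_ms = NA_real_, responded = FALSE, ssd_ms = NA_real_,
                    correct = NA, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    cat_k <- out$category[k]
    choc <- cat_k == "chocolate"
    go_mean <- if (is.null(lat)) .pop$go_rt_neutral[1] +
                 (if (choc) .pop$go_rt_choc_shift else 0)
               else if (choc) lat$go_rt_choc else lat$go_rt_neutral
    go_rt <- rtnorm(1, go_mean, .pop$go_rt_trial_sd, 150, 2500)
    if (out$trial_type[k] == "go") {
      if (stats::runif(1) < .pop$go_omission_p) {
        out$responded[k] <- FALSE
      } else {
        out$responded[k] <- TRUE
        out$rt_ms[k] <- go_rt
        out$correct[k] <- stats::runif(1) > 0.02
      }
    } else {
      ssrt_mean <- if (is.null(lat)) .pop$ssrt_neutral[1] +
                     (if (choc) .pop$ssrt_choc_shift else 0)
                   else if (choc) lat$ssrt_choc else lat$ssrt_neutral
      ssrt_k <- rtnorm(1, ssrt_mean, .pop$ssrt_trial_sd, 80, 800)
      out$ssd_ms[k] <- ssd[[cat_k]]
      respond <- go_rt < ssd[[cat_k]] + ssrt_k
      out$responded[k] <- respond
      if (respond) out$rt_ms[k] <- go_rt
      out$correct[k] <- !respond
      ssd[[cat_k]] <- if (respond) max(ssd[[cat_k]] - st$step, st$min)
                      else min(ssd[[cat_k]] + st$step, st$max)
    }
  }
  out
}

#' Generate one single-category IAT session
#'
#' Compatible (chocolate + approach) and incompatible (chocolate +
#' avoidance) blocks, each with practice and test phases. The participant's
#' latent D-score sets the block mean difference relative to the trial RT
#' spread.
#'
#' @param participant latent row or `NULL` for population means.
#' @param config a [study_config()].
#' @return data.frame with `trial_index`, `block`, `phase`, `rt_ms`,
#'   `correct`.
#' @export
generate_sciat_session <- function(participant, config) {
  cfg <- config
  lat <- participant
  base <- if (is.null(lat)) .pop$iat_base_rt[1] else lat$iat_base_rt
  d <- if (is.null(lat)) .pop$iat_d[1] else lat$iat_d
  diff <- d * .pop$iat_rt_trial_sd
  blocks <- expand.grid(block = c("compatible", "incompatible"),
                        phase = c("practice", "test"),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    nb <- if (blocks$phase[b] == "practice") cfg$n_iat_practice
          else cfg$n_iat_test
    mu <- base + (if (blocks$block[b] == "incompatible") diff / 2 else -diff / 2)
    # shifted lognormal: right-skewed, essentially no trials under 300 ms
    rt <- 250 + stats::rlnorm(nb, log(pmax(mu - 250, 80)), 0.35)
    rt <- pmin(rt, 9500)
    corr <- stats::runif(nb) > .pop$iat_error_p
    rt[!corr] <- rt[!corr] + 80
    rows[[b]] <- data.frame(block = blocks$block[b], phase = blocks$phase[b],
                            rt_ms = rt, correct = corr,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial_index = seq_len(nrow(out)), out)
  out
}

# Draw screened participants by repeatedly sampling candidate batches.
draw_screened_participants <- function(cfg) {
  got <- list()
  n_have <- 0
  rejected <- list()
  guard <- 0
  while (n_have < cfg$n_participants && guard < 50) {
    guard <- guard + 1
    cand <- simulate_candidates(max(2 * cfg$n_participants, 20))
    keep <- screen_participants(cand)
    rejected[[guard]] <- attr(keep, "screen_log")
    got[[guard]] <- keep
    n_have <- n_have + nrow(keep)
  }
  all <- do.call(rbind, got)
  if (nrow(all) < cfg$n_participants)
    stop("could not assemble enough eligible participants")
  out <- all[seq_len(cfg$n_participants), , drop = FALSE]
  out$id <- sprintf("p%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "screen_log") <- do.call(rbind, rejected)
  out
}

#' Generate a complete synthetic study
#'
#' Produces participants (screened from a wider candidate pool), all VR
#' trial recordings with gaze streams, web stop-signal and SC-IAT trial
#' tables, ad-libitum intake from the configured sparse linear model, and
#' the ground truth of every generated quantity. Fully reproducible under
#' `config$rng_seed`.
#'
#' @param config a [study_config()].
#' @param detail `"trials"` generates per-sample VR trajectories and all
#'   web-task trial tables; `"features"` generates only participant-level
#'   tables (see [generate_feature_table()] for the light-weight interface).
#' @return object of class `cohort`: list with `participants`, `trials`
#'   (long-format samples), `sst_trials`, `iat_trials`, `ground_truth`
#'   (participant-level true features and per-trial truth), and `config`.
#' @examples
#' cfg <- study_config(n_participants = 2, n_vr_trials = 8, rng_seed = 3)
#' coh <- generate_cohort(cfg)
#' table(coh$trials$trial_type[!duplicated(paste(coh$trials$participant_id,
#'                                               coh$trials$trial_index))])
#' @export
generate_cohort <- function(config, detail = c("trials", "features")) {
  detail <- match.arg(detail)
  cfg <- config
  validate_study_config(cfg)
  set.seed(cfg$rng_seed)
  participants <- draw_screened_participants(cfg)
  latents <- participant_latents(participants, cfg)
  truth <- true_features(participants, latents, cfg)
  intake <- intake_from_features(truth, cfg)
  participants$intake_kcal <- intake$observed
  truth$intake_expected <- intake$expected

  trials <- NULL; trial_truth <- NULL; sst <- NULL; iat <- NULL
  if (detail == "trials") {
    vr <- lapply(seq_len(nrow(latents)), function(i)
      generate_participant_vr(latents[i, ], cfg))
    trials <- do.call(rbind, lapply(vr, `[[`, "samples"))
    trial_truth <- do.call(rbind, lapply(vr, `[[`, "truth"))
    sst <- do.call(rbind, lapply(seq_len(nrow(latents)), function(i) {
      s <- generate_sst_session(latents[i, ], cfg)
      cbind(participant_id = latents$participant_id[i], s,
            stringsAsFactors = FALSE)
    }))
    iat <- do.call(rbind, lapply(seq_len(nrow(latents)), function(i) {
      s <- generate_sciat_session(latents[i, ], cfg)
      cbind(participant_id = latents$participant_id[i], s,
            stringsAsFactors = FALSE)
    }))
    rownames(trials) <- rownames(trial_truth) <- NULL
    rownames(sst) <- rownames(iat) <- NULL
  }
  structure(list(participants = participants,
                 trials = trials, sst_trials = sst, iat_trials = iat,
                 ground_truth = list(participants = truth,
                                     trials = trial_truth,
                                     latents = latents),
                 config = cfg),
            class = "cohort")
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (seed %d)\n",
              nrow(x$participants), x$config$rng_seed))
  if (!is.null(x$trials))
    cat(sprintf("  VR samples: %d rows, %d trials/participant\n",
                nrow(x$trials), x$config$n_vr_trials))
  cat(sprintf("  intake: %.0f kcal mean (range %.0f-%.0f)\n",
              mean(x$participants$intake_kcal),
              min(x$participants$intake_kcal),
              max(x$participants$intake_kcal)))
  invisible(x)
}

#' Participant-level feature tables without per-sample trajectories
#'
#' Samples the same latent participant model as [generate_cohort()] but
#' returns the participant-level quantities directly: the 16-predictor true
#' feature vector, a measured version with per-feature measurement noise
#' emulating trial-averaged extraction, intake, and 2x2 cell means of the
#' main biometric parameters. Intended for simulation studies (feature
#' selection, ANOVA power) where per-sample trajectories are not needed.
#'
#' @param config a [study_config()].
#' @param measurement_noise add extraction-level noise to the measured
#'   features (`TRUE`) or return the true values (`FALSE`).
#' @return list with `features` (measured predictors + `intake_kcal`),
#'   `truth` (true features + expected intake), `participants`, and
#'   `cell_means` (participant x category x trial_type means of pv, pa,
#'   maxz, tts, dwell_first, dwell_total).
#' @export
generate_feature_table <- function(config, measurement_noise = TRUE) {
  cfg <- config
  validate_study_config(cfg)
  set.seed(cfg$rng_seed)
  participants <- draw_screened_participants(cfg)
  latents <- participant_latents(participants, cfg)
  truth <- true_features(participants, latents, cfg)
  intake <- intake_from_features(truth, cfg)
  participants$intake_kcal <- intake$observed
  truth$intake_expected <- intake$expected

  feats <- truth[, c("participant_id", predictor_set())]
  if (measurement_noise) {
    sem <- c(fcq_trait = 0, fcq_state = 0, bis15 = 0, ssrt_choc = 25,
             rt_go = 15, ssd_mean = 20, fa_rate = 0.05, d_score = 0.08,
             pv_choc = 0.03, pa_choc = 0.3, tts_choc = 8, bd_choc = 0.01,
             maxz_choc = 0.005, it_choc = 8, dwell_first_choc = 15,
             dwell_total_choc = 20)
    for (nm in predictor_set())
      feats[[nm]] <- feats[[nm]] + stats::rnorm(nrow(feats), 0, sem[[nm]])
  }
  feats$intake_kcal <- participants$intake_kcal

  d <- cfg$object_depth
  cells <- expand.grid(participant_id = participants$id,
                       category = cfg$categories,
                       trial_type = c("go", "stop"),
                       stringsAsFactors = FALSE)
  idx <- match(cells$participant_id, latents$participant_id)
  choc <- cells$category == "chocolate"
  pv <- ifelse(choc, latents$pv_choc[idx], latents$pv_neutral[idx])
  t_s <- 1875 * d / pv / 1000
  n_tr_cell <- pmax(round(cfg$n_vr_trials / 4), 2)
  msd <- .pop$reach_trial_sd / 1000  # reach jitter feeds cell-mean noise
  # interrupted reaches truncate the speed profile: stop-trial peaks sit
  # below go-trial peaks, with participant-level (not cell-level) spread
  is_stop <- cells$trial_type == "stop"
  n_p <- nrow(latents)
  pv_stop_shift <- rtnorm(n_p, 0.2, 0.1, -0.1, 0.5)[idx]
  pa_stop_shift <- rtnorm(n_p, 0.4, 0.3, -0.5, 1.3)[idx]
  cells$pv <- pv - is_stop * pv_stop_shift +
    stats::rnorm(nrow(cells), 0, 0.05 / sqrt(n_tr_cell))
  cells$pa <- (10 / sqrt(3)) * d / t_s^2 - is_stop * pa_stop_shift +
    stats::rnorm(nrow(cells), 0, (0.5 + 1000 * msd) / sqrt(n_tr_cell))
  # stop points do not differ by category (stopping is equally effective)
  cells$maxz <- ifelse(cells$trial_type == "go", d, truth$maxz_choc[idx]) +
    stats::rnorm(nrow(cells), 0, 0.01 / sqrt(n_tr_cell))
  cells$tts <- ifelse(cells$trial_type == "stop",
                      ifelse(choc, latents$stop_lat_choc[idx],
                             latents$stop_lat_neutral[idx]) +
                        stats::rnorm(nrow(cells),
                                     0, .pop$stop_lat_trial_sd /
                                       sqrt(n_tr_cell)),
                      NA_real_)
  d1 <- ifelse(choc, latents$dwell_first_choc[idx],
               latents$dwell_first_neutral[idx])
  dex <- ifelse(choc, latents$dwell_extra_choc[idx],
                latents$dwell_extra_neutral[idx])
  cells$dwell_first <- d1 + stats::rnorm(nrow(cells),
                                         0, .pop$dwell_trial_sd /
                                           sqrt(n_tr_cell))
  cells$dwell_total <- d1 + dex +
    stats::rnorm(nrow(cells), 0, 1.5 * .pop$dwell_trial_sd / sqrt(n_tr_cell))

  list(features = feats, truth = truth, participants = participants,
       cell_means = cells)
}
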