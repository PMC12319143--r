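# End-to-end pipeline: simulate -> extract -> gaze -> score-sst ->
# score-iat -> stats -> fit, with per-stage CSV outputs, structured
# exclusion logging, and a run manifest carrying config, seed and file
# digests. Identical config + seed reproduces identical digests.

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  path
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

stage_files <- function(out_dir) {
  files <- c(
    participants = "participants.csv",
    trials = "vr_trials.csv",
    truth = "ground_truth_participants.csv",
    trial_truth = "ground_truth_trials.csv",
    sst = "sst_trials.csv",
    iat = "iat_trials.csv",
    kin = "kinematics_trials.csv",
    kin_summary = "kinematics_summary.csv",
    gaze = "gaze_trials.csv",
    gaze_summary = "gaze_summary.csv",
    sst_results = "sst_results.csv",
    iat_results = "iat_results.csv",
    stats = "group_statistics.csv",
    features = "features.csv",
    weights = "fit_weights.csv",
    fit = "fit_report.json",
    config = "config.json",
    manifest = "manifest.json")
  stats::setNames(file.path(out_dir, files), names(files))
}

require_stage_input <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' aborted: missing input %s", stage,
                 basename(path)), call. = FALSE)
  path
}

#' Assemble the per-participant feature table from scored stage outputs
#'
#' Merges questionnaires, web-task scores (SSRT, go RT, mean SSD,
#' false-alarm rate), the D-score, and the chocolate-trial biometric and
#' gaze parameters into the fixed 16-predictor set plus intake.
#'
#' @param participants participant table with questionnaires and
#'   `intake_kcal`.
#' @param kin_summary long kinematic cell summary ([filter_and_aggregate()]).
#' @param gaze_summary long gaze cell summary.
#' @param sst_results output of [score_sst()].
#' @param iat_results output of [score_sciat()].
#' @return data.frame, one row per participant, columns [predictor_set()]
#'   plus `intake_kcal`; rows with invalid scores carry `NA` so that
#'   downstream fitting is complete-case.
#' @export
build_features <- function(participants, kin_summary, gaze_summary,
                           sst_results, iat_results) {
  pick <- function(sumtab, var, trial_type) {
    sl <- sumtab[sumtab$variable == var & sumtab$category == "chocolate" &
                   sumtab$trial_type == trial_type, ]
    sl$mean[match(participants$id, sl$participant_id)]
  }
  sst <- sst_results[match(participants$id, sst_results$participant_id), ]
  iat <- iat_results[match(participants$id, iat_results$participant_id), ]
  out <- data.frame(
    participant_id = participants$id,
    fcq_trait = participants$fcq_trait,
    fcq_state = participants$fcq_state,
    bis15 = participants$bis15,
    ssrt_choc = ifelse(sst$valid, sst$ssrt_choc, NA_real_),
    rt_go = sst$rt_go,
    ssd_mean = sst$ssd_mean,
    fa_rate = sst$fa_rate,
    d_score = ifelse(iat$valid, iat$d_score, NA_real_),
    pv_choc = pick(kin_summary, "pv", "go"),
    pa_choc = pick(kin_summary, "pa", "go"),
    tts_choc = pick(kin_summary, "tts", "stop"),
    bd_choc = pick(kin_summary, "bd", "stop"),
    maxz_choc = pick(kin_summary, "maxz", "stop"),
    it_choc = pick(kin_summary, "it", "go"),
    dwell_first_choc = pick(gaze_summary, "dwell_first", "go"),
    dwell_total_choc = pick(gaze_summary, "dwell_total", "go"),
    intake_kcal = participants$intake_kcal,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the complete analysis pipeline
#'
#' Executes every stage in order on a synthetic cohort: simulation,
#' kinematic and gaze extraction, stop-signal and SC-IAT scoring, group
#' statistics, and intake model fitting. Each stage writes a CSV/JSON
#' artifact into `out_dir`; the run manifest records the config snapshot,
#' the seed, per-stage row counts and exclusions, and an MD5 digest of
#' every file.
#'
#' @param config a [study_config()] or the path to a YAML/JSON file with
#'   `study_config()` arguments.
#' @param out_dir output directory (created if missing).
#' @param seed overrides `config$rng_seed` when non-`NULL`.
#' @param fit_seed seed for the cross-validation folds.
#' @return the manifest, invisibly (list with `config`, `seed`, `stages`,
#'   `digests`, `created`).
#' @examples
#' \donttest{
#' cfg <- study_config(n_participants = 2, n_vr_trials = 8, rng_seed = 1)
#' mf <- run_pipeline(cfg, tempfile("run"))
#' names(mf$digests)
#' }
#' @export
run_pipeline <- function(config = study_config(), out_dir, seed = NULL,
                         fit_seed = 1L) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$rng_seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- stage_files(out_dir)
  log <- list()

  # -- simulate ----------------------------------------------------------
  coh <- generate_cohort(cfg)
  write_csv_plain(coh$participants, fp[["participants"]])
  write_csv_plain(coh$trials, fp[["trials"]])
  write_csv_plain(coh$ground_truth$participants, fp[["truth"]])
  write_csv_plain(coh$ground_truth$trials, fp[["trial_truth"]])
  write_csv_plain(coh$sst_trials, fp[["sst"]])
  write_csv_plain(coh$iat_trials, fp[["iat"]])
  jsonlite::write_json(unclass(cfg), fp[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log$simulate <- list(participants = nrow(coh$participants),
                       vr_samples = nrow(coh$trials))

  # -- extract kinematics ------------------------------------------------
  trials <- read_csv_plain(require_stage_input(fp[["trials"]], "extract"))
  trials$gaze_hit <- as.logical(trials$gaze_hit)
  kin <- extract_kinematics(trials, object_depth = cfg$object_depth,
                            collision_radius = cfg$collision_radius)
  write_csv_plain(kin, fp[["kin"]])
  kin_sum <- filter_and_aggregate(kin)
  write_csv_plain(kin_sum, fp[["kin_summary"]])
  log$extract <- list(trials = nrow(kin),
                      unusable = sum(!kin$usable),
                      flagged_cells = sum(kin_sum$flagged))

  # -- gaze --------------------------------------------------------------
  gz <- extract_gaze(trials, sample_rate = cfg$sample_rate)
  write_csv_plain(gz, fp[["gaze"]])
  gz_sum <- filter_and_aggregate(gz, vars = c("dwell_first", "dwell_total"))
  write_csv_plain(gz_sum, fp[["gaze_summary"]])
  log$gaze <- list(trials = nrow(gz))

  # -- score web tasks ---------------------------------------------------
  sst_tab <- read_csv_plain(require_stage_input(fp[["sst"]], "score-sst"))
  sst_tab$responded <- as.logical(sst_tab$responded)
  sst_res <- score_sst(sst_tab, categories = cfg$categories)
  write_csv_plain(sst_res, fp[["sst_results"]])
  log$score_sst <- list(participants = nrow(sst_res),
                        invalid = sum(!sst_res$valid))

  iat_tab <- read_csv_plain(require_stage_input(fp[["iat"]], "score-iat"))
  iat_tab$correct <- as.logical(iat_tab$correct)
  iat_res <- score_sciat(iat_tab)
  write_csv_plain(iat_res, fp[["iat_results"]])
  log$score_iat <- list(participants = nrow(iat_res),
                        rejected = sum(!iat_res$valid))

  # -- group statistics --------------------------------------------------
  cells <- summary_wide(rbind(kin_sum, gz_sum))
  gstats <- group_statistics(
    cells, data.frame(participant_id = coh$participants$id,
                      intake_kcal = coh$participants$intake_kcal))
  write_csv_plain(gstats, fp[["stats"]])
  log$stats <- list(rows = nrow(gstats))

  # -- features + fit ----------------------------------------------------
  feats <- build_features(coh$participants, kin_sum, gz_sum, sst_res,
                          iat_res)
  write_csv_plain(feats, fp[["features"]])
  n_complete <- sum(stats::complete.cases(
    feats[, c(intersect(predictor_set(), names(feats)), "intake_kcal")]))
  fit <- NULL
  if (n_complete > 6) {
    fit <- intake_fit(feats, seed = fit_seed)
    w <- coef(fit)
    write_csv_plain(cbind(data.frame(predictor = rownames(w)), w),
                    fp[["weights"]])
    report <- lapply(fit$models, function(m)
      list(weights = as.list(m$weights), intercept = m$intercept,
           selected = m$selected, mae_in = m$mae_in, mae_out = m$mae_out,
           alpha = m$alpha, lambda = m$lambda))
    jsonlite::write_json(list(n = fit$n, models = report), fp[["fit"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log$fit <- list(complete_cases = n_complete, fitted = !is.null(fit))

  # -- manifest ----------------------------------------------------------
  outputs <- fp[names(fp) != "manifest"]
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("stopreach")),
    seed = cfg$rng_seed, fit_seed = fit_seed,
    config = unclass(cfg),
    stages = log,
    digests = as.list(tools::md5sum(sort(unname(outputs)))),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, fp[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Accept a study_config, a plain list of arguments, or a YAML/JSON path.
load_config <- function(config) {
  if (inherits(config, "study_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    args <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
            else jsonlite::read_json(config, simplifyVector = TRUE)
    known <- names(formals(study_config))
    args <- args[intersect(names(args), known)]
    if (!is.null(args$intake_model$true_weights))
      args$intake_model$true_weights <-
        unlist(args$intake_model$true_weights)
    return(do.call(study_config, args))
  }
  if (is.list(config)) return(do.call(study_config, config))
  stop("config must be a study_config, an argument list, or a file path")
}
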