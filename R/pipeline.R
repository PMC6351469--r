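## End-to-end pipeline: simulate (or ingest) -> postural scores -> gaze
## features -> importance/selection -> leave-one-out prediction -> cohort
## report. Modelling runs on the patient subgroup only; the group comparison
## uses all subjects. Every artifact is stamped with a config hash and all
## randomness derives from one seed, so a rerun with the same config
## reproduces every numeric output exactly.

#' Pipeline configuration
#'
#' All defaults equal the package's stated design choices: 25 Hz CoP
#' resampling with a one-period (0.04 s) averaging window, 1 s local
#' windows over the final 25 s, I-VT at 30 deg/s with 60 ms minimum
#' fixation and 75 ms maximum bridgeable gap, a 500-tree forest with
#' `ceiling(p/3)` features per split and minimum leaf 2, five importance
#' runs and a 0.1 selection threshold.
#'
#' @param cohort A [cohort_config()] to simulate from, or `NULL` when
#'   reading CSV inputs.
#' @param gaze_csv,cop_csv,clinical_csv Input paths (used when `cohort` is
#'   `NULL`).
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param cop_rate,swarii_window,window_len,keep_last CoP processing
#'   parameters.
#' @param ivt_threshold,min_fixation,max_gap Gaze event detection
#'   parameters.
#' @param forest A [forest_config()] (its seed is overridden by `seed`).
#' @param n_importance_runs,selection_threshold Importance protocol.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), gaze_csv = NULL,
                            cop_csv = NULL, clinical_csv = NULL,
                            out_dir = tempfile("posturogaze_run_"),
                            seed = 1,
                            cop_rate = 25, swarii_window = 1 / cop_rate,
                            window_len = 1, keep_last = 25,
                            ivt_threshold = 30, min_fixation = 60,
                            max_gap = 75,
                            forest = forest_config(),
                            n_importance_runs = 5,
                            selection_threshold = 0.1) {
  structure(list(cohort = cohort, gaze_csv = gaze_csv, cop_csv = cop_csv,
                 clinical_csv = clinical_csv, out_dir = out_dir, seed = seed,
                 cop_rate = cop_rate, swarii_window = swarii_window,
                 window_len = window_len, keep_last = keep_last,
                 ivt_threshold = ivt_threshold, min_fixation = min_fixation,
                 max_gap = max_gap, forest = forest,
                 n_importance_runs = n_importance_runs,
                 selection_threshold = selection_threshold),
            class = "pipeline_config")
}

config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL                    # location must not change the hash
  fnv1a_hash(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}

#' Read and validate a cohort from CSV files
#'
#' Expects `gaze_csv` (subject_id, t_s, gaze_x_deg, gaze_y_deg, valid),
#' `cop_csv` (subject_id, condition, t_s, cop_x_cm, cop_y_cm) and
#' `clinical_csv` (subject_id, group, optionally attention_subscore and
#' planted-truth columns). Gaze timestamps must be uniform and increasing,
#' CoP timestamps strictly increasing per subject/condition; offending
#' subjects are named in the error. Subjects present in one table but not
#' the other are dropped with a warning.
#'
#' @param gaze_csv,cop_csv,clinical_csv File paths.
#' @return List with `gaze` (named list of `gaze_recording`s), `cop` (named
#'   list of `cop_recording`s) and `clinical` (data frame).
#' @export
read_recordings <- function(gaze_csv, cop_csv, clinical_csv) {
  need <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0)
      stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  }
  gz <- read.csv(gaze_csv, stringsAsFactors = FALSE)
  need(gz, c("subject_id", "t_s", "gaze_x_deg", "gaze_y_deg", "valid"),
       gaze_csv)
  cp <- read.csv(cop_csv, stringsAsFactors = FALSE)
  need(cp, c("subject_id", "condition", "t_s", "cop_x_cm", "cop_y_cm"),
       cop_csv)
  cl <- read.csv(clinical_csv, stringsAsFactors = FALSE)
  need(cl, c("subject_id", "group"), clinical_csv)

  gaze <- list()
  for (s in unique(gz$subject_id)) {
    d <- gz[gz$subject_id == s, ]
    dt <- diff(d$t_s)
    if (any(dt <= 0))
      stopf("gaze timestamps for subject %s are not increasing (first at row %d)",
            s, which(dt <= 0)[1] + 1)
    if (max(dt) - min(dt) > 1e-6)
      stopf("gaze sampling for subject %s is not uniform", s)
    rate <- 1 / median(dt)
    gaze[[s]] <- gaze_recording(s, rate, d$gaze_x_deg, d$gaze_y_deg,
                                as.logical(d$valid))
  }
  cop <- list()
  for (s in unique(cp$subject_id)) {
    for (cond in unique(cp$condition[cp$subject_id == s])) {
      d <- cp[cp$subject_id == s & cp$condition == cond, ]
      bad <- which(diff(d$t_s) <= 0)
      if (length(bad) > 0)
        stopf("CoP timestamps for subject %s (%s) are not strictly increasing (row %d)",
              s, cond, bad[1] + 1)
      cop[[paste0(s, ".", cond)]] <-
        cop_recording(s, cond, d$t_s, d$cop_x_cm, d$cop_y_cm)
    }
  }

  in_gaze <- unique(gz$subject_id)
  in_cop <- unique(cp$subject_id)
  common <- intersect(intersect(in_gaze, in_cop), cl$subject_id)
  dropped <- setdiff(union(in_gaze, in_cop), common)
  if (length(dropped) > 0) {
    warning(sprintf("subject(s) %s missing from one of the tables; dropped",
                    paste(dropped, collapse = ", ")))
    gaze <- gaze[names(gaze) %in% common]
    keep <- vapply(cop, function(r) r$subject_id %in% common, TRUE)
    cop <- cop[keep]
    cl <- cl[cl$subject_id %in% common, ]
  }
  list(gaze = gaze, cop = cop, clinical = cl)
}

impute_median <- function(X) {
  log <- character()
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) {
      X[na, j] <- median(X[!na, j])
      log <- c(log, sprintf("%s: %d value(s) imputed with cohort median %.4g",
                            colnames(X)[j], sum(na), median(X[!na, j])))
    }
  }
  list(X = X, log = log)
}

#' Run the full oculo-postural pipeline
#'
#' Simulates a cohort (or reads CSVs), computes postural scores for all
#' subjects, extracts the 18 oculomotor biomarkers, then -- on the patient
#' subgroup only -- runs repeated out-of-bag permutation importance,
#' quartile-threshold selection, and leave-one-out prediction with all
#' features and with the selected subset. Writes `scores.csv`,
#' `features.csv`, `importance.csv`, `predictions_all.csv`,
#' `predictions_selected.csv`, `report.json` and `run_log.json` into
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort)
    gaze <- cohort$gaze
    cop <- cohort$cop
    clinical <- cohort$truth
  } else {
    bundle <- read_recordings(config$gaze_csv, config$cop_csv,
                              config$clinical_csv)
    gaze <- bundle$gaze
    cop <- bundle$cop
    clinical <- bundle$clinical
  }

  scored <- score_cohort(cop, seed = config$seed, rate = config$cop_rate,
                         swarii_window = config$swarii_window,
                         window_len = config$window_len,
                         keep_last = config$keep_last)
  scores <- scored$scores

  features <- extract_gaze_features(gaze,
                                    velocity_threshold = config$ivt_threshold,
                                    min_fixation = config$min_fixation,
                                    max_gap = config$max_gap,
                                    window_len = config$window_len)

  merged <- merge(features, scores, by = "subject_id")
  merged <- merge(merged, clinical[, c("subject_id", "group")],
                  by = "subject_id")
  merged <- merged[order(merged$subject_id), ]
  pat <- merged[merged$group == "patient", ]

  fn <- oculomotor_feature_names()
  Xp <- as.matrix(pat[, fn])
  rownames(Xp) <- pat$subject_id
  imp_res <- impute_median(Xp)
  Xp <- imp_res$X
  yp <- pat$score

  cfg <- config$forest
  cfg$seed <- config$seed
  importance <- oob_permutation_importance(
    Xp, yp, cfg, n_runs = config$n_importance_runs,
    threshold = config$selection_threshold)
  selected <- select_features(importance, config$selection_threshold)

  pred_all <- loo_predict(Xp, yp, cfg, subject_id = pat$subject_id)
  pred_sel <- if (length(selected) >= 1)
    loo_predict(Xp, yp, cfg, features = selected,
                subject_id = pat$subject_id) else NULL

  report <- cohort_report(scores,
                          clinical[, intersect(names(clinical),
                                               c("subject_id", "group",
                                                 "attention_subscore"))])

  # ---- artifacts (no timestamps: reruns must be byte-identical) ----
  out <- function(f) file.path(config$out_dir, f)
  write.csv(scores, out("scores.csv"), row.names = FALSE)
  write.csv(features, out("features.csv"), row.names = FALSE)
  imp_df <- data.frame(feature = rownames(importance$imp_runs),
                       importance$imp_runs,
                       quartile25 = importance$quartile25,
                       selected = importance$selected,
                       row.names = NULL)
  write.csv(imp_df, out("importance.csv"), row.names = FALSE)
  write.csv(pred_all$table, out("predictions_all.csv"), row.names = FALSE)
  if (!is.null(pred_sel))
    write.csv(pred_sel$table, out("predictions_selected.csv"),
              row.names = FALSE)
  report_json <- list(
    config_hash = hash,
    groups = cbind(group = rownames(report$groups), report$groups),
    rank_sum = report$rank_sum[c("statistic", "p_value", "method",
                                 "n1", "n2")],
    attention = if (!is.null(report$attention))
      report$attention[c("r", "p_value", "n")] else NULL,
    selected_features = selected,
    rmse_norm_all = pred_all$rmse_norm,
    rmse_norm_all_excl = pred_all$rmse_norm_excl,
    rmse_norm_selected = if (!is.null(pred_sel)) pred_sel$rmse_norm else NULL,
    rmse_norm_selected_excl = if (!is.null(pred_sel))
      pred_sel$rmse_norm_excl else NULL)
  jsonlite::write_json(report_json, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows",
                       null = "null")
  jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                            importance_seeds = importance$seeds,
                            imputation_log = imp_res$log,
                            n_subjects = nrow(merged),
                            n_patients = nrow(pat)),
                       out("run_log.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(config = config, config_hash = hash, scores = scores,
                 features = features, importance = importance,
                 selected = selected, prediction_all = pred_all,
                 prediction_selected = pred_sel, report = report,
                 model = scored$model, clinical = clinical))
}
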