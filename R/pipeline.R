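#' End-to-end pipeline configuration
#'
#' Collects every tunable of the analysis: preprocessing (resampling target,
#' epoch length, rejection threshold), adaptive SSA (window `L`, retained
#' components `C`, eigenvalue-similarity `k_sim`, EOG amplitude switch),
#' feature bands (CoG search window, fixed alpha band), and classification
#' (folds, SVM cost, seed).
#'
#' @param input_mode `"synthetic"` (generate from `cohort`) or `"csv_dir"`
#'   (read a cohort written by [write_cohort_csv()] from `data_dir`).
#' @param cohort A [cohort_spec()] (synthetic mode).
#' @param data_dir Directory with a cohort manifest (csv_dir mode).
#' @param channels Analysis channels (default occipital O1, O2).
#' @param fs_target Resampling target, Hz (default 200).
#' @param epoch_seconds Epoch length, s (default 4).
#' @param amp_threshold Epoch rejection threshold, uV (default 200).
#' @param eog_amp_threshold 1-vs-2 component removal switch, uV (default 100).
#' @param L,C,k_sim SSA parameters (defaults 60, 12, 0.05).
#' @param cog_n,cog_m CoG search band, Hz (defaults 7, 14).
#' @param fixed_band Conventional alpha band, Hz (default 8-12).
#' @param cv_folds Cross-validation folds (default 10).
#' @param svm_cost Linear-SVM cost (default 1).
#' @param seed Master seed for cohort generation and fold splits.
#' @param keep_channels Keep per-channel feature columns.
#' @param output_dir If non-`NULL`, write feature CSV, results JSON, ROC
#'   CSVs, rejection log and a config snapshot there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "csv_dir"),
                            cohort = cohort_spec(), data_dir = NULL,
                            channels = c("O1", "O2"),
                            fs_target = 200, epoch_seconds = 4,
                            amp_threshold = 200, eog_amp_threshold = 100,
                            L = 60, C = 12, k_sim = 0.05,
                            cog_n = 7, cog_m = 14, fixed_band = c(8, 12),
                            cv_folds = 10, svm_cost = 1, seed = 0,
                            keep_channels = FALSE, output_dir = NULL) {
  input_mode <- match.arg(input_mode)
  stopifnot(fs_target > 0, epoch_seconds > 0, amp_threshold > 0,
            eog_amp_threshold > 0, C <= L, L < round(fs_target * epoch_seconds),
            k_sim > 0, cog_n < cog_m, fixed_band[1] < fixed_band[2],
            cv_folds >= 2, svm_cost > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' The five reported feature sets
#'
#' ABP#1 (fixed-band frequency-domain energy), ABP#2 (fixed-band
#' time-domain energy of the SSA rhythm), iABP (individualized-band
#' time-domain energy), iAPF (CoG peak frequency), and iABP + iAPF.
#' @return Named list mapping feature-set label to feature column names.
#' @export
feature_sets <- function() {
  list("ABP#1" = "abp1", "ABP#2" = "abp2", "iABP" = "iABP",
       "iAPF" = "iAPF", "iABP+iAPF" = c("iABP", "iAPF"))
}

#' Extract the per-subject feature table for a cohort
#'
#' Runs preprocessing (resample, segment, amplitude rejection) and
#' [subject_features()] for every recording. Subjects with no surviving
#' epochs are excluded with a reason rather than failing the run.
#'
#' @param cohort List of `labeled_recording`s (see [generate_cohort()],
#'   [read_cohort_csv()]).
#' @param cfg A [pipeline_config()].
#' @return List with `features` (data.frame: subject_id, group, true_iapf,
#'   feature columns, n_epochs_total/kept), `excluded` (data.frame of
#'   subject_id, reason).
#' @export
cohort_features <- function(cohort, cfg = pipeline_config()) {
  p <- feature_params(L = cfg$L, C = cfg$C, k_sim = cfg$k_sim,
                      eog_amp_threshold = cfg$eog_amp_threshold,
                      fixed_band = cfg$fixed_band,
                      cog_n = cfg$cog_n, cog_m = cfg$cog_m,
                      keep_channels = cfg$keep_channels)
  rows <- list(); excluded <- list(); logs <- list()
  for (subj in cohort) {
    res <- tryCatch({
      rec <- resample_to(subj$recording, cfg$fs_target)
      es <- segment_epochs(rec, cfg$epoch_seconds)
      n_total <- length(es$epochs)
      peaks <- es$peak_amplitudes
      es <- reject_epochs(es, cfg$amp_threshold)
      logs[[length(logs) + 1L]] <-
        data.frame(subject_id = subj$subject_id,
                   epoch = seq_len(n_total),
                   kept = seq_len(n_total) %in% es$kept_indices,
                   peak_amplitude = peaks)
      if (length(es$epochs) == 0L) stop("all epochs rejected", call. = FALSE)
      ft <- subject_features(es, channels = cfg$channels, params = p)
      cbind(data.frame(subject_id = subj$subject_id, group = subj$group,
                       true_iapf = if (is.null(subj$true_iapf)) NA_real_
                                   else subj$true_iapf,
                       n_epochs_total = n_total), ft)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = subj$subject_id, group = subj$group,
                   reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(subject_id = character(),
                                  group = character(), reason = character()),
       epoch_log = if (length(logs)) do.call(rbind, logs) else NULL)
}

#' Run the full analysis pipeline
#'
#' Generates or reads a cohort, extracts per-subject alpha features,
#' compares group iAPF with a pooled two-sample t test, and evaluates all
#' five feature sets with a stratified 10-fold linear SVM. Deterministic
#' given the configuration (including its seed).
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report`: list with `features`, `excluded`, `cv` (named
#'   list of [crossval_linear_svm()] results), `iapf_test`, `group_summary`,
#'   `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  cohort <- switch(cfg$input_mode,
    synthetic = generate_cohort(cfg$cohort),
    csv_dir = read_cohort_csv(cfg$data_dir))
  cf <- cohort_features(cohort, cfg)
  feats <- cf$features
  if (is.null(feats) || length(unique(feats$group)) < 2L ||
      min(table(feats$group)) < 2L)
    stop("fewer than 2 subjects per group survived preprocessing",
         call. = FALSE)
  gs <- do.call(rbind, lapply(split(feats, feats$group), function(d)
    data.frame(group = d$group[1L], n = nrow(d),
               iapf_mean = mean(d$iAPF), iapf_sd = stats::sd(d$iAPF),
               iabp_mean = mean(d$iABP))))
  iapf_test <- pooled_t(gs$iapf_mean[1L], gs$iapf_sd[1L], gs$n[1L],
                        gs$iapf_mean[2L], gs$iapf_sd[2L], gs$n[2L])
  cv <- lapply(feature_sets(), function(cols)
    crossval_linear_svm(feats, feats$group, feature_subset = cols,
                        k = cfg$cv_folds, cost = cfg$svm_cost,
                        seed = cfg$seed))
  report <- structure(
    list(features = feats, excluded = cf$excluded, epoch_log = cf$epoch_log,
         cv = cv, iapf_test = iapf_test, group_summary = gs, config = cfg),
    class = "run_report")
  if (!is.null(cfg$output_dir)) write_run_report(report, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Alpha-rhythm pipeline report\n")
  cat(sprintf("  subjects analyzed: %d (%d excluded)\n",
              nrow(x$features), nrow(x$excluded)))
  for (i in seq_len(nrow(x$group_summary)))
    cat(sprintf("  %s: n = %d, iAPF %.3f +/- %.3f Hz\n",
                x$group_summary$group[i], x$group_summary$n[i],
                x$group_summary$iapf_mean[i], x$group_summary$iapf_sd[i]))
  cat(sprintf("  group iAPF t = %.3f (df %.1f, p = %.2g)\n",
              x$iapf_test$statistic, x$iapf_test$df, x$iapf_test$p.value))
  cat("  feature set        accuracy    AUC\n")
  for (nm in names(x$cv))
    cat(sprintf("  %-16s %8.2f%% %10.4f\n", nm,
                100 * x$cv[[nm]]$mean_accuracy, x$cv[[nm]]$auc))
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' Emits `features.csv`, `excluded.csv`, `rejection_log.csv` (per subject
#' and epoch: kept flag and peak amplitude), `results.json` (per feature
#' set: fold accuracies, mean accuracy, AUC, seed), one `roc_<set>.csv`
#' per feature set, and `config.txt` (flat key = value snapshot).
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(report$excluded, file.path(dir, "excluded.csv"),
                   row.names = FALSE)
  if (!is.null(report$epoch_log))
    utils::write.csv(report$epoch_log, file.path(dir, "rejection_log.csv"),
                     row.names = FALSE)
  res <- lapply(report$cv, function(cv)
    list(fold_accuracies = cv$fold_accuracies,
         mean_accuracy = cv$mean_accuracy, auc = cv$auc, seed = cv$seed,
         features = cv$features))
  res$iapf_t_test <- report$iapf_test[c("statistic", "df", "p.value")]
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$cv)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    utils::write.csv(as.data.frame(report$cv[[nm]]$roc_points),
                     file.path(dir, paste0("roc_", safe, ".csv")),
                     row.names = FALSE)
  }
  writeLines(.config_lines(report$config), file.path(dir, "config.txt"))
  invisible(dir)
}

.config_lines <- function(cfg) {
  flat <- list(
    input_mode = cfg$input_mode, fs_target = cfg$fs_target,
    epoch_seconds = cfg$epoch_seconds, amp_threshold = cfg$amp_threshold,
    eog_amp_threshold = cfg$eog_amp_threshold, L = cfg$L, C = cfg$C,
    k_sim = cfg$k_sim, cog_n = cfg$cog_n, cog_m = cfg$cog_m,
    fixed_band = paste(cfg$fixed_band, collapse = ","),
    channels = paste(cfg$channels, collapse = ","),
    cv_folds = cfg$cv_folds, svm_cost = cfg$svm_cost, seed = cfg$seed)
  paste(names(flat), unlist(flat), sep = " = ")
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value` (comments with `#`); keys mirror the
#' arguments of [pipeline_config()]; unknown keys error. Values listed
#' comma-separated (e.g. `fixed_band = 8,12`) become numeric/character
#' vectors.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file (e.g. from CLI flags).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("bad config line: ", paste(p, collapse = "="),
                              call. = FALSE)
    key <- trimws(p[[1L]]); val <- trimws(p[[2L]])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (anyNA(num)) parts else num
  }
  allowed <- setdiff(names(formals(pipeline_config)), c("cohort"))
  bad <- setdiff(names(args), allowed)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- utils::modifyList(args, list(...))
  do.call(pipeline_config, args)
}
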