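#' Write a synthetic cohort to plain-text files
#'
#' One CSV per subject (header row of channel labels, one sample per line),
#' a YAML sidecar per subject with the sampling rate and group label, and a
#' cohort `manifest.csv` (subject_id, group, file, true_iapf).
#'
#' @param cohort List of `labeled_recording`s.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(cohort, function(subj) {
    file <- paste0(subj$subject_id, ".csv")
    utils::write.csv(as.data.frame(t(subj$recording$data)),
                     file.path(dir, file), row.names = FALSE)
    yaml::write_yaml(list(subject_id = subj$subject_id,
                          fs = subj$recording$fs, group = subj$group),
                     file.path(dir, paste0(subj$subject_id, ".yaml")))
    data.frame(subject_id = subj$subject_id, group = subj$group,
               file = file,
               true_iapf = if (is.null(subj$true_iapf)) NA_real_
                           else subj$true_iapf)
  }))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read one recording from CSV
#'
#' @param file CSV with a header row of channel labels, one sample per line.
#' @param fs Sampling rate, Hz; if `NULL`, read from the `.yaml` sidecar
#'   next to `file`.
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(file, fs = NULL) {
  if (is.null(fs)) {
    sidecar <- sub("\\.csv$", ".yaml", file)
    if (!file.exists(sidecar))
      stop("no fs given and no sidecar found: ", sidecar, call. = FALSE)
    fs <- yaml::read_yaml(sidecar)$fs
  }
  df <- utils::read.csv(file, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs, channel_labels = colnames(df))
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `manifest.csv`, per-subject CSVs and
#'   YAML sidecars.
#' @return List of `labeled_recording`s.
#' @export
read_cohort_csv <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_recording_csv(file.path(dir, manifest$file[i]))
    structure(list(recording = rec, group = manifest$group[i],
                   subject_id = manifest$subject_id[i],
                   true_iapf = manifest$true_iapf[i],
                   true_alpha_amp = NA_real_, eog_onsets = numeric(0)),
              class = "labeled_recording")
  })
}
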