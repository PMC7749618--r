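#' Multichannel EEG recording
#'
#' @param data Numeric channels x samples matrix, in uV. Row names, if
#'   present, are used as channel labels.
#' @param fs Sampling rate, Hz.
#' @param channel_labels Optional labels overriding row names.
#' @return An `eeg_recording`: list with `data`, `fs`, `channel_labels`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(fs > 0, length(channel_labels) == nrow(data),
            !anyDuplicated(channel_labels))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channel(s) x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Anti-aliased downsampling of a recording
#'
#' Applies a zero-phase low-pass (flat to `0.4 * target_fs`, raised-cosine
#' roll-off reaching zero at `0.45 * target_fs`) and then reduces the rate.
#' Integer rate ratios are decimated directly; other rational ratios go
#' through [signal::resample()] after the same anti-alias filter. Output
#' length is `floor(N * target_fs / fs)`. Upsampling is not supported.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target rate, Hz (<= `rec$fs`).
#' @return An [eeg_recording()] at `target_fs`.
#' @export
resample_to <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"), target_fs > 0)
  if (target_fs > rec$fs)
    stop("upsampling is not supported", call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$data)
  out_len <- floor(n * target_fs / rec$fs)
  ratio <- rec$fs / target_fs
  filt <- t(apply(rec$data, 1L, .fft_lowpass, fs = rec$fs,
                  pass = 0.4 * target_fs, stop = 0.45 * target_fs))
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- round(ratio)
    out <- filt[, seq(1L, by = q, length.out = out_len), drop = FALSE]
  } else {
    fr <- .as_fraction(target_fs / rec$fs)
    out <- t(apply(filt, 1L, function(x)
      signal::resample(x, p = fr[1], q = fr[2])[seq_len(out_len)]))
  }
  eeg_recording(out, target_fs, rec$channel_labels)
}

# small-denominator rational approximation of a ratio in (0, 1)
.as_fraction <- function(r, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < 1e-9) return(c(p, q))
  }
  stop("sampling-rate ratio is not a small rational number", call. = FALSE)
}

#' Cut a recording into non-overlapping fixed-length epochs
#'
#' Splits the recording into consecutive `epoch_seconds` blocks; trailing
#' samples that do not fill a whole epoch are discarded.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_seconds Epoch length, s (default 4).
#' @return An `epoch_set`: list with `epochs` (list of channels x samples
#'   matrices), `fs`, `epoch_seconds`, `channel_labels`, `kept_indices`
#'   (original epoch numbers), `rejected_count`, `peak_amplitudes`.
#' @export
segment_epochs <- function(rec, epoch_seconds = 4) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_seconds > 0)
  ns <- round(rec$fs * epoch_seconds)
  n_ep <- floor(ncol(rec$data) / ns)
  if (n_ep < 1L)
    stop("recording shorter than one epoch", call. = FALSE)
  epochs <- lapply(seq_len(n_ep), function(k)
    rec$data[, ((k - 1L) * ns + 1L):(k * ns), drop = FALSE])
  structure(list(epochs = epochs, fs = rec$fs,
                 epoch_seconds = epoch_seconds,
                 channel_labels = rec$channel_labels,
                 kept_indices = seq_len(n_ep), rejected_count = 0L,
                 peak_amplitudes = vapply(epochs, function(e) max(abs(e)),
                                          numeric(1))),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epoch(s) of %g s at %g Hz (%d rejected)\n",
              length(x$epochs), x$epoch_seconds, x$fs, x$rejected_count))
  invisible(x)
}

#' Amplitude-threshold epoch rejection
#'
#' An epoch is kept iff the absolute value never exceeds `amp_threshold` on
#' any channel; an artifact on any channel discards the whole epoch.
#' Idempotent; the surviving set may be empty (downstream stages must
#' check).
#'
#' @param es An [segment_epochs()] result.
#' @param amp_threshold Rejection threshold, uV (default 200).
#' @return An `epoch_set` with `kept_indices` and `rejected_count` updated.
#' @export
reject_epochs <- function(es, amp_threshold = 200) {
  stopifnot(inherits(es, "epoch_set"), amp_threshold > 0)
  keep <- es$peak_amplitudes <= amp_threshold
  es$epochs <- es$epochs[keep]
  es$kept_indices <- es$kept_indices[keep]
  es$peak_amplitudes <- es$peak_amplitudes[keep]
  es$rejected_count <- es$rejected_count + sum(!keep)
  es
}
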