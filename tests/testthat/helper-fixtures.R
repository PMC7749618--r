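# shared fixtures: everything is generated in code, nothing read from disk

fs_default <- 200
epoch_t <- (0:799) / fs_default   # one 4-s epoch at 200 Hz

tone <- function(f0, amp = 1, t = epoch_t) amp * sin(2 * pi * f0 * t)

# recording with a given channels x samples matrix of pure tones
tone_recording <- function(f0, amp = 20, fs = fs_default, dur = 4,
                           channels = c("O1", "O2")) {
  tt <- (seq_len(round(fs * dur)) - 1) / fs
  data <- matrix(rep(amp * sin(2 * pi * f0 * tt), length(channels)),
                 nrow = length(channels), byrow = TRUE,
                 dimnames = list(channels, NULL))
  eeg_recording(data, fs)
}

quiet_group <- function(...) {
  td_group(bg_scale = 0, eog_rate = 0, emg_rate = 0, iapf_sd = 0, ...)
}

low_band_power <- function(x, fs, lim = 2) {
  ps <- power_spectrum(x, fs)
  sum(ps$power[ps$freqs > 0 & ps$freqs < lim])
}

spectrum_argmax <- function(x, fs) {
  ps <- power_spectrum(x, fs)
  ps$freqs[-1][which.max(ps$power[-1])]   # skip DC
}
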