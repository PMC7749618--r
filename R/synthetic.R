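#' Group-level generative parameters for a synthetic EEG cohort
#'
#' Describes one group (e.g. typically developing vs. ASD children) of a
#' simulated resting-state cohort: the distribution of the subject-level
#' alpha peak frequency and alpha amplitude, the 1/f background, and the
#' rates and sizes of ocular (EOG) and muscular (EMG) artifacts.
#'
#' @param label Group name.
#' @param iapf_mean,iapf_sd Subject alpha peak frequency distribution, Hz.
#'   One frequency is drawn per subject and shared across channels.
#' @param alpha_amp_mean,alpha_amp_sd Subject alpha amplitude distribution,
#'   uV (amplitude of the modulated carrier).
#' @param alpha_bw Bandwidth of the alpha process, Hz: the amplitude
#'   envelope is low-pass random with cutoff `alpha_bw / 2`, so spectral
#'   sidebands extend about `alpha_bw / 2` either side of the peak.
#' @param bg_scale RMS of the 1/f^exponent background, uV.
#' @param bg_exponent Spectral slope of the background (power ~ 1/f^exponent).
#' @param eog_rate,eog_amp,eog_dur Blink-like EOG bumps: events per minute,
#'   peak amplitude (uV), duration (s). Bumps are smooth raised-cosine
#'   deflections shared across channels.
#' @param emg_rate,emg_amp Muscle bursts: events per minute and peak
#'   amplitude (uV); each burst is 0.2 s of 50-90 Hz band-passed noise.
#' @return A `group_spec` list.
#' @export
group_spec <- function(label,
                       iapf_mean, iapf_sd,
                       alpha_amp_mean, alpha_amp_sd,
                       alpha_bw = 1, bg_scale = 3, bg_exponent = 1,
                       eog_rate = 6, eog_amp = 150, eog_dur = 0.5,
                       emg_rate = 3, emg_amp = 30) {
  stopifnot(iapf_mean > 7, iapf_mean < 14, iapf_sd >= 0,
            alpha_amp_mean >= 0, alpha_amp_sd >= 0, alpha_bw > 0,
            bg_scale >= 0, eog_rate >= 0, eog_amp >= 0, eog_dur > 0,
            emg_rate >= 0, emg_amp >= 0)
  structure(as.list(environment()), class = "group_spec")
}

#' Default typically-developing group
#'
#' Occipital alpha peak frequency 7.92 +/- 0.21 Hz, alpha amplitude
#' 20 +/- 3.5 uV; artifact and background defaults from [group_spec()].
#' @param ... Overrides passed to [group_spec()].
#' @export
td_group <- function(...) {
  args <- utils::modifyList(
    list(label = "TD", iapf_mean = 7.92, iapf_sd = 0.21,
         alpha_amp_mean = 20, alpha_amp_sd = 3.5),
    list(...))
  do.call(group_spec, args)
}

#' Default ASD group
#'
#' Occipital alpha peak frequency 7.54 +/- 0.23 Hz, alpha amplitude
#' 14 +/- 3.0 uV (about 30% below the TD default).
#' @param ... Overrides passed to [group_spec()].
#' @export
asd_group <- function(...) {
  args <- utils::modifyList(
    list(label = "ASD", iapf_mean = 7.54, iapf_sd = 0.23,
         alpha_amp_mean = 14, alpha_amp_sd = 3.0),
    list(...))
  do.call(group_spec, args)
}

#' Full simulated montage
#' @export
eeg_montage <- function() c("F3", "F4", "Tp7", "Tp8", "P3", "P4", "O1", "O2")

#' Cohort-level generative parameters
#'
#' @param groups List of two [group_spec()] objects.
#' @param n_per_group Subjects per group (>= 2).
#' @param fs Sampling rate, Hz (> 28 so the 14-Hz upper analysis edge is
#'   below Nyquist).
#' @param duration Recording length, s (>= 4, one full epoch).
#' @param channels Channel labels to synthesize.
#' @param seed Integer master seed; per-subject child seeds are derived
#'   deterministically from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = list(td_group(), asd_group()),
                        n_per_group = 50, fs = 1000, duration = 300,
                        channels = c("O1", "O2"), seed = 0) {
  stopifnot(length(groups) == 2L,
            all(vapply(groups, inherits, logical(1), "group_spec")),
            n_per_group >= 2, fs > 28, duration >= 4,
            length(channels) >= 1, !anyDuplicated(channels))
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 fs = fs, duration = duration, channels = channels,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Smooth blink-like EOG deflection
#'
#' A raised-cosine (Hann) bump of `round(dur * fs)` samples, rescaled so its
#' maximum equals `amp` exactly; endpoints are zero and, for durations of
#' 0.3 s or more, its spectral energy is concentrated below 2 Hz.
#'
#' @param dur Duration, s (> 0).
#' @param amp Peak amplitude, uV.
#' @param fs Sampling rate, Hz (> 0).
#' @return Numeric vector of length `round(dur * fs)`.
#' @export
eog_event <- function(dur, amp, fs) {
  if (!is.finite(dur) || dur <= 0 || !is.finite(fs) || fs <= 0)
    stop("dur and fs must be positive", call. = FALSE)
  n <- round(dur * fs)
  if (n < 1L) return(numeric(0))
  if (n == 1L) return(amp)
  h <- sin(pi * (0:(n - 1L)) / (n - 1L))^2
  amp * h / max(h)
}

# zero-phase FFT low-pass: unit gain below `pass` Hz, raised-cosine roll-off
# to zero at `stop` Hz
.fft_lowpass <- function(x, fs, pass, stop) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  gain <- rep(1, n)
  trans <- f > pass & f < stop
  gain[trans] <- 0.5 * (1 + cos(pi * (f[trans] - pass) / (stop - pass)))
  gain[f >= stop] <- 0
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

.fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  gain <- as.numeric(f >= lo & f <= hi)
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# 1/f^exponent background with RMS `scale`; flat below 0.5 Hz
.pink_background <- function(n, fs, scale, exponent) {
  if (scale <= 0) return(numeric(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  shape <- 1 / pmax(f, 0.5)^(exponent / 2)
  shape[1L] <- 0                           # no DC offset
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE)) / n
  x * scale / stats::sd(x)
}

# narrowband alpha process: amplitude-modulated sinusoid at f0 so the true
# peak frequency is exact; modulation depth 0.3, envelope cutoff bw/2
.alpha_process <- function(n, fs, f0, amp, bw) {
  t <- (0:(n - 1L)) / fs
  m <- .fft_lowpass(stats::rnorm(n), fs, pass = bw / 2, stop = bw)
  m <- 0.3 * m / stats::sd(m)
  env <- pmax(1 + m, 0)
  amp * env * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
}

# draw from Normal(mean, sd) truncated at +/- 3 sd (keeps true_iapf within
# the documented invariant)
.rnorm_trunc3 <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (abs(x - mean) <= 3 * sd) return(x)
  }
}

#' Simulate one labeled subject recording
#'
#' Each channel is the sum of a narrowband alpha process centered at the
#' subject's alpha peak frequency (drawn once per subject, shared across
#' channels), a 1/f background, Poisson-timed EOG bumps (shared event times
#' across channels), and Poisson-timed EMG bursts. Deterministic given
#' `seed`.
#'
#' @param g A [group_spec()].
#' @param fs Sampling rate, Hz.
#' @param duration Length, s (>= 4).
#' @param channels Channel labels.
#' @param seed Integer seed.
#' @param subject_id Identifier stored on the result.
#' @return A `labeled_recording`: list with `recording` ([eeg_recording()]),
#'   `group`, `subject_id`, `true_iapf` (Hz), `true_alpha_amp` (uV) and
#'   `eog_onsets` (s).
#' @export
generate_subject <- function(g, fs, duration, channels = c("O1", "O2"),
                             seed = 0, subject_id = g$label) {
  if (duration < 4) stop("duration must allow at least one 4-s epoch",
                         call. = FALSE)
  stopifnot(fs > 28)
  n <- round(fs * duration)
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  f0 <- min(max(.rnorm_trunc3(g$iapf_mean, g$iapf_sd), 7.05), 13.95)
  amp <- max(.rnorm_trunc3(g$alpha_amp_mean, g$alpha_amp_sd), 0.5)

  n_eog <- stats::rpois(1, g$eog_rate * duration / 60)
  eog_onsets <- sort(stats::runif(n_eog, 0, max(duration - g$eog_dur, 0)))
  eog <- numeric(n)
  if (n_eog > 0) {
    bump <- eog_event(g$eog_dur, g$eog_amp, fs)
    for (t0 in eog_onsets) {
      i0 <- round(t0 * fs) + 1L
      idx <- i0:min(i0 + length(bump) - 1L, n)
      eog[idx] <- eog[idx] + bump[seq_along(idx)]
    }
  }

  emg_hi <- min(90, 0.45 * fs)
  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  for (ch in seq_along(channels)) {
    x <- .alpha_process(n, fs, f0, amp, g$alpha_bw) +
      .pink_background(n, fs, g$bg_scale, g$bg_exponent) + eog
    n_emg <- stats::rpois(1, g$emg_rate * duration / 60)
    if (n_emg > 0 && emg_hi > 50) {
      nb <- round(0.2 * fs)
      for (t0 in stats::runif(n_emg, 0, max(duration - 0.2, 0))) {
        burst <- .fft_bandpass(stats::rnorm(nb), fs, 50, emg_hi)
        burst <- burst * sin(pi * (0:(nb - 1L)) / (nb - 1L))^2
        burst <- burst * g$emg_amp / max(abs(burst))
        i0 <- round(t0 * fs) + 1L
        idx <- i0:min(i0 + nb - 1L, n)
        x[idx] <- x[idx] + burst[seq_along(idx)]
      }
    }
    data[ch, ] <- x
  }
  structure(list(recording = eeg_recording(data, fs),
                 group = g$label, subject_id = subject_id,
                 true_iapf = f0, true_alpha_amp = amp,
                 eog_onsets = eog_onsets),
            class = "labeled_recording")
}

# run code under a private RNG state; returns a restore function
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# deterministic child seed below 2^31
.child_seed <- function(master, index) {
  (as.double(master %% 2147483647L) * 48271 + index * 10007) %% 2147483647
}

#' Simulate a labeled two-group cohort
#'
#' Generates `2 * n_per_group` recordings, `n_per_group` per group, with
#' per-subject seeds derived deterministically from the cohort seed, so the
#' whole cohort is reproducible from its spec.
#'
#' @param spec A [cohort_spec()].
#' @return List of `labeled_recording`s (group 1 first).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", 2L * spec$n_per_group)
  k <- 0L
  for (gi in 1:2) {
    g <- spec$groups[[gi]]
    for (si in seq_len(spec$n_per_group)) {
      k <- k + 1L
      out[[k]] <- generate_subject(
        g, spec$fs, spec$duration, spec$channels,
        seed = .child_seed(spec$seed, k),
        subject_id = sprintf("%s%03d", g$label, si))
    }
  }
  out
}
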