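#' One-sided periodogram power spectrum
#'
#' Rectangular-window periodogram on the FFT grid (bin width
#' `fs / length(x)`): `P(f_k) = |X_k|^2 / N^2`, doubled at bins that fold
#' (all but DC and, for even N, Nyquist), so `sum(P)` equals the mean
#' square of the series.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @return A `power_spectrum`: list with `freqs`, `power`, `bin_width`.
#' @export
power_spectrum <- function(x, fs) {
  x <- as.numeric(x)
  N <- length(x)
  if (N == 0L) stop("empty series", call. = FALSE)
  nb <- N %/% 2L + 1L
  p <- (Mod(stats::fft(x))[seq_len(nb)] / N)^2
  dbl <- rep(2, nb); dbl[1L] <- 1
  if (N %% 2L == 0L) dbl[nb] <- 1
  structure(list(freqs = (seq_len(nb) - 1L) * fs / N, power = p * dbl,
                 bin_width = fs / N),
            class = "power_spectrum")
}

#' Average several power spectra on a common grid
#' @param spectra List of [power_spectrum()] objects with identical grids.
#' @return A [power_spectrum()].
#' @export
mean_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  f0 <- spectra[[1L]]$freqs
  pw <- rowMeans(vapply(spectra, function(s) {
    stopifnot(length(s$freqs) == length(f0))
    s$power
  }, numeric(length(f0))))
  structure(list(freqs = f0, power = pw, bin_width = spectra[[1L]]$bin_width),
            class = "power_spectrum")
}

#' Frequency band definition
#'
#' @param a,b Band edges, Hz (`0 < a < b`).
#' @param kind `"fixed"` (conventional band) or `"individualized"`
#'   (derived from a subject's alpha center of gravity).
#' @export
band_definition <- function(a, b, kind = c("fixed", "individualized")) {
  stopifnot(a > 0, b > a)
  structure(list(a = a, b = b, kind = match.arg(kind)),
            class = "band_definition")
}

#' Amplitude-adaptive ocular-artifact removal for one epoch channel
#'
#' SSA-decomposes the epoch and removes the leading subspace, where
#' large-amplitude, low-frequency ocular (EOG) activity concentrates: when
#' the epoch's peak absolute amplitude exceeds `eog_amp_threshold`, the
#' components of the two largest eigenvalues are dropped; otherwise only
#' the largest. Returns the sum of the remaining components.
#'
#' @param s Numeric series (one channel of one epoch).
#' @param fs Sampling rate, Hz.
#' @param L SSA window length (default 60).
#' @param eog_amp_threshold Amplitude above which two components are
#'   removed, uV (default 100).
#' @return Cleaned series with attribute `n_removed` (1 or 2).
#' @export
clean_epoch <- function(s, fs, L = 60, eog_amp_threshold = 100) {
  s <- as.numeric(s)
  k <- if (max(abs(s)) > eog_amp_threshold) 2L else 1L
  d <- ssa_decompose(s, L, fs, n_rc = k)
  out <- s - colSums(d$rcs)   # sum of all RCs equals s, so drop the top k
  attr(out, "n_removed") <- k
  out
}

# rhythm extraction from an existing decomposition: group the top-C
# components by eigenvalue similarity + peak frequency, keep groups whose
# peak lies in [a, b], and sum their RCs
.extract_from_decomposition <- function(d, band, C, k_sim = 0.05,
                                        freq_tol = d$fs / d$source_len) {
  comps <- seq_len(min(C, d$n_rc))
  # drop numerically-zero components: their FFT peak is meaningless noise
  comps <- comps[d$eigenvalues[comps] > 1e-9 * max(d$eigenvalues[1], 0)]
  if (length(comps) == 0L) {
    out <- numeric(d$source_len)
    attr(out, "empty_band") <- TRUE
    return(out)
  }
  groups <- rhythm_groups(d, comps, freq_tol = freq_tol, k_sim = k_sim)
  keep <- Filter(function(g) g$peak >= band$a && g$peak <= band$b, groups)
  if (length(keep) == 0L) {
    out <- numeric(d$source_len)
    attr(out, "empty_band") <- TRUE
    return(out)
  }
  ix <- sort(unique(unlist(lapply(keep, `[[`, "components"))))
  out <- colSums(d$rcs[ix, , drop = FALSE])
  attr(out, "components") <- ix
  out
}

#' Extract a band-limited rhythm from a (cleaned) epoch
#'
#' SSA-decomposes the series, restricts attention to the top `C` components
#' by eigenvalue, groups them into rhythms (eigenvalue-similar periodic
#' pairs linked at `k_sim`, then single-linkage merging of components whose
#' FFT peak frequencies differ by at most one bin), and returns the
#' elementwise sum of the groups whose peak frequency falls inside `band`.
#' If no group qualifies, an all-zero series is returned with attribute
#' `empty_band = TRUE`.
#'
#' @param s Numeric series (already artifact-cleaned).
#' @param fs Sampling rate, Hz.
#' @param band A [band_definition()] within Nyquist.
#' @param L SSA window length (default 60).
#' @param C Number of leading components considered (default 12; `C <= L`).
#' @param k_sim Eigenvalue-similarity threshold (default 0.05).
#' @return The extracted rhythm series.
#' @export
extract_rhythm <- function(s, fs, band, L = 60, C = 12, k_sim = 0.05) {
  if (C > L) stop("C must not exceed L", call. = FALSE)
  stopifnot(band$b < fs / 2)
  d <- ssa_decompose(s, L, fs, n_rc = C)
  .extract_from_decomposition(d, band, C, k_sim = k_sim)
}

#' Frequency-domain absolute band energy
#'
#' Ten times the summed spectral power over all bins with
#' `a <= f <= b` (closed interval).
#'
#' @param ps A [power_spectrum()].
#' @param band A [band_definition()].
#' @return Energy value (uV^2-scale units).
#' @export
band_power_freq <- function(ps, band) {
  sel <- ps$freqs >= band$a - 1e-9 & ps$freqs <= band$b + 1e-9
  if (!any(sel)) stop("no spectral bins inside the band", call. = FALSE)
  10 * sum(ps$power[sel])
}

#' Time-domain absolute energy
#'
#' Ten times the sum of squared samples of an extracted-rhythm series.
#'
#' @param x Numeric series.
#' @return Energy value.
#' @export
band_power_time <- function(x) 10 * sum(as.numeric(x)^2)

#' Center-of-gravity alpha peak frequency
#'
#' Power-weighted mean frequency over the bins `n <= f <= m`; more robust
#' to split or broad alpha peaks than the tallest-bin estimate. The result
#' always lies in `[n, m]` and is invariant to rescaling the spectrum.
#'
#' @param ps A [power_spectrum()].
#' @param n,m Band edges, Hz (defaults 7 and 14).
#' @return CoG frequency in Hz.
#' @export
cog_frequency <- function(ps, n = 7, m = 14) {
  sel <- ps$freqs >= n - 1e-9 & ps$freqs <= m + 1e-9
  tot <- sum(ps$power[sel])
  if (!any(sel) || tot <= 0)
    stop("no spectral power inside the alpha search band", call. = FALSE)
  sum(ps$power[sel] * ps$freqs[sel]) / tot
}

#' Individualized alpha band around a center-of-gravity frequency
#'
#' @param cog CoG frequency, Hz.
#' @return A [band_definition()] spanning `0.8 * cog` to `1.2 * cog`.
#' @export
individualized_band <- function(cog) {
  stopifnot(cog > 0)
  band_definition(0.8 * cog, 1.2 * cog, kind = "individualized")
}

#' Default analysis parameters for feature extraction
#'
#' @param L SSA window length. @param C Leading components retained.
#' @param k_sim Eigenvalue-similarity threshold.
#' @param eog_amp_threshold 1-vs-2 component removal switch, uV.
#' @param fixed_band Conventional alpha band, Hz.
#' @param cog_n,cog_m CoG search band edges, Hz.
#' @param keep_channels If `TRUE`, report per-channel feature columns
#'   instead of averaging over channels.
#' @export
feature_params <- function(L = 60, C = 12, k_sim = 0.05,
                           eog_amp_threshold = 100,
                           fixed_band = c(8, 12), cog_n = 7, cog_m = 14,
                           keep_channels = FALSE) {
  stopifnot(C <= L, fixed_band[1] < fixed_band[2], cog_n < cog_m)
  as.list(environment())
}

# per-channel feature extraction over an epoch set; returns one row of
# channel-level features
.channel_features <- function(es, ch, p) {
  fs <- es$fs
  fixed <- band_definition(p$fixed_band[1], p$fixed_band[2])
  cleaned <- lapply(es$epochs, function(e)
    clean_epoch(e[ch, ], fs, L = p$L, eog_amp_threshold = p$eog_amp_threshold))
  spectra <- lapply(cleaned, power_spectrum, fs = fs)
  ms <- mean_spectrum(spectra)
  iapf <- cog_frequency(ms, n = p$cog_n, m = p$cog_m)
  indiv <- individualized_band(iapf)
  decomps <- lapply(cleaned, ssa_decompose, L = p$L, fs = fs, n_rc = p$C)
  abp2 <- mean(vapply(decomps, function(d)
    band_power_time(.extract_from_decomposition(d, fixed, p$C, p$k_sim)),
    numeric(1)))
  iabp_series <- lapply(decomps, .extract_from_decomposition,
                        band = indiv, C = p$C, k_sim = p$k_sim)
  iabp <- mean(vapply(iabp_series, band_power_time, numeric(1)))
  c(iAPF = iapf, iABP = iabp,
    abp1 = band_power_freq(ms, fixed), abp2 = abp2,
    n_two_removed = sum(vapply(cleaned, function(x)
      attr(x, "n_removed") == 2L, logical(1))),
    n_empty_band = sum(vapply(iabp_series, function(x)
      isTRUE(attr(x, "empty_band")), logical(1))))
}

#' Per-subject alpha features from surviving epochs
#'
#' For each analysis channel: every epoch is EOG-cleaned, the epoch-mean
#' periodogram gives the channel's CoG alpha peak frequency (iAPF) and the
#' fixed-band frequency-domain energy (ABP#1); the SSA-extracted rhythm in
#' the fixed band gives the time-domain energy (ABP#2), and re-extraction
#' in the channel's individualized `0.8-1.2 x CoG` band gives iABP.
#' Features are averaged over epochs, then over channels (or kept
#' per-channel with `keep_channels`).
#'
#' @param es An [segment_epochs()]/[reject_epochs()] result.
#' @param channels Channel labels to analyze (default O1, O2).
#' @param params A [feature_params()] list.
#' @return One-row `data.frame` with columns `iAPF`, `iABP`, `abp1`,
#'   `abp2`, audit counters `n_two_removed` (epoch-channels where the
#'   high-amplitude two-component rule fired) and `n_empty_band`
#'   (epoch-channels whose individualized band held no rhythm group), and
#'   `n_epochs_used` (plus per-channel columns when requested).
#' @export
subject_features <- function(es, channels = c("O1", "O2"),
                             params = feature_params()) {
  stopifnot(inherits(es, "epoch_set"))
  if (length(es$epochs) == 0L)
    stop("no surviving epochs for this subject", call. = FALSE)
  miss <- setdiff(channels, es$channel_labels)
  if (length(miss) > 0)
    stop("channel(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- lapply(channels, function(lbl)
    .channel_features(es, match(lbl, es$channel_labels), params))
  tab <- do.call(rbind, rows)
  counters <- c("n_two_removed", "n_empty_band")
  avg <- colMeans(tab[, setdiff(colnames(tab), counters), drop = FALSE])
  out <- as.data.frame(as.list(avg))
  for (nm in counters) out[[nm]] <- sum(tab[, nm])  # epoch-channel counts
  if (isTRUE(params$keep_channels)) {
    for (i in seq_along(channels))
      for (nm in names(rows[[i]]))
        out[[paste(nm, channels[i], sep = "_")]] <- rows[[i]][[nm]]
  }
  out$n_epochs_used <- length(es$epochs)
  out
}
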