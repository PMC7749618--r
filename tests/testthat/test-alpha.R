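test_that("adaptive cleaning removes large slow ocular activity but keeps
           the alpha peak", {
  s <- 20 * tone(10) + 300 * tone(0.5)
  cl <- clean_epoch(s, fs_default)
  expect_equal(attr(cl, "n_removed"), 2L)
  expect_gt(1 - low_band_power(cl, fs_default) / low_band_power(s, fs_default),
            0.9)
  expect_equal(rc_peak_frequency(cl, fs_default), 10)

  # blink-shaped bump instead of a slow oscillation
  bump <- numeric(800)
  bump[201:600] <- eog_event(2, 300, fs_default)[1:400]
  s2 <- 20 * tone(10) + bump
  cl2 <- clean_epoch(s2, fs_default)
  expect_gt(1 - low_band_power(cl2, fs_default) /
              low_band_power(s2, fs_default), 0.9)
  expect_equal(rc_peak_frequency(cl2, fs_default), 10)
})

test_that("low-amplitude epochs lose only the single largest component", {
  s <- 20 * tone(10)
  cl <- clean_epoch(s, fs_default)
  expect_equal(attr(cl, "n_removed"), 1L)
  expect_lte(sum(cl^2) / sum(s^2), 0.6)  # one member of the tone pair goes
  expect_equal(rc_peak_frequency(cl, fs_default), 10)
  z <- clean_epoch(rep(0, 800), fs_default)
  expect_equal(max(abs(z)), 0)
})

test_that("rhythm extraction isolates the in-band oscillation", {
  s <- tone(10) + tone(4)
  r <- extract_rhythm(s, fs_default, band_definition(8, 12))
  expect_equal(rc_peak_frequency(r, fs_default), 10)
  ps <- power_spectrum(r, fs_default)
  oob <- ps$freqs < 8 | ps$freqs > 12
  expect_lt(sum(ps$power[oob]) / sum(ps$power), 0.1)

  # nothing in band: all-zero output, flagged
  r0 <- extract_rhythm(tone(4), fs_default, band_definition(8, 12))
  expect_equal(max(abs(r0)), 0)
  expect_true(attr(r0, "empty_band"))

  # individualized band around the tone selects the same components
  s1 <- 20 * tone(10)
  ra <- extract_rhythm(s1, fs_default, band_definition(8, 12))
  rb <- extract_rhythm(s1, fs_default, individualized_band(10))
  expect_identical(attr(ra, "components"), attr(rb, "components"))
  expect_equal(ra, rb)

  expect_error(extract_rhythm(s, fs_default, band_definition(8, 12), C = 70),
               "C must not exceed")
})

test_that("a pure on-bin tone yields exact CoG and near-total extraction", {
  s <- 20 * tone(10)
  expect_equal(cog_frequency(power_spectrum(s, fs_default)), 10,
               tolerance = 1e-9)
  r <- extract_rhythm(s, fs_default, band_definition(8, 12))
  expect_gt(sum(r^2) / sum(s^2), 0.95)
})

test_that("frequency-domain band energy follows the closed-interval sum", {
  freqs <- seq(0, 100, by = 0.25)
  p <- numeric(length(freqs))
  p[freqs >= 8 & freqs <= 12] <- 1   # 17 bins
  ps <- structure(list(freqs = freqs, power = p, bin_width = 0.25),
                  class = "power_spectrum")
  expect_equal(band_power_freq(ps, band_definition(8, 12)), 170)
  ps$power[] <- 0
  expect_equal(band_power_freq(ps, band_definition(8, 12)), 0)
  # staircase spectrum over [7, 14]: 10 x arithmetic series
  sel <- freqs >= 7 & freqs <= 14
  ps$power[sel] <- seq_len(sum(sel))
  expect_equal(band_power_freq(ps, band_definition(7, 14)),
               10 * sum(seq_len(sum(sel))))
  expect_error(band_power_freq(ps, band_definition(200, 300)), "bins")
})

test_that("time-domain energy is ten times the sum of squares", {
  expect_equal(band_power_time(c(1, 1, 1, 1)), 40)
  expect_equal(band_power_time(numeric(10)), 0)
  expect_equal(band_power_time(c(3, -4)), 250)
})

test_that("CoG frequency is the power-weighted band mean, scale-invariant", {
  freqs <- seq(0, 100, by = 0.25)
  mk <- function(p) structure(list(freqs = freqs, power = p,
                                   bin_width = 0.25),
                              class = "power_spectrum")
  p <- numeric(length(freqs)); p[freqs == 10] <- 5
  expect_equal(cog_frequency(mk(p)), 10)
  # symmetric about 10.5 within [7, 14]
  p2 <- numeric(length(freqs))
  p2[freqs == 9.5] <- 2; p2[freqs == 11.5] <- 2; p2[freqs == 10.5] <- 7
  expect_equal(cog_frequency(mk(p2)), 10.5)
  # uniform over [7, 14]
  p3 <- as.numeric(freqs >= 7 & freqs <= 14)
  expect_equal(cog_frequency(mk(p3)), 10.5)
  expect_equal(cog_frequency(mk(1000 * p3)), cog_frequency(mk(p3)))
  expect_error(cog_frequency(mk(numeric(length(freqs)))), "power")
})

test_that("the individualized band spans 0.8 to 1.2 times the CoG", {
  b <- individualized_band(7.9)
  expect_equal(c(b$a, b$b), c(6.32, 9.48))
  expect_equal(b$kind, "individualized")
  b2 <- individualized_band(10)
  expect_equal(c(b2$a, b2$b), c(8, 12))
  for (cog in c(7.2, 9.7, 13.4))
    expect_equal(individualized_band(cog)$a / individualized_band(cog)$b,
                 2 / 3)
})

test_that("subject features recover a pure tone and scale quadratically", {
  es <- reject_epochs(segment_epochs(tone_recording(10, amp = 20, dur = 20)))
  ft <- subject_features(es)
  expect_equal(ft$iAPF, 10, tolerance = 0.25)
  expect_equal(ft$n_epochs_used, 5L)

  # doubling the signal multiplies energies by 4, leaves iAPF unchanged
  g <- quiet_group(iapf_mean = 9.5, bg_scale = 1, alpha_amp_mean = 15,
                   alpha_amp_sd = 0)
  subj <- generate_subject(g, 200, 20, c("O1", "O2"), seed = 2)
  es1 <- segment_epochs(subj$recording)
  rec2 <- eeg_recording(2 * subj$recording$data, 200)
  es2 <- segment_epochs(rec2)
  f1 <- subject_features(es1)
  f2 <- subject_features(es2)
  expect_equal(f2$iAPF, f1$iAPF, tolerance = 1e-10)
  expect_equal(f2$abp2, 4 * f1$abp2, tolerance = 1e-8)
  expect_equal(f2$iABP, 4 * f1$iABP, tolerance = 1e-8)
  expect_equal(f2$abp1, 4 * f1$abp1, tolerance = 1e-8)

  expect_error(subject_features(reject_epochs(es1, 1e-6)), "channel|epoch")
})

test_that("rhythm extraction never adds energy", {
  set.seed(12)
  for (i in 1:3) {
    s <- 10 * tone(runif(1, 8.5, 11)) + rnorm(800, sd = 3)
    r <- extract_rhythm(s, fs_default, band_definition(8, 12))
    expect_lte(band_power_time(r), band_power_time(s) * (1 + 1e-9))
  }
})

test_that("synthetic groups separate in the measured direction", {
  spec <- cohort_spec(n_per_group = 6, fs = 1000, duration = 60, seed = 21)
  cf <- cohort_features(generate_cohort(spec),
                        pipeline_config(cohort = spec))
  f <- cf$features
  expect_equal(nrow(f), 12)
  m <- tapply(f$iAPF, f$group, mean)
  expect_lt(m[["ASD"]], m[["TD"]])
  e <- tapply(f$iABP, f$group, mean)
  expect_lt(e[["ASD"]], e[["TD"]])
})
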