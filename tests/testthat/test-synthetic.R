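test_that("sd_waveform: stereotyped shape and peak index", {
  w <- sd_waveform(5, 120, "stereotyped", 0, 256)
  expect_equal(min(w$wave), -5)
  expect_equal(w$wave[w$peak_index], -5)
  expect_equal(length(w$wave) / 256, 120, tolerance = 0.01)
  expect_lt(abs(w$peak_index / 256 - 60), 1)       # trough at mid-span
  expect_equal(w$wave[1], 0)                        # smooth onset/offset
  wa <- sd_waveform(5, 120, "stereotyped", 2, 256)
  expect_equal(max(wa$wave), 2, tolerance = 1e-6)  # afterpotential positivity
  expect_error(sd_waveform(5, 120, "no-such-variant"), "unknown variant")
  expect_error(sd_waveform(-1, 120), "amplitude_mv")
})

test_that("default waveform energy is concentrated below 10 mHz", {
  w <- sd_waveform(5.4, 120, "stereotyped", 0, 256)
  # analysed the way the pipeline sees it: 400-s window at 0.1 Hz around the peak
  pad <- numeric(400 * 256)
  i0 <- 200 * 256 - w$peak_index
  pad[(i0 + 1):(i0 + length(w$wave))] <- w$wave
  x01 <- pad[seq(1, length(pad), by = 2560)]
  sp <- spectrum_segment(x01, 0.1, "psd")
  nondc <- sp$freqs > 0
  frac <- sum(sp$values[nondc & sp$freqs <= 0.01]) / sum(sp$values[nondc])
  expect_gt(frac, 0.9)
  # dominant bin sits in the DC-shift band, consistent with a ~2-5 mHz peak
  expect_lte(sp$freqs[nondc][which.max(sp$values[nondc])], 0.01)
})

test_that("atypical variants deform as documented", {
  dh <- sd_waveform(5, 120, "double_hump", 0, 256)
  w <- dh$wave
  s <- sign(diff(w)); s <- s[s != 0]
  expect_equal(sum(diff(s) == 2), 2)  # exactly two troughs
  expect_equal(min(w), -5)
  lo <- sd_waveform(5, 120, "low_amplitude", 0, 256)
  expect_equal(min(lo$wave), -1.5)    # 0.3x the nominal amplitude
  pr <- sd_waveform(5, 120, "prolonged", 0, 256)
  expect_equal(length(pr$wave), round(2.5 * 120 * 256))
  lap <- sd_waveform(5, 120, "large_afterpotential", 0, 256)
  expect_gt(max(lap$wave), 5)         # positivity dominates the negativity
})

test_that("double_hump has exactly two sub -A/2 local minima", {
  w <- sd_waveform(4, 100, "double_hump", 0, 64)$wave
  # local minimum: strictly below both nearest differing neighbours
  n <- length(w)
  minima <- c()
  for (i in 2:(n - 1)) {
    l <- i - 1
    while (l > 1 && w[l] == w[i]) l <- l - 1
    r <- i + 1
    while (r < n && w[r] == w[i]) r <- r + 1
    if (w[l] > w[i] && w[r] > w[i] && w[i - 1] >= w[i]) minima <- c(minima, i)
  }
  minima <- minima[!duplicated(w[minima])]
  expect_equal(sum(w[minima] < -2), 2)
})

test_that("generator determinism and per-subject seed independence", {
  spec <- generator_spec(n_subjects = 2, duration_s = 5400, fs = 32, seed = 5)
  a <- generate_subject(spec, 1)
  b <- generate_subject(spec, 1)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))
  c2 <- generate_subject(spec, 2)
  expect_false(identical(a$recording$data[1:1000, 1], c2$recording$data[1:1000, 1]))
  spec2 <- generator_spec(n_subjects = 2, duration_s = 5400, fs = 32, seed = 6)
  expect_false(identical(generate_subject(spec2, 1)$recording$data, a$recording$data))
})

test_that("cohort bookkeeping: ids, annotation consistency, DC offsets", {
  spec <- generator_spec(n_subjects = 3, duration_s = 5400, fs = 32,
                         channels_per_subject = 4, seed = 12)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 3)
  ids <- sapply(cohort, function(s) s$recording$subject_id)
  expect_equal(anyDuplicated(ids), 0)
  for (s in cohort) {
    expect_true(all(s$annotations$subject == s$recording$subject_id))
    expect_true(all(s$annotations$channel %in% s$recording$channel_labels))
    expect_true(all(s$annotations$t_peak_s < recording_duration(s$recording)))
    expect_true(all(apply(s$recording$data, 2, median) > 70))  # offset > 70 mV
  }
})

test_that("drawn SD amplitudes follow the truncated normal", {
  # oracle: closed-form mean of N(5.4, 3.6^2) truncated to (0.5, Inf)
  alpha <- (0.5 - 5.4) / 3.6
  mu_trunc <- 5.4 + 3.6 * dnorm(alpha) / (1 - pnorm(alpha))
  set.seed(50)
  draws <- sdstrip:::draw_truncated(600, 5.4, 3.6, 0.5)
  expect_true(all(draws > 0.5))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu_trunc), 3 * se)
})

test_that("annotations sit on local minima of the preprocessed trace", {
  # stereotyped-only, low-noise world for the placement invariant
  spec <- generator_spec(n_subjects = 1, duration_s = 5400, fs = 32,
                         channels_per_subject = 3, sd_rate_per_hour = 2,
                         noise_scale_mv = 0.2, artifact_rate_per_hour = 0,
                         atypical_mix = c(low_amplitude = 0, prolonged = 0,
                                          double_hump = 0, large_afterpotential = 0),
                         seed = 31)
  s <- generate_subject(spec, 1)
  prep <- preprocess_recording(s$recording)
  ann <- s$annotations
  expect_gt(nrow(ann), 0)
  for (r in seq_len(nrow(ann))) {
    j <- match(ann$channel[r], prep$channel_labels)
    t <- round(ann$t_peak_s[r])
    win <- prep$data[(t - 60):(t + 60), j]
    t_min <- which.min(win) - 61  # offset of the trough from the mark
    expect_lte(abs(t_min), 20)
  }
})

test_that("zero-SD recordings are possible at low rates and warn when too short", {
  spec <- generator_spec(n_subjects = 1, duration_s = 3600, fs = 32,
                         sd_rate_per_hour = 0, seed = 2)
  s <- generate_subject(spec, 1)
  expect_equal(nrow(s$annotations), 0)
  short <- generator_spec(n_subjects = 1, duration_s = 2000, fs = 32,
                          sd_rate_per_hour = 20, seed = 2)
  expect_warning(s2 <- generate_subject(short, 1), "too short")
  expect_equal(nrow(s2$annotations), 0)
})
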