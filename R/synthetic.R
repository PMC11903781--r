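#' Synthetic ECoG generator specification
#'
#' Describes a cohort of full-band-like multichannel ECoG recordings with
#' injected SD waveforms and ground-truth annotations, so the whole pipeline
#' can be exercised without patient data. Defaults emulate the reported
#' characteristics of full-band strip recordings: a DC offset above 70 mV
#' with slow drift, SD negativities of mean 5.4 mV (SD 3.6, truncated above
#' 0.5 mV) lasting about two minutes, an optional positive afterpotential,
#' a 34% share of atypical variants, minutes-scale inter-channel spread
#' delays, and unannotated high-amplitude artifacts.
#'
#' @param n_subjects number of subjects (default 5).
#' @param channels_per_subject electrode-strip contacts (default 6).
#' @param duration_s recording length per subject in seconds (default 14400,
#'   i.e. 4 h — long enough for tens of SD waveforms per subject while
#'   keeping a full cohort computable on one CPU in minutes).
#' @param fs raw sampling rate in Hz (default 256).
#' @param dc_offset_mv lower bound of the per-channel DC offset (default 70).
#' @param drift_step_mv random-walk drift step scale in mV per sqrt(s)
#'   (default 0.05, giving a few mV of wander per hour).
#' @param noise_scale_mv standard deviation of the slow (< 0.5 Hz) background
#'   noise in mV (default 0.3).
#' @param hf_background logical; add 0.5-50 Hz-like background activity
#'   (default TRUE; it is almost entirely removed by the 0.5-Hz low-pass).
#' @param sd_rate_per_hour SD wave rate on the strip (default 2.5).
#' @param amplitude_mean_mv,amplitude_sd_mv peak-negativity amplitude
#'   distribution, truncated above 0.5 mV (defaults 5.4 and 3.6).
#' @param duration_mean_s mean negative-phase duration (default 120).
#' @param afterpotential_fraction fraction of waveforms followed by a slight
#'   positivity (default 0.5).
#' @param atypical_mix named fractions for variants `low_amplitude`,
#'   `prolonged`, `double_hump`, `large_afterpotential`; defaults sum to
#'   0.34, matching the reported share of atypical waveforms.
#' @param interchannel_delay_s range of per-channel onset delays in seconds
#'   as an SD spreads along the strip (default c(60, 300)).
#' @param artifact_rate_per_hour rate of unannotated high-amplitude
#'   transients per channel-hour (default 0.5).
#' @param seed master seed; together with the spec it fully determines the
#'   output.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_subjects = 5, channels_per_subject = 6,
                           duration_s = 14400, fs = 256, dc_offset_mv = 70,
                           drift_step_mv = 0.05, noise_scale_mv = 0.3,
                           hf_background = TRUE, sd_rate_per_hour = 2.5,
                           amplitude_mean_mv = 5.4, amplitude_sd_mv = 3.6,
                           duration_mean_s = 120, afterpotential_fraction = 0.5,
                           atypical_mix = c(low_amplitude = 0.12, prolonged = 0.10,
                                            double_hump = 0.06, large_afterpotential = 0.06),
                           interchannel_delay_s = c(60, 300),
                           artifact_rate_per_hour = 0.5, seed = 1L) {
  stopifnot(n_subjects >= 1, channels_per_subject >= 1, duration_s > 0, fs > 0,
            sd_rate_per_hour >= 0, artifact_rate_per_hour >= 0,
            all(atypical_mix >= 0), sum(atypical_mix) <= 1,
            length(interchannel_delay_s) == 2)
  structure(as.list(environment()), class = "generator_spec")
}

#' Build one synthetic SD waveform
#'
#' Piecewise raised-cosine construction: a smooth unimodal negative
#' deflection reaching `-amplitude_mv` over roughly `duration_s`, optionally
#' followed by a positive afterpotential (raised cosine, 0.8x the duration).
#' Variants deform the stereotype: `low_amplitude` scales the negativity to
#' 0.3x, `prolonged` stretches the duration 2.5x, `double_hump` produces two
#' negative phases (both below half the nominal amplitude), and
#' `large_afterpotential` forces a positivity larger than the negativity.
#'
#' @param amplitude_mv peak negativity in mV (> 0; the trough is at
#'   `-amplitude_mv` for the stereotyped variant).
#' @param duration_s nominal span of the negative phase in seconds.
#' @param variant one of `"stereotyped"`, `"low_amplitude"`, `"prolonged"`,
#'   `"double_hump"`, `"large_afterpotential"`.
#' @param afterpotential_mv amplitude of the positive after-phase (0 = none).
#' @param fs sampling rate in Hz.
#' @return list with `wave` (voltage series at `fs`, mV) and `peak_index`
#'   (1-based sample index of the peak negativity).
#' @export
sd_waveform <- function(amplitude_mv, duration_s, variant = "stereotyped",
                        afterpotential_mv = 0, fs = 256) {
  stopifnot(amplitude_mv > 0, duration_s > 0)
  variants <- c("stereotyped", "low_amplitude", "prolonged", "double_hump",
                "large_afterpotential")
  if (!variant %in% variants) stop("unknown variant '", variant, "'")
  A <- amplitude_mv
  D <- duration_s
  if (variant == "low_amplitude") A <- 0.3 * A
  if (variant == "prolonged") D <- 2.5 * D
  if (variant == "large_afterpotential") afterpotential_mv <- 1.2 * A
  bump <- function(depth, len_s) {
    n <- max(round(len_s * fs), 3)
    -depth * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))) / 2
  }
  if (variant == "double_hump") {
    span <- 1.5 * D
    n <- round(span * fs)
    wave <- numeric(n)
    b1 <- bump(A, 0.55 * span)
    b2 <- bump(0.85 * A, 0.55 * span)
    o2 <- n - length(b2)
    wave[seq_along(b1)] <- wave[seq_along(b1)] + b1
    wave[(o2 + 1):n] <- wave[(o2 + 1):n] + b2
    peak_index <- which.min(wave)
  } else {
    wave <- bump(A, D)
    peak_index <- which.min(wave)
  }
  if (afterpotential_mv > 0) {
    post <- -bump(afterpotential_mv, 0.8 * duration_s)
    wave <- c(wave, post[-1])
  }
  list(wave = wave, peak_index = peak_index)
}

draw_truncated <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  for (k in 1:100) {
    bad <- out <= lower
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower + 1e-6)
}

# slow band-limited noise: white at 1 Hz, linearly interpolated to fs
slow_noise <- function(duration_s, fs, sd_mv) {
  knots <- rnorm(duration_s + 1, 0, sd_mv)
  approx(seq(0, duration_s), knots, xout = seq(0, duration_s - 1 / fs, by = 1 / fs))$y
}

#' Generate one synthetic subject
#'
#' Per channel: DC offset (> `dc_offset_mv`) + random-walk drift + slow
#' background noise (+ optional high-frequency background) + injected SD
#' waveforms + unannotated artifacts. Each SD wave appears on a contiguous
#' run of channels with cumulative onset delays drawn from
#' `interchannel_delay_s`, emulating spread along the strip; the annotation
#' for each channel is placed at that channel's peak-negativity time.
#'
#' @param spec a [generator_spec].
#' @param subject_index 1-based subject number (also seeds the subject).
#' @return list with `recording` (an [sd_recording]) and `annotations`
#'   (an [sd_annotations]).
#' @export
generate_subject <- function(spec, subject_index = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed((spec$seed %% 1000003L) * 2011L + subject_index * 7919L)
  fs <- spec$fs
  dur <- spec$duration_s
  nch <- spec$channels_per_subject
  n <- round(dur * fs)
  subject_id <- sprintf("S%02d", subject_index)

  x <- matrix(0, n, nch)
  for (j in seq_len(nch)) {
    offset <- spec$dc_offset_mv + runif(1, 1, 30)
    drift_knots <- cumsum(rnorm(dur + 1, 0, spec$drift_step_mv))
    drift <- approx(seq(0, dur), drift_knots, xout = seq(0, dur - 1 / fs, by = 1 / fs))$y
    ch <- offset + drift + slow_noise(dur, fs, spec$noise_scale_mv)
    if (isTRUE(spec$hf_background)) # differenced white noise: high-pass-shaped
      ch <- ch + 0.2 * diff(rnorm(n + 1))
    x[, j] <- ch
  }

  # SD waves on the strip
  hours <- dur / 3600
  n_events <- rpois(1, spec$sd_rate_per_hour * hours)
  margin_lo <- 600
  margin_hi <- dur - 600 - 5 * spec$interchannel_delay_s[2] - 3 * spec$duration_mean_s
  ann <- list()
  if (margin_hi <= margin_lo) {
    if (n_events > 0) warning("recording too short to place SDs; generating a zero-SD record")
    n_events <- 0
  }
  if (n_events > 0) {
    t0 <- sort(runif(n_events, margin_lo, margin_hi))
    # enforce >= 500 s separation between wave onsets to keep marks distinct
    if (n_events > 1) for (e in 2:n_events) t0[e] <- max(t0[e], t0[e - 1] + 500)
    t0 <- t0[t0 <= margin_hi]
    variants <- c("stereotyped", names(spec$atypical_mix))
    probs <- c(1 - sum(spec$atypical_mix), spec$atypical_mix)
    for (t_on in t0) {
      n_on <- sample(min(3, nch):nch, 1)
      c0 <- sample(seq_len(nch - n_on + 1), 1)
      chans <- c0:(c0 + n_on - 1)
      if (runif(1) < 0.5) chans <- rev(chans)
      delays <- cumsum(c(0, runif(n_on - 1, spec$interchannel_delay_s[1],
                                  spec$interchannel_delay_s[2])))
      amp_event <- draw_truncated(1, spec$amplitude_mean_mv, spec$amplitude_sd_mv, 0.5)
      dur_event <- draw_truncated(1, spec$duration_mean_s, 30, 60)
      variant <- sample(variants, 1, prob = probs)
      for (k in seq_along(chans)) {
        j <- chans[k]
        amp <- max(0.5, amp_event * runif(1, 0.75, 1.25))
        after <- if (runif(1) < spec$afterpotential_fraction) 0.3 * amp * runif(1, 0.5, 1.5) else 0
        w <- sd_waveform(amp, dur_event, variant, after, fs)
        i0 <- round((t_on + delays[k]) * fs) + 1
        i1 <- min(i0 + length(w$wave) - 1, n)
        x[i0:i1, j] <- x[i0:i1, j] + w$wave[seq_len(i1 - i0 + 1)]
        ann[[length(ann) + 1]] <- data.frame(
          subject = subject_id, channel = sprintf("ch%d", j),
          t_peak_s = (i0 - 1 + w$peak_index - 1) / fs, label_class = "definite")
      }
    }
  }

  # unannotated brief high-amplitude artifacts (rect or exponential decay)
  for (j in seq_len(nch)) {
    n_art <- rpois(1, spec$artifact_rate_per_hour * hours)
    if (n_art == 0) next
    for (a in seq_len(n_art)) {
      amp <- runif(1, 10, 100) * sample(c(-1, 1), 1)
      len <- round(runif(1, 1, 30) * fs)
      i0 <- sample.int(n - len, 1)
      shape <- if (runif(1) < 0.5) rep(1, len) else exp(-(0:(len - 1)) / (len / 4))
      x[i0:(i0 + len - 1), j] <- x[i0:(i0 + len - 1), j] + amp * shape
    }
  }

  rec <- sd_recording(x, fs, sprintf("ch%d", seq_len(nch)), subject_id)
  anns <- if (length(ann)) do.call(rbind, ann) else
    data.frame(subject = character(), channel = character(),
               t_peak_s = numeric(), label_class = character())
  list(recording = rec, annotations = sd_annotations(anns))
}

#' Generate a synthetic cohort
#'
#' Subjects are generated independently from per-subject seeds derived
#' deterministically from the master seed, so the cohort is reproducible and
#' individual subjects can be regenerated in isolation.
#'
#' @param spec a [generator_spec].
#' @return list of per-subject lists, each with `recording` and
#'   `annotations` (see [generate_subject]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  lapply(seq_len(spec$n_subjects), function(i) generate_subject(spec, i))
}
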