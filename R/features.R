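#' The ten time-domain statistics of a series
#'
#' Mean, population variance, skewness, excess kurtosis, histogram entropy,
#' mean-cross rate, zero-cross rate and the three quartiles. Moments use the
#' 1/N (population) convention. Entropy is estimated from a 10-bin
#' equal-width histogram over `[min, max]` with natural logarithms, skipping
#' empty bins. Cross rates count sign changes of `x - mean(x)` and of `x`.
#' Quartiles use linear interpolation (type 7). On a zero-variance input,
#' skewness, kurtosis and entropy are 0 by convention so downstream
#' classifiers never see missing values.
#'
#' @param x numeric series of length >= 2.
#' @return named numeric vector of 10 statistics:
#'   `mean, var, skew, kurt, entropy, mcr, zcr, q1, q2, q3`.
#' @export
time_stats <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  if (anyNA(x) || any(is.infinite(x))) stop("input must be finite")
  mu <- sum(x) / n
  d <- x - mu
  v <- sum(d^2) / n
  if (v > 0) {
    skew <- (sum(d^3) / n) / v^1.5
    kurt <- (sum(d^4) / n) / v^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  rng <- range(x)
  H <- 0
  if (rng[2] > rng[1]) {
    b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * 10), 9)
    p <- tabulate(b + 1L, 10L) / n
    p <- p[p > 0]
    H <- -sum(p * log(p))
  }
  mcr <- sum(d[-n] * d[-1] < 0)
  zcr <- sum(x[-n] * x[-1] < 0)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  c(mean = mu, var = v, skew = skew, kurt = kurt, entropy = H,
    mcr = mcr, zcr = zcr, q1 = q[1], q2 = q[2], q3 = q[3])
}

#' Time-domain features of a segment with sub-windows
#'
#' The ten [time_stats] for the full segment plus, for each full sub-window
#' of `sub_len` samples starting at indices 0, `advance`, 2*`advance`, ...,
#' another ten. With the defaults a 40-sample (400 s at 0.1 Hz) segment has
#' two sub-windows (samples 1..30 and 11..40), for 30 features. A segment
#' shorter than `sub_len` yields only the full-segment block.
#'
#' @param x segment samples (mV at the feature rate).
#' @param sub_len sub-window length in samples (default 30).
#' @param advance sub-window start step in samples (default 10, i.e. 20
#'   samples of overlap between consecutive sub-windows).
#' @return named numeric vector (`t.full.*`, `t.sub1.*`, ...).
#' @export
subsegment_time_features <- function(x, sub_len = 30, advance = 10) {
  out <- time_stats(x)
  names(out) <- paste0("t.full.", names(out))
  n <- length(x)
  if (n >= sub_len) {
    starts <- seq(1, n - sub_len + 1, by = advance)
    for (w in seq_along(starts)) {
      s <- time_stats(x[starts[w]:(starts[w] + sub_len - 1)])
      names(s) <- paste0("t.sub", w, ".", names(s))
      out <- c(out, s)
    }
  }
  out
}

#' One-sided spectrum of a segment
#'
#' Unnormalised forward DFT magnitudes over bins 0..N/2 (DC through Nyquist)
#' with frequencies `k * fs / N`. The PSD is the squared magnitude. The DC
#' bin is retained here (it feeds the spectral [time_stats]) but is excluded
#' from peak search and quadrant counting downstream, where baseline
#' correction has made it uninformative.
#'
#' @param x segment samples; length >= 4.
#' @param fs sampling rate of the segment in Hz (default 0.1).
#' @param kind `"ft"` for magnitude or `"psd"` for power.
#' @return list with `freqs` (Hz, ascending from 0) and `values`.
#' @export
spectrum_segment <- function(x, fs = 0.1, kind = c("ft", "psd")) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 4) stop("need at least 4 samples")
  f <- fft(x)
  idx <- 1:(n %/% 2 + 1)
  v <- Mod(f[idx])
  # round-off junk in numerically-zero bins would otherwise masquerade as
  # peaks (and differ between FFT implementations); floor it to exact zero
  v[v < 1e-9 * sum(abs(x))] <- 0
  if (kind == "psd") v <- v^2
  list(freqs = (idx - 1) * fs / n, values = v)
}

# local maxima (strictly above both neighbours; plateau -> leftmost index),
# on the non-DC part of a spectrum
local_maxima_idx <- function(v) {
  n <- length(v)
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j + 1 <= n && v[j + 1] == v[i]) j <- j + 1
      if (j < n && v[j + 1] < v[i]) out <- c(out, i)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

peak_prominence <- function(v, p) {
  hgt <- v[p]
  minL <- hgt
  i <- p - 1
  while (i >= 1 && v[i] <= hgt) { minL <- min(minL, v[i]); i <- i - 1 }
  minR <- hgt
  i <- p + 1
  while (i <= length(v) && v[i] <= hgt) { minR <- min(minR, v[i]); i <- i + 1 }
  hgt - max(minL, minR)
}

#' Spectral peak features
#'
#' Local maxima of the spectrum (DC bin excluded), ranked by topographic
#' prominence — the height of a peak above the higher of its two bounding
#' saddles — with ties broken toward lower frequency. Returns the (x = Hz,
#' y = value) coordinates of the top five in rank order, padding missing
#' slots with (0, 0), plus the absolute maximum value of the spectrum.
#'
#' @param sp a spectrum from [spectrum_segment].
#' @return named numeric vector: `peak1.x, peak1.y, ..., peak5.x, peak5.y, max`.
#' @export
peak_features <- function(sp) {
  keep <- sp$freqs > 0
  v <- sp$values[keep]
  f <- sp$freqs[keep]
  pk <- local_maxima_idx(v)
  prom <- vapply(pk, function(p) peak_prominence(v, p), 0)
  ord <- order(-prom, pk)
  out <- numeric(11)
  for (k in seq_len(min(5, length(pk)))) {
    out[2 * k - 1] <- f[pk[ord[k]]]
    out[2 * k] <- v[pk[ord[k]]]
  }
  out[11] <- max(v)
  names(out) <- c(paste0("peak", rep(1:5, each = 2), c(".x", ".y")), "max")
  out
}

#' Quadrant counts of spectral peaks
#'
#' All local maxima (not only the top five) are mapped onto a Cartesian
#' plane by linearly rescaling the frequency span and the value span of the
#' (non-DC) spectrum to \[-1, 1\]; the count of peaks in each quadrant is
#' returned. Points landing exactly on an axis are assigned to the positive
#' side, so the four counts always partition the local maxima. A flat
#' spectrum (degenerate value span) yields all zeros.
#'
#' @param sp a spectrum from [spectrum_segment].
#' @return integer vector `nq1` (+,+), `nq2` (-,+), `nq3` (-,-), `nq4` (+,-).
#' @export
quadrant_counts <- function(sp) {
  keep <- sp$freqs > 0
  v <- sp$values[keep]
  f <- sp$freqs[keep]
  out <- c(nq1 = 0, nq2 = 0, nq3 = 0, nq4 = 0)
  if (length(v) < 2 || max(v) == min(v)) return(out)
  pk <- local_maxima_idx(v)
  for (p in pk) {
    X <- 2 * (f[p] - f[1]) / (f[length(f)] - f[1]) - 1
    Y <- 2 * (v[p] - min(v)) / (max(v) - min(v)) - 1
    q <- if (X >= 0 && Y >= 0) 1 else if (X < 0 && Y >= 0) 2 else if (X < 0 && Y < 0) 3 else 4
    out[q] <- out[q] + 1
  }
  out
}

spectral_features <- function(x, fs, kind) {
  sp <- spectrum_segment(x, fs, kind)
  st <- time_stats(sp$values)
  out <- c(peak_features(sp), quadrant_counts(sp), st)
  names(out) <- paste0(kind, ".", names(out))
  out
}

#' The fixed feature registry
#'
#' Names, in order, of every feature produced by [extract_features] for a
#' segment of `n_samples`. For the default 40-sample segment this is 80
#' features: 30 time-domain (full segment + two 30-sample sub-windows) and
#' 50 frequency-domain (5 prominence-ranked peak coordinate pairs, the
#' absolute maximum, 4 quadrant counts, and the 10 statistics, for each of
#' the FT and the PSD). Trained models store this registry; a mismatch at
#' predict time is an error.
#'
#' @param n_samples segment length in samples (default 40).
#' @param sub_len,advance sub-window parameters (see
#'   [subsegment_time_features]).
#' @return character vector of feature names.
#' @export
feature_registry <- function(n_samples = 40, sub_len = 30, advance = 10) {
  st <- c("mean", "var", "skew", "kurt", "entropy", "mcr", "zcr", "q1", "q2", "q3")
  nsub <- if (n_samples >= sub_len) (n_samples - sub_len) %/% advance + 1 else 0
  tnames <- c(paste0("t.full.", st),
              if (nsub > 0) paste0("t.sub", rep(seq_len(nsub), each = 10), ".", st))
  spn <- c(paste0("peak", rep(1:5, each = 2), c(".x", ".y")), "max",
           paste0("nq", 1:4), st)
  c(tnames, paste0("ft.", spn), paste0("psd.", spn))
}

#' Registry version string
#'
#' Bumped whenever the feature definitions or their order change; stored in
#' model files and checked at predict time.
#' @export
feature_registry_version <- function() "sdstrip-features-1"

#' Extract the full feature vector of one segment
#'
#' Computes every feature in [feature_registry] for a fixed-length segment
#' sampled at the feature rate (0.1 Hz by default): 80 features for the
#' standard 40-sample, 400-s segment.
#'
#' @param x segment samples (mV), length >= 30.
#' @param fs segment sampling rate in Hz (default 0.1).
#' @param sub_len,advance sub-window parameters.
#' @return named numeric vector matching [feature_registry].
#' @export
extract_features <- function(x, fs = 0.1, sub_len = 30, advance = 10) {
  if (length(x) < 30) stop("segment must have at least 30 samples")
  out <- c(subsegment_time_features(x, sub_len, advance),
           spectral_features(x, fs, "ft"),
           spectral_features(x, fs, "psd"))
  stopifnot(identical(names(out), feature_registry(length(x), sub_len, advance)))
  out
}

#' Extract features for many segments at once
#'
#' C++ fast path used by the sliding-window detector; numerically equivalent
#' to calling [extract_features] column by column (asserted in the tests).
#'
#' @param segs numeric matrix, samples x segments.
#' @inheritParams extract_features
#' @return numeric matrix, segments x features, with registry column names.
#' @export
extract_features_batch <- function(segs, fs = 0.1, sub_len = 30, advance = 10) {
  stopifnot(is.matrix(segs), nrow(segs) >= 30)
  out <- .features_batch(segs, fs, as.integer(sub_len), as.integer(advance))
  colnames(out) <- feature_registry(nrow(segs), sub_len, advance)
  out
}
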