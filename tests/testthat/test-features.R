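# direct-formula oracle for the ten statistics
oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  c(mean = mu, var = v,
    skew = if (v > 0) (sum((x - mu)^3) / n) / sqrt(v)^3 else 0,
    kurt = if (v > 0) (sum((x - mu)^4) / n) / v^2 - 3 else 0,
    entropy = {
      r <- range(x)
      if (r[1] == r[2]) 0 else {
        cuts <- seq(r[1], r[2], length.out = 11)
        cnt <- hist(x, breaks = cuts, plot = FALSE, right = FALSE)$counts
        # hist(right = FALSE) puts the max into the last bin already
        p <- cnt[cnt > 0] / n
        -sum(p * log(p))
      }
    },
    mcr = sum(diff(sign(x - mu)) != 0 & (x - mu)[-n] * (x - mu)[-1] < 0),
    zcr = sum(x[-n] * x[-1] < 0),
    q1 = unname(quantile(x, 0.25)), q2 = unname(quantile(x, 0.5)),
    q3 = unname(quantile(x, 0.75)))
}

test_that("time_stats matches direct formula evaluation to 1e-12", {
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(40, sd = sample(c(0.1, 1, 50), 1))
    expect_equal(time_stats(x), oracle_stats(x), tolerance = 1e-12)
  }
})

test_that("time_stats worked examples and degenerate conventions", {
  s <- time_stats(c(1, 2, 3, 4))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["var"]], 1.25)
  expect_equal(s[["q2"]], 2.5)
  s <- time_stats(rep(7, 40))
  expect_equal(unname(s[c("var", "skew", "kurt", "entropy", "mcr", "zcr")]),
               rep(0, 6))
  s <- time_stats(c(1, -1, 1, -1))
  expect_equal(s[["mean"]], 0)
  expect_equal(s[["mcr"]], 3)
  expect_equal(s[["zcr"]], 3)
  expect_error(time_stats(3), "at least 2")
})

test_that("time_stats invariances: translation and scaling", {
  set.seed(11)
  x <- rnorm(40)
  a <- time_stats(x)
  b <- time_stats(x + 17.3)
  expect_equal(a[c("var", "skew", "kurt", "entropy", "mcr")],
               b[c("var", "skew", "kurt", "entropy", "mcr")])
  d <- time_stats(2 * x)
  expect_equal(d[["var"]], 4 * a[["var"]])
  expect_equal(d[["mcr"]], a[["mcr"]])
  expect_equal(d[["zcr"]], a[["zcr"]])
})

test_that("sub-segment scheme yields the documented feature counts", {
  set.seed(12)
  expect_length(subsegment_time_features(rnorm(40)), 30)  # full + 2 windows
  expect_length(subsegment_time_features(rnorm(30)), 20)  # full + 1 window
  expect_length(subsegment_time_features(rnorm(60)), 50)  # windows at 0,10,20,30
  expect_length(subsegment_time_features(rnorm(25)), 10)  # too short: full only
  # windows really start at 0, advance, 2*advance, ...
  x <- rnorm(60)
  f <- subsegment_time_features(x)
  expect_equal(unname(f["t.sub3.mean"]), mean(x[21:50]))
})

test_that("spectrum: sinusoid bin, PSD = FT squared, constant segment", {
  x <- sin(2 * pi * 10 * (0:39) / 40)  # bin 10 -> 0.025 Hz at fs = 0.1
  sp <- spectrum_segment(x, 0.1, "ft")
  expect_equal(sp$freqs[which.max(sp$values)], 0.025)
  psd <- spectrum_segment(x, 0.1, "psd")
  expect_equal(psd$values, sp$values^2)
  flat <- spectrum_segment(rep(3, 40), 0.1, "ft")
  expect_equal(flat$values[flat$freqs > 0], rep(0, 20))
  expect_equal(length(flat$freqs), 21)  # DC..Nyquist
})

# definitional prominence oracle, structurally unlike the implementation:
# bounding region = up to the nearest strictly-higher sample on each side
oracle_peaks <- function(v) {
  n <- length(v)
  is_pk <- function(i) {
    if (i < 2 || v[i] <= v[i - 1]) return(FALSE)
    j <- i
    while (j + 1 <= n && v[j + 1] == v[i]) j <- j + 1
    j < n && v[j + 1] < v[i]
  }
  pk <- Filter(is_pk, seq_len(n))
  prom <- vapply(pk, function(p) {
    higher <- which(v > v[p])
    lb <- max(c(0, higher[higher < p]))
    rb <- min(c(n + 1, higher[higher > p]))
    saddleL <- if (lb + 1 <= p - 1) min(v[(lb + 1):(p - 1)]) else v[p]
    saddleR <- if (p + 1 <= rb - 1) min(v[(p + 1):(rb - 1)]) else v[p]
    v[p] - max(saddleL, saddleR)
  }, 0)
  list(idx = pk, prom = prom)
}

rank_oracle <- function(v) {
  o <- oracle_peaks(v)
  o$idx[order(-o$prom, o$idx)]
}

test_that("peak_features matches the exhaustive-scan oracle on small spectra", {
  # exhaustive over all value-{0,1,2} spectra of 4..7 bins, then random larger
  for (nb in 4:7) {
    grids <- as.matrix(expand.grid(rep(list(0:2), nb)))
    for (r in seq_len(nrow(grids))) {
      v <- as.numeric(grids[r, ])
      sp <- list(freqs = seq_len(nb + 1) - 1, values = c(9, v)) # prepend DC
      pf <- peak_features(sp)
      want <- head(rank_oracle(v), 5)
      got_x <- pf[seq(1, 9, by = 2)]
      expect_equal(unname(got_x[got_x > 0]), want[seq_along(got_x[got_x > 0])])
      expect_equal(unname(pf[["max"]]), max(v))
    }
  }
  set.seed(13)
  for (i in 1:200) {
    v <- sample(0:2, 32, replace = TRUE)
    sp <- list(freqs = 0:32, values = c(9, v))
    pf <- peak_features(sp)
    want <- head(rank_oracle(v), 5)
    got_x <- unname(pf[seq(1, 9, by = 2)])
    expect_equal(got_x[got_x > 0], want[seq_along(got_x[got_x > 0])])
  }
})

test_that("peak_features: flat spectrum, single peak, tie toward lower frequency", {
  flat <- list(freqs = 0:20, values = rep(2, 21))
  pf <- peak_features(flat)
  expect_equal(unname(pf[1:10]), rep(0, 10))
  expect_equal(unname(pf[["max"]]), 2)
  x <- sin(2 * pi * 10 * (0:39) / 40)
  pf <- peak_features(spectrum_segment(x, 0.1))
  expect_equal(unname(pf[["peak1.x"]]), 0.025)
  expect_gt(pf[["peak1.y"]], 19)
  expect_equal(unname(pf[3:10]), rep(0, 8))
  two <- list(freqs = 0:8, values = c(9, 0, 5, 0, 0, 0, 5, 0, 0))
  pf <- peak_features(two)
  expect_equal(unname(pf[["peak1.x"]]), 2)  # equal prominence: lower f first
  expect_equal(unname(pf[["peak2.x"]]), 6)
})

test_that("quadrant_counts partitions local maxima with positive-side boundaries", {
  none <- list(freqs = 0:10, values = c(5, 10:0)[1:11])
  expect_equal(sum(quadrant_counts(none)), 0)
  # one peak at high frequency and high value -> upper-right
  v <- c(9, 0, 0, 0, 0, 0, 0, 0, 3, 0)
  sp <- list(freqs = 0:9, values = v)
  expect_equal(unname(quadrant_counts(sp)), c(1, 0, 0, 0))
  # partition property on random spectra
  set.seed(14)
  for (i in 1:50) {
    v <- sample(0:3, 24, replace = TRUE)
    sp <- list(freqs = 0:24, values = c(9, v))
    qc <- quadrant_counts(sp)
    expect_equal(sum(qc), length(oracle_peaks(v)$idx))
  }
  flat <- list(freqs = 0:10, values = rep(1, 11))
  expect_equal(unname(quadrant_counts(flat)), c(0, 0, 0, 0))
})

test_that("extract_features: 80 unique names, deterministic, scale behaviour", {
  set.seed(15)
  x <- rnorm(40)
  f <- extract_features(x)
  expect_length(f, 80)
  expect_equal(anyDuplicated(names(f)), 0)
  expect_identical(f, extract_features(x))
  expect_identical(names(f), feature_registry())
  f2 <- extract_features(2 * x)
  expect_equal(f2[["t.full.var"]], 4 * f[["t.full.var"]])
  expect_equal(f2[["t.full.mcr"]], f[["t.full.mcr"]])
  expect_equal(f2[["t.full.zcr"]], f[["t.full.zcr"]])
  # translation leaves spectral non-DC features unchanged
  f3 <- extract_features(x + 50)
  expect_equal(f3[["ft.peak1.y"]], f[["ft.peak1.y"]])
  expect_equal(f3[["ft.max"]], f[["ft.max"]])
  expect_error(extract_features(rnorm(20)), "at least 30")
})

test_that("batched C++ extraction equals the reference R path", {
  set.seed(16)
  segs <- matrix(rnorm(40 * 25, sd = rep(c(0.2, 5), length.out = 25)), 40, 25)
  segs[, 1] <- 3.14                    # constant segment edge case
  segs[, 2] <- sin(2 * pi * 7 * (0:39) / 40)
  batch <- extract_features_batch(segs)
  expect_equal(dim(batch), c(25, 80))
  for (j in seq_len(ncol(segs)))
    expect_equal(batch[j, ], extract_features(segs[, j]), tolerance = 1e-10)
  # non-default segment length
  segs60 <- matrix(rnorm(60 * 5), 60, 5)
  b60 <- extract_features_batch(segs60)
  expect_equal(ncol(b60), 100)  # 50 time (4 sub-windows) + 50 spectral
  expect_equal(b60[3, ], extract_features(segs60[, 3]), tolerance = 1e-10)
})
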