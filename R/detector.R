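#' Detection thresholds
#'
#' An excursion of the probability trace must stay at or above `theta_p` for
#' at least `theta_d` seconds to be declared an SD detection. The selected
#' operating point in this package's defaults is theta_p = 0.5 and
#' theta_d = 50 s, a deliberately conservative combination with a low
#' false-positive rate.
#'
#' @param theta_p probability threshold in (0, 1).
#' @param theta_d duration threshold in seconds (must be >= the trace
#'   stride).
#' @return a `detection_params` list.
#' @export
detection_params <- function(theta_p = 0.5, theta_d = 50) {
  stopifnot(theta_p > 0, theta_p < 1, theta_d > 0)
  structure(list(theta_p = theta_p, theta_d = theta_d), class = "detection_params")
}

#' Number of sliding-window evaluations
#'
#' One window per stride while a full window fits:
#' `floor((len_s - window_s)/stride_s) + 1`. In steady state this is one
#' evaluation per stride-second per channel — e.g. one day of six-channel
#' data at a 1-s stride costs about 6 x 86400 = 518,400 evaluations.
#'
#' @param len_s channel length in seconds.
#' @param window_s window length in seconds (default 400).
#' @param stride_s window advance in seconds (default 1).
#' @export
n_sliding_windows <- function(len_s, window_s = 400, stride_s = 1) {
  if (len_s < window_s) return(0L)
  as.integer(floor((len_s - window_s) / stride_s) + 1)
}

#' Compute the SD probability time series P_SD(t) for one channel
#'
#' A fixed-length window advances in `stride_s` increments over the 1-Hz
#' preprocessed channel; for each full window the data are decimated to the
#' model's feature rate (phase 0 within the window), features are extracted,
#' and the model probability is stamped at the *window centre*
#' (start + window_s/2) — the timestamp convention all thresholding and
#' evaluation in this package relies on.
#'
#' @param x preprocessed 1-Hz voltage series (mV).
#' @param model an `sd_model` whose `segment_length_s` equals `window_s`.
#' @param window_s window length in seconds (default 400).
#' @param stride_s window advance in seconds, typically 1 or 10.
#' @param channel,subject labels stored in the trace.
#' @return an `sd_probability_trace`: `times` (s, window centres, constant
#'   step `stride_s`), `p_sd` in \[0,1\], plus window metadata.
#' @export
sliding_probability <- function(x, model, window_s = 400, stride_s = 1,
                                channel = "ch1", subject = "subject") {
  stopifnot(inherits(model, "sd_model"))
  if (abs(model$config$segment_length_s - window_s) > 1e-9)
    stop("model segment length (", model$config$segment_length_s,
         " s) does not match window_s (", window_s, " s)")
  n <- length(x)
  trace <- function(times, p) structure(
    list(channel = channel, subject = subject, times = times, p_sd = p,
         window_s = window_s, stride_s = stride_s),
    class = "sd_probability_trace")
  if (n < window_s) {
    warning("channel shorter than one window; empty trace")
    return(trace(numeric(0), numeric(0)))
  }
  decim <- round(1 / model$preprocess$feature_rate_hz)
  starts <- seq(1, n - window_s + 1, by = stride_s)
  offs <- seq(1, window_s, by = decim) - 1
  segs <- matrix(x[outer(offs, starts, "+")], nrow = length(offs))
  feats <- extract_features_batch(segs, fs = model$preprocess$feature_rate_hz)
  p <- predict(model, feats)
  trace(times = (starts - 1) + window_s / 2, p = p)
}

#' @export
print.sd_probability_trace <- function(x, ...) {
  cat(sprintf("<sd_probability_trace> %s/%s: %d values, window %g s, stride %g s\n",
              x$subject, x$channel, length(x$p_sd), x$window_s, x$stride_s))
  invisible(x)
}

#' Extract supra-threshold detection events from a probability trace
#'
#' Maximal runs of consecutive trace samples with `p_sd >= theta_p`
#' (inclusive comparison) are events if their span — `n_samples * stride_s`,
#' counting one sampling interval per sample — is at least `theta_d`
#' (inclusive). Events are disjoint and time-ordered. An SD that produces
#' several probability peaks yields several events here; merging them onto
#' one ground-truth mark is the evaluator's job, not the detector's.
#'
#' @param trace an `sd_probability_trace`.
#' @param params a [detection_params]; `theta_d` must be >= the trace
#'   stride.
#' @return data frame with one row per event: `subject`, `channel`,
#'   `t_start`, `t_end` (`= t_start + span`), `t_peak` (time of maximum
#'   probability), `peak_p`.
#' @export
threshold_events <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "sd_probability_trace"))
  if (params$theta_d < trace$stride_s)
    stop("theta_d must be at least the trace stride")
  empty <- data.frame(subject = character(), channel = character(),
                      t_start = numeric(), t_end = numeric(),
                      t_peak = numeric(), peak_p = numeric())
  if (length(trace$p_sd) == 0) return(empty)
  above <- trace$p_sd >= params$theta_p
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    span <- r$lengths[k] * trace$stride_s
    if (span < params$theta_d) next
    i0 <- starts[k]; i1 <- ends[k]
    pk <- i0 + which.max(trace$p_sd[i0:i1]) - 1
    out[[length(out) + 1]] <- data.frame(
      subject = trace$subject, channel = trace$channel,
      t_start = trace$times[i0], t_end = trace$times[i1] + trace$stride_s,
      t_peak = trace$times[pk], peak_p = trace$p_sd[pk])
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Run the detector over a whole recording
#'
#' Convenience wrapper: [sliding_probability] on every channel followed by
#' [threshold_events].
#'
#' @param rec an [sd_recording] preprocessed to 1 Hz.
#' @param model an `sd_model`.
#' @param params a [detection_params].
#' @inheritParams sliding_probability
#' @return list with `events` (all channels, row-bound) and `traces`
#'   (one `sd_probability_trace` per channel).
#' @export
detect_recording <- function(rec, model, params = detection_params(),
                             window_s = 400, stride_s = 1) {
  stopifnot(inherits(rec, "sd_recording"))
  if (abs(rec$sample_rate_hz - 1) > 1e-9) stop("recording must be preprocessed to 1 Hz")
  traces <- lapply(seq_along(rec$channel_labels), function(j)
    sliding_probability(rec$data[, j], model, window_s, stride_s,
                        channel = rec$channel_labels[j], subject = rec$subject_id))
  events <- do.call(rbind, lapply(traces, threshold_events, params = params))
  list(events = events, traces = traces)
}
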