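#' Construct a multichannel ECoG recording
#'
#' A recording holds equal-length monopolar voltage channels in millivolts,
#' sampled at a fixed rate. All times in the package are recording-relative
#' seconds (0 at the first sample); wall-clock time is out of scope.
#'
#' @param data numeric matrix, samples x channels, in mV. Missing samples
#'   must be `NA` (never silent zeros).
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param channel_labels character vector, one label per column.
#' @param subject_id subject identifier string.
#' @param start_time offset of the first sample in seconds (default 0).
#' @return an object of class `sd_recording` with fields `subject_id`,
#'   `channel_labels`, `sample_rate_hz`, `data`, `start_time`.
#' @export
sd_recording <- function(data, sample_rate_hz, channel_labels = NULL,
                         subject_id = "subject", start_time = 0) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  if (!is.matrix(data) || !is.numeric(data)) stop("data must be a numeric matrix (samples x channels)")
  if (ncol(data) < 1 || nrow(data) < 1) stop("recording must have at least one channel and one sample")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 || sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive scalar")
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%d", seq_len(ncol(data)))
  if (length(channel_labels) != ncol(data)) stop("one channel label per column required")
  if (any(is.infinite(data))) stop("voltages must be finite (use NA for missing samples)")
  colnames(data) <- channel_labels
  structure(list(subject_id = as.character(subject_id),
                 channel_labels = as.character(channel_labels),
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 data = data,
                 start_time = as.numeric(start_time)),
            class = "sd_recording")
}

#' @export
print.sd_recording <- function(x, ...) {
  cat(sprintf("<sd_recording> subject '%s': %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, ncol(x$data), nrow(x$data), x$sample_rate_hz,
              nrow(x$data) / x$sample_rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `sd_recording`.
#' @return duration in seconds (`n_samples / sample_rate_hz`).
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$sample_rate_hz

#' Construct a set of SD annotations
#'
#' Ground-truth marks: one row per SD waveform per channel, at the timestamp
#' of the peak DC-shift negativity. Ground-truth sets use `label_class`
#' "definite"; adjudication files may also carry "probable" and "possible".
#'
#' @param df data frame with columns `subject`, `channel`, `t_peak_s` and
#'   optionally `label_class`.
#' @return an `sd_annotations` data frame, sorted by (channel, t_peak_s).
#' @export
sd_annotations <- function(df) {
  if (nrow(df) > 0) {
    need <- c("subject", "channel", "t_peak_s")
    if (!all(need %in% names(df))) stop("annotations need columns subject, channel, t_peak_s")
    if (!is.numeric(df$t_peak_s) || anyNA(df$t_peak_s)) stop("t_peak_s must be numeric")
    if (any(df$t_peak_s < 0)) stop("t_peak_s must be non-negative")
    if (is.null(df$label_class)) df$label_class <- "definite"
    ok <- c("definite", "probable", "possible")
    if (!all(df$label_class %in% ok)) stop("label_class must be one of: ", paste(ok, collapse = ", "))
    df <- df[order(df$channel, df$t_peak_s), c("subject", "channel", "t_peak_s", "label_class")]
  } else {
    df <- data.frame(subject = character(), channel = character(),
                     t_peak_s = numeric(), label_class = character())
  }
  rownames(df) <- NULL
  class(df) <- c("sd_annotations", "data.frame")
  df
}

# ---- EDF (European Data Format) ---------------------------------------------

pad_ascii <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

#' @rdname read_recording
#' @param rec an `sd_recording` to write.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "sd_recording"))
  fs <- rec$sample_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- rec$data
  if (anyNA(x)) stop("EDF cannot carry NA samples")
  nch <- ncol(x)
  nrec <- ceiling(nrow(x) / fs)
  if (nrow(x) < nrec * fs) # pad the final partial record by edge replication
    x <- rbind(x, matrix(rep(x[nrow(x), ], nrec * fs - nrow(x)), ncol = nch, byrow = TRUE))
  # physical range must survive the 8-character ASCII header fields, so the
  # digitization uses the header-representable values, not the exact ones
  fmt_phys <- function(v) {
    s <- formatC(v, format = "g", digits = 6)
    s[nchar(s) > 8] <- formatC(v[nchar(s) > 8], format = "g", digits = 3)
    s
  }
  pmin_s <- fmt_phys(floor(apply(x, 2, min) * 1e4) / 1e4)
  pmax_s <- fmt_phys(ceiling(apply(x, 2, max) * 1e4) / 1e4)
  bad <- as.numeric(pmax_s) <= as.numeric(pmin_s)
  pmax_s[bad] <- fmt_phys(as.numeric(pmin_s)[bad] + 1)
  pmin_n <- as.numeric(pmin_s); pmax_n <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_ascii("0", 8),
                pad_ascii(rec$subject_id, 80),
                pad_ascii("sdstrip", 80),
                pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
                pad_ascii(256 + 256 * nch, 8),
                pad_ascii("", 44),
                pad_ascii(nrec, 8),
                pad_ascii(1, 8),
                pad_ascii(nch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) writeChar(paste(vapply(vals, pad_ascii, "", width), collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", nch), 80)
  field(rep("mV", nch), 8)
  field(pmin_s, 8)
  field(pmax_s, 8)
  field(rep(dmin, nch), 8)
  field(rep(dmax, nch), 8)
  field(rep("", nch), 80)
  field(rep(fs, nch), 8)
  field(rep("", nch), 32)
  scale <- (dmax - dmin) / (pmax_n - pmin_n)
  dig <- matrix(0L, nrow(x), nch)
  for (j in seq_len(nch))
    dig[, j] <- as.integer(pmin(pmax(round((x[, j] - pmin_n[j]) * scale[j] + dmin), dmin), dmax))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(as.vector(dig[idx, ])), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  subject <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  rdn <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- rdn(16)
  rdn(80)
  physdim <- rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (length(unique(spr)) != 1) stop("channels of unequal length are not supported")
  raw <- readBin(con, "integer", n = nrec * sum(spr), size = 2, endian = "little", signed = TRUE)
  if (length(raw) < nrec * sum(spr)) stop("truncated EDF data section")
  x <- matrix(0, nrec * spr[1], nch)
  pos <- 0
  for (r in seq_len(nrec)) {
    for (j in seq_len(nch)) {
      x[((r - 1) * spr[1] + 1):(r * spr[1]), j] <- raw[(pos + 1):(pos + spr[j])]
      pos <- pos + spr[j]
    }
  }
  unit_to_mv <- function(u) {
    u <- tolower(u)
    if (u %in% c("uv", "µv", "μv")) 1e-3
    else if (u %in% c("mv", "")) 1
    else if (u == "v") 1e3
    else { warning("unknown physical dimension '", u, "'; assuming mV"); 1 }
  }
  for (j in seq_len(nch)) {
    g <- (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    x[, j] <- ((x[, j] - dmin[j]) * g + pmin[j]) * unit_to_mv(physdim[j])
  }
  sd_recording(x, spr[1] / rec_dur, labels, subject)
}

# ---- HDF5 -------------------------------------------------------------------
# Layout (this package's own, documented): datasets /data (samples x channels,
# float64 mV), /channel_labels, and scalar /subject_id, /sample_rate_hz,
# /start_time at the file root.

write_hdf5 <- function(rec, path) {
  stopifnot(inherits(rec, "sd_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(rec$channel_labels, path, "channel_labels")
  rhdf5::h5write(rec$subject_id, path, "subject_id")
  rhdf5::h5write(rec$sample_rate_hz, path, "sample_rate_hz")
  rhdf5::h5write(rec$start_time, path, "start_time")
  invisible(path)
}

read_hdf5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  sd_recording(rhdf5::h5read(path, "data"),
               as.numeric(rhdf5::h5read(path, "sample_rate_hz")),
               as.character(rhdf5::h5read(path, "channel_labels")),
               as.character(rhdf5::h5read(path, "subject_id")),
               as.numeric(rhdf5::h5read(path, "start_time")))
}

#' Read or write a recording (EDF or HDF5)
#'
#' EDF files store 16-bit integers, so an EDF round trip is exact only to the
#' per-channel digitization step; the HDF5 carrier is lossless float64.
#' Channel units are normalised to mV on read (EDF physical dimensions uV, mV
#' and V are recognised). The sampling rate is always taken from the file
#' header; nothing is resampled.
#'
#' @param path file path.
#' @param format `"edf"`, `"hdf5"`, or `"auto"` (by file extension).
#' @return `read_recording`: an [sd_recording]. `write_recording`: `path`,
#'   invisibly.
#' @export
read_recording <- function(path, format = c("auto", "edf", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, edf = read_edf(path), hdf5 = read_hdf5(path))
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "hdf5")) {
  stopifnot(inherits(rec, "sd_recording"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format, edf = write_edf(rec, path), hdf5 = write_hdf5(rec, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("edf")) "edf"
  else if (ext %in% c("h5", "hdf5", "he5")) "hdf5"
  else stop("cannot guess format from extension '", ext, "'; pass format=")
}

# ---- annotations / events CSV -----------------------------------------------

#' Read or write SD annotations (CSV)
#'
#' CSV columns: `subject,channel,t_peak_s[,label_class]`. Rows are validated
#' and sorted by (channel, t_peak_s) on read.
#'
#' @param path CSV file path.
#' @return `read_annotations`: an [sd_annotations] data frame.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.numeric(df$t_peak_s)) stop("t_peak_s column must be numeric")
  sd_annotations(df)
}

#' @rdname read_annotations
#' @param aset an [sd_annotations] set.
#' @export
write_annotations <- function(aset, path) {
  write.csv(as.data.frame(aset), path, row.names = FALSE)
  invisible(path)
}

#' Read or write detection events (CSV)
#'
#' CSV columns: `channel,t_start,t_end,t_peak,peak_p`.
#' @param events data frame of detection events (see [threshold_events]).
#' @param path CSV file path.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "t_start", "t_end", "t_peak", "peak_p")
  if (!all(need %in% names(df))) stop("events CSV needs columns ", paste(need, collapse = ","))
  df
}

# ---- feature tables ---------------------------------------------------------

#' Write or read a labelled feature table (CSV)
#'
#' The header is the fixed feature registry plus `label`, `subject`,
#' `channel`, `t_center_s` metadata columns.
#' @param ts an `sd_training_set` (see [build_training_set]).
#' @param path CSV file path.
#' @export
write_feature_table <- function(ts, path) {
  stopifnot(inherits(ts, "sd_training_set"))
  df <- cbind(as.data.frame(ts$x), label = ts$label, ts$meta)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("label", "subject", "channel", "t_center_s")
  feats <- setdiff(names(df), meta_cols)
  new_training_set(as.matrix(df[, feats, drop = FALSE]), df$label,
                   df[, intersect(meta_cols[-1], names(df)), drop = FALSE],
                   segments = NULL)
}

# ---- model files (JSON) -----------------------------------------------------

#' Save or load a trained model
#'
#' The model file is JSON: the fitted backend state (gradient-boosted trees
#' or SVM support vectors) together with the sidecar fields needed to apply
#' it safely — the feature registry (names and version), selected features,
#' segment length and preprocessing parameters. At predict time the registry
#' in the file must match the one compiled into the package.
#'
#' @param model an `sd_model` from [train_model].
#' @param path JSON file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sd_model"))
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (identical(obj$backend$kind, "gbt")) {
    # trees arrive as data frames; restore the list-of-vectors layout
    obj$backend$fit$trees <- lapply(obj$backend$fit$trees, function(tr) {
      list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
           left = as.integer(tr$left), right = as.integer(tr$right),
           value = as.numeric(tr$value))
    })
  } else if (identical(obj$backend$kind, "svm_rbf")) {
    obj$backend$fit$sv <- as.matrix(obj$backend$fit$sv)
  }
  class(obj) <- "sd_model"
  obj
}

# ---- config (YAML) ----------------------------------------------------------

#' Read a YAML configuration file
#'
#' Recognised top-level keys: `preprocess` (see [preprocess_config]),
#' `detection` (see [detection_params]), `generator` (see [generator_spec])
#' and `model`. Unknown keys are passed through untouched.
#' @param path YAML file path.
#' @return named list of configuration sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preprocess)) cfg$preprocess <- do.call(preprocess_config, cfg$preprocess)
  if (!is.null(cfg$detection)) cfg$detection <- do.call(detection_params, cfg$detection)
  if (!is.null(cfg$generator)) cfg$generator <- do.call(generator_spec, cfg$generator)
  cfg
}
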