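#' Classifier configuration
#'
#' @param model_kind `"gbt"` (gradient-boosted trees, the default and the
#'   better performer) or `"svm_rbf"` (RBF-kernel SVM with Platt-calibrated
#'   probabilities).
#' @param segment_length_s analysis segment length in seconds (default 400;
#'   40 samples at 0.1 Hz is considered the minimum for feature computation,
#'   so lengths below 300 s are refused).
#' @param k_features number of top-ranked features used by the model
#'   (default 30).
#' @param hyperparameters named list overriding backend defaults. gbt:
#'   `nrounds` (100), `max_depth` (3), `eta` (0.1), `lambda` (1), `gamma`
#'   (0), `min_child_weight` (1), `scale_pos_weight` (1; set
#'   `"balanced"` to weight classes inversely to frequency). svm_rbf:
#'   `C` (1), `gamma` (`"scale"` heuristic or numeric).
#' @param random_seed integer seed applied before any randomised step.
#' @return a `model_config` list.
#' @export
model_config <- function(model_kind = c("gbt", "svm_rbf"), segment_length_s = 400,
                         k_features = 30, hyperparameters = list(),
                         random_seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(segment_length_s >= 300, k_features >= 1)
  structure(list(model_kind = model_kind, segment_length_s = segment_length_s,
                 k_features = k_features, hyperparameters = hyperparameters,
                 random_seed = as.integer(random_seed)),
            class = "model_config")
}

new_training_set <- function(x, label, meta, segments = NULL) {
  stopifnot(is.matrix(x), length(label) == nrow(x))
  structure(list(x = x, label = as.character(label), meta = meta,
                 segments = segments),
            class = "sd_training_set")
}

#' @export
print.sd_training_set <- function(x, ...) {
  cat(sprintf("<sd_training_set> %d rows (%d sd / %d non_sd), %d features, %d subject(s)\n",
              nrow(x$x), sum(x$label == "sd"), sum(x$label == "non_sd"),
              ncol(x$x), length(unique(x$meta$subject))))
  invisible(x)
}

#' Build a labelled training set from a preprocessed recording
#'
#' Positive rows are `pos_len_s` windows centred on each annotated peak
#' negativity; negative rows come from a greedy left-to-right tiling of each
#' channel *that has at least one SD* with non-overlapping `pos_len_s`
#' windows containing no annotation. Each window is then trimmed to the
#' central `analysis_len_s`, decimated to 0.1 Hz, and passed through
#' [extract_features]. Windows extending past the recording bounds are
#' dropped (positives with a warning).
#'
#' @param rec an [sd_recording] preprocessed to 1 Hz (see
#'   [preprocess_recording]).
#' @param ann an [sd_annotations] ground-truth set for this recording.
#' @param pos_len_s context window length in seconds (default 1000).
#' @param analysis_len_s analysed segment length in seconds (default 400).
#' @param feature_rate_hz rate at which features are computed (default 0.1).
#' @return an `sd_training_set`: feature matrix `x`, `label` ("sd"/"non_sd"),
#'   `meta` (subject, channel, t_center_s) and the 1-Hz analysis `segments`
#'   (columns) for curation.
#' @export
build_training_set <- function(rec, ann, pos_len_s = 1000, analysis_len_s = 400,
                               feature_rate_hz = 0.1) {
  stopifnot(inherits(rec, "sd_recording"))
  if (abs(rec$sample_rate_hz - 1) > 1e-9)
    stop("recording must be preprocessed to 1 Hz")
  if (nrow(ann) > 0 && !all(ann$channel %in% rec$channel_labels))
    stop("annotations refer to channels absent from the recording")
  dur <- recording_duration(rec)
  half_pos <- pos_len_s / 2
  half_an <- analysis_len_s / 2
  decim <- round(1 / feature_rate_hz)
  segs <- list(); labels <- character(); meta <- list()

  grab <- function(channel, t_center) {
    ic <- round(t_center) + 1
    idx <- (ic - half_an):(ic + half_an - 1)
    rec$data[idx, channel]
  }

  for (r in seq_len(nrow(ann))) {
    t <- ann$t_peak_s[r]
    ic <- round(t) + 1
    if (ic - half_pos < 1 || ic + half_pos - 1 > nrow(rec$data)) {
      warning(sprintf("annotation at t=%.0f s on %s too close to the recording edge; skipped",
                      t, ann$channel[r]))
      next
    }
    segs[[length(segs) + 1]] <- grab(ann$channel[r], t)
    labels <- c(labels, "sd")
    meta[[length(meta) + 1]] <- data.frame(subject = rec$subject_id,
                                           channel = ann$channel[r], t_center_s = t)
  }

  for (channel in unique(ann$channel)) {
    tmarks <- ann$t_peak_s[ann$channel == channel]
    s <- 0
    while (s + pos_len_s <= dur) {
      inside <- tmarks[tmarks >= s & tmarks < s + pos_len_s]
      if (length(inside) == 0) {
        segs[[length(segs) + 1]] <- grab(channel, s + half_pos)
        labels <- c(labels, "non_sd")
        meta[[length(meta) + 1]] <- data.frame(subject = rec$subject_id,
                                               channel = channel, t_center_s = s + half_pos)
        s <- s + pos_len_s
      } else {
        s <- floor(min(inside)) + 1
      }
    }
  }

  if (length(segs) == 0)
    return(new_training_set(matrix(numeric(0), 0, length(feature_registry())),
                            character(0),
                            data.frame(subject = character(), channel = character(),
                                       t_center_s = numeric()),
                            segments = matrix(numeric(0), analysis_len_s, 0)))
  segmat <- do.call(cbind, segs)
  feats <- extract_features_batch(segmat[seq(1, analysis_len_s, by = decim), , drop = FALSE],
                                  fs = feature_rate_hz)
  new_training_set(feats, labels, do.call(rbind, meta), segments = segmat)
}

#' Merge training sets from several subjects
#' @param ... `sd_training_set` objects (or one list of them).
#' @export
combine_training_sets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "sd_training_set")) parts <- parts[[1]]
  new_training_set(do.call(rbind, lapply(parts, `[[`, "x")),
                   unlist(lapply(parts, `[[`, "label")),
                   do.call(rbind, lapply(parts, `[[`, "meta")),
                   segments = do.call(cbind, lapply(parts, `[[`, "segments")))
}

#' Remove artifact-corrupted positive samples
#'
#' Positive rows whose source 1-Hz analysis segment contains any
#' `|voltage| > max_abs_mv` are removed; negatives are untouched. This is the
#' curation step that strips large DC-shift artifacts from the positive set;
#' the removal count is reported as attribute `removed` and via a message.
#'
#' @param ts an `sd_training_set` with stored segments.
#' @param max_abs_mv absolute-amplitude threshold in mV (default 30).
#' @return the curated `sd_training_set`.
#' @export
curate_positives <- function(ts, max_abs_mv = 30) {
  stopifnot(inherits(ts, "sd_training_set"))
  if (!is.numeric(max_abs_mv) || max_abs_mv <= 0) stop("threshold must be positive")
  if (is.null(ts$segments)) stop("training set has no stored segments to curate on")
  peak <- apply(abs(ts$segments), 2, max)
  drop <- ts$label == "sd" & peak > max_abs_mv
  message(sum(drop), " positive sample(s) removed by curation")
  out <- new_training_set(ts$x[!drop, , drop = FALSE], ts$label[!drop],
                          ts$meta[!drop, , drop = FALSE],
                          ts$segments[, !drop, drop = FALSE])
  attr(out, "removed") <- sum(drop)
  out
}

# ---- backends ---------------------------------------------------------------

gbt_defaults <- function() list(nrounds = 100, max_depth = 3, eta = 0.1,
                                lambda = 1, gamma = 0, min_child_weight = 1,
                                scale_pos_weight = 1)

fit_gbt <- function(X, y01, hp = list()) {
  hp <- modifyList(gbt_defaults(), hp)
  if (identical(hp$scale_pos_weight, "balanced"))
    hp$scale_pos_weight <- sum(y01 == 0) / max(sum(y01 == 1), 1)
  w <- ifelse(y01 == 1, hp$scale_pos_weight, 1)
  fit <- .gbt_fit(X, as.numeric(y01), as.numeric(w), as.integer(hp$nrounds),
                  as.integer(hp$max_depth), hp$eta, hp$lambda, hp$gamma,
                  hp$min_child_weight)
  fit$hyperparameters <- hp
  fit
}

predict_gbt <- function(fit, X) 1 / (1 + exp(-.gbt_margin(fit$trees, X)))

gbt_importance <- function(fit, feature_names) {
  imp <- ifelse(fit$split_count > 0, fit$gain_sum / pmax(fit$split_count, 1), 0)
  names(imp) <- feature_names
  imp
}

platt_fit <- function(f, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    p <- 1 / (1 + exp(z))
    eps <- 1e-12
    -sum(t * log(pmax(p, eps)) + (1 - t) * log(pmax(1 - p, eps)))
  }
  opt <- stats::optim(c(A = -1, B = 0), nll, method = "BFGS")
  list(A = unname(opt$par[1]), B = unname(opt$par[2]))
}

fit_svm <- function(X, y01, hp = list()) {
  hp <- modifyList(list(C = 1, gamma = "scale", tol = 1e-3, max_passes = 5), hp)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- scale(X, center = center, scale = scale)
  gamma <- hp$gamma
  if (identical(gamma, "scale")) gamma <- 1 / (ncol(Xs) * max(stats::var(as.vector(Xs)), 1e-12))
  yy <- ifelse(y01 == 1, 1, -1)
  sol <- .svm_smo(Xs, yy, hp$C, gamma, hp$tol, as.integer(hp$max_passes))
  keep <- sol$alpha > 1e-8
  sv <- Xs[keep, , drop = FALSE]
  coef <- (sol$alpha * yy)[keep]
  f <- .svm_decision(sv, coef, sol$b, gamma, Xs)
  platt <- platt_fit(f, y01)
  list(sv = sv, coef = coef, b = sol$b, gamma = gamma,
       center = center, scale = scale, platt = platt,
       hyperparameters = hp)
}

predict_svm <- function(fit, X) {
  Xs <- scale(X, center = fit$center, scale = fit$scale)
  f <- .svm_decision(fit$sv, fit$coef, fit$b, fit$gamma, Xs)
  1 / (1 + exp(fit$platt$A * f + fit$platt$B))
}

# ---- feature ranking and training -------------------------------------------

#' Rank features by average gain across leave-one-patient-out folds
#'
#' For each fold (one subject held out) a gradient-boosted model is fitted on
#' the remaining subjects using all features; a feature's importance in a
#' fold is its average split gain (total gain / number of splits using it),
#' and the final score is the mean across folds. Requires at least two
#' subjects and the gbt backend.
#'
#' @param ts an `sd_training_set` spanning >= 2 subjects.
#' @param cfg a [model_config] (its hyperparameters are used for the ranking
#'   fits).
#' @return data frame `feature`, `importance`, sorted by decreasing
#'   importance (ties keep registry order).
#' @export
rank_features <- function(ts, cfg = model_config()) {
  stopifnot(inherits(ts, "sd_training_set"))
  subjects <- unique(ts$meta$subject)
  if (length(subjects) < 2) stop("feature ranking requires at least 2 subjects (no folds otherwise)")
  set.seed(cfg$random_seed)
  y01 <- as.numeric(ts$label == "sd")
  imp <- matrix(0, length(subjects), ncol(ts$x))
  for (i in seq_along(subjects)) {
    tr <- ts$meta$subject != subjects[i]
    fit <- fit_gbt(ts$x[tr, , drop = FALSE], y01[tr], cfg$hyperparameters)
    imp[i, ] <- gbt_importance(fit, colnames(ts$x))
  }
  score <- colMeans(imp)
  ord <- order(-score, seq_along(score))
  data.frame(feature = colnames(ts$x)[ord], importance = score[ord],
             row.names = NULL)
}

#' Train a classifier on selected features
#'
#' @param ts an `sd_training_set` containing both classes.
#' @param cfg a [model_config].
#' @param selected character vector of feature names the model uses; default
#'   is the top `cfg$k_features` of [rank_features] (requires >= 2 subjects),
#'   or all features if `ts` has a single subject.
#' @return an `sd_model` carrying the fitted backend, the selected features,
#'   the feature-registry version and the preprocessing parameters assumed at
#'   predict time.
#' @export
train_model <- function(ts, cfg = model_config(), selected = NULL) {
  stopifnot(inherits(ts, "sd_training_set"))
  if (length(unique(ts$label)) < 2) stop("training requires both classes")
  if (is.null(selected)) {
    selected <- if (length(unique(ts$meta$subject)) >= 2)
      head(rank_features(ts, cfg)$feature, cfg$k_features)
    else colnames(ts$x)
  }
  if (!all(selected %in% colnames(ts$x))) stop("selected features missing from the training set")
  set.seed(cfg$random_seed)
  X <- ts$x[, selected, drop = FALSE]
  y01 <- as.numeric(ts$label == "sd")
  fit <- switch(cfg$model_kind,
                gbt = fit_gbt(X, y01, cfg$hyperparameters),
                svm_rbf = fit_svm(X, y01, cfg$hyperparameters))
  structure(list(config = unclass(cfg),
                 selected_features = selected,
                 registry = list(version = feature_registry_version(),
                                 names = feature_registry(round(cfg$segment_length_s / 10))),
                 preprocess = unclass(preprocess_config()),
                 backend = list(kind = cfg$model_kind, fit = fit)),
            class = "sd_model")
}

#' @export
print.sd_model <- function(x, ...) {
  cat(sprintf("<sd_model> %s, %d features, %g-s segments (registry %s)\n",
              x$backend$kind, length(x$selected_features),
              x$config$segment_length_s, x$registry$version))
  invisible(x)
}

#' Predict SD probability from a feature matrix
#'
#' @param object an `sd_model`.
#' @param newdata numeric matrix with (at least) the model's selected
#'   features as named columns, e.g. from [extract_features_batch].
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.sd_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1, dimnames = list(NULL, names(newdata)))
  if (!identical(object$registry$version, feature_registry_version()))
    stop("model was built against feature registry '", object$registry$version,
         "'; this package provides '", feature_registry_version(), "'")
  miss <- setdiff(object$selected_features, colnames(newdata))
  if (length(miss)) stop("feature(s) missing from newdata: ", paste(miss, collapse = ", "))
  X <- newdata[, object$selected_features, drop = FALSE]
  p <- switch(object$backend$kind,
              gbt = predict_gbt(object$backend$fit, X),
              svm_rbf = predict_svm(object$backend$fit, X))
  pmin(pmax(p, 0), 1)
}

# ---- cross-validation and hyperparameter search -----------------------------

auc_pooled <- function(p, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-patient-out cross-validation
#'
#' Each subject serves exactly once as the held-out test set. Feature
#' selection is refit inside every fold (gbt average-gain ranking on the
#' training subjects only), so the held-out subject never influences either
#' the selected features or the fitted model. Metrics are pooled over all
#' held-out predictions (threshold 0.5 for the count-based ones).
#'
#' @param ts an `sd_training_set` spanning >= 2 subjects.
#' @param cfg a [model_config].
#' @return list with `predictions` (subject, label, p), `metrics` (pooled
#'   accuracy, precision, recall, F1, AUC) and `folds` (per-subject row
#'   counts).
#' @export
lopo_cv <- function(ts, cfg = model_config()) {
  stopifnot(inherits(ts, "sd_training_set"))
  subjects <- unique(ts$meta$subject)
  if (length(subjects) < 2) stop("LOPO-CV requires at least 2 subjects")
  preds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    te <- ts$meta$subject == subjects[i]
    tr_set <- new_training_set(ts$x[!te, , drop = FALSE], ts$label[!te],
                               ts$meta[!te, , drop = FALSE])
    sel <- if (length(unique(tr_set$meta$subject)) >= 2)
      head(rank_features(tr_set, cfg)$feature, cfg$k_features)
    else head(colnames(ts$x), cfg$k_features)
    model <- train_model(tr_set, cfg, selected = sel)
    preds[[i]] <- data.frame(subject = subjects[i], label = ts$label[te],
                             p = predict(model, ts$x[te, , drop = FALSE]))
  }
  preds <- do.call(rbind, preds)
  y01 <- as.numeric(preds$label == "sd")
  yhat <- as.numeric(preds$p >= 0.5)
  tp <- sum(yhat == 1 & y01 == 1); fp <- sum(yhat == 1 & y01 == 0)
  fn <- sum(yhat == 0 & y01 == 1); tn <- sum(yhat == 0 & y01 == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(predictions = preds,
       metrics = list(accuracy = (tp + tn) / length(y01), precision = precision,
                      recall = recall, f1 = f1, auc = auc_pooled(preds$p, y01)),
       folds = table(preds$subject))
}

#' Exhaustive hyperparameter grid search scored by pooled LOPO F1
#'
#' @param ts an `sd_training_set` spanning >= 2 subjects.
#' @param cfg a [model_config]; each grid point overrides its
#'   `hyperparameters`.
#' @param grid named list of value vectors; the full cross-product is
#'   evaluated. Ties in F1 are broken by first-in-grid order.
#' @return list with `best` (hyperparameter list), `best_f1`, and `results`
#'   (one row per grid point, in grid order).
#' @export
grid_search <- function(ts, cfg = model_config(), grid) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) stop("grid must be non-empty")
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  f1 <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    cfg_r <- cfg
    cfg_r$hyperparameters <- modifyList(cfg$hyperparameters, as.list(combos[r, , drop = FALSE]))
    f1[r] <- lopo_cv(ts, cfg_r)$metrics$f1
  }
  best <- which.max(f1) # which.max takes the first maximum: first-in-grid tie-break
  list(best = as.list(combos[best, , drop = FALSE]), best_f1 = f1[best],
       results = cbind(combos, f1 = f1))
}
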