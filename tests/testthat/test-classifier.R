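# a quiet 1-Hz recording with known annotation placement
flat_rec <- function(dur_s, nch = 1, subject = "S01") {
  set.seed(77)
  sd_recording(matrix(rnorm(dur_s * nch, sd = 0.1), dur_s, nch),
               1, sprintf("ch%d", 1:nch), subject)
}

test_that("build_training_set: positives per annotation, edge windows dropped", {
  rec <- flat_rec(6000)
  ann <- sd_annotations(data.frame(subject = "S01", channel = "ch1",
                                   t_peak_s = c(1200, 2500, 4000)))
  ts <- build_training_set(rec, ann)
  expect_equal(sum(ts$label == "sd"), 3)
  expect_equal(ncol(ts$x), 80)
  # annotation too close to the edge is skipped with a warning
  ann2 <- sd_annotations(data.frame(subject = "S01", channel = "ch1",
                                    t_peak_s = c(300, 2500)))
  expect_warning(ts2 <- build_training_set(rec, ann2), "edge")
  expect_equal(sum(ts2$label == "sd"), 1)
  expect_error(build_training_set(rec, sd_annotations(data.frame(
    subject = "S01", channel = "ch9", t_peak_s = 100))), "absent")
  expect_error(build_training_set(
    sd_recording(matrix(0, 100, 1), 256), ann), "1 Hz")
})

test_that("build_training_set: negative tiling rules", {
  # channel of 10,500 s with one SD at t = 10,200: ten SD-free 1000-s windows
  rec <- flat_rec(10500)
  ann <- sd_annotations(data.frame(subject = "S01", channel = "ch1",
                                   t_peak_s = 10200))
  expect_warning(ts <- build_training_set(rec, ann), "edge") # positive dropped
  expect_equal(sum(ts$label == "non_sd"), 10)
  # channels without any SD contribute no negatives
  rec2 <- flat_rec(6000, nch = 2)
  ann2 <- sd_annotations(data.frame(subject = "S01", channel = "ch1",
                                    t_peak_s = 3000))
  ts2 <- build_training_set(rec2, ann2)
  expect_true(all(ts2$meta$channel == "ch1"))
  # no negative window overlaps an annotation
  marks <- c(1300, 2400, 4700)
  ann3 <- sd_annotations(data.frame(subject = "S01", channel = "ch1",
                                    t_peak_s = marks))
  ts3 <- build_training_set(flat_rec(9000), ann3)
  neg_c <- ts3$meta$t_center_s[ts3$label == "non_sd"]
  for (t in marks)
    expect_false(any(t >= neg_c - 500 & t < neg_c + 500))
  expect_equal(sum(ts3$label == "sd"), 3)
})

test_that("curate_positives removes exactly the artifact-bearing positives", {
  rec <- flat_rec(6000)
  ann <- sd_annotations(data.frame(subject = "S01", channel = "ch1",
                                   t_peak_s = c(1200, 2500, 4000)))
  rec$data[2480:2489, 1] <- 50  # 50-mV artifact inside the second positive
  ts <- build_training_set(rec, ann)
  expect_message(cur <- curate_positives(ts, 30), "1 positive")
  expect_equal(attr(cur, "removed"), 1)
  expect_equal(nrow(cur$x), nrow(ts$x) - 1)
  expect_false(any(cur$label == "sd" & cur$meta$t_center_s == 2500))
  expect_equal(sum(cur$label == "non_sd"), sum(ts$label == "non_sd"))
  expect_message(same <- curate_positives(ts, Inf), "0 positive")
  expect_equal(nrow(same$x), nrow(ts$x))
  expect_error(curate_positives(ts, -3), "positive")
})

# synthetic feature sets with controllable signal
signal_ts <- function(n_per_subject = 60, n_subjects = 4, p = 12,
                      informative = 7, strength = 3, seed = 5) {
  set.seed(seed)
  n <- n_per_subject * n_subjects
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- rep(c("sd", "non_sd"), length.out = n)
  if (!is.na(informative))
    x[, informative] <- x[, informative] + ifelse(y == "sd", strength, 0)
  new_training_set(x, y, data.frame(
    subject = rep(sprintf("P%d", 1:n_subjects), each = n_per_subject),
    channel = "ch1", t_center_s = seq_len(n)))
}

test_that("rank_features puts the only informative feature first", {
  ts <- signal_ts()
  rk <- rank_features(ts, model_config(hyperparameters = list(nrounds = 30)))
  expect_equal(rk$feature[1], "f07")
  expect_gt(rk$importance[1], max(rk$importance[-1]) * 3)
  expect_equal(nrow(rk), 12)
  expect_error(rank_features(signal_ts(n_subjects = 1)), "2 subjects")
})

test_that("rank_features on pure-noise labels shows no dominant feature", {
  shares <- sapply(1:3, function(s) {
    ts <- signal_ts(informative = NA, seed = 100 + s)
    rk <- rank_features(ts, model_config(hyperparameters = list(nrounds = 30)))
    max(rk$importance) / sum(rk$importance)
  })
  expect_lt(mean(shares), 3 / 12)  # < 3x the uniform share, averaged over seeds
})

test_that("top-k selection returns exactly k names from the registry", {
  ts <- tiny_training_set()
  rk <- rank_features(ts, model_config(hyperparameters = list(nrounds = 30)))
  expect_equal(nrow(rk), 80)
  expect_length(head(rk$feature, 30), 30)
  expect_true(all(rk$feature %in% feature_registry()))
})

test_that("training: separable data, determinism, one-class refusal", {
  ts <- signal_ts(strength = 10)
  for (kind in c("gbt", "svm_rbf")) {
    cfg <- model_config(kind, k_features = 12, random_seed = 7)
    m <- train_model(ts, cfg, selected = colnames(ts$x))
    p <- predict(m, ts$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(mean((p >= 0.5) == (ts$label == "sd")), 1)
    m2 <- train_model(ts, cfg, selected = colnames(ts$x))
    expect_equal(predict(m2, ts$x), p)
  }
  one <- new_training_set(ts$x, rep("sd", nrow(ts$x)), ts$meta)
  expect_error(train_model(one), "both classes")
})

test_that("label-permuted data gives chance-level held-out AUC", {
  set.seed(8)
  n <- 600; p <- 10
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- sample(rep(c("sd", "non_sd"), each = n / 2))
  tr <- seq_len(n / 2)
  ts <- new_training_set(x[tr, ], y[tr],
                         data.frame(subject = "P1", channel = "ch1", t_center_s = tr))
  m <- train_model(ts, model_config(hyperparameters = list(nrounds = 30)),
                   selected = colnames(x))
  p_te <- predict(m, x[-tr, ])
  auc <- sdstrip:::auc_pooled(p_te, as.numeric(y[-tr] == "sd"))
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("LOPO-CV: partition property and perfect separable cohort", {
  ts <- signal_ts(strength = 10)
  cv <- lopo_cv(ts, model_config(k_features = 5,
                                 hyperparameters = list(nrounds = 30)))
  expect_equal(nrow(cv$predictions), nrow(ts$x))     # each row predicted once
  expect_equal(length(cv$folds), 4)
  expect_equal(sort(unique(cv$predictions$subject)), sort(unique(ts$meta$subject)))
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(cv$metrics$f1, 1)
  expect_error(lopo_cv(signal_ts(n_subjects = 1)), "2 subjects")
})

test_that("grid_search: exhaustive table, sane selection, tie-breaking", {
  ts <- signal_ts(strength = 3)
  cfg <- model_config(k_features = 5)
  single <- grid_search(ts, cfg, grid = list(nrounds = 25))
  expect_equal(single$best$nrounds, 25)
  expect_equal(nrow(single$results), 1)
  # interaction signal: a single stump cannot represent x1*x2 > 0
  set.seed(9)
  n <- 240
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, sprintf("f%02d", 1:4)))
  y <- ifelse(x[, 1] * x[, 2] > 0, "sd", "non_sd")
  ts_xor <- new_training_set(x, y, data.frame(
    subject = rep(c("P1", "P2"), each = n / 2), channel = "ch1", t_center_s = 1:n))
  g <- grid_search(ts_xor, model_config(k_features = 4),
                   grid = list(nrounds = c(1, 60), max_depth = c(1, 3)))
  expect_equal(nrow(g$results), 4)
  expect_equal(g$best$nrounds, 60)
  expect_equal(g$best$max_depth, 3)
  expect_error(grid_search(ts, cfg, grid = list()), "non-empty")
})

test_that("class weighting is available and changes the decision balance", {
  ts <- signal_ts(strength = 1.5)
  keep <- ts$label == "non_sd" | seq_len(nrow(ts$x)) %% 4 == 1  # ~1:4 imbalance
  ts2 <- new_training_set(ts$x[keep, ], ts$label[keep], ts$meta[keep, ])
  base <- train_model(ts2, model_config(hyperparameters = list(nrounds = 30)),
                      selected = colnames(ts2$x))
  bal <- train_model(ts2, model_config(hyperparameters = list(
    nrounds = 30, scale_pos_weight = "balanced")), selected = colnames(ts2$x))
  expect_gte(sum(predict(bal, ts2$x) >= 0.5), sum(predict(base, ts2$x) >= 0.5))
})
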