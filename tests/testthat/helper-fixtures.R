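# Shared fixtures, built in code. The memoised model keeps the slow pieces
# (cohort generation + preprocessing + training) to a single run per suite.

.fixture_env <- new.env(parent = emptyenv())

# Small 2-subject cohort at a reduced raw rate; enough SDs to train a usable
# gbt model in ~10 s.
tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    spec <- generator_spec(n_subjects = 2, channels_per_subject = 4,
                           duration_s = 5400, fs = 64, sd_rate_per_hour = 4,
                           seed = 424241L)
    .fixture_env$spec <- spec
    .fixture_env$cohort <- generate_cohort(spec)
    .fixture_env$prep <- lapply(.fixture_env$cohort,
                                function(s) preprocess_recording(s$recording))
  }
  list(spec = .fixture_env$spec, cohort = .fixture_env$cohort,
       prep = .fixture_env$prep)
}

tiny_training_set <- function() {
  if (is.null(.fixture_env$ts)) {
    fx <- tiny_cohort()
    tss <- mapply(function(p, s) build_training_set(p, s$annotations),
                  fx$prep, fx$cohort, SIMPLIFY = FALSE)
    .fixture_env$ts <- combine_training_sets(tss)
  }
  .fixture_env$ts
}

tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    cfg <- model_config(hyperparameters = list(nrounds = 50), random_seed = 99L)
    .fixture_env$model <- train_model(tiny_training_set(), cfg)
  }
  .fixture_env$model
}

# A constant-probability model through the real code path: a gbt with zero
# trees has margin 0 everywhere, so p = 0.5 for every window.
stub_model <- function(segment_length_s = 400) {
  structure(list(
    config = unclass(model_config(segment_length_s = segment_length_s)),
    selected_features = feature_registry()[1],
    registry = list(version = feature_registry_version(), names = feature_registry()),
    preprocess = unclass(preprocess_config()),
    backend = list(kind = "gbt", fit = list(trees = list()))),
    class = "sd_model")
}

# build a probability trace by hand (times follow the window-centre convention)
make_trace <- function(p, stride_s = 1, window_s = 400, channel = "ch1",
                       subject = "S01", t0 = window_s / 2) {
  structure(list(channel = channel, subject = subject,
                 times = t0 + stride_s * (seq_along(p) - 1), p_sd = p,
                 window_s = window_s, stride_s = stride_s),
            class = "sd_probability_trace")
}
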