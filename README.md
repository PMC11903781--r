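# sdstrip

Automated detection of **spreading depolarizations (SDs)** in full-band
(DC-coupled) electrocorticography, from sparsely sampled slow potentials.

SDs are slowly propagating waves of near-complete neuronal depolarization
that recur for days after stroke, trauma or haemorrhage and drive secondary
brain injury. On a DC-coupled ECoG strip an SD shows up, channel by channel,
as a negative shift of the slow potential of roughly 5 mV lasting ~2 min
(spectral peak of a few mHz), usually followed by a slight positivity.
Reading these events out of multi-day six-channel recordings requires scarce
specialist expertise. `sdstrip` is for neurophysiology researchers and
neurocritical-care tool builders who want that read-out automated — and it
deliberately uses minimal information: one voltage sample every 10 s
(0.1 Hz) from a single channel at a time.

## Method

1. **Preprocess** raw 256-Hz data: subtract the 10-min moving median
   (removes the >70 mV DC offset and drift while passing any transient
   shorter than half the window *exactly*), FIR low-pass at 0.5 Hz
   (zero-phase), decimate to 1 Hz.
2. **Features**: each 400-s window, decimated to 0.1 Hz (40 samples),
   yields 80 features — mean, variance, skewness γ, excess kurtosis K,
   entropy H, mean/zero-cross rates and quartiles Q1–Q3 on the full window
   and two 30-sample sub-windows (30 features), plus peak coordinates,
   absolute maxima, quadrant counts and the same ten statistics for the FT
   and PSD (50 features).
3. **Classifier**: gradient-boosted trees (default) or RBF-kernel SVM,
   trained on 1000-s windows centred on expert-marked SD peaks vs SD-free
   windows, with gain-based feature ranking and leave-one-patient-out
   cross-validation (both backends are implemented in the package, in C++).
4. **Detection**: slide the window in 1-s (or 10-s) steps to get
   P_SD(t); an SD is detected when P_SD ≥ θ_P continuously for ≥ θ_D
   seconds (defaults θ_P = 0.5, θ_D = 50 s).
5. **Evaluation**: events are matched to expert marks within ±200 s;
   reports sensitivity, precision, F1, OBJ = TP² − 2·FP², and FP/day.

A bundled synthetic-ECoG generator (DC offset + drift + noise + injected SD
waveforms with ground-truth annotations, including atypical variants and
artifacts) makes the whole pipeline testable without patient data.

## Worked example

```r
library(sdstrip)

# a 5-subject synthetic cohort: 6 channels x 4 h at 256 Hz per subject
spec   <- generator_spec(n_subjects = 5, seed = 101)
cohort <- generate_cohort(spec)
prep   <- lapply(cohort, function(s) preprocess_recording(s$recording))

tss <- mapply(function(p, s) build_training_set(p, s$annotations),
              prep, cohort, SIMPLIFY = FALSE)
ts  <- curate_positives(combine_training_sets(tss))
#> 13 positive sample(s) removed by curation
ts
#> <sd_training_set> 539 rows (259 sd / 280 non_sd), 80 features, 5 subject(s)

cv <- lopo_cv(ts, model_config(random_seed = 3))
round(unlist(cv$metrics), 3)
#>  accuracy precision    recall        f1       auc
#>     0.980     0.984     0.973     0.979     0.988
```

Pooled over the five held-out subjects, 98% of 400-s segments are classified
correctly and the area under the ROC curve is 0.99 — the classifier
separates SD from SD-free segments almost perfectly on this synthetic world.

```r
model <- train_model(ts, model_config(random_seed = 3))
det   <- detect_recording(prep[[1]], model, detection_params(0.5, 50))
evaluate_detections(det$events, cohort[[1]]$annotations,
                    recording_hours = 6 * 4)
#> <sd_eval_report> TP=48 FP=5 FN=2 over 24 h
#>   sensitivity 0.960 | precision 0.906 | F1 0.932 | OBJ 0.0 x 1e5 | 5.0 FP/day
```

On subject 1's continuous recording, 44 detection events recover 48 of the
50 annotated SD waveforms (an event can evidence two nearby waveforms on a
channel, and one SD may fire several events — the evaluator reconciles
both), at five false positives per 24 channel-hours; the two misses are
low-amplitude waveforms near the noise floor.

(Counts above are what the code prints for this seed; your numbers will
match them exactly with the same seed.)

## Command line

```sh
inst/cli/sdstrip simulate   --out-dir cohort/ --seed 17
inst/cli/sdstrip preprocess --in cohort/S01.h5 --out prep.h5
inst/cli/sdstrip extract    --in prep.h5 --annotations cohort/S01_annotations.csv --out features.csv
inst/cli/sdstrip train      --features features.csv --model-kind gbt --k 30 --out model.json
inst/cli/sdstrip detect     --in prep.h5 --model model.json --theta-p 0.5 --theta-d 50 --out events.csv
inst/cli/sdstrip evaluate   --events events.csv --annotations cohort/S01_annotations.csv \
                            --hours 24 --out report.json
```

## Documentation

See the methods vignette (`vignettes/sdstrip-methods.Rmd`) for the model,
its assumptions, every numerical convention the method left open, what the
synthetic generator does and does not emulate, and known limitations.
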