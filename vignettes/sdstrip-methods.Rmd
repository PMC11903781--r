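---
title: "Detecting spreading depolarizations from sparse slow-potential sampling"
author: "sdstrip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spreading depolarizations from sparse slow-potential sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spreading depolarizations (SDs) are slowly propagating waves of near-complete
neuronal depolarization that recur for days after acute brain injury and drive
secondary lesion growth. On full-band (DC-coupled) electrocorticography an SD
appears, channel by channel, as a large negative shift of the slow potential —
typically around 5 mV, lasting about two minutes, with spectral content
concentrated below 10 mHz — often followed by a smaller positivity. Reading
these events out of multi-day, multichannel recordings requires rare
specialist expertise; `sdstrip` implements an automated detector that needs
remarkably little information: one voltage sample every 10 seconds (0.1 Hz)
from a single channel.

The pipeline is: (1) baseline-correct, low-pass and decimate the raw signal;
(2) summarise sliding 400-s windows by 80 time- and frequency-domain features;
(3) score each window with a trained probabilistic classifier, producing an SD
probability time series $P_{SD}(t)$; (4) declare a detection when $P_{SD}$
stays at or above a probability threshold $\theta_P$ for at least a duration
threshold $\theta_D$; (5) score detections against expert marks with a
±200-s matching window and report sensitivity, precision, $F_1$,
$\mathrm{OBJ} = TP^2 - 2\,FP^2$ and false positives per day.

## Preprocessing

**Moving-median baseline.** Full-band amplifiers superimpose the biology on a
DC offset of tens of millivolts plus slow electrode drift. Subtracting a
centred 10-minute moving median removes both while passing any transient that
occupies less than half the window *exactly* — the median of a window more
than half of which is baseline is the baseline. A mean would not have this
property, and a conventional high-pass (cutoffs near 5–10 mHz) distorts the SD
waveform itself. Numerical choices: the window half-width is
`floor(window_s * fs / 2)` samples, so the window size is always odd and the
median is an order statistic; at the edges the window shrinks symmetrically to
the available samples rather than padding — no data are fabricated, and a
linear trend still maps to zero everywhere. A 30-minute window
(`median_window_s = 1800`) reproduces the gentler correction conventionally
used for manual review displays.

**FIR low-pass.** A linear-phase Hamming-windowed-sinc filter with 0.5 Hz
cutoff, unit DC gain and a 0.2 Hz transition band (> 50 dB stopband). Whether
the original method compensated the filter's group delay is not documented;
we apply the filter centre-aligned (zero net delay) so that feature windows
and annotations stay aligned. Edges are handled by replicating the first and
last samples, which keeps constants exactly constant.

**Decimation.** Every n-th sample starting at index 0. The composition
"filter then decimate" is computed in a single fused pass that evaluates the
convolution only at the kept samples; the tests assert bitwise equality with
the naive composition. The further 1 Hz → 0.1 Hz step before feature
extraction applies no extra anti-alias filter: the signal is already
band-limited to 0.5 Hz and the analysis targets the < 10 mHz band, so the
bare decimation matches the method being reproduced; `lowpass_fir` can be
inserted manually if desired.

## Features

Each 400-s, 0.1-Hz segment (40 samples) yields exactly 80 features.

*Time domain (30).* Mean, population variance, skewness, excess kurtosis,
histogram entropy, mean-cross rate, zero-cross rate and the three quartiles
(linear interpolation), computed for the full segment and for each full
30-sample sub-window advanced by 10 samples — two sub-windows for 40 samples.
The original description has consecutive sub-segments "overlapping" by 10 samples, yet
counts exactly two sub-segments for a 40-sample segment; only a 10-sample
*advance* (20-sample overlap) yields two full windows, so that reading is
implemented and the step is exposed as a parameter.

*Frequency domain (50).* One-sided unnormalised DFT magnitudes (FT) and their
squares (PSD). For each transform: the (frequency, value) coordinates of the
five most prominent local maxima, the absolute maximum, the number of peaks
in each quadrant after rescaling both axes to $[-1, 1]$, and the ten
statistics applied to the spectrum values. Conventions the original description leaves
open, fixed here and versioned in the feature registry: magnitudes (not
complex parts) are used; the DC bin is excluded from peak search and quadrant
counting (baseline correction makes it uninformative) but included in the
spectral statistics vector; peak prominence is topographic (height above the
higher of the two bounding saddles) with ties broken toward lower frequency;
plateau peaks take their leftmost index; axis boundary points count to the
positive quadrant; entropy uses 10 equal-width bins over the observed range
with natural logarithms; zero-variance segments return 0 for skewness,
kurtosis and entropy so classifiers never see missing values.

## Classifiers

Two families are provided, matching the original comparison: gradient-boosted
decision trees (`gbt`, the better performer and the default) and an RBF-kernel
soft-margin SVM (`svm_rbf`). Because no suitable boosted-tree or kernel-SVM
backend is available in the target environment, both are implemented in the
package (C++): the gbt is a deterministic exact-greedy gradient booster with
logistic loss and L2-regularised leaves; the SVM is a deterministic SMO solver,
with probabilities via Platt sigmoid calibration fitted on the training
decision values (how the original SVM produced probabilities is not
documented). Feature importance is xgboost-style *average gain*: a feature's
total split gain divided by its split count, averaged over
leave-one-patient-out folds.

Training sets follow the original construction: positives are 1000-s windows
centred on each annotated peak negativity; negatives greedily tile
SD-containing channels with non-overlapping SD-free 1000-s windows; both are
trimmed to the central 400 s before decimation to 0.1 Hz. The original
curation step — removal of positives corrupted by large DC-shift artifacts —
states no criterion; we use an absolute-amplitude threshold on the 1-Hz analysis
segment, default 30 mV — several times the largest plausible SD negativity
yet below the 10–100 mV artifact range — applied to positives only.

Cross-validation is leave-one-patient-out with feature selection *refit
inside each fold*, so the held-out subject never influences feature ranking
or fitting; reported metrics are pooled over all held-out predictions
(whether the original metrics were pooled or fold-averaged is not
documented; pooled is implemented). Hyperparameter search is an exhaustive grid scored by pooled
LOPO $F_1$ with first-in-grid tie-breaking; the original search grid is not documented,
so the default grid covers tree count {100, 300}, depth {3, 5} and learning
rate {0.05, 0.1} for gbt, and C {1, 10} with the scale-heuristic or fixed
kernel width for the SVM. Class weighting (`scale_pos_weight`) is available
but off by default.

## Continuous detection

`sliding_probability` advances the 400-s window in 1-s (or 10-s) steps over
the 1-Hz preprocessed channel, decimating each window at phase 0 from its own
start. Probabilities are stamped at the **window centre** — a convention the
source never states but on which threshold alignment and evaluation depend;
it is fixed and documented here. Consecutive 1-s-stride windows therefore
sample different 0.1-Hz phases of the signal; this is accepted as the plain
reading of the method. An excursion must satisfy $P_{SD} \ge \theta_P$
(inclusive; strict vs inclusive is not documented for the original method) for a span of at
least $\theta_D$ (also inclusive), where a run of $n$ samples spans
$n \times \mathrm{stride}$ seconds. One SD frequently raises several distinct
probability peaks; the detector deliberately does *not* merge them — merging
is the evaluator's job, which is what makes TP counts comparable to
per-waveform expert marks.

## Evaluation

Each expert mark owns a 400-s window centred on its peak-negativity
timestamp, and windows are scored independently: a mark is one true positive
if *any* supra-threshold event falls inside its window (however many events
do), and a false negative otherwise; events inside no window are false
positives. An early design draft assigned each event exclusively to its
nearest mark, but that undercounts: when two waveforms on a channel sit less
than ~400 s apart, one sustained probability excursion can legitimately
evidence both, and exclusive assignment turned the second into a spurious
false negative (about a fifth of all misses on the synthetic cohort).
Per-window counting matches the stated rule that only windows *without*
aligned detections are false negatives; the nearest-mark attribution is kept
in the diagnostic assignment table. Specificity is not reported for continuous data because no
true-negative unit exists there; it appears only in segment-classification
(cross-validation) metrics. Daily false-positive rates divide by total
channel-hours / 24, so "per day" means per 24 h of recording summed over
channels (one day of a six-channel strip is 144 channel-hours).
Post-hoc adjudication — expert re-review upgrading some detections from
false positive to real SD — only adjusts the FP count and rate; original
counts are always retained.

## The synthetic world

No patient recordings are publicly available, so the package carries a
generator whose defaults *are* the documented signal characteristics:
256-Hz sampling, six monopolar channels, DC offsets above 70 mV with
random-walk drift, slow background noise (0.3 mV), peak negativities drawn
from N(5.4, 3.6²) mV truncated above 0.5 mV, ~2-minute durations, optional
afterpotentials, a 34% share of atypical variants (low-amplitude, prolonged,
double-hump, large-afterpotential — the documented share of atypical
waveforms), SD
waves spreading over a contiguous run of channels with 60–300 s per-channel
delays, and unannotated 10–100 mV artifacts. Values the documented signal characteristics do not pin down
were fixed once at realistic levels and documented: 4-h recordings at 2.5 SD
waves/h (tens of waveforms per subject at desk-scale compute), drift scale
0.05 mV/√s, afterpotential fraction 0.5. The SD waveform itself is a
piecewise raised-cosine family — only empirical summary statistics of SD
waveforms are documented, no analytic form; the family satisfies the documented
constraints (smooth unimodal negativity, ≥ 90% of non-DC energy below
10 mHz at the default duration).

Two deliberate deviations are worth noting. First, amplitude truncation is
exact rejection sampling, so the mean of drawn amplitudes is the truncated
normal mean (≈ 6.0 mV), not 5.4; tests assert against the closed-form
truncated mean. Second, the generator emulates *waveform statistics*, not
biophysics: variant shape within a wave is shared across channels, noise is
Gaussian and stationary, and no spreading-depression (high-frequency
suppression) accompanies the DC shift — so a green end-to-end test
establishes that the pipeline recovers events of the documented morphology
from realistic noise and artifacts, not that it would reproduce clinical
performance numbers. Reproducing clinical patient-cohort metrics is explicitly out of scope —
patient recordings are not publicly available; the evaluation arithmetic is
exercised on fixed worked-example counts instead.

## Worked example

```{r}
library(sdstrip)

spec <- generator_spec(n_subjects = 5, seed = 101)
cohort <- generate_cohort(spec)
prep <- lapply(cohort, function(s) preprocess_recording(s$recording))

tss <- mapply(function(p, s) build_training_set(p, s$annotations),
              prep, cohort, SIMPLIFY = FALSE)
ts <- curate_positives(combine_training_sets(tss))

cv <- lopo_cv(ts, model_config(random_seed = 3))
unlist(cv$metrics)

model <- train_model(ts, model_config(random_seed = 3))
det <- detect_recording(prep[[1]], model, detection_params(0.5, 50))
evaluate_detections(det$events, cohort[[1]]$annotations,
                    recording_hours = 6 * 4)
```

## Known limitations

- Single-channel only: multi-channel fusion, inter-channel delay inference
  and high-frequency (0.5–50 Hz) spreading-depression detection are out of
  scope.
- The EDF carrier quantises to 16 bits; HDF5 is the lossless format.
- `lowpass_fir` on full-length 256-Hz day-scale signals is direct
  convolution and slow; the fused `preprocess_channel` path is the intended
  route for raw data.
- The gbt and SVM backends are small-data implementations (exact greedy
  splits, full kernel matrix); they are not tuned for cohorts of millions of
  rows.
- Threshold comparisons are inclusive and probabilities are stamped at
  window centres; models and thresholds tuned under other conventions are
  not directly transferable.
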