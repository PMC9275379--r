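---
title: "Recognizing arousal and valence from micro-expressions, EEG and peripheral signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing arousal and valence from micro-expressions, EEG and peripheral signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During passive emotion-elicitation tasks (watching emotional video clips)
people keep a nearly neutral face, so conventional facial-expression
classifiers see little signal. Genuine affect still leaks in two ways:
as *micro-expressions* — brief (65–500 ms), involuntary, low-intensity
facial movements — and as central and autonomic physiological changes (EEG
band-power composition, skin conductance, pulse). `microfusion` implements
a pipeline that (1) spots the micro-expression apex frame of each trial,
(2) treats the apex time as the most emotional moment and cuts a region of
interest (ROI) around it in the facial video and in every physiological
stream, (3) classifies each modality for binary arousal and binary valence
(self-report ratings on the 1–9 SAM scale, binarized at 5), and (4) fuses
the three per-modality decisions.

The package also ships a synthetic multimodal generator with known ground
truth. Real multimodal affect datasets of this kind are access-restricted;
beyond that, a generator with planted effects is the only way to validate
parameter recovery end to end, because the latent affective state of a real
subject is never observable directly.

## Spotting and the region of interest

For a trial of $n$ frames, the first frame stands in for the
micro-expression onset and the last for its offset (both depict a neutral
face in the poker-face regime). Ten regions are placed around the facial
components where muscle movements concentrate — eyebrows, eyes, nose root
and wings, mouth corners, chin — and each frame $f$ is scored

$$ s(f) = \frac{1}{|R|}\sum_{p \in R}
   \frac{|I_f(p) - I_1(p)| + |I_f(p) - I_n(p)|}{2}, $$

the mean absolute intensity difference against onset and offset over all
region pixels $R$. The apex is $\arg\max_f s(f)$ (ties to the earliest
frame, so the result is deterministic). The spec-level ambiguity of whether
onset- and offset-differences are averaged or summed is immaterial for the
argmax; we average, which keeps $s(f)$ on the intensity scale.

The video ROI is a fixed window of 20 or 60 frames centred on the apex
(⌊window/2⌋ frames before it). A window that would overrun either end of
the trial is shifted, never shrunk, so the video model always sees a
constant input shape. The apex frame index is mapped into each signal
stream as `round(apex / fps * rate)` and a window of `signal_roi_seconds`
(default 15 s, `"all"` for the whole trial) is cut the same way. All
indices in the public API are 0-based with half-open windows; this keeps
the cross-stream arithmetic literal, and R subscripts are derived
internally.

## Cleaning and features

* EEG: 4th-order Butterworth band-pass 1–45 Hz applied forward–backward
  (zero phase), common average reference, per-channel z-score. The filter
  family and order are not dictated by the method; a zero-phase Butterworth
  is the standard choice for biosignals because it preserves waveform
  timing. Per-window features are the five band powers (delta 1–4, theta
  4–8, alpha 8–12, beta 12–30, gamma 30–45 Hz; bins assigned
  low-inclusive), computed from a plain (untapered) periodogram and
  averaged across channels — one scalar per band, so a trial stores
  `n_windows x 5` values regardless of channel count. A per-channel
  variant would multiply the feature width by the channel count and was
  deliberately not made the default.
* GSR: band-pass 0.1–15 Hz, sliding median (0.5 s kernel, reflected
  edges) to remove transient artifacts, z-score. Window features:
  mean, SD, mean |first difference|, mean |second difference|. The
  difference summaries are scalars because a per-window feature vector is
  required; their absolute-value form captures the magnitude of phasic
  change, which is what sympathetic arousal modulates.
* PPG: band-pass 0.7–2.5 Hz (the pulse fundamental), z-score; window
  features are mean and SD.
* All SDs in the package use the population convention (divide by $n$),
  stated once and used everywhere.
* Windows are non-overlapping, 1 s by default; a trailing partial window
  is dropped. Constant channels cannot be z-scored and are returned as
  zeros with a warning rather than NaNs.

## Classifiers

**Video.** The ROI frames are cropped to the face box (a lost box is
carried forward from the last valid frame, keeping the tensor shape
fixed), min–max normalized per frame, and resized bilinearly to 64×64.
The classifier is a compact 3D spatiotemporal convolutional model: two
blocks of 3×3×3 convolutions (8 then 16 filters, stride 2, ReLU) whose
filters are fixed and seeded, followed by average pooling over time and a
4×4 spatial grid, and a softmax head trained for 50 epochs with Adam under
class-weighted cross-entropy. Fixing the convolutional filters (random
convolutional features) is a deliberate design choice: at 60×64×64 inputs
and a few hundred trials, training the filters by backpropagation buys
little over random projections, while fixed filters make training
deterministic, seconds-fast on a single CPU, and immune to the instability
of deep training in the low-sample regime. The architecture (filter
counts, pooling grid, epochs, learning rate) is fully configurable.

**EEG and physiological sequences.** A stacked LSTM — 80 then 30 units,
2-unit softmax read out at the last window — trained for 100 epochs with
Adam (start 0.001, halved on a validation-loss plateau with patience 5,
floored at 0.0001). The validation split is the last 20% of training
trials grouped by subject, so no subject straddles the split. Batch sizes
are 128 for EEG, 32 for GSR, 64 for PPG and 32 for the fused physiological
sequence (the method leaves the fused case open; 32 matches its GSR
component, the wider of the two streams). The LSTM is implemented directly
in R with batched matrix operations; its backpropagation-through-time
gradients are verified against numerical differentiation in the test
suite, and training is bit-reproducible for a fixed seed.

**Classical baselines.** SVM (RBF kernel, regularization 200), KNN (5
neighbours) and random forest (500 trees) operate on flat per-trial
vectors: the mean over windows of the per-window features. SVM and RF
receive the class weights natively. KNN has no native cost weighting, so
its neighbour-vote fractions are re-weighted by the class weights — with
balanced data this reduces to the plain vote fraction. One caveat worth
knowing: the SVM's probability outputs come from Platt scaling, which can
partially undo the decision-boundary shift induced by class weights; the
cost-sensitivity property is therefore guaranteed (and tested) on the
weighted KNN vote and the weighted-cross-entropy LSTM, not on calibrated
SVM probabilities.

**Class weights.** `weight_c = N / (2 N_c)`, i.e. balanced weighted class
masses, computed on each training fold.

## Fusion and evaluation

Decisions are fused at the decision level, either by majority vote over
the three modality decisions (three binary voters cannot tie) or by the
weighted probability sum

$$ p^x = a\,p^x_{video} + b\,p^x_{EEG} + c\,p^x_{physio},
   \qquad a + b + c = 1, $$

with $(a,b,c)$ found by exhaustively scanning the 0.01-step simplex grid
(5,151 candidate triples) for the best training F-score; ties resolve to
the lexicographically smallest $(a,b)$, so a tie between "all weight on
one modality" solutions deterministically prefers the physiological
corner. Because the corners of the grid reproduce each single modality
exactly, the learned weights can never score below the best single
modality on training data.

Evaluation is subject-independent: subjects are shuffled once (seeded) and
dealt into 6 leave-some-subject-out folds, larger test groups first (23
subjects give test sizes 4,4,4,4,4,3; 18 give 3×6). Metrics are accuracy,
precision, recall and F1 with "high" as the positive class; undefined
ratios are reported as 0; the reported result is the unweighted mean over
folds. Remaining tie rules, fixed once: a rating of exactly 5 is "low"; a
fused probability of exactly 0.5 is "high".

## The synthetic generator

Each trial carries a latent (arousal, valence) state dealt evenly over the
four combinations within every subject, so the dataset is balanced up to
rounding. Ratings are drawn so that the binarized rating matches the
latent state with probability `rating_fidelity` (default 0.95) — this is
the label-noise ceiling of everything downstream. Defaults mirror the
acquisition conditions the pipeline targets: 80 s trials at 30 fps,
32-channel EEG at 128 Hz, GSR/PPG at 128 Hz, 23 subjects × 10 trials.

* **Video**: a static landmark-like face intensity pattern (bright
  ellipse, darker eye/mouth patches) plus per-pixel Gaussian noise
  (`noise_sd`, default 0.02). One micro-expression is planted per trial: a
  triangular additive intensity bump (duration drawn from 65–500 ms at the
  configured fps, peak exactly at the apex frame, amplitude
  `apex_effect_amplitude`, default 0.1 = 5× the pixel noise). Arousal is
  coded by bump location (eyebrows = high vs chin = low), valence by a
  second bump (mouth corners = high vs nose root = low); location coding
  survives the per-frame min–max normalization that amplitude coding would
  not.
* **EEG**: unit-variance pink noise per channel; inside a Hann-tapered
  window of `signal_effect_seconds` (default 15 s) around the apex time,
  high arousal adds a beta+gamma oscillation (22 and 38 Hz) and valence an
  asymmetry-style alpha (10 Hz) change whose left/right amplitudes — and
  channel mean — differ by state, all scaled by `band_shift_strength`.
* **GSR**: tonic level, slow sinusoid and linear drift, plus phasic
  skin-conductance-response bumps (fast rise, slow decay) whose count and
  amplitude increase with high arousal and cluster in the apex window.
* **PPG**: a pulse train at 1.0–1.2 Hz whose instantaneous rate and
  amplitude rise inside the apex window under high arousal.

GSR and PPG deliberately carry arousal only: electrodermal activity and
heart-rate changes index sympathetic arousal, not hedonic valence, and
giving the physiological channel a valence code it does not plausibly have
would overstate what fusion can do.

What the generator does **not** emulate: photorealistic faces, eye blinks,
head pose, macro-expression contamination, EEG artifacts (ocular,
muscular), respiration coupling, sensor drift or dropout. Passing the
recovery suites therefore demonstrates that the pipeline's machinery is
correct and sensitive at realistic effect scales — not that these accuracy
levels transfer to real recordings, where spotting confounds and label
noise are harsher.

## Validation conditions and expected behaviour

`synthetic_experiment_config()` pins the end-to-end validation setup: 23
subjects × 10 trials of 20 s (a full-length 80 s trial adds nothing to the
validation because all effects are local to the apex window, while 20 s
keeps the full 6-fold run in minutes on one CPU), 60-frame video ROI,
15 s signal ROI, LSTM classifiers, both fusion methods. Under the default
(strong) effect sizes every single modality recovers the latent state with
fold-mean F-scores above 0.9; with all effect strengths at zero the same
pipeline sits at chance (F ≈ 0.5), confirming that nothing in the
machinery manufactures signal. Apex spotting recovers the planted apex
within half the micro-expression duration in ≥95% of trials at an
amplitude of 5× pixel noise.

## Numerical choices and degenerate inputs

* Zero-phase filtering via `signal::filtfilt`; the 4th-order Butterworth
  was verified numerically stable even at the 0.1 Hz GSR low cut.
* Periodogram with no taper; band bins low-inclusive, high-exclusive;
  a band entirely above Nyquist is an error, not silently empty.
* Min–max of a constant frame is undefined; such frames pass through
  clamped to [0, 1] (an all-white frame stays all-white).
* `find_apex` ties break to the earliest frame; ROI windows shift rather
  than shrink at trial boundaries; both keep shapes fixed and results
  deterministic.
* All randomness is derived from explicit integer seeds via a small
  multiplicative hash kept below 2^31, so per-trial generation is
  order-independent and lazily reproducible.

## Limitations

The video model's fixed convolutional filters trade representational
power for determinism and speed; on real video with subtle texture-level
expressions a fully trained spatiotemporal network may be needed. The
spotting strategy assumes one dominant apex per trial and neutral
first/last frames; blinks and head motion violate this in real data. The
synthetic validation bounds what can be claimed about real recordings, as
discussed above.
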