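---
title: "Detecting and classifying dentate spikes from single-channel LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying dentate spikes from single-channel LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspiker)
```

Dentate spikes (DSs) are brief (< 30 ms), large (> 1 mV) positive field
transients of the dentate-gyrus hilus, driven by synchronous input from
the entorhinal cortex during quiet rest and slow-wave sleep. Their two
subtypes differ in origin and function: DS1 is driven by the lateral and
DS2 by the medial entorhinal cortex, producing current sinks in the
outer and middle molecular layers respectively. Telling the types apart
classically requires a laminar probe and current source density (CSD)
analysis; this package implements a waveform-based classifier (WFbC)
that does it from one channel, plus everything needed to validate it.

This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
show. All quantitative statements below are either definitions or
properties that the package's test suite and acceptance script compute.

## Detection

Detection operates on one target channel at the canonical rate of
1 kHz (1 sample = 1 ms; `decimate_to_1khz()` anti-alias-resamples
higher rates). The stages, in order:

1. *Reference subtraction* (optional): the LFP of a channel outside the
   dentate gyrus is subtracted from the target. Movement and electrical
   artifacts hit all electrodes with the same waveform (common mode), so
   the difference cancels them exactly while laminar-graded
   physiological events survive.
2. *Zero-phase band-pass*: 1–200 Hz fourth-order Butterworth, applied
   forward–backward (`signal::filtfilt`). Zero-phase filtering avoids
   group-delay shifts of the detected peaks; the filter's waveform
   distortion is compensated later by the offset correction.
3. *Thresholded peaks*: local maxima of the filtered trace above
   `threshold_multiplier` (default 7) times the median absolute
   amplitude of the whole filtered trace. The median is global per
   signal, not windowed. When two candidates are closer than 50 ms the
   smaller peaks are deleted first until the spacing condition holds.
4. *Peak offset correction*: each peak is moved to the maximum of the
   raw LFP within a 20 ms window, because filtering deforms the
   waveform. Ties go to the earliest sample (deterministic and
   order-independent).
5. *Tukey outlier filter* (optional): events whose raw peak amplitude
   falls outside `[Q1 − 1.5 IQR, Q3 + 1.5 IQR]` of the detected
   amplitude distribution are discarded as residual artifacts.
   Quartiles use the conventional linear-interpolation definition, and
   the interval is closed (a value exactly on a fence is kept).

Events whose ±200 ms window would cross a signal edge are dropped
rather than padded, so every downstream waveform window is fully
sampled; spacing is re-enforced after the offset correction.

## Delta states and DS rate

DSs occur almost exclusively during periods of strong delta (0–5 Hz)
activity. The recording is decomposed by empirical mode decomposition
(EMD, implemented here as classical sifting with cubic-spline envelopes,
mirrored end extrema, and the normalized squared-difference stopping
rule at tolerance 0.05). The delta-dominant intrinsic mode function
(IMF) is by default the fifth — the index that covers the delta band
for 1 kHz hippocampal LFP — with an automatic mode that instead picks
the IMF carrying the most 0–5 Hz spectral power. Automatic selection
uses absolute band power rather than the band-power *fraction*: slow
residual drift modes have a fraction near 1 with negligible power and
would otherwise always win.

Relative delta power is computed per non-overlapping one-minute window
as the fraction of the IMF's Welch spectral power (8 s Hann segments,
50% overlap) below 5 Hz; a window is *strong delta* when the fraction
strictly exceeds 0.9. The DS rate is the mean number of detected events
per strong one-minute window; with no strong window the rate is
undefined and flagged rather than returned as zero.

## Waveform metrics

All shape metrics are computed on the mean waveform across events
(−200..+200 ms), never on single trials, which can carry overlapping
events. The *scaled* mean waveform is its z-score, removing the laminar
amplitude gradient. The *width* is the distance between the second
upward concavities flanking the peak: the mean waveform is resampled to
4 kHz by cubic spline (reducing the 1 ms quantization of the native
grid), the second derivative is taken as central differences, and the
start/end width limits are its local maxima in −15..−5 ms and
5..15 ms. Because the limits are second-derivative argmaxima, the width
is invariant to gain and offset — the motivation for a width-based
metric is precisely that LFP shape is far less distorted along the
probe than amplitude is. Argmax ties take the earliest time; an argmax
sitting exactly on a band boundary is returned but flagged
low-confidence. The half-height width uses the mean over −200..−100 ms
as baseline (an event-free segment by the spacing rule) with linear
interpolation at the half-level crossings. No smoothing is applied
before the second derivative; the spline provides the only implicit
regularization. The search bands are applied on the resampled grid.

On a noiseless Gaussian pulse of scale `sigma` these definitions give a
width of `2 * sigma * sqrt(3)` and a half-height width of
`2 * sigma * sqrt(2 log 2)`, which the test suite checks at
`sigma = 4 ms` to within the 0.25 ms grid.

## CSD-based classification (CSDbC)

For each event the spatial CSD profile
`-sigma * (V(y_{i+1}) - 2 V(y_i) + V(y_{i-1}))` (unit conductivity,
interior electrodes only, no spatial smoothing) is evaluated at the
offset-corrected peak sample. The event-by-channel matrix is projected
onto its first principal component — which retains the bimodal
separation between sink configurations; a warning is emitted when the
first two PCs explain ≤ 85% of the variance — and clustered with a
two-component Gaussian mixture. Each cluster's mean CSD defines a main
source (maximum) and main sink (most negative value *above*, i.e.
shallower than, the source; if no negative value lies above the source
the global minimum is used and the result flagged). The cluster with
the shallower sink is DS1. Equal sink channels are flagged ambiguous
and broken deterministically toward the stronger sink being DS2.

## Waveform-based classification (WFbC)

Each event is represented by the raw-LFP amplitudes in a −15..+15 ms
window (31 features at 1 kHz). A two-component Gaussian mixture is fit
to the raw feature rows — no standardization and no PCA, which degrade
accuracy for this problem. If one cluster holds fewer than 5% of the
*total* detected events it is treated as an artifact group, excluded,
and clustering repeats on the remainder until both clusters hold
5–95% of the total (a hard iteration guard of 20 protects against
pathological inputs; the percentage is always measured against the
original total, not the surviving set). The cluster whose mean waveform
has the lower sum over +10..+50 ms is DS2, reflecting its pronounced
post-peak negativity; an exact tie is flagged and broken toward the
cluster with the lower minimum in that window.

The mixture is initialized from a seeded k-means partition of the raw
feature rows and refined by EM (mclust), with a fallback chain of
covariance parameterizations (full → shared full → diagonal →
spherical) for near-singular fits. k-means anchoring matters: it locks
the split onto the dominant raw-variance direction (event amplitude),
which makes labels essentially reproducible across seeds; free
model-based initialization can land on alignment-jitter directions,
where the two cluster means differ by a fraction-of-a-millisecond time
shift — a difference the dissimilarity index reads as a spurious type
contrast.

### Single-type check

The dissimilarity index (DI) between the two cluster means is the mean
absolute difference of their second derivatives, each min-max scaled to
[0, 1], within ±10 ms of the peak (the scaling span equals the
comparison window). DI ≤ 0.06 (0.07 in borderline datasets) indicates a
single DS type: the clusters are merged and the pooled mean waveform's
width metrics vote on the type — width > 19 ms, start limit < −9.5 ms
and end limit > 9.5 ms each vote DS1, majority of the three decides.
A ±1 sample relative shift between cluster means alone costs a DI of
about 0.1 at these waveform scales, which is why the classifier's split
direction (previous section) matters so much, and why populations whose
clustering locks onto alignment rather than amplitude can exceed the
threshold even when only one type is present. The threshold is used as
given; it is deliberately not auto-adjusted.

### Experiment procedures

`window_size_sweep()` re-runs the classifier across feature windows and
GMM seeds against a reference labeling, to verify the −15..+15 ms
default on a given dataset. `subsample_experiment()` repeatedly draws
random event subsets at given totals and DS2 proportions and reports
median/IQR accuracy and the fraction of rounds collapsing to a single
cluster — the procedure behind the recommendation to feed the
classifier more than 500 events.

## Validation metrics

`accuracy()` is the fraction of events labeled identically;
`precision_recall()` and `confusion_normalized()` use the standard
definitions with row-normalized confusion matrices whose diagonals are
the recalls; undefined ratios are flagged, never silently zero.
Events excluded by the artifact loop are dropped from both labelings
before comparison, and the dropped count is reported.
`metric_agreement()` wraps an ordinary least-squares fit, reporting
Pearson's r, the slope, and the Wald t-test p-value of the slope
against 1. The coefficient of variation uses the sample
(n − 1) standard deviation, as do all standard deviations in the
package.

## The synthetic generator

`synthesize_recording()` builds laminar LFP in which every stage of the
pipeline is testable against ground truth. Its defaults *are* the
validation conditions used by the test suite and the acceptance script:

* 30 min, 1 kHz, 8 depth-ordered channels; 500 events per type.
* Event templates: a Gaussian main lobe (scale set so the
  second-derivative width equals the nominal width: 22 ms for DS1,
  14 ms for DS2) plus a delayed negative lobe (relative depth −0.12 for
  DS1, −0.3 for DS2) reproducing the DS2 post-peak negativity. Widths
  and depths jitter per event (log-normal, 8% and 15%) because real
  waveforms vary smoothly from trial to trial — this within-type
  variability is also what the mixture clustering of a single-type
  population should split on. Peak times are continuous (uniform
  sub-sample offsets): analog events are not locked to the sampling
  grid, and grid-locking would make detection offsets artificially
  discrete.
* Peak amplitudes: log-normal, mean 1.5 mV, sd 0.25 mV per type,
  truncated to the Tukey fences of the drawn population shrunk by a
  background allowance (`delta_amp/2 + 2 * noise_sd`), so that
  *measured* amplitudes (event + state rhythm + noise) stay inside the
  fences of the detected population and the outlier filter removes only
  what it is meant to remove.
* Laminar profiles: per-channel gains constructed so the discrete
  second spatial difference has one dominant sink above one dominant
  source, DS1's sink one channel shallower than DS2's, common source in
  the hilus (where amplitudes are largest, gain 1). Channel 1 is a
  low-gain superficial channel usable as reference.
* Background: independent per-channel pink (1/f) noise, sd 0.1 mV,
  spectrally flattened below 0.5 Hz (no baseline wander at event scale)
  and rolled off above 300 Hz — LFP sampled at or downsampled to 1 kHz
  is anti-alias filtered, and because second-derivative metrics weight
  noise by frequency squared, unphysical near-Nyquist noise would
  dominate them.
* States: alternating delta-on (3 Hz, 0.3 mV, slowly amplitude
  modulated) and delta-off epochs (7 Hz theta, 0.15 mV), 120 s / 60 s,
  common across channels, with 1 s ramps. The delta amplitude is chosen
  so the delta tone is absorbed by the same IMF that carries 4–8 Hz
  activity in off epochs — the mechanism that makes per-IMF relative
  delta power state-discriminative. Events are placed only in delta-on
  epochs, on the depolarized crest of the delta cycle (UP-state-like),
  with ≥ 250 ms spacing and ≥ 200 ms edge margins.
* Artifacts (optional): sharp biphasic transients with an identical
  waveform on every channel, default 7.5 mV (5× the mean event
  amplitude), so reference subtraction cancels them exactly and,
  when detection runs without mitigation, they form the small distinct
  cluster the WFbC artifact loop is designed to excise.

What the generator does **not** emulate: spiking units and their
contamination of the LFP, theta-nested gamma, behavioral state
transitions beyond the two-state schedule, electrode drift,
heterogeneous per-channel noise, and volume-conduction geometry beyond
the fixed gain profiles. Passing the synthetic validation therefore
shows that the implementation is correct and self-consistent under
realistic amplitudes and noise — not that classification accuracy on
any particular real recording will match the synthetic numbers.

## Problem sizes and numerical choices

The test suite and acceptance script use a 30-min main session
(1000 events), a 20-min artifact session, a 10-min single-channel
session for state segmentation, 50-round subsampling at totals 200 and
1000, and 10 GMM seeds for the single-type path; these sizes keep each
stage's intent measurable while the whole validation completes in a few
minutes on one core. Other numerical choices collected here: quartiles
by linear interpolation; strict inequality for the strong-delta
threshold; earliest-sample tie-breaks for argmax searches; EMD sift
tolerance 0.05 with at most 10 sifts and 12 IMFs; Welch segments of
8 s; GMM fallback chain as above; and the artifact-loop guard of 20
iterations.

## A worked session

```{r example}
out <- synthesize_recording(synth_config(duration_s = 600,
                                         n_events = c(150, 150), seed = 42))
catalog <- detect_dentate_spikes(out$recording, out$target_channel,
                                 out$reference_channel)
wf <- classify_wfbc(out$recording, catalog, channel = out$target_channel,
                    seed = 1)
cs <- classify_csdbc(out$recording, catalog, seed = 1)
glance(wf)
evaluate_classifications(cs, wf)
```

```{r plot, fig.width = 6, fig.height = 4}
plot_type_waveforms(wf, out$recording, channel = out$target_channel)
```

## Known limitations

* The DI threshold separates "same type" from "different types" by a
  narrow margin: noise floors of 0.03–0.05 against a two-type contrast
  near 0.11 under the default synthetic conditions. Populations whose
  clustering locks onto alignment jitter can exceed 0.06 with only one
  type present; the alternate 0.07 threshold exists for such borderline
  data.
* EMD mode indices are dataset-specific: the "fifth IMF" default is
  appropriate for 1 kHz hippocampal LFP but should be replaced by
  `auto = TRUE` when the sampling rate or noise structure differs.
* Widths are defined only for mean waveforms; no per-event width is
  provided by design.
* The detector uses one global threshold per signal; recordings with
  grossly non-stationary noise floors should be segmented upstream.
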