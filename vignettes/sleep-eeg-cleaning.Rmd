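---
title: "Cleaning multichannel sleep EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning multichannel sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepscrub)
```

## The problem

Sleep EEG is long (8 h), multichannel (from a handful to 256 electrodes) and
physiologically heterogeneous: wake, light and deep NREM and REM differ in
amplitude, spectrum and muscle tone. Artifacts — movement and muscle bursts,
sweat drifts, electrode pops and flatlines, gel bridges, failing references,
detached channels — are equally heterogeneous and rarely affect all channels
at once. Whole-epoch or whole-channel rejection therefore wastes data;
channel-resolved detection plus time-resolved repair preserves it.
`sleepscrub` implements that strategy as a fully non-interactive pipeline:
all decisions are parameterized, every run is reproducible, and a static
quality figure replaces interactive review for the first pass.

## Detectors

A detector is declarative: *scope* (channel-wise, pairwise over local
neighbors, pairwise over all channels), a *chain* of signal primitives, a
*criterion*, and event post-processing (padding, merging). The primitives
are deliberately cheap — zero-phase Butterworth filters (order 4 per pass,
applied forward and backward so event boundaries are not shifted), the
Hilbert-transform amplitude envelope, per-channel z-scoring, absolute
one-sample gradients, and running medians — because an overnight
high-density recording leaves no budget for anything heavier.

The nine default detectors and their thresholds (300 µV, 5 µV/30 s, envelope
z > 8 and z > 3, gradient z > 25, 1 µV/1 s, r < 0.3, 0.5 µV, r > 0.9) are a
starting point, not an oracle; every value is exposed in a YAML-serializable
form (`detector_set_to_yaml()`). Three parameters adapt to the sample rate:
the jump median-filter order (nearest odd integer to 9·fs/250), the flatline
gradient threshold (1 µV · 250/fs, since a gradient per sample shrinks with
oversampling), and the highfreq band edge (120 Hz when Nyquist allows,
0.95 · Nyquist otherwise; the detector is dropped with a warning when that
edge reaches 80 Hz, so low sample rates yield a smaller set).

Two documented interpretations of the pairwise rules: the *similar*
(bridging) criterion fires when **any** local neighbor pair is within
0.5 µV maximum absolute difference over the window — both members of a
numerically identical pair are flagged, which is the observable signature of
a gel bridge; and partners whose window has zero variance are excluded from
correlation-based criteria (the correlation is undefined there), with a
window flagged only when the qualifying fraction *strictly* exceeds the
neighbor-fraction parameter.

### Envelope smoothing

The envelope is smoothed with a centered moving average, default **1 s**.
This default matters: the raw Hilbert magnitude of a band-limited signal
fluctuates on the time scale of the band's inverse bandwidth, so a z > 3
threshold on a lightly smoothed envelope fires on momentary fluctuations of
perfectly ordinary background — hundreds of sub-second events over a night.
One-second smoothing makes the z-scored envelope respond to amplitude
changes sustained for about a second or more, which is the time scale of the
artifacts these detectors target (muscle bursts, sweat drifts). Shorter
smoothing is available per detector for users hunting brief events.

### Stage restriction and z-scoring

By default every detector sees the whole recording, and z-scores are
computed over all samples of a channel. When a detector restricts stages,
the restriction is applied by masking: excluded samples do not enter the
z-score statistics and cannot generate events, but filters still run over
the continuous signal (filter state must not jump across stage boundaries).
Whether whole-night or stage-restricted statistics are more appropriate is
data-dependent — a night rich in slow waves needs a high low-frequency
threshold precisely because the statistics include slow-wave epochs — so
both are exposed.

## Grid algebra

Events are discretized onto a boolean channels × segments grid (5-s
segments; an element is set when the summed event overlap *strictly* exceeds
`element_min_proportion` of the segment's actual duration, default 0, i.e.
any overlap). Five steps follow: OR-pooling into the basic grid; spatial
expansion; segment rejection; temporal expansion; repair composition. The
threshold comparisons use ≥ (the enabled threshold 1.0 still fires on a
fully artifactual column), and *disabling* a step is a distinct state
(`NULL`), not threshold 1.0. Temporal expansion computes each channel's
artifactual fraction over non-rejected segments only, so a block of globally
bad segments does not nominate every channel as a bad channel. Spatial
expansion is a single pass: channels added by expansion do not recruit
further channels. Rejection is driven by basic ∨ spatial by default
(switchable to basic only). The repair grid is the union of the three
artifact grids minus rejected segments — by construction `repair ∧
rejection` is empty, and the package asserts this on every grid set.

Typical enabled values are 0.75 (spatial), 0.25 (rejection) and 0.25
(temporal); all three default to off.

## Spherical-spline repair

Bad channels are reconstructed per segment from the clean channels with the
spherical-spline kernel

g(x) = (1/4π) Σₙ₌₁ᴺ (2n+1) / (n(n+1))ᵐ Pₙ(x),

evaluated at cosines of inter-electrode angles after centering the montage
on its centroid and projecting to the unit sphere. Defaults m = 4, N = 20
terms, and a ridge term λ = 10⁻⁵ on the knot system (tolerating noisy and
nearly coincident electrodes) follow common EEG practice; all are exposed in
`spline_params()`. The augmented linear system (kernel + ridge, constant
row/column) is solved once per segment and applied to all time samples, so
repair is linear in the data and reproduces constant fields exactly.

Because adjacent segments may be repaired with different clean sets, each
repaired run is linearly crossfaded with its surroundings over 0.1 s
centered on every boundary where a channel's repaired status or solution
changes — including between two repaired segments with different clean sets.
Samples outside flagged spans and crossfade zones are bit-identical to the
input. A segment with fewer than three clean channels is not repairable; it
is left unmodified and reported in a residual table rather than silently
filled. Fixed-value repair (NaN or zero) is exact to the flagged spans with
no crossfade.

## Selection

Clean-data selection keeps samples in requested stages and non-rejected
segments, forms maximal uninterrupted runs and drops runs below the minimum
duration. A transition between two *requested* stages does not interrupt a
bout by default (flag to change); the minimum duration is ≥ by default with
a strict-inequality flag. Trials mode returns one block per bout;
pseudocontinuous mode concatenates the same samples and keeps the boundary
table.

## Agreement evaluation

`confusion_from_grids()` counts channel-segment elements; κ uses chance
agreement pₑ = p₁q₁ + (1−p₁)(1−q₁) from the two prevalences. Published
comparisons often print only N, the two prevalences and sensitivity; these
four values determine the entire confusion matrix, and
`metrics_from_summary()` reconstructs it with real-valued counts (no integer
rounding) so the residual disagreement with printed values is transparently
the 3-decimal rounding of the inputs (about ±0.006 on the derived metrics).

## The synthetic fixture

`gen_recording()` emulates the study conditions end to end: 16 channels on a
Fibonacci hemisphere, 250 Hz, 10 minutes spanning W/N1/N2/N3/R in 30-s
epochs, and 40 injected artifacts covering all nine target classes.

* **Background**: 1/f pink noise, spatially mixed with kernel
  exp(−d/(0.5·radius)) and normalized to 15 µV RMS per channel — typical
  scalp amplitudes, with neighbor correlations around 0.5–0.7.
* **Stage oscillations**: 10 Hz alpha in W (20 µV), 13 Hz spindle bursts in
  N2 (25 µV, 1 s every 6 s), 0.75 Hz slow waves in N3 (40 µV), with a smooth
  topographic gain.
* **Muscle tone**: an independent per-channel broadband (≥ 40 Hz) component,
  6 µV RMS, whose level cycles sinusoidally (depth 0.6, period 97 s,
  channel-specific phase). This is the feature that makes z-scored
  high-frequency envelopes behave as they do on real data: the slow,
  *bounded* level variation dominates the envelope's standard deviation, so
  z > 3 is reached only by genuine bursts, never by the tone itself. The
  simplification relative to real data is deliberate and documented: real
  muscle tone is also stage-modulated (wake ≫ N3), but a rare discrete high
  level parks the wake baseline exactly at the z = 3 boundary, which makes
  detection behavior a coin flip rather than a property; the fixture trades
  that realism for determinate statistics. Consequently, passing tests show
  the detectors recover their target classes against realistic amplitudes,
  correlations and spectra — they do not show robustness to stage-modulated
  EMG, eye movements, cardiac artifacts or electrode impedance drift, none
  of which the generator emulates.
* **Injections** realize each detector's target signature with margins
  measured against the same whole-night z statistics the detectors use
  (self-masking included — an artifact inflates its own channel's variance):
  700 µV 1.5 Hz bursts under Hann envelopes; 40-s attenuations to a
  sub-microvolt floor (a dried electrode; the flatline detector legitimately
  co-fires there); 6-s 240 µV 0.5 Hz drifts (z-excursion ≈ 10; longer or
  stronger drifts saturate their own z-score); 5-s 30 µV RMS 60–120 Hz
  bursts; 220 µV steps with 0.5-s exponential recovery; 2.5–3 s holds with
  continuous entry/exit; 60-s replacements by independent noise (deviant);
  60-s exact copies of a neighbor (bridging; truth on both channels); and
  20-s common 4–12 Hz sources at 40 µV RMS on all channels (reference
  failure, pairwise r ≈ 0.95). The reference source is deliberately
  low/mid-frequency: that is what a failing reference physically injects
  (the reference electrode's own EEG), and any strong common source above
  ~14 Hz turns the order-9 median filter into a gradient-spike generator on
  every channel, conflating two artifact classes.
* **Schedule**: channel-wise injections live on channels E1–E12 in the first
  six minutes; the long pairwise artifacts occupy E9–E16 in the last four
  minutes, aligned to 30-s windows, one at a time, so no channel carries two
  conflicting signatures at once — mirroring the fact that distinct physical
  faults rarely coincide on one electrode within minutes.

Every generated quantity is checked by tests against its own specification
(RMS within 10%, spectral slope within ±0.3, exact flatline gradients, exact
bridging copies), and the recovery test requires each default detector to
reach event-level sensitivity ≥ 0.9 and precision ≥ 0.8 against ground
truth, where a detected event counts as correct when it overlaps at least
half of an injected span of *any* class on that channel (detectors
deliberately overlap in coverage: a channel pop is both a jump and a
low-frequency transient).

## Numerical and interface choices

* Time is seconds from recording start; intervals are half-open
  [start, end); sample *i* (0-based) covers [i/fs, (i+1)/fs).
* Gap merging is strict (a gap exactly equal to the merge interval is kept);
  element marking is strict (overlap must exceed the proportion); grid
  thresholds are ≥.
* Pairwise windows are anchored at time 0, non-overlapping, final partial
  window dropped.
* EDF output uses a symmetric physical range per channel, so the write→read
  round trip is exact to one 16-bit quantization step of that range.
* The test problem sizes — a 16-channel 10-minute fixture, 1000 random 8×20
  grids, 1000 random signals, a 32-electrode interpolation field — were
  chosen so the full suite completes in about a minute while exercising
  every code path at realistic scale.

## Known limitations

No ICA pre-cleaning (component-based removal of ocular/cardiac activity is
out of scope), no interactive scrolling viewer, no topographic head-map
rendering, no detectors for events that are analysis targets rather than
artifacts (spindles, slow waves, eye movements), and no resampling — the
caller should decimate to ≤ 250/256 Hz first. Detection quality on real
recordings depends on reference, montage and population; the defaults are a
vetted starting point that users are expected to tune with the quality
figure and summary tables in hand.
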