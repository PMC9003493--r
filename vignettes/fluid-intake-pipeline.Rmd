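---
title: "Methods: the sipwise fluid-intake pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sipwise fluid-intake pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipwise)
```

## Overview and assumptions

`sipwise` estimates cumulative fluid intake from a single accelerometer
axis aligned with a water bottle's vertical. The pipeline assumes:

* **uniform sampling at a known rate** (default 20 Hz). All stages are
  sample-indexed; `sample_rate_hz` is only used to convert to seconds.
* **tilt shows up on one axis.** Upright the axis reads the gravity
  component (~1 raw unit); a drinking gesture is a smooth transient
  excursion lasting 1–6 s. Only relative amplitudes matter, because peak
  normalization removes scale.
* **sip height grows as the bottle empties.** Draining the bottle forces a
  steeper tilt, so the per-sip maximum inclination rises within a drinking
  cycle and drops back after a refill. The first-sip detector rests
  entirely on this monotonicity.
* **the bottle volume is known** and refills are complete. Partial refills
  are outside the model: the self-correction always targets integer
  multiples of the bottle volume.

## Preprocessing

`preprocess_stream()` chains four steps.

**Moving average** (`ma_window`, default 5 samples = 0.25 s). A centred
sliding mean whose window shrinks symmetrically at the stream edges, so
output length equals input length. Two numerical details are deliberate:
the interior is computed with `stats::filter` (each output summed
independently) rather than prefix-sum differences, because prefix sums
accumulate rounding error that breaks the exact equality of constant
stretches — and the segmentation below detects plateaus by exact equality.
Even window lengths behave as the next odd size, since a centred window
needs an odd support.

**Peak segmentation** (`segmentation_threshold`). A sample is a local
minimum (maximum) iff strictly below (above) both neighbours; plateaus
collapse to a single extremum, and the terminal runs of the stream count
as delimiting minima when they lie below their single neighbour — without
this, a session that ends on a quiet baseline would silently lose its last
gesture. Every pair of consecutive sub-threshold minima containing a local
maximum above both delimiters *and above the threshold* yields one
segment. The "above the threshold" condition is what keeps pure sensor
noise (a parked bottle, a cup holder in a car) from emitting spurious
segments: noise wiggles produce plenty of minima/maxima pairs, but none
that clear a threshold sitting well above the noise band. Segment bounds
step over delimiting plateaus to their inner edge, so zero-noise quiet
gaps are not dragged into the neighbouring episode.

The threshold appears twice in this field's convention with the same name:
once in raw units (segmentation) and once in the normalized domain (the
feature threshold, fixed at 10). They cannot be the same number, so the
configuration exposes both: `segmentation_threshold` (raw units) and
`th_norm` (= 10). When `segmentation_threshold` is `NULL` it is estimated
per stream as `median + 0.25 * (max - median)`; if the whole span above
the median is below 0.1 raw units (a tenth of gravity — far less than any
drinking tilt) the stream is declared gesture-free and nothing is emitted.

**Normalization.** Each segment is mapped affinely onto `[10, 20]`; any
non-constant segment attains exactly 10 and 20, and the output is
invariant under positive affine transforms of the raw values. A degenerate
constant segment maps to all 10s (the floor), consistent with 10 being the
minimum normalized value.

**Window fitting** (`episode_len` = 120 samples = 6 s, `pad_value` = 10).
Shorter gestures are right-padded; longer ones are truncated to the first
120 samples rather than discarded — discarding would silently drop slow
sips. The raw-domain maximum of the source segment (`raw_max`) rides along
with every episode; it later serves as the sip height p(i).

## Episode features and the sip classifier

Five features per episode: peak count above `th_norm`, `raw_max`, peak
duration (samples above `th_norm`), the stable-portion count (samples at
or above `(1 - stable_fraction) * max`, default band 20 %, read
multiplicatively so it is scale-free), and the final sample's height.
`raw_max` is intentionally taken *before* normalization: after
normalization every episode's maximum is identically 20 and carries no
information, while the raw maximum measures the actual tilt.

The classifier is a fully connected network written directly in R:
Glorot-uniform initialization, ReLU hidden activation (the field's default
where unstated), sigmoid output, weighted binary cross-entropy, explicit
backpropagation, minibatch SGD (sip regime: 300 epochs, batch 100, lr
0.01) or Adam (first-sip regime: 150 epochs, batch 10). Features are
standardized with constants estimated on the training split and stored in
the model, because the features mix counts, durations and raw
accelerations. The 80:20 train–validation split is a seeded stratified
shuffle. Everything downstream of the seed is deterministic, so identical
data and seed give bit-identical weights.

Two robustness choices came out of observing training on tiny networks:

* **Multi-restart fitting** (`n_restarts`, default 3). A 3-neuron ReLU
  network occasionally lands in a poor local minimum from an unlucky
  initialization and no amount of further epochs rescues it. Restarts use
  seeds derived deterministically from the base seed and the lowest final
  training loss wins.
* **First-sip learning rate 0.01.** At the regime's fixed 150-epoch
  budget, Adam at the generic 0.001 default reproducibly plateaus short of
  convergence even on cleanly separable gradient features; 0.01 converges
  with a wide margin. The sip regime keeps SGD at 0.01.

## First-sip detection

Features are backward differences of the sip-height sequence at lags 1–3.
For i ≤ 3 the missing references clamp to p(1), yielding neutral
near-zero features instead of an error; the first sip of a session is
labelled a first sip by convention, and at run time `estimate_session()`
opens the first cycle on the first detected sip. Because first sips are
rare (one per cycle), training weights rows by inverse class frequency.

The features are translation-invariant but **not** scale-invariant, so the
detector must be trained on height sequences in the same units the
pipeline produces (raw episode maxima — baseline ~1 plus amplitudes of a
few tenths), not on arbitrary rescalings.

## Volume estimation

State: cumulative intake V_intake, per-sip estimate V_sip (cold-started at
`v_bottle / expected_sips_per_bottle`), sip counter S_count, and the
intake recorded at the cycle start. Per detected sip:

* **non-first sip** — add V_sip, capped so the running cycle never exceeds
  one bottle volume; once a cycle's estimate reaches the full bottle it
  stays constant until the next first sip.
* **first sip** — close the previous cycle: snap its consumption onto
  k·V_bottle for the integer k ≥ 1 minimizing the residual, re-estimate
  V_sip = k·V_bottle / S_count, then open the new cycle and add the new
  V_sip.

Numerical/semantic choices:

* k is chosen against the cycle's **uncapped** consumption estimate
  (S_count · V_sip). Using the capped value would make k = 2 unreachable
  after a missed first sip (the cap pins the cycle at exactly one bottle),
  and recovering exactly that scenario — freeze at one bottle, then snap
  to two — is the point of the correction.
* k < 1 is never considered; a first sip arriving with an empty cycle
  (S_count = 0) opens the cycle without a correction, which covers both
  the session start and duplicate first-sip detections.
* Ties (residual exactly half a bottle) break toward the smaller k.
* The correction closes the old cycle *before* adding the new first sip's
  volume, so the snap covers exactly the sips that emptied the bottle.
  The literal add-then-correct line order is available via
  `literal_order = TRUE`.

Consequences, which the test suite asserts: intake is non-decreasing;
under perfect detection every first-sip-time estimate is exact; with a
fraction q of sips dropped the post-correction cycle totals still sit on
whole bottles and the intra-cycle error is bounded by roughly
q·V_bottle + V_sip.

## The simulator: what it emulates, what it does not

`simulate_session()` builds a session from a stated world: baseline 1.0
(upright gravity), raised-cosine sip bumps of 1.5–4 s (within the 1–6 s
envelope; a raised cosine has a single interior maximum, so a clean sip
has exactly one peak), amplitudes `0.5 + (rank − 1)·0.05` within each
cycle and resetting to 0.5 at a refill, quiet gaps of 2–5 s, Gaussian
sensor noise of sd 0.01 (about 1 % of gravity, typical of consumer IMUs),
and non-sip bouts drawn from six kernels: walking (~2 Hz sinusoid, amp
0.3), stairs (1.5 Hz, amp 0.45), bag sway (1 Hz plus jostle), stationary
(noise sd 0.005), car (noise sd 0.03) and sub-second fidget spikes. Every
cycle resets to the base amplitude, so the refill drop equals
`(sips_per_cycle − 1) · increment` — at least three increments whenever a
cycle has four or more sips, which is what makes the gradient features
linearly separable. Per-sip true volumes are equal within a cycle and sum
to the bottle volume, matching the estimator's constant-V_sip model.

What it does **not** emulate: per-person gesture signatures, multi-axis
coupling, sensor drift or saturation, partial refills, or the messy
amplitude overlap of real non-sip gestures with real sips. A green test on
simulated data therefore establishes that the algorithms are implemented
correctly and recover a world obeying their own assumptions — not that the
pipeline reaches any particular accuracy on human data.

## Known limitations

* Gradient features tie the detector to the training height scale (see
  above); deployments with different mounting or units must retrain.
* The k ≥ 1 snap misfires on a spurious first-sip detection mid-cycle: a
  one-sip "cycle" still maps to a full bottle. The duplicate guard only
  covers back-to-back detections.
* The auto segmentation threshold assumes the stream's median is the
  resting baseline; a session dominated by sustained tilt would mislead
  it. Supply `segmentation_threshold` explicitly in such cases.
* Accuracy-per-energy ranking takes externally measured energy figures;
  the package does not model energy consumption.
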