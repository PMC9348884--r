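---
title: "Classifying beam-jet hits from side-microscope images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying beam-jet hits from side-microscope images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jetwatch)
```

## The physical picture and the classification model

A gas dynamic virtual nozzle (GDVN) emits a liquid microjet a few
micrometres wide that carries protein crystals through the focus of an XFEL
beam. A pulsed, backlit side microscope records one frame per pulse train at
10 Hz. Three image features carry all the information the classifier needs:

* the **nozzle**, a large dark silhouette whose position is stable over a
  run;
* the **jet**, a dark, quasi-vertical column a few pixels wide emerging from
  the nozzle tip, which disintegrates into droplets at its natural breakup
  length, typically beyond 200 µm from the interaction region;
* on a **hit**, a jet explosion that removes jet material across the full
  width of the column close to the nozzle, leaving a short, bounded,
  jet-free band.

The pipeline turns this into four deterministic stages: ZNCC template
matching to find the nozzle and fix a region of interest (ROI); adaptive
Gaussian-weighted local thresholding to a binary jet mask; a row-by-row
break scan with a gap-width bound and a distance-from-nozzle bound; and a
sliding FIFO window that ORs per-frame verdicts into instance verdicts.
Every stage is pure given its inputs, so a fixed frame sequence and
configuration reproduce identical outputs bit for bit.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `pixel_size_um` | (required) | µm/px | optical scale; converts the distance rule to pixels |
| `roi_length_px` / `roi_halfwidth_px` | 400 / 100 | px | ROI extent downstream / lateral of the tip |
| `threshold_window` (W) | 13 | px | adaptive threshold window, odd |
| `threshold_offset` (C) | 7 | 16-bit counts | margin below the local mean |
| `threshold_sigma` | 0.3·((W−1)/2−1)+0.8 | px | Gaussian weight width |
| `max_gap_px` | 20 | px | largest gap that still counts as a beam-induced break |
| `max_break_distance_um` | 200 | µm | gaps starting farther out are droplet breakup |
| `sma_window` | 10 | frames | FIFO window (1 s at 10 Hz); 1 = per-frame decisions |
| `min_run` | 2 | px | contiguous mask pixels for a row to count as jet |
| `rematch_every` | 0 | frames | 0 = match the nozzle once per sequence |

The pixel scale has no default deliberately: the distance rule is physical
(µm), and silently assuming a magnification would corrupt it. The ROI is
sized generously relative to the breakup length so a single setting serves
many nozzle types without user input.

**Choosing C.** The offset C is a noise margin: a pixel is jet only if it
sits more than C counts below its local mean. C = 7 is the published
operating point for low-noise 16-bit sensor data and is kept as the default.
On the 16-bit scale, however, C should track the background noise: with
additive noise of standard deviation σ_n, pixel-minus-local-mean fluctuates
with standard deviation close to σ_n, so a useful margin is a small z-score,
and the package's benchmarks use C = 3·σ_n when σ_n is large. The jet's
contrast (tens of thousands of counts) dwarfs any plausible margin, so
detection is insensitive to C over a wide range; only the noise floor-
induced false-positive rate depends on it.

## The synthetic scene generator

`render_scene()` draws, in order: a uniform bright background with an
optional linear illumination ramp; the nozzle silhouette (pixel-identical to
`default_nozzle_template()`, so noiseless matching is exact by
construction); the jet column, tilted by a small angle, solid up to the
breakup length and a 4-on/5-off droplet train beyond it; for hits, a
full-width gap whose half-open band spans exactly `break_gap_px` rows;
optional splatter speckle scattered laterally around the break; and additive
Gaussian noise, clamped and rounded to the 16-bit range. All randomness
flows from the scene seed, and `generate_sequence()` derives per-frame seeds
from one sequence seed, so sequences are reproducible and label counts under
`hit_fraction` are exact by stratified assignment rather than binomial
sampling.

Default geometry (chosen once as a plausible GDVN viewing condition, since
the source imagery's optical scale is not published): 480 × 320 px at
1 µm/px, tip at (70, 160), jet 4 px wide, breakup at 300 µm, interaction
point 100 µm below the tip with a 10 px gap, background ≈ 52000 counts, jet
≈ 12000 counts. Benchmarks perturb jet angle (sd 0.8°) and lateral position
(sd 1.5 px) frame to frame, and use noise at 2–3 % of full scale.

What the generator does **not** emulate: real explosion morphology (it cuts
a clean band instead of a turbulent plume), partial hits at the jet edge,
jet instability and curvature, defocus, fixed-pattern sensor noise, and
nozzle-to-nozzle shape variation. Splatter is a phenomenological speckle
with no calibrated size or density, and it defaults to off so that noiseless
benchmarks are deterministic; a dedicated test checks that enabling it does
not erase the break. Passing synthetic benchmarks therefore demonstrates the
algorithm's correctness and noise robustness under the stated model, not its
accuracy on any particular instrument's data — on real data the adaptive
threshold and the two break bounds are the knobs that need site calibration.

## Numerical and algorithmic choices

* **Correlation variant.** "Cross-correlation coefficient" is implemented
  as zero-normalized cross-correlation: it is the variant that delivers the
  illumination invariance the rest of the pipeline assumes. It is computed
  with an FFT for the numerator and summed-area tables for per-window means
  and variances, which is exact up to floating-point error and is verified
  against a per-window `cor()` oracle in the tests. Scores are clamped to
  [−1, 1]; windows with numerically zero variance score 0; ties break at
  the smallest row, then the smallest column.
* **Matching frequency.** The nozzle is matched once per sequence and the
  ROI reused (`rematch_every = 0`), since nozzle and background are static
  over a run; periodic re-matching is available and verified to give
  identical verdicts on steady scenes.
* **Coordinates.** All user-facing coordinates are 1-based (row, col) with
  closed boxes, the R convention; the ROI spans the tip column ± the
  half-width inclusive. Distances measure from the tip row: row *r* of the
  ROI lies (r − 1)·`pixel_size_um` µm downstream.
* **Border handling.** The local mean uses symmetric reflection padding;
  zero padding would darken borders and fabricate edge breaks.
* **Gaussian σ.** Not published; the conventional imaging-toolkit mapping
  from window size (σ ≈ 2.3 at W = 13) is used and exposed in the config.
* **Break semantics.** "Simultaneous discontinuity on both sides of the
  jet" is implemented as rows with no qualifying jet run at all — with a
  row-presence profile, both edges broken is equivalent to the row band
  being empty. The distance rule applies to the gap's upstream edge (the
  conservative reading). `min_run = 2` stops single salt pixels from
  counting as jet presence. A frame with no jet rows anywhere is a miss
  flagged `no_jet`, never a hit: an absent or unstable jet is not evidence
  of beam overlap, and the flag routes those frames to the operator.
* **Window warm-up.** Before the FIFO fills, decisions OR over the partial
  window, preserving "any hit ⇒ hit" from frame one. Sliding windows are
  the default; a tumbling mode (disjoint 1 s blocks) is available since the
  per-second phrasing of instances admits either reading.
* **Degenerate Dice.** When neither truth nor prediction contains a hit,
  2TP + FP + FN = 0; the coefficient is defined as 1 (perfect agreement)
  with a warning. Quartiles in run summaries use linear interpolation
  between order statistics (R's default type 7).
* **Evaluation granularity.** Predictions are scored at instance level;
  frame-level ground truth is lifted to instances with the same windowed-OR
  rule the classifier uses, so both sides of the comparison live on the
  same footing.

## Benchmark problem sizes

The package's own benchmarks use 400-frame sequences at 50 % hits for the
end-to-end checks (noiseless, and with 3 % full-scale noise plus jitter,
scored overall and per 100-frame run), a 100-frame noisy beam-off sequence
with breakup beyond 200 µm, 50 localization trials at 2 % noise, 100 random
64 × 64 images for the thresholding oracle, the full 2^10 truth table for
the FIFO window, and 1000 random profiles for the break-rule enumeration.
These sizes give stable statistics while keeping the whole suite fast on a
single CPU.

## Known limitations

* Partial hits (beam clipping the jet edge) and unstable-jet episodes are
  not sub-classified; the former surface as misses, the latter are partly
  absorbed by the `no_jet` flag and the distance rule.
* The classifier emits decisions only; driving motor feedback from them is
  out of scope.
* Jet diameter, speed and breakup length are not measured.
* Throughput is logged per run as information, not asserted: real-time
  behaviour depends on hardware.
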