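---
title: "Inferring facial paralysis from mouse facial videography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring facial paralysis from mouse facial videography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fapa)
```

## The problem and the approach

Experimental facial paralysis in the mouse — irreversible after facial-nerve
transection, reversible over roughly two weeks after a crush injury — is
classically scored by eye from whisker motion. `fapa` implements an automated
alternative built from two measurement channels and one decision layer:

1. **Whisker kinematics.** A paint-marked whisker is segmented per frame by
   color distance, cleaned, and reduced to the angle of the mask centroid
   about the whiskerpad insertion point. The per-session angle trace is
   rebased so its minimum is 0°; protraction increases the angle. From the
   trace we extract a movement-onset changepoint, minimum-to-minimum
   movement cycles with amplitudes and areas, long/short amplitude classes,
   and a short-time Fourier spectrogram.
2. **Facial motion.** Frames of the lateral face are aligned to a baseline
   video through four anatomical landmarks, cropped into anterior (A),
   middle (M) and posterior (P) zones, and described per frame by a
   histogram of oriented gradients (HOG: 8 unsigned orientation bins, 32-px
   cells, one cell per block, square-root gamma compression). Each frame's
   descriptor is reduced to the scalar
   `Diff(x) = ||HOG(frame 1) − HOG(frame x)||`; the session mean of `Diff`
   is the movement summary a session contributes.
3. **Decision layer.** Per-zone movement thresholds turn summaries into
   binary "low movement" flags; ten fixed models combine the flags by OR or
   AND across zones, at group, group-normalized, or individual threshold
   scope. The recommended model is model 2: anterior AND middle low. A
   per-frame variant of the same rule yields a movement/no-movement call per
   frame; a session is declared paralyzed when strictly more than 90% of its
   frames are still.

Two further analyses reuse the HOG machinery: **expression prototypes**
(the mean descriptor of 250 resting frames; an emotional prototype is the
mean of the 10 stimulation frames least correlated with it) with per-frame
Pearson-similarity traces, and **electrophysiology correlates** (100-ms
PSTHs z-scored against a 10-s pre-event baseline, and normalized
cross-covariance between binned firing and behavioral traces).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| HOG orientations / cell / block | 8 / 32 px / 1 | published descriptor configuration |
| gamma compression exponent | 0.5 | "power compression law" with no printed exponent; square-root is the standard HOG choice |
| Diff reduction | L2 norm | the published subtraction yields a vector while every downstream formula is scalar; the Euclidean norm is symmetric and zero iff descriptors are identical (L1 selectable) |
| group threshold | mean + sample sd | printed rule; the printed sd formula lacks the squared deviations and is treated as a typo for the sample standard deviation (n − 1) |
| two-session threshold | (baseline + 24 h post-injury)/2 | the minimal published design |
| session normalization | per-mouse min–max | the "N" in the normalized models; z-score selectable |
| low flag / verdict ties | strictly below; strictly > 90% | ties resolve toward *not* declaring paralysis |
| mask cleanup radius | 5 px | the published cleanup margin |
| cycle prominence filter | ¼ of trace range | see below |
| changepoint penalty | 5 × trace variance | mean-shift SSE cost; a constant trace returns a no-change sentinel |
| spectrogram | 0.5-s Hann, 50% overlap, per-window demean | resolves the 0–5 Hz post-injury band; without demeaning the DC offset of a rebased trace dominates the lowest bins |
| prototype sizes | 250 basal frames, k = 10 | published counts; the basal window is the 250 frames immediately preceding the first stimulus (unstated in the source; earliest-index tie-break in the bottom-k selection) |
| PSTH | 100-ms bins, 10-s baseline | published; the −2..2 range is display clipping only, never applied before analysis |

## Design choices where the design was open

* **Transform family.** Four landmarks admit an affine fit, but a
  similarity transform (rotation, translation, uniform scale) is the
  default: the head-fixed face is nearly rigid and similarity cannot
  introduce shear. Affine is available via `method = "affine"`. One
  transform is fitted per session; per-frame landmark lists are accepted.
* **AND-sum models.** The printed "+" models carry no cutoff; they are read
  as *all* used zones low, the only reading under which the anterior+middle
  sum model differs from its OR counterpart and is the most specific model.
* **d′ operand order.** The printed formula subtracts the z of the hit from
  the z of the false alarm, which would make a good detector negative; the
  conventional `z(hit) − z(FA)` is implemented, with 1/(2N) correction of
  extreme rates.
* **Mask cleanup.** Rather than a morphological opening (which erodes a
  legitimately small marker blob away entirely at radius 5), cleanup keeps
  the largest connected component plus any marker pixels within 5 px of it
  — the literal "within a range of 5 pixels around" rule.
* **Cycle prominence.** Minimum-to-minimum cycle detection on a measured
  angle trace is exquisitely sensitive to tracking jitter: near the flat
  extremes of a sweep, sub-degree noise manufactures spurious local minima
  and floods the cycle list with near-zero amplitudes. Minima whose
  topographic prominence is below one quarter of the trace's range are
  therefore discarded by default (`min_prominence = 0` restores the literal
  every-minimum behavior). An endpoint strictly below its neighbor counts
  as a minimum, so a single minimum-to-minimum arc forms one cycle.
* **Cycle frequency.** "Each movement cycle was considered 1 Hz" is read as
  frequency = cycles per second computed from cycle durations, consistent
  with the spectrogram analyses.
* **Threshold anchoring.** The two-session threshold is only meaningful
  when its "paralyzed" session is genuinely still. For an uninjured (sham)
  mouse no such session exists; `infer_timeline(..., anchor = )` therefore
  accepts a reference timeline (e.g. a transection mouse) from which the
  thresholds are built, mirroring the published practice of deriving
  thresholds from the transection group.

## What the synthetic generator emulates — and what it does not

`render_face_video()` builds a face as three vertical texture bands (A | M |
P) of band-limited noise; each band translates rigidly per frame along a
smooth, bounded, seeded random path scaled by that zone's motion
multiplier. `simulate_timeline()` chains 23 such sessions (baseline; 0.5,
6, 24 h; days 2–20) under three injury schedules: transection (A and M
frozen from the first post-injury session, permanently), crush (frozen
until the recovery session — default session 15, i.e. day 12 — then ramping
0.6/0.8/1.0 back to baseline over three sessions), and sham (never frozen).
The posterior zone keeps moving in every schedule, as the ear does in vivo.
Whisker traces are raised sinusoids plus 0.1° Gaussian jitter (the
sub-degree precision of a sub-pixel centroid at a high-contrast marker);
spike trains are 1-ms-thinned inhomogeneous Poisson processes whose rate
follows the motion trace at a programmable lag.

The generator captures zone-separable motion energy, injury time courses,
and motion-locked firing. It does **not** capture elastic tissue
deformation, illumination changes, occlusion, camera shake, whisker
crossings, or any taste physiology — "stimulation" is a timestamp plus a
programmed zone displacement. A green test therefore establishes that the
pipeline's algebra and decision logic are correct and self-consistent on
controllable input, not that the thresholds transfer to any particular rig.
Default sessions in the timeline tests run 2 s rather than the full 2 min
for runtime; the 2-min/3,600-frame accounting is checked explicitly in the
acceptance suite.

## Numerical notes, degenerate inputs, limitations

* Zero-gradient HOG cells stay zero instead of becoming NaN (ε = 1e-12
  guard); cell histograms are otherwise unit-L2.
* `Diff(1)` is exactly 0 by construction; min–max normalization refuses
  all-equal session sets rather than dividing by zero.
* Empty marker masks are legal in segmentation, warn in cleanup, error in
  angle extraction; traces interpolate up to 5 consecutive missing frames
  and refuse sessions with more than 50% missing.
* Changepoint detection returns `NA` (with zero improvement) when no split
  clears the penalty — a motionless trace, not an error.
* A session verdict at exactly 90% stillness is *not* paralyzed; a zone
  summary exactly at threshold is *not* low.
* The cross-covariance sign convention is: positive lag means the first
  series leads the second.
* Compressed video (MP4/AVI) is not decoded in this build — no video codec
  is available to the package's dependency set — so sessions are exchanged
  as directories of ASCII PGM frames (`extract_frames()`, `write_frames()`)
  or as in-memory arrays.
* Known limitations: single-whisker, marker-based tracking only; one
  transform per session assumes the head stays fixed; the prominence
  default can suppress genuinely tiny cycles that co-occur with large ones
  in the same trace.
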