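---
title: "Two-stage chromaticity thresholding: model, parameters and design notes"
author: "ChromaThresh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage chromaticity thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChromaThresh)
```

## The problem and the model

Many inspection tasks — locating small components on a circuit board,
delineating a skin lesion — begin by suppressing a chromatically
near-uniform background. Intensity-based thresholds (Otsu-style methods)
are brittle here because illumination varies across and between images while
the background *color* does not. ChromaThresh therefore works entirely in the
chromaticity channels of HSV space: hue `H` (half-degree bins, 0–179) and
saturation `S` (0–255). The value plane `V` is carried along but never
consulted, which makes both output masks exactly invariant to uniform
illumination rescaling; the test suite asserts this byte-for-byte.

The model is that background pixels occupy one *continuous* band in the hue
histogram and one continuous band in the saturation histogram of the
hue-matched pixels, while foreground objects contribute small, well-separated
histogram populations. Segmentation then reduces to finding those two bands
automatically:

1. **Smoothing.** The channel histogram is normalized to a PMF and smoothed
   with a boundary-truncated moving average (window `windowSize`, default 5).
   Smoothing the histogram rather than the image keeps the cost independent
   of image resolution.
2. **Nomination.** Scanning bins in ascending order (bins already nominated
   are not re-used as anchors), the window centered at a bin is nominated
   wholesale when either its mean smoothed PMF (`avgArea`) or its mean
   arctan absolute forward difference (`avgGradient`) reaches its cutoff.
   Both comparisons are inclusive (`>=`). The area criterion captures mass;
   the gradient criterion captures the shoulders of a mode, so a background
   band is nominated together with its flanks. At the top histogram boundary
   the final forward difference does not exist and is omitted, with the
   divisor shrunk accordingly.
3. **Maximum continuous range.** Nominated bins are grouped into runs in
   which consecutive bins differ by at most a continuity limit; the run with
   the most members wins, ties going to the run with the smallest low bin.
   For hue the selection must contain the peak bin of the smoothed hue PMF:
   the largest run is extracted repeatedly, discarding peak-free runs, until
   the peak's run emerges. For saturation there is no peak constraint — the
   background saturation band need not contain the histogram maximum.
   The selected run's `[min, max]` become the background range.
4. **Global threshold.** A pixel is background iff its hue *and* saturation
   both fall inside their ranges (inclusive); background is written 0,
   foreground 255.
5. **Local refinement.** Foreground blobs (8-connected components) are
   detected in the global mask; blobs whose bounding-box area (height ×
   width) reaches `minBlobArea` (500 px) are re-thresholded: the crop's hue
   histogram is rebuilt from pixels whose hue lies within the global range
   widened by `c1`, the saturation histogram from local-hue-matched pixels
   within the global saturation range widened by `c2`, and both are reduced
   by the same nominate/select machinery (both with limit `limit2`, and
   without a peak constraint — the local stage has no analogue of the global
   peak loop). The refined patches are pasted onto an all-background canvas,
   so everything outside a relevant bounding box is background by
   construction. This removes shadows (background whose chromaticity drifted
   out of the global ranges but stays within the `c1`/`c2` confinement) and
   sub-floor specks, at the cost of dropping any true object whose bounding
   box is smaller than the floor.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoffGradient` | 0.001 | PMF slope | nomination gradient cutoff |
| `cutoffArea` | 1/180 ≈ 0.0056 | PMF mass | nomination area cutoff (hue) |
| `cutoffAreaSat` | 1/180 | PMF mass | area cutoff for the 256-bin saturation PMF |
| `windowSize` | 5 | bins | smoothing / nomination window |
| `limit1` | 2 (pca) / 4 (skin) | bins | hue run continuity |
| `limit2` | 4 | bins | saturation (and all local) run continuity |
| `c1` | 6 (pca) / 12 (skin) | hue bins | local hue confinement slack |
| `c2` | 12 | sat levels | local saturation confinement slack |
| `minBlobArea` | 500 | px | bounding-box floor for local refinement |

The two presets encode settings suited to board-like images (`"pca"`: tight
hue continuity, small hue slack, for near-uniform manufactured backgrounds)
and lesion-like images (`"skin"`: looser continuity and slack, for organic
backgrounds with broader chromatic spread). `limit1`/`limit2` absorb small
discontinuities in the background band; `c1`/`c2` set how far a local
region's background may drift from the global ranges (shadows, shading)
before the local stage stops treating it as background.

`cutoffAreaSat` deserves a note: the area cutoff is defined as one over the
hue histogram length, and it is not restated for the 256-bin saturation
histogram. We reuse the same numeric value (1/180) for saturation, so the
saturation criterion is slightly *stricter* relative to a uniform PMF
(uniform mass is 1/256 < 1/180); `cutoffAreaSat` is exposed as its own knob
for users who prefer 1/256.

## Numerical conventions

* **RGB→HSV.** `grDevices::rgb2hsv` with hue mapped to `round(deg/2)` in
  0–179 (round half-up; 180 wraps to 0), S and V scaled to 0–255. At zero
  saturation hue is undefined and set to 0 — such pixels are classified by
  the saturation test anyway. Different HSV implementations can disagree by
  ±1 bin at bin edges; the nominated ranges are several bins wider than the
  underlying modes, so classification is insensitive to this.
* **Ties.** The smoothed-PMF argmax breaks ties toward the smallest bin
  (a constant-hue image yields a 5-bin plateau whose left edge is reported
  as the peak); run-size ties break toward the run with the smallest low bin.
* **Inclusive comparisons everywhere**: nomination cutoffs, run gaps
  (`<= limit`), range membership, and the blob floor (`>= 500`).
* **Degenerate inputs.** An empty hue shortlist or an empty nominated set is
  an error in the global stage — a pre-processing tool should surface
  pathological inputs rather than guess. In the local stage the same
  conditions trigger a per-blob fallback: the blob is re-thresholded with
  the *global* ranges and a warning is emitted. The fallback is
  whole-blob (both channels), which preserves stage-1 behavior for crops
  that consist entirely of foreground (their confined histograms are empty).
* **Blob geometry.** 8-connectivity; bounding boxes are 1-based inclusive
  row/column indices; relevance is bounding-box area, not pixel count.
  Overlapping bounding boxes are processed in label order and overwrite
  (last writer wins).

## The synthetic generator

`makeFixture()` assembles images in HSV space — background hue/saturation
sampled uniformly from stated bands, rectangular or disc components
overwriting their footprints, an optional shadow region shifting hue and
saturation, per-channel Gaussian noise (default sd 1.5 bins/levels, rounded
and clipped) — and converts to RGB for storage, returning both the RGB array
and the exact pre-conversion planes plus a ground-truth mask that is exact by
construction. All randomness flows from one seed; identical spec + seed gives
identical bytes. Canvases default to 256×256, which keeps the full suite and
the test run inside a minute on one CPU while leaving component and blob
sizes comfortably astride the 500 px floor.

`makeFixtureSuite()` fixes six named conditions: a clean board (background
hue band 72–93, saturation 137–255, six 36×36 components at hues 25 and 123
— the histogram geography of the green-board worked example, multimodal hue
PMF); a shadow board (narrow hue band 78–88 with a shadow region shifted by
+10 hue bins / −10 saturation levels: outside the derived global ranges but
inside the `c1 = 6`/`c2 = 12` confinement, so stage 2 recovers it); a speck
board (4×4 extra components whose bounding boxes stay far below the floor);
a lesion-like disc on a skin-toned background (bimodal); a near-gray
low-saturation image (unimodal, hue pinned at 0 per the undefined-hue
convention); and a red background straddling the 0/179 hue wrap.

What the generator does *not* emulate: texture, specular highlights, chromatic
aberration, JPEG artefacts, gradual multi-axis illumination fields, or
foreground objects sharing the background hue. Passing on these fixtures
shows the machinery implements the intended selection semantics and recovers
its own generative model; it does not certify performance on real
dermoscopy or board photographs, whose background bands are wider and whose
noise is not Gaussian.

## Known limitations

* **Hue wrap.** Hue is treated linearly, so a red background that straddles
  the 0/179 wrap is split into two distant runs and only the peak's side is
  selected; the `redWrap` fixture documents the resulting over-segmentation.
* **Chromatic foregrounds matching the background** are classified as
  background by construction — the method separates by chromaticity only.
* **Near-gray images through the RGB route.** At very low saturation, hue is
  numerically unstable under 8-bit quantization (a handful of coarse hue
  values appear), so the RGB path can fragment the hue PMF of an almost-gray
  image; the HSV-plane route behaves as intended. Images whose *background*
  is nearly achromatic are best thresholded on saturation alone, which this
  method does implicitly only when the fragmented hue run still covers the
  background hues.
* **True objects smaller than `minBlobArea`** disappear from the stage-2
  mask; use the global mask when tiny objects matter.
* **Exact-cutoff flicker.** A background band whose uniform mass sits exactly
  at `cutoffArea` (e.g. a perfectly uniform 180-bin hue histogram) is
  nominated only up to sampling fluctuation; real backgrounds concentrate
  mass well above the cutoff.

## Problem sizes used by the tests

The unit and acceptance suites run on 256×256 fixtures and 10–30 px
oracle rasters, with 50-replicate randomized equivalence checks per
primitive; the whole suite completes in well under a minute on one CPU.
These sizes were chosen because every qualitative behavior the fixtures
probe (range recovery, shadow recovery, speck suppression) is
scale-free: the histograms depend on pixel *proportions*, not counts, and
500-px blobs exist comfortably at this scale.
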