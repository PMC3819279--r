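---
title: "Edge-directed upscaling with tedi: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-directed upscaling with tedi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Single-image upscaling is an ill-posed inverse problem: many
high-resolution (HR) images are consistent with one low-resolution (LR)
observation. Generic linear interpolators resolve the ambiguity by
smoothness, which blurs exactly the structures a radiologist relies on —
edges. Covariance-adaptive interpolators (NEDI and its descendants)
resolve it by assuming local covariance is scale-invariant, which
preserves edges but lets estimation errors propagate into whirl-like
textures and ringing.

`tedi` takes a conservative middle path built on three assumptions:

1. **Edges detected in the LR input are trustworthy** ("true" edges):
   any edge present at low resolution reflects real anatomy, and should
   appear sharpened in the HR result.
2. **Edges detected only in the pre-interpolated HR image are suspect**
   ("pseudo" edges): they were manufactured by the interpolator and
   should be suppressed.
3. **Everything else is best left alone**: pixels with no edge evidence
   keep their bilinear value bit-exactly, so the method cannot damage
   smooth regions and its worst case degrades gracefully to bilinear.

Orientation handling is deliberately coarse. Each edge pixel's gradient
angle (mod 180°) is quantized into four 45° bins (RH, LV, RV, LH), and
each bin gets one fixed 5×5 blending mask with three non-zero taps:
`ratio` at the center, `√ratio` at the two offsets that run along the
bin's edge tangent, normalized to sum 1. Four directions are a modelling
choice, not a limitation of the code: finer direction estimates (as in
NEDI) buy adaptivity at the price of noise sensitivity, and for low-field
MR material four bins were judged enough.

## Tunable parameters

| parameter | default | units | meaning / why this value |
|---|---|---|---|
| `factor` | 2 | — | integer magnification; 2 for quantitative work, 4 for visual inspection (single-shot with one refinement pass; set `iterate=TRUE` for repeated ×2) |
| `canny_threshold` | 0.1 | normalized gradient | hysteresis high threshold on the `[0,1]`-normalized gradient magnitude |
| `low_ratio` | 0.4 | — | hysteresis low:high ratio (the detector's single published threshold is read as the high one) |
| `sigma` | 1.0 | px | Gaussian scale of the derivative-of-Gaussian gradient |
| `ratio` | 4.0 | — | center emphasis of the sharpening mask; the mean-SNR-vs-ratio curve produced by `calibrate_ratio()` rises quickly to ratio ≈ 4 and is nearly flat beyond (gains < 0.1 dB), so 4 is the knee |
| `true_edge_tolerance` | 1 | px (Chebyshev) | matching radius between HR-detected edges and projected LR edges; a factor-2 projection displaces edges by ≤ 1 px |
| NEDI `window` | 4 | LR px | classic 16-equation / 4-tap training window |
| NEDI `variance_floor` | 8/255² | intensity² | windows flatter than this use the bilinear fallback |
| NEDI `regularization` | 1e−6 | — | diagonal loading of the normal equations |
| MI `bins` | 256 | — | equal-width histogram bins on `[0,1]` |

## Grid alignment

Integer-factor resampling is corner-anchored: LR pixel `(i, j)` maps to
HR pixel `(k i, k j)`, which gives every LR edge pixel an exact HR
address for projection. Two consequences are worth knowing. First, at
×2 the even-even HR lattice consists of *exact copies* of LR samples, so
the pre-interpolation error lives entirely on the odd lattice. Second,
the HR grid has no source samples beyond the last LR row/column; reads
there are edge-clamped (and the NEDI implementation pads each doubling
with one linearly-extrapolated ring so that planar intensity is
reproduced exactly at borders too). Fractional factors use center-aligned
continuous coordinates; bit-compatibility with MATLAB's `imresize`
(anti-aliased, center-aligned) is explicitly not attempted.

## Two design decisions that were genuinely open

**Which angle convention do the orientation bins use?** The published
LV mask offsets `(−1,−2)/(+1,+2)` run along an LV edge tangent only if
the gradient angle is measured in the standard mathematical orientation
(y axis up). Measured with rows increasing downward — the other common
image convention — the same offsets are 45–90° off the tangent, and
sharpening demonstrably *blurs* (we verified this empirically before
fixing the convention). `tedi` therefore bins the y-up gradient angle;
non-maximum suppression uses its own internally consistent rows-down
geometry, which is unaffected by the mod-180 sign flip.

**What exactly is the "true" edge set on the HR grid?** The projected LR
pixels alone are a degenerate choice under corner anchoring: they are
exact bilinear copies, so sharpening only them cannot repair any
interpolation error (and measurably lowers PSNR on every test corpus).
`tedi` instead treats as true the projected pixels *plus* the HR-detected
edge pixels within the matching tolerance of a projection — the HR
realization of the LR edge — with orientation labels inherited from the
nearest projected pixel. HR detections with no LR support remain pseudo.
This is the reading under which the method is non-vacuous, and it is the
one all tests encode.

## Refinement semantics

Both operators use parallel (gather) semantics: softening and sharpening
read from the unmodified pseudo HR image and write to a fresh output, so
results are independent of scan order and bit-reproducible. The true and
pseudo sets are disjoint by construction. Convolution-like reads use
replicate (edge-clamp) padding everywhere, avoiding dark halos at
borders; outputs are clipped to `[0, 1]`.

## The synthetic phantoms, and what a green test does not establish

The clinical images the benchmark protocol was designed around are
confidential, so all tests run on seeded phantoms: oriented step edges
(1-px anti-aliased boundary so the detector has a localizable maximum),
disks, rings, gratings, checkerboards, smooth blob fields, and a
stylized "spine band" (a bright curved band fading bright-to-dark on a
dark background, echoing cervical-spine geometry). The default benchmark
corpus is 12 phantoms of 360 × 320 — the image count and region-of-
interest size of the original clinical set — with additive Gaussian
noise of sd 0.02, chosen once as a plausible noise floor for low-field
MR magnitude images. The phantoms emulate edge geometry and mild noise;
they do **not** emulate MR-specific physics (Rician noise statistics,
motion and partial-volume artifacts, bias fields, k-space truncation).
A green benchmark therefore establishes correct mechanics and sane
relative behaviour of the interpolators on edge-rich material, not
clinical performance, and the absolute metric values here are not
comparable to any published clinical table (whose SNR formula, in
addition, is not recoverable).

The degradation protocol is a 50% nearest-neighbour downscale keeping
the top-left sample of each 2 × 2 block (the source convention is
unstated; this one is fixed and documented). At ×4 the protocol is
visual: a same-size reference does not exist, and the benchmark scores
against a bilinear ×2 enlargement of the original as a stylized
reference — quantitative conclusions should use ×2.

## Numerical choices

* **SNR** is the standard signal-power/error-power ratio in dB
  (`10·log10(Σref² / Σ(ref−test)²)`); identical pairs report an infinite
  sentinel, serialized as `"inf"` in CSV and excluded from mean ± sd
  aggregation.
* **SSIM** uses the canonical construction — 11 × 11 Gaussian window
  (σ = 1.5), `K1 = 0.01`, `K2 = 0.03`, dynamic range 1 — with the 5-px
  border excluded from the mean so padding plays no role; it agrees with
  scikit-image's `structural_similarity(gaussian_weights=True, sigma=1.5,
  use_sample_covariance=False)` to ~1e−10 on test pairs.
* **Mutual information** uses 256 equal-width bins and base-2 logs.
  Finite-sample bias ≈ `(bins−1)²/(2 n ln 2)` is non-negligible at this
  binning (~0.7 bits for a 256 × 256 image), so "independent images give
  MI ≈ 0" holds only at coarser binnings; tests assert the bias-aware
  bounds.
* **NEDI** declines the trained predictor when the training window is
  flat (variance floor) or its normal matrix is rank-deficient — the
  singularity threshold is tied to the diagonal loading
  (`pivot < max(1e−8·scale, 10·reg)`), since otherwise ridge loading
  masks degeneracy and planar ramps come back with ~1e−4 error instead
  of exactly. The fallback (4-neighbour average) is exact on planes and
  constants; the fallback fraction is reported as an attribute.
* **Canny** normalizes gradient magnitude by its maximum before
  thresholding, so thresholds are scale-free; a constant image has no
  maximum and returns an empty edge map directly.
* Non-maximum suppression breaks plateau ties asymmetrically
  (`≥` on one side, `>` on the other) so ridges stay one pixel wide.

## Known limitations

* **Bin-boundary orientations.** At step orientations whose gradient
  angle falls exactly on a bin boundary (0°, 45°, 90°, 135°) the single
  offset pair per 45° bin is maximally (≥ 18°) off the true tangent, and
  its cross-edge component slightly perturbs the projected copy pixels.
  Measured on 256 × 256 oriented-step phantoms, TEDI narrows the 10–90%
  transition at mid-bin angles (2.6 → 2.3 px at 30°/60°) but widens it
  by one 0.1-px measurement quantum at 0°/45°/90°. The corresponding
  acceptance property is left failing on purpose rather than weakened:
  it is an honest consequence of the 4-bin × 3-tap design.
* **CEM is approximate.** It is reconstructed from a two-sentence
  description, flagged experimental, and excluded from acceptance gates.
* **2-D only.** No volumes, no DICOM/NIfTI; convert upstream.
* TEDI's PSNR advantage over bilinear is modest on this phantom corpus
  (the acceptance bar is ≥, met at 30.62 vs 30.60 dB over the default
  12-phantom corpus as computed by `scripts/acceptance.R`); its design
  goal is edge fidelity at bilinear-level cost, not broadband MSE gains.
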