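# tedi — true edge-directed interpolation for grayscale medical images

`tedi` upscales low-resolution (LR) 2-D grayscale images — the motivating
case is low-field fetal spine MRI, where acquisition constraints leave
clinically important edge structure blurred — while explicitly preserving
detected edges. Generic interpolators (bilinear, bicubic) smooth across
edges; covariance-based edge-directed methods such as NEDI preserve them
but propagate estimation errors into whirl and ringing artifacts. TEDI
("true" edge-directed interpolation) takes a third route: interpolate
cheaply first, then repair the result only where edge evidence says so.

## Method

1. **Pre-interpolation.** The LR image is upscaled by an integer factor
   `k` (default 2) with bilinear interpolation → the *pseudo HR* image.
   Integer factors are corner-anchored: LR pixel `(i, j)` sits at HR pixel
   `(k i, k j)`.
2. **Edge evidence.** A Canny detector (Gaussian σ = 1, derivative-of-
   Gaussian gradients, non-maximum suppression, hysteresis with high
   threshold 0.1 on the normalized gradient scale, low = 0.4·high) runs on
   both the LR input and the pseudo HR image. Each edge pixel's gradient
   angle θ (mod 180°, y axis up) is quantized into four orientation bins:

   | bin | angle | name |
   |-----|-------|------|
   | RH | [0°, 45°) | right-horizontal |
   | LV | [45°, 90°) | left-vertical |
   | RV | [90°, 135°) | right-vertical |
   | LH | [135°, 180°) | left-horizontal |

   The four classes are pairwise disjoint and their union is exactly the
   edge map (`EM = RH ∪ LV ∪ RV ∪ LH`).
3. **True vs pseudo edges.** LR edges are projected onto the HR lattice.
   HR-detected edges within Chebyshev distance 1 of a projection join the
   projected pixels as *true* edges (structure that exists in the input);
   HR edges with no LR support are *pseudo* edges (artifacts of the
   pre-interpolation).
4. **Refinement.** Pseudo-edge pixels are softened by the mean of their 8
   neighbours. True-edge pixels are sharpened with an orientation-specific
   5×5 blending mask with three non-zero taps: weight `ratio` at the
   center and `√ratio` at the two along-edge offsets (LV: `(−1,−2)` /
   `(+1,+2)`; the other bins are its symmetry images). `ratio = 4` — i.e.
   normalized weights `{0.5, 0.25, 0.25}` — is the plateau of the mean-SNR
   sweep reproduced by `calibrate_ratio()`. Both operators read from the
   unmodified pseudo HR image; every other pixel keeps its bilinear value
   exactly.

The package also provides the NEDI baseline (4-tap covariance-trained
predictors with geometric duality, ×2ⁿ factors, bilinear fallback on
smooth/degenerate windows), an approximate CEM baseline, the metric suite
(SNR, PSNR, SSIM, mutual information, wall-clock TC), a seeded phantom
generator standing in for the confidential clinical images, and a
degrade-then-interpolate benchmark harness.

## Worked example

```r
library(tedi)
ref <- make_phantom(phantom_spec("ring", c(360, 320), noise_sigma = 0.02, seed = 2020))
lr  <- degrade(ref)                        # 50% nearest-neighbour, 180 x 160
hr  <- tedi_interpolate(lr, tedi_config(factor = 2))
print(hr)
#> <gray_image 360 x 320, 8-bit source, range [0.114, 0.877]>
attr(hr, "n_true"); attr(hr, "n_pseudo")
#> [1] 1632      # pixels sharpened (edge structure confirmed in the LR input)
#> [1] 415       # pixels softened (edges only the pre-interpolation created)

rbind(evaluate_pair(ref, hr, "tedi", "ring"),
      evaluate_pair(ref, resample(lr, 2, "bilinear"), "bilinear", "ring"))
#>     method image_id snr_db psnr_db   ssim mi_bits tc_seconds
#> 1     tedi     ring  24.12   31.58 0.7480   1.379         NA
#> 2 bilinear     ring  23.79   31.25 0.7469   1.389         NA

print(detect_edges(lr, threshold = 0.1))
#> <edge_detection 180 x 160: 587 edge pixels (RH 147, LV 146, RV 150, LH 144)>
```

TEDI recovers ~0.3 dB PSNR over plain bilinear on this ring phantom by
sharpening the 1 632 confirmed edge pixels and suppressing the 415
spurious ones; the remaining 113 153 pixels are bit-identical to bilinear.

## Command line

```sh
inst/cli/tedi interp    --input lr.png --output hr.png --method tedi --factor 2
inst/cli/tedi phantom   --out-dir corpus/ --n 12 --height 360 --width 320 --seed 2013
inst/cli/tedi benchmark --out report.csv --methods bilinear,nedi,tedi --n 12 --seed 2013
```

`benchmark` degrades every corpus image to 50% (nearest-neighbour
replication), re-interpolates with each method, scores against the
original, and writes per-image rows plus a `mean ± sd` aggregate CSV.

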