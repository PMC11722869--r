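# edgethresh

Ground-truth-driven threshold selection for classical edge detectors on
noisy images.

Classical edge detectors — Sobel, Prewitt, Roberts, Laplacian-of-Gaussian
(LoG) and Canny — all hinge on a threshold that separates true boundaries
from noise response, and the right value shifts with the image, its detail
content, and the kind and strength of noise corrupting it. In medical
imaging (retinal vessels, brain tumor boundaries, lung CT), where reference
segmentations with known boundaries exist, the threshold can instead be
*searched*: detect at many candidate thresholds, score each detection
against the ground-truth edge map with an objective measure, and keep the
best. `edgethresh` implements that approach end to end for researchers
studying detector robustness under noise:

* the five classical detectors, each driven by a normalized threshold in
  (0, 1) (a `(low, high)` hysteresis pair for Canny);
* noise simulators for Gaussian, salt-and-pepper, speckle and Rician
  (magnitude-MRI) noise with seeded reproducibility;
* objective edge-quality measures — precision/recall/F1, Pratt's figure of
  merit, and a bounded performance ratio;
* spatial-information (SI) statistics and low/medium/high-detail (LD/MD/HD)
  complexity classification;
* a candidate-threshold dataset (by default 1800 stored values: 300 per
  single-threshold operator and 300 Canny pairs) searched exhaustively
  (grid search, GS) or by best-of-k seeded subsampling (random search,
  RS3/RS6/RS9);
* seeded synthetic phantoms with exact 1-pixel ground-truth boundaries, and
  a pipeline crossing corpus × noise × detector × selection method.

## The measures

With `tp` detected pixels matched to ground truth, `fp` spurious and `fn`
missed (exact-pixel or within a Euclidean tolerance *t*):

* **F** = 2·P·R / (P + R), with P = tp/(tp+fp), R = tp/(tp+fn);
* **FoM** (Pratt) = 1/max(N_I, N_D) · Σ_i 1/(1 + α d_i²), where d_i is the
  distance from detected pixel *i* to the nearest true edge pixel and
  α = 1/9;
* **PR** = tp/(tp + fp + fn), a bounded single-number ratio.

The search methods maximize one of these per image; GS scans every
candidate, RS-k takes the best of k candidates drawn without replacement,
so GS is an upper bound for every RS draw.

## Worked example

Generate a medium-complexity phantom, corrupt it with 5% salt-and-pepper
noise, and compare the automatic (Otsu) Canny baseline with grid and random
threshold search:

```r
library(edgethresh)

ph    <- make_phantom("MD", c(96, 96), seed = 42)
noisy <- apply_noise(ph$image, noise_spec("salt_pepper", 0.05, seed = 1))

std <- standard_detect(noisy, "canny")
evaluate_edges(std, ph$gt, tolerance = 1)
#> <eval_result> P 0.674  R 0.954  F 0.790  FoM 0.837  PR 0.653  (tp 578 fp 279 fn 28)

grid_search(noisy, ph$gt, "canny")
#> <search_result> canny via GS (k = 100): low 0.1941 high 0.4851, f = 0.8742

random_search(noisy, ph$gt, "canny", k = 9, seed = 2)
#> <search_result> canny via RS (k = 9): low 0.1267 high 0.3168, f = 0.7902
```

The automatic Canny threshold under-thresholds the noisy image (precision
0.674); scanning the 100-pair candidate dataset lifts F from 0.790 to
0.874, and even 9 random candidates recover F 0.790 at a fraction of the
cost. Complexity classification works the same way on image statistics:

```r
b <- calibrate_boundaries(make_corpus(4, c(96, 96), seed = 3))
round(b, 4)
#>     b1     b2
#> 0.2166 0.4922
classify_complexity(spatial_information(ph$image), b)
#> <complexity_class> MD (boundaries 0.2166 / 0.4922)
```

A command-line front end over the same functions is installed at
`inst/cli/edgethresh.R` (`add-noise`, `detect`, `evaluate`, `complexity`,
`simulate`, `generate-thresholds`, `optimize`, `run-experiment`).

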