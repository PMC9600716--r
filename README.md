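# demarcate

Unsupervised demarcation-line candidates for magnifying endoscopy images.

## What it is for

In magnifying narrow-band imaging (M-NBI) of the stomach, the
*demarcation line* (DL) is the boundary between an early cancerous lesion
and the surrounding background mucosa. It determines the horizontal extent
of an endoscopic resection, and drawing it reliably is hard for
inexperienced endoscopists. `demarcate` proposes DL **candidates** on a
single still image using nothing but the image itself — no annotations, no
trained model — and leaves the final choice to the viewing endoscopist.

The pipeline:

1. **SLIC superpixels** on Gaussian-smoothed CIE L\*a\*b\* planes
   (defaults: 100 segments, compactness 5, sigma 5 per plane);
2. a **12-dimensional feature vector** per superpixel: the mean of the six
   color planes L\*, a\*, b\*, H, S, V plus the local Shannon entropy of
   each plane,

   $$H(S) = -\sum_{l=0}^{L-1} \frac{n_l}{T}\,\log_2 \frac{n_l}{T},$$

   with the entropy (over L = 256 levels on fixed canonical ranges)
   quantifying the irregularity of microvascular / microsurface texture;
3. **k-means** over the superpixel features (k-means++ seeding, up to 300
   iterations, best of 10 seeded trials by minimum inertia);
4. **cluster boundaries** — every pixel with a 4-neighbor in a different
   cluster — extracted as the DL candidate, swept over k = 2…6.

Candidates can be scored against an expert-drawn DL with the
nearest-pixel Euclidean distance (mean over reference pixels of the
distance to the nearest candidate pixel) after resampling both to a common
564 × 515 frame. A seeded synthetic-image generator produces two-region,
endoscopy-like images with exact ground truth, so the whole pipeline is
testable without clinical data.

## Worked example

```r
library(demarcate)

spec   <- random_synthetic_spec(seed = 1)   # two-region endoscopy-like image
sample <- generate_sample(spec)             # image + ground-truth boundary

cfg   <- pipeline_config(seed = 1)          # study defaults, seeded
sweep <- run_pipeline(sample, cfg, out_dir = "out")
print(sweep)
#> candidate_sweep over k = 2, 3, 4, 5, 6
#>   k = 2 : 710 boundary pixels
#>   k = 3 : 1221 boundary pixels
#>   k = 4 : 1232 boundary pixels
#>   k = 5 : 1544 boundary pixels
#>   k = 6 : 1560 boundary pixels

sapply(sweep, function(b) dl_distance(sample$boundary, b))
#>    k2    k3    k4    k5    k6
#> 1.338 1.130 1.106 1.106 1.065
```

The distances are mean nearest-pixel errors in pixels against the planted
boundary: on this high-contrast 256 × 256 sample the k = 2 candidate
already traces the region interface to within ~1.3 px, and more clusters
refine it slightly while adding extra (harmless, since the metric is
directional) internal boundaries. `out/` receives one overlay PNG,
boundary CSV, cluster label map and model JSON per k, and a
`manifest.json` that makes the run reproducible bit for bit.

With `random_synthetic_spec(seed, vignette = TRUE)` the generator adds the
endoscope's dark corners and radial illumination falloff; k = 2 then locks
onto the field-of-view/corner interface (errors around 80 px) and lesion
recovery needs k ≥ 4 — the same mechanism that makes shaded clinical
frames demand more clusters.

A thin command-line front end is included:

```sh
Rscript inst/cli/demarcate.R synth --seed 1 --out samples
Rscript inst/cli/demarcate.R run --image samples/sample_seed1.png --out out
Rscript inst/cli/demarcate.R eval --reference expert_mask.png --candidates out --out eval
```

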