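# TexConcord

Does an MRI texture feature still mean the same thing when the scan is
repeated with a different acquisition matrix? With the field of view fixed,
the matrix size (256×256 … 512×512 at FOV 200 mm) trades spatial resolution
against per-voxel signal: small matrices blur fine tissue structure, large
matrices drown it in noise. Radiomic features computed from such images
inherit that trade-off, and a feature that does not agree with itself across
reasonable matrix choices is not a usable tissue descriptor.

TexConcord is an R package for radiologists, medical physicists and
radiomics researchers that quantifies this agreement end to end:

* a **synthetic multi-tissue phantom** (trabecular "bone", lobular "fat",
  smooth striped "muscle") whose acquisition at any matrix size is simulated
  by centered **k-space truncation** of a 512×512 reference plus
  matrix-dependent Gaussian noise (noise sd ∝ (m/512)², since SNR scales
  with voxel area) — a paired design in which every matrix size of a slice
  derives from the same reference;
* **ROI handling**: proportional mask scaling across matrices, ±3σ intensity
  normalization `N(x,y) = round(255·(I−(μ−3σ))/(6σ))` with clipping, and
  min–max gray-level quantization (default 64 levels);
* the classical **2D texture-feature set of 307 features** in 8 families —
  GLCM (220: 11 Haralick statistics × 4 directions × distances 1–5),
  run-length (20), gradient (5), causal autoregressive (5), Haar wavelet
  energies (16), histogram (9), Gabor (24), HOG (8) — plus a 794-feature 3D
  subset (GLCM/RLM over the 13 offsets of the 26-neighborhood, 3D gradient,
  histogram);
* **Lin's concordance correlation coefficient** per feature between every
  pair of matrix sizes across subjects,

  ρc = 2·cov(x,y) / (σx² + σy² + (μx − μy)²),

  aggregated per family and overall into transition reports (neighboring
  one-step transitions and all 10 pairs), stratified by tissue and
  normalization;
* **SNR and sharpness comparators** (within-ROI or background SNR; mean
  per-mm Sobel gradient amplitude) that expose the two opposing trends the
  concordance curves are read against.

## Worked example

A reduced run (4 subjects, matrices 128/192/256 from a 256 reference, 2
slices) finishes in under a minute:

```r
library(TexConcord)
cfg <- runConfig(nSubjects = 4L, matrixSizes = c(128L, 192L, 256L),
                 masterSeed = 42L, nSlices = 2L, noiseScale = 4,
                 referenceMatrix = 256L)
run <- runPipeline(cfg)

tt <- transitionTable(run$transitions[["2D.raw.bone"]]$neighboring)
tt[tt$family %in% c("ALL", "GLCM", "HIST"), c(4:8)]
#>       pair family  mean_ccc n_defined n_excluded
#>    128-192    ALL  0.038623       306          1
#>    128-192   GLCM  0.005930       220          0
#>    128-192   HIST  0.322029         9          0
#>    192-256    ALL  0.054708       306          1
#>    192-256   GLCM -0.000503       220          0
#>    192-256   HIST  0.470195         9          0

qualityTable(run$quality)[qualityTable(run$quality)$tissue == "bone", ]
#>   matrix_size tissue snr_mean sharpness_mean  estimator n
#>           128   bone    5.251          9.456 within_roi 8
#>           192   bone    3.166         25.977 within_roi 8
#>           256   bone    2.581         49.420 within_roi 8
```

Each `mean_ccc` row is the average Lin's coefficient over the defined
features of that family for one matrix-size transition: here the first-order
histogram features agree far better across matrices (0.32–0.47) than the
co-occurrence features (~0), which at this reduced scale are dominated by
acquisition noise — the feature-fragility phenomenon the package measures.
`n_excluded` counts features whose coefficient is undefined (zero variance
on both sides). The quality report shows the two opposing physical trends:
within-ROI SNR falls (5.3 → 2.6) and per-mm sharpness rises (9.5 → 49.4) as
the matrix grows.

At the full study scale — `runPipeline(runConfig(masterSeed = 1))`, i.e. 20
subjects, 5 matrices, 5 slices, raw + normalized ROIs — the mid-range
transitions (384↔448) show the highest average concordance for the
structured tissues, the extreme transitions (256↔320, 448↔512) the lowest,
and ±3σ normalization pulls the three tissue curves together.

`writePhantomSeries()` / `readImageStack()` round-trip a series through
16-bit TIFF images, PNG masks and a JSON manifest; real acquisitions
exported to the same layout are analyzed identically (`inputMode = "real"`).
A thin CLI over these functions is in `inst/scripts/texconcord.R`.

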