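# mitosted

Simulation and analysis of dual-channel STED/confocal images of
mitochondria, for microscopists and image analysts who want a fully
synthetic, seed-reproducible test bed for quantitative claims about
mitochondrial ultrastructure: inner-membrane (IM) cristae imaged at STED
resolution alongside mtDNA nucleoids imaged at confocal resolution.

The package implements, end to end:

* **STED physics.** Dye depletion follows `F(I) = F0 / (1 + I/Is)`, so the
  saturation power `Is` is the depletion power at which fluorescence halves,
  and the effective PSF obeys `d_eff = d0 / sqrt(1 + I_dep/Is)`. Saturation
  power is estimated from simulated on/off depletion series
  (`simulate_depletion_series()`, `fit_saturation_power()`), and resolution
  from image pairs by Fourier ring correlation (1/7 threshold;
  `estimate_frc_resolution()`) or Gaussian line-profile FWHM
  (`measure_fwhm_profile()`).
* **Synthetic specimens.** Tubular mitochondrial networks 200–700 nm in
  diameter with transverse cristae spaced 70 nm apart, and nucleoids placed
  by a landmark model — branch/tip occupancy 0.677, exponential
  nearest-distance law with rate `-log(0.35)/0.6 ≈ 1.75 µm⁻¹`
  (`generate_network()`, `sample_nucleoids()`, `render_density()`).
* **Segmentation.** A deterministic Hessian ridge filter (or a
  random-forest pixel classifier over the same filter bank), morphological
  closing into labelled mitochondria, and nucleoid detection with per-blob
  half-maximum area refinement (`segment_cristae()`,
  `segment_mitochondria()`, `detect_nucleoids()`).
* **Morphometry.** Guo–Hall skeletons with tip/branch-point landmarks,
  geodesic length, cristae counts, and the three-class rule — Class I:
  length < 2.5 µm **and** < 6 cristae; Class III: length > 5 µm **or**
  > 12 cristae; Class II otherwise (`skeletonize_component()`,
  `classify_mitochondrion()`).
* **Spatial statistics.** Landmark-to-nucleoid nearest distances,
  below-cutoff fractions (strict `< 0.6 µm`), exponential MLE with
  bootstrap CI and KS goodness of fit, per-mitochondrion
  mtDNA/mitochondrion area ratios, and Mann–Whitney group comparisons
  (`nearest_distances()`, `fit_exponential()`, `area_ratios()`,
  `compare_groups()`).

`run_pipeline()` chains simulate → acquire → segment → morphometry →
stats with a single seed and writes CSV/TIFF/JSON outputs plus a run
manifest; `exec/mitograph` is a thin command-line front end.

## Worked example

```r
library(mitosted)

## STED physics: enhancement at the printed operating point
resolution_enhancement(I_dep = 34.7, Is = 0.864)
#> [1] 6.415765

## recover a saturation power from a noisy depletion series
s <- simulate_depletion_series(Is = 0.864, noise = 0.02, seed = 7)
fit_saturation_power(s)$Is_mW
#> [1] 0.8029955

## a synthetic field through the whole pipeline
cfg <- pipeline_config(scene = scene_params(n_components = 3,
                                            field_um = c(8, 8)),
                       seed = 9)
res <- run_pipeline(cfg, out_dir = "out")
res$records[, c("label", "length_um", "n_cristae", "class")]
#>   label length_um n_cristae class
#> 1     1  9.302691       120   III
#> 2     2  2.787645        16   III
#> 3     3 11.778814       107   III
res$report$landmark_stats$tip$fraction_below
#> [1] 0.4705882
```

The first number is the fold resolution gain `sqrt(1 + I_dep/Is)` for a
34.7 mW depletion beam and a 0.864 mW dye: ~6.4×, i.e. a 250 nm confocal
PSF sharpened to ~39 nm. The saturation fit recovers the true 0.864 mW
from a single 2%-noise series to within ~7%; averaging over replicate
series (as `scripts/acceptance.R` does) brings the median within a
fraction of a percent. The pipeline records give each
segmented mitochondrion's skeleton length, cristae count and morphology
class (here three long, cristae-dense Class III networks — at the default
70 nm spacing a multi-micron tubule carries many tens of cristae), and the
report's tip statistic is the fraction of skeleton tips with a detected
nucleoid closer than 0.6 µm — on a field this small and crowded the
per-run value scatters widely around the generator's landmark model; the
distance-law tests use the larger, sparser fields described in the
vignette.

## Conventions

Scene coordinates are continuous micrometres with the origin at a field
corner; images are numeric matrices indexed `[x, y]` whose pixel centres
sit at `(i - 0.5) * pixel_size`. All lengths carry their unit in the
argument name (`*_nm`, `*_um`). Every stochastic function takes a `seed`
and is bit-reproducible.
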