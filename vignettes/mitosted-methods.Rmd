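---
title: "Models and methods behind mitosted"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitosted}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosted)
```

mitosted simulates and analyses dual-channel super-resolution images of
mitochondria: an inner-membrane (IM) channel acquired at STED resolution
and an mtDNA channel acquired at confocal resolution. This vignette is the
package's own account of the models it implements, the parameters that
matter, and the choices made where the design was genuinely open.

## The depletion model

A STED microscope sharpens its effective point-spread function by
depleting fluorescence everywhere except the very centre of the excitation
spot. The package models dye response to depletion power $I$ with

$$F(I) = \frac{F_0}{1 + I/I_s},$$

where $I_s$ (mW) is the *saturation power*: by construction
$F(I_s) = F_0/2$, which is the operational definition used when the
quantity is measured (the depletion power at which fluorescence falls to
50%). This hyperbolic law is the unique simple choice consistent with the
standard resolution scaling

$$d_\mathrm{eff} = \frac{d_0}{\sqrt{1 + I_\mathrm{dep}/I_s}},$$

implemented in `effective_fwhm()`. An exponential depletion law would not
reproduce that square-root dependence, which is why it was rejected. With
$d_0 = 250$ nm (the confocal default), $I_s = 0.864$ mW and
$I_\mathrm{dep} = 34.7$ mW the enhancement factor is
`r round(sqrt(1 + 34.7/0.864), 2)`-fold, i.e. a ~39 nm effective FWHM.

`simulate_depletion_series()` reproduces the bench protocol for measuring
$I_s$: one power series with excitation on, one with excitation off. The
excitation-off series captures *secondary excitation* — fluorescence
excited by the depletion beam itself — modelled as a component linear in
depletion power that appears identically in both series.
`fit_saturation_power()` subtracts the off series, clips negatives,
normalizes by the zero-power point and least-squares fits $1/(1 + I/I_s)$;
if the model fit fails it falls back to the monotone interpolation
crossing of 0.5. A series whose normalized curve never reaches 0.5 is an
error ("does not reach saturation"), not a number.

## Image formation

`simulate_acquisition()` convolves a continuous fluorophore-density map
with an isotropic Gaussian PSF at the effective FWHM, scales the result so
the brightest pixel equals the photon budget, then applies Poisson shot
noise, a constant background and Gaussian read noise (clipped at zero).
The donut geometry of the depletion beam is not modelled explicitly; its
entire effect is carried by the effective-FWHM law, which is what the
downstream estimators can observe. Defaults — 150 photons at the brightest
pixel, background 2, read noise 1 count — are typical of low-power
live-cell STED, where photon budgets are deliberately small.

Energy is conserved: without noise, the integrated signal equals the
integrated density times the photon-budget scale factor (the PSF kernel
has unit mass and convolution is circular).

## Resolution estimation

**Fourier ring correlation** (`estimate_frc_resolution()`) takes two
frames of the same scene with independent noise, apodizes with a Tukey
window ($\alpha = 0.25$), correlates the Fourier transforms per
one-pixel-wide frequency ring, smooths the curve with a 3-ring moving
average and reports the inverse of the first frequency where it drops
below $1/7$. These constants follow common FRC practice; the measurement
protocol behind the published curves does not state them. Two degenerate
cases are flagged rather than numbered: identical frames (FRC ≡ 1; only
the Nyquist bound $2\,\mathrm{px}$ can be stated) and uncorrelated noise
(no resolution exists; `NA` with `no_signal = TRUE`).

**Line-profile FWHM** (`measure_fwhm_profile()`) samples a
bilinear-interpolated profile between two points and fits a Gaussian plus
constant offset, reporting $2\sqrt{2\ln 2}\,\sigma$. Two accuracy details
matter at STED scales: axis-aligned profiles are snapped to pixel centres,
because interpolating between centres convolves the profile with a
triangle kernel and widens a 44 nm peak by several nanometres; and a
`width_um` argument averages parallel profiles along the structure, which
suppresses shot noise without biasing the width. A profile over flat
background is an error, not a fit.

## The synthetic scene generator

No raw image data are distributed with the study this package models, so
the generator is the package's test bed. It emulates:

* tubular mitochondria 200–700 nm in diameter, grown as curvature-capped
  random walks with side branches grafted at a Poisson rate along the
  trunk; different components keep a minimum envelope separation and a
  tubule avoids its own earlier path (a self-crossing tubule would not be
  resolvable as a single organelle in 2D);
* transverse cristae at 70 nm spacing, perpendicular to the local
  centreline, spanning the tubule interior but keeping a fixed 90 nm gap
  to the boundary membrane so that a 40 nm PSF cannot bridge the junction
  (in 200 nm tubules cristae remain unresolvable from the membrane — a
  genuine physical limit, not a generator defect);
* mtDNA nucleoids as disks, placed by a landmark model: every tip and
  branch point independently carries a nucleoid with probability 0.677;
  each unoccupied landmark receives one whose nearest distance follows an
  exponential law with rate $\lambda = -\ln(0.35)/0.6 = 1.7497\ \mu m^{-1}$
  (equivalently, 65.0% of nearest distances below 0.6 µm); additional
  nucleoids are scattered along the tubules at 0.5 µm⁻¹.

"Length" of a mitochondrion means the full organelle extent — centreline
plus the rounded cap at every free tip. That is the quantity a manual
trace of an organelle yields, and it is used consistently in the truth
labels and in the skeleton measurement.

When a target mtDNA/mitochondrion area ratio is requested (the control
default is 0.291), the nucleoid radius is solved against the *rasterized
union* of the disks, because nucleoids that crowd near landmarks overlap
and cover less area than $\sum \pi r^2$.

What the generator does **not** emulate: 3D structure, cristae remodeling
dynamics, nucleoid clusters, motion, or the texture of real cytoplasmic
background. Passing tests therefore demonstrate that the estimators
recover known truth under this idealized geometry and Poisson noise —
they do not certify performance on real micrographs.

## Segmentation

The deterministic default (`method = "ridge-threshold"`) computes a
scale-normalized Hessian ridge response (most-negative eigenvalue,
maximized over 30 and 50 nm scales), normalizes to $[0,1]$, and thresholds
strictly above 0.3. The default scales bracket the width of a crista
imaged at 40 nm resolution; when cristae sit at their native 70 nm
spacing they blur into the tubule body, and the scale bank must then also
include a tubule-width scale (~200 nm) for the mask to cover the
structure — the standard multiscale reasoning for tubular-structure
filters. Raising the threshold can only shrink the mask (monotonicity is
property-tested). A random-forest pixel classifier over
the same filter bank (Gaussian smooth, gradient magnitude, both Hessian
eigenvalues per scale) is available as `method = "pixel-classifier"`,
filling the same contract as an interactively trained classification tool:
probability image in, threshold out. It requires labels or a fitted model;
the tests train it on synthetic truth.

Whole mitochondria are obtained from the cristae/membrane mask by
morphological closing (disk radius 70 nm — the cristae spacing), hole
filling and 8-connected labelling; components smaller than 0.05 µm² are
discarded as specks. Nucleoids are detected in the confocal channel by
Gaussian smoothing (σ 60 nm), block-median background subtraction (2 µm
window, larger than any nucleoid), Otsu thresholding and connected
components; each blob's area is refined at its own half-maximum, which
approximately undoes the confocal blur for area measurement (a blurred
disk's half-max contour sits close to the true disk edge). Merged blobs
can optionally be split by a distance-map watershed.

Because segmentation quality cannot meaningfully be scored below the
diffraction limit, mask accuracy is evaluated against the *resolution
footprint* of the truth: the geometric support dilated by half the PSF
FWHM. Dice against this footprint is ≥ 0.8 across seeds in the property
suite.

## Morphometry

Skeletons come from Guo–Hall thinning (compiled in `src/`), which
preserves topology and yields 8-connected, single-pixel-wide centrelines.
Geodesic length counts orthogonal steps as 1 and diagonal steps as
$\sqrt 2$ pixels, skipping diagonals that shortcut an existing 4-path.
Thinning retracts from rounded tubule ends by roughly one radius, so each
tip adds the distance from the tip to the component boundary along the
outward skeleton direction (`extend_tips = TRUE`); without this the
module's own 5% length-recovery requirement is unattainable for thick
tubules. Tips are degree-1 skeleton pixels; branch points are pixels with
≥ 3 skeleton neighbours, merged within a 3-pixel radius. Network length is
total skeleton length, not longest path: whole networks are treated as
single mitochondria.

Cristae are counted as connected components of the cristae mask whose
centroid lies in the mitochondrion label, after excluding boundary
membrane: ring-like components (filled area > 1.25 × area) and components
longer than 1.2 µm. Merged adjacent cristae undercount by design; the
tests quantify this against generator truth (±1 at the spacings used).

The three-class rule is evaluated Class III first (length > 5 µm **or**
count > 12), then Class II (length ≥ 2.5 µm **or** count ≥ 6), else
Class I. The "or" clauses of the printed rule overlap — a 1 µm
mitochondrion with 13 cristae is claimed by both the Class II and
Class III wordings — and III-first precedence preserves the reading that
many-cristae organelles are the large class. Ties at 2.5 µm and 6 cristae
fall to Class II, exactly as the closed interval "2.5–5 µm" reads. The
partition is property-tested over a boundary-inclusive grid.

Areas are pixel counts × (pixel size)² in µm². The labelled region extends
to the outer edge of the segmented membrane band while the organelle
boundary is the band midline, so areas are counted after eroding the
region by a fixed 25 nm half-band (membrane half-thickness plus filter
spread).

## Spatial statistics

Nearest distances are 2D Euclidean minima from each landmark (tip, branch
point, or an externally supplied site such as a manually annotated fusion
event) to nucleoid *centroids* — centroids rather than boundaries because
at confocal resolution the boundary is an artefact of the threshold while
the centroid is stable. The below-cutoff fraction uses a strict
inequality at the default 0.6 µm cutoff, matching how the published
fractions are stated. The exponential rate is the maximum-likelihood
estimator $\hat\lambda = 1/\bar d$ with a seeded percentile bootstrap
(1000 resamples) and a one-sample Kolmogorov–Smirnov check. Group
comparisons default to a two-sided Mann–Whitney U (exact for ≤ 20
observations per group and no ties), with Kolmogorov–Smirnov available via
configuration; the test behind the original "no significant change"
statement is not named anywhere, so this default is a documented package
choice. Identical constant samples return $p = 1$ with a degenerate flag.

One subtlety the tests respect: the exponential law is defined per
landmark, but the *measured* nearest distance can be claimed by a
neighbouring landmark's nucleoid. On dense branched networks this
contaminates the law upward. Scenes built to verify the distance law
therefore use long, unbranched, well-separated tubules, where each
landmark's nearest nucleoid is its own draw.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and is bit-reproducible
(`withr::with_seed`; no global RNG state leaks). The test suite uses
problem sizes chosen to give each estimate a standard error comfortably
inside its tolerance: 100 replicate depletion series per dye; a 10.24 µm
field for FRC; ~360 tips across six fields for the distance fraction; 300
mitochondria per condition (rendered in batches of 60) for the class
mixtures; six 12 µm fields for the area ratio; 10⁴ draws for rate
recovery. The full pipeline on a 10 × 10 µm field at 20 nm pixels runs in
roughly half a minute on one core.

## Known limitations

* Everything is 2D; projections of 3D networks are not modelled.
* The depletion-only subtraction is linear; real secondary excitation may
  saturate.
* Cristae in sub-300 nm tubules cannot be counted by component analysis
  at 40 nm resolution (they merge with the membrane), so class mixtures
  rendered for end-to-end tests draw diameters from 300–500 nm.
* The pixel classifier is trained per-image on synthetic truth; no
  pretrained model for real data is shipped.
* Fusion/fission events are not detected; their coordinates are inputs.
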