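---
title: "Digital PET/CT phantoms and NEMA-style image-quality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital PET/CT phantoms and NEMA-style image-quality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petctiq)
```

## What the package models

Image-quality phantoms are fillable objects scanned to characterize a
PET/CT system: hollow spheres of graded size played against a uniform
radioactive background probe contrast recovery and lesion detectability, a
low-density "lung" cylinder probes attenuation/scatter correction, and
low-contrast CT inserts probe the scanner's ability to resolve a few
Hounsfield units above water. `petctiq` implements digital twins of two
such phantoms and the full analysis protocol around them:

* the **NEMA IEC body phantom** — six spheres (10, 13, 17, 22, 28, 37 mm;
  the two largest cold, the rest hot), a 50 mm lung insert, torso-shaped
  body;
* the **NIM PET/CT phantom** — the same PET geometry extended with 4 mm
  and 7 mm micro-lesion spheres, plus a bolt-on CT module (150 mm
  diameter, 20 mm thick) holding three low-contrast inserts of 0.5, 1.0
  and 1.5 % (5, 10, 15 HU above the water-equivalent background).

Default fills follow the standard acquisition: background
6.6 kBq/mL, hot spheres 26.4 kBq/mL, so the true sphere-to-background
ratio is R = 4; PET scan time 8 min; CT at 512 x 512, 2 mm pixels.

## Metrics

For each hot sphere *j*, percent contrast recovery is

$$Q_{H,j} = \frac{C_{H,j}/C_{B,j} - 1}{R - 1} \times 100\%$$

and for cold spheres $Q_{C,j} = (1 - C_{C,j}/C_{B,j}) \times 100\%$,
where $C_{H,j}$, $C_{C,j}$ are sphere-ROI means and $C_{B,j}$ is the mean
of the background ROI means at the matching ROI size. Percent background
variability is the coefficient of variation of the background ROI means,
$N_j = SD_{B,j}/C_{B,j} \times 100\%$, with the sample (n−1) standard
deviation taken **across the 60 background ROI means**, not within-ROI
voxels — the NEMA convention; the alternative reading of "SD of the
activity concentration in the background ROI" as a within-ROI voxel SD
would measure texture, not ROI-to-ROI reproducibility, and is not what
phantom reports tabulate. The lung residual error per slice is
$\Delta C_{lung,i} = C_{lung,i}/C_{B,37mm} \times 100\%$ against the mean
of all 60 37-mm background means; the scalar summary is the unweighted
mean over the five analysis slices (the reference reports print a single
number without stating the aggregation; an unweighted mean is the
neutral choice).

On the CT side, each insert is compared with its three surrounding
background ROIs: mean ΔCT = mean of (insert − background_i), and
CNR = (CT_I − CT_B)/SD_B. With three backgrounds two conventions exist;
this package computes **one CNR per background and averages**
(`convention = "per_background"`), because only that convention
reproduces the published reference values 2.47 / 4.69 / 7.25 at two
decimals — dividing the mean contrast by an RMS-pooled SD does not. The
discriminating test is part of the suite. Uniformity is the maximum
absolute HU difference between four peripheral ROIs and the centre ROI;
absolute values are used because the purified-water mode has peripherals
below the centre value.

## ROI protocol

Twelve 37 mm background ROIs per slice are placed on the five slices
nearest 0, ±10 and ±20 mm from the sphere plane (ties broken toward the
head end) — 60 ROIs — with concentric smaller ROIs of every other sphere
size at the same centres (including 4 and 7 mm for the NIM phantom).
Placement enforces the margin rule strictly: every ROI edge at least
15 mm from the phantom boundary and from every sphere surface, the lung
insert avoided, and the twelve ROIs pairwise non-overlapping. Because the
reference images show the layout only pictorially, positions are found by
a deterministic farthest-point packing over a 2 mm candidate grid; the
default torso (300 x 230 mm rounded rectangle, corner radius 77 mm) fits
exactly twelve conformant ROIs, and the same phantom always yields the
same layout. ROI statistics use the voxel-centre-in-circle rule with no
partial weighting; since every metric is a ratio of ROI means, partial
voxel weighting would change results negligibly at 2-3 mm pixels.

Sphere centres sit on the standard 57.2 mm NEMA circle at equal angular
spacing; the 7 mm sphere is anchored at the 10-o'clock angle, where it is
seen in the phantom's reference images. The sphere ROI diameter equals
the sphere inner diameter; the lung ROI is 30 mm.

A hot sphere is reported *not detected* when its measured contrast does
not exceed twice the background variability at its size
(`detect_factor = 2`). The criterion is an artifact convention — scanner
reports state the fact of non-detection without one — and is
configurable; undetected spheres keep their raw measurement in
`measured_contrast` and show `NA` contrast, mirroring the dashes in
published tables.

## The simulators and what they do (and do not) emulate

**PET.** The acquisition model is a 2D parallel-beam, slice-wise system:
a pixel-driven discrete Radon transform with linear radial interpolation
(sinogram values are line integrals in activity·mm), scaled so total
expected counts per slice equal `sensitivity x activity x time`, then
independent Poisson draws, then OSEM — the standard multiplicative
ordered-subset EM update, with the same sparse matrix (and its exact
transpose) used for forward and backprojection. The PSF variants model
resolution as an isotropic image-space Gaussian inside the forward and
backward operators (a documented simplification of detector-space
resolution modelling); the symmetric zero-padded kernel is self-adjoint,
so the update remains a true EM step. Time-of-flight is modelled as the
classical variance-reduction gain `2D/(c Δt)` (c = 0.3 mm/ps, floored at
1) applied to the expected count level before the noise draw. This
reproduces the *noise and contrast trends* of TOF reconstruction — the
suite verifies that the gain lowers measured background variability over
a dozen seeds — but is explicitly not a TOF-binned reconstruction.
Defaults: 2 iterations (the clinical protocol), 8 subsets (subset counts
are rarely published; 8 divides every angle set used here), 4.5 mm PSF.
The printed reconstruction voxel "2.44 x 3.66 x 2.44 mm" has an odd
middle value; the simulator reads it as 2.44 mm square in-plane pixels
with 3.66 mm slices, since a slice-wise model needs square pixels and
this is the one physically plausible assignment.

Attenuation and scatter are not transported. The lung-insert residual
error is exercised by injecting a configurable fraction of the background
activity (default 8 %) into the lung region of the activity map before
projection or blurring — enough to give the residual-error metric a
non-trivial target of the right magnitude, with no claim about any real
scanner's correction accuracy.

An **ideal mode** bypasses reconstruction: rasterized activity, Gaussian
blur, stationary Gaussian noise. It exists because most metric properties
(scale invariance, monotonicity of contrast in sphere size, background
variability falling with ROI size, parameter recovery as blur and noise
vanish) are properties of the *metrics*, testable without paying for
OSEM.

**CT.** The CT module is rasterized in HU (water 0, air −1000, inserts at
+5/10/15, lung at `1000(ρ−1) = −700` for ρ = 0.3) and degraded with
stationary Gaussian noise (default SD 2.1 HU, the centre of the 1.8-2.4
HU band implied by the reference background SDs). All CT metrics are ROI
means and SDs, for which stationary noise is sufficient; correlated
reconstruction-kernel texture, beam hardening and helical artifacts are
out of scope and the boundary between background material and injected
water is modelled as invisible except through noise (the
water-equivalence the phantom is built to demonstrate). The declared
water/background interface sits at 58 mm radius, and the uniformity rings
(background mode at 0.36 x that radius, water mode clear of the rim's
partial-volume band) are placed to keep every ROI off the inserts and the
rim — positions in the reference figures are pictorial, so clearance
drove the defaults; all are configurable.

**Rasterization.** Geometry is described by signed distance functions;
interior and exterior voxels are classified exactly, and only voxels
straddling a surface are refined by supersample³ point sampling (default
4³). Activity is therefore conserved up to the boundary discretization,
and the suite checks that the error shrinks as the supersampling grows.

## Synthetic scale and determinism

Tests and the acceptance script run the simulators at desk scale —
64-128 pixel matrices, 48-96 projection angles, single-slice
reconstructions where a slice suffices — which preserves every property
being asserted (the system model is scale-free) while keeping the whole
suite quick. The clinical-scale defaults (256 matrix, 180 angles, 512 CT
matrix) remain available through the configuration objects. Every
stochastic stage derives from one integer seed; rasterization, ROI
placement and all arithmetic are fully deterministic.

## Reference measurements

The published clinical measurements of the phantom's validation study —
the NIM vs NEMA comparison, three scanners (A/B/C), four reconstruction
algorithms, and the CT low-contrast / boundary / uniformity ROI values —
ship as CSV (`reference_tables()`). They are *inputs*: the comparison
module reproduces their printed deviation figures (2.68 % contrast at
13 mm, 0.32 % background variability, 0.12 % residual error, 5.48 % A-vs-B
at 22 mm, 22.4 % OSEM→OSEM-PSF-TOF at 10 mm) exactly, and the CT metric
functions reproduce 5.18/9.75/15.40 HU and CNR 2.47/4.69/7.25. The real
acquisitions behind them are not reproducible by a desk-scale simulator;
the simulator is held instead to the property suite above.

## Known limitations

* No attenuation, scatter, randoms or detector normalization physics;
  the residual lung error is injected, not emergent.
* TOF is a count-level gain, not a timing-binned reconstruction.
* CT noise is white; kernel-correlated texture would change within-ROI
  SDs (but not ROI-mean statistics) on real scans.
* DICOM I/O is not included; volumes move as NIfTI-1, tables as CSV.
* Sphere walls ("hollow glass") are ignored: geometry is activity-defined.

```{r example, eval = FALSE}
phantom <- build_nim_phantom()
cfg <- recon_config(matrix = 128, pixel_mm = 2.6, slice_mm = 5,
                    psf_fwhm_mm = 8, seed = 1)
vol <- simulate_pet_volume(phantom, cfg = cfg, mode = "ideal",
                           noise_sd = 0.1, seed = 1)
result <- analyze_pet(vol, phantom)
tidy(result)
autoplot(result)
```
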