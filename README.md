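# petctiq

Digital PET/CT image-quality phantoms and NEMA-style analysis in R.

Physicists qualify PET/CT scanners by imaging fillable phantoms: hollow
spheres of graded size against a uniform radioactive background measure
contrast recovery and lesion detectability, a low-density lung insert
measures residual attenuation/scatter-correction error, and low-contrast
CT inserts measure how few Hounsfield units the CT side can resolve.
`petctiq` provides digital twins of two such phantoms — the NEMA IEC body
phantom and the NIM PET/CT phantom, which extends it with 4 mm and 7 mm
micro-lesion spheres and a bolt-on CT module — together with the complete
analysis protocol: voxel rasterization of activity and HU maps, a
desk-scale PET simulator (parallel-beam projection, Poisson counting
noise, OSEM reconstruction with optional Gaussian PSF modelling and a
time-of-flight count-gain approximation), a Gaussian-noise CT simulator,
deterministic NEMA-conformant ROI placement, and the standard metrics.

For hot sphere *j* with background ratio *R*:

```
Q_H,j = (C_H,j / C_B,j − 1) / (R − 1) × 100 %          contrast recovery
Q_C,j = (1 − C_C,j / C_B,j) × 100 %                     cold-sphere contrast
N_j   = SD_B,j / C_B,j × 100 %                          background variability
ΔC_lung,i = C_lung,i / C_B,37mm × 100 %                 lung residual error
CNR   = (CT_I − CT_B) / SD_B                            CT low-contrast CNR
```

where `C_B,j` and `SD_B,j` are the mean and sample SD of the 60
background ROI means at ROI size *j* (12 ROIs × 5 slices), and the CNR of
each insert is averaged over its three background ROIs. The package also
ships the phantom's published validation measurements (two phantoms,
three scanners, four reconstruction algorithms, CT tables) as CSV and
reproduces their comparison arithmetic exactly.

## Worked example

```r
library(petctiq)

phantom <- build_nim_phantom()             # 8 spheres, lung, CT module, R = 4
cfg <- recon_config(matrix = 128, pixel_mm = 2.6, slice_mm = 5,
                    psf_fwhm_mm = 8, seed = 1)
vol <- simulate_pet_volume(phantom, cfg = cfg, mode = "ideal",
                           noise_sd = 0.1, seed = 1)
analyze_pet(vol, phantom)
#> PET image-quality result: nim_petct (R = 4.00)
#> # A tibble: 8 × 6
#>   sphere_size role  contrast measured_contrast background_variability detected
#>         <dbl> <chr>    <dbl>             <dbl>                  <dbl> <lgl>
#> 1          37 cold      84.9              84.9                  0.135 TRUE
#> 2          28 cold      79.0              79.0                  0.158 TRUE
#> 3          22 hot       76.9              76.9                  0.187 TRUE
#> 4          17 hot       68.4              68.4                  0.260 TRUE
#> 5          13 hot       60.1              60.1                  0.313 TRUE
#> 6          10 hot       48.3              48.3                  0.442 TRUE
#> 7           7 hot       31.0              31.0                  0.536 TRUE
#> 8           4 hot       10.8              10.8                  1.23  TRUE
#> Residual lung error: 7.95 %
```

Contrast falls with sphere size — the Gaussian resolution model spills
small spheres into the background — while background variability rises as
the ROI shrinks; the residual lung error recovers the 8 % of background
counts injected into the lung insert to emulate imperfect
attenuation/scatter correction. `tidy()`, `glance()` and `autoplot()`
work on the result; `as_metric_table()` feeds it to the comparison
module:

```r
tabs <- reference_tables()
max_abs_deviation(tabs$phantom_comparison$nim_petct,
                  tabs$phantom_comparison$nema_iec, "contrast")
#> $value
#> [1] 2.68
#> $sphere_size
#> [1] 13
```

— the largest contrast difference between the two phantoms on the same
scanner is 2.68 % at the 13 mm sphere, i.e. adding the micro-lesion
spheres barely perturbs the standard metrics.

The CT side works the same way: `simulate_ct_volume()` then
`analyze_ct()` returns per-insert mean ΔCT and CNR, boundary-noise SDs
and uniformity. A command-line front end (`inst/cli/petctiq`) exposes
`simulate-pet`, `simulate-ct`, `analyze-pet`, `analyze-ct`, `compare` and
`fixtures` subcommands over the same functions.

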