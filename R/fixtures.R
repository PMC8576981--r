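#' Generate a self-contained fixture bundle
#'
#' Writes, under `dir`: rasterized NIM and NEMA IEC activity maps, one
#' simulated PET volume per reconstruction-algorithm variant, one
#' simulated CT volume (all NIfTI-1), CSV copies of the shipped reference
#' measurement tables, and a `checksums.csv` of MD5 digests. All
#' stochastic stages derive from `seed`, so the same seed reproduces the
#' same checksums. `scale = "tiny"` uses coarse desk-scale grids suitable
#' for tests; `"standard"` uses the clinical matrix and voxel defaults.
#'
#' @param seed Integer seed.
#' @param scale `"tiny"` or `"standard"`.
#' @param dir Output directory (created if needed).
#' @return Tibble of written files and their MD5 checksums, invisibly.
#' @export
generate_fixtures <- function(seed = 1L, scale = c("tiny", "standard"),
                              dir = "fixtures") {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  nim <- build_nim_phantom()
  nema <- build_nema_iec_phantom()
  if (scale == "tiny") {
    spacing <- 4; super <- 2
    cfg0 <- list(matrix = 64, pixel_mm = 5.2, slice_mm = 10, iterations = 2,
                 subsets = 8)
    angles <- 48
    ctcfg <- ct_scan_config(matrix = 64, pixel_mm = 2.6, seed = seed)
  } else {
    spacing <- 2; super <- 4
    cfg0 <- list(matrix = 256, pixel_mm = 2.44, slice_mm = 3.66,
                 iterations = 2, subsets = 8)
    angles <- 180
    ctcfg <- ct_scan_config(matrix = 512, pixel_mm = 2, seed = seed)
  }

  write_volume(rasterize_activity(nim, spacing = spacing, supersample = super),
               p("nim_activity.nii"))
  write_volume(rasterize_activity(nema, spacing = spacing, supersample = super),
               p("nema_activity.nii"))
  for (alg in c("OSEM", "OSEM_PSF", "OSEM_TOF", "OSEM_PSF_TOF")) {
    cfg <- do.call(recon_config, c(list(algorithm = alg, seed = seed), cfg0))
    vol <- simulate_pet_volume(nim, acquisition_config(), cfg,
                               slices = 0, angle_count = angles, seed = seed)
    write_volume(vol, p(paste0("nim_pet_", tolower(alg), ".nii")))
  }
  write_volume(simulate_ct_volume(nim, ctcfg), p("nim_ct.nii"))

  src <- c("pet_iq_phantom_comparison.csv", "pet_iq_system_comparison.csv",
           "pet_iq_algorithm_comparison.csv", "pet_iq_residual_errors.csv",
           "ct_low_contrast.csv", "ct_boundary_noise.csv",
           "ct_uniformity.csv")
  for (f in src) {
    file.copy(system.file("extdata", f, package = "petctiq", mustWork = TRUE),
              p(f), overwrite = TRUE)
  }

  files <- sort(setdiff(list.files(dir), "checksums.csv"))
  sums <- tibble(file = files,
                 md5 = vapply(file.path(dir, files), function(f) {
                   as.character(tools::md5sum(f))
                 }, character(1), USE.NAMES = FALSE))
  readr::write_csv(sums, p("checksums.csv"))
  invisible(sums)
}
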