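#' Simulate a reconstructed PET volume of a phantom
#'
#' End-to-end desk-scale acquisition: the phantom is rasterized slice by
#' slice on the reconstruction grid, forward projected
#' ([forward_project()]), scaled to the count level implied by the
#' acquisition settings (times the TOF effective-count gain for the `_TOF`
#' algorithm variants), Poisson noise is drawn ([add_poisson_noise()]), and
#' each slice is reconstructed with [osem_reconstruct()].
#'
#' `mode = "ideal"` is a fast path for metric studies that do not need
#' reconstruction: the rasterized activity is convolved in-plane with a
#' Gaussian of `cfg$psf_fwhm_mm` and stationary Gaussian noise of standard
#' deviation `noise_sd` is added. With `noise_sd = 0` and
#' `psf_fwhm_mm = 0` the ideal path returns the rasterized activity
#' unchanged.
#'
#' Imperfect CT-based attenuation/scatter correction is emulated, not
#' physically simulated: a configurable `residual_fraction` of the
#' background activity is injected into the lung-insert region of the
#' activity map before projection/blurring (default 0.08), so the residual
#' lung error metric has a non-trivial target.
#'
#' @param spec A `phantom_spec`.
#' @param acq An [acquisition_config()].
#' @param cfg A [recon_config()].
#' @param mode `"recon"` (full OSEM path) or `"ideal"`.
#' @param slices Slice-centre z positions in mm (default: slices of
#'   thickness `cfg$slice_mm` covering the central +/- 20 mm analysis
#'   range).
#' @param angle_count Projection angles for the recon path (default 96).
#' @param supersample Rasterization supersampling (default 2).
#' @param residual_fraction Fraction of background activity injected into
#'   the lung insert (default 0.08).
#' @param noise_sd Ideal-mode Gaussian noise SD in kBq/mL (default 5% of
#'   the background activity).
#' @param seed Seed for all stochastic stages (default `cfg$seed`).
#' @return A [voxel_volume()]; unit `"counts"` for the recon path,
#'   `"kBq_per_mL"` for the ideal path.
#' @export
simulate_pet_volume <- function(spec, acq = acquisition_config(),
                                cfg = recon_config(),
                                mode = c("recon", "ideal"),
                                slices = NULL, angle_count = 96,
                                supersample = 2,
                                residual_fraction = 0.08,
                                noise_sd = NULL, seed = cfg$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  mode <- match.arg(mode)
  n <- cfg$matrix
  if (is.null(slices)) {
    k <- ceiling(20 / cfg$slice_mm)
    slices <- (-k:k) * cfg$slice_mm
  }
  slices <- sort(slices)
  dz <- if (length(slices) > 1) min(diff(slices)) else cfg$slice_mm
  extent <- list(
    x = c(-1, 1) * n * cfg$pixel_mm / 2,
    y = c(-1, 1) * n * cfg$pixel_mm / 2,
    z = c(min(slices) - dz / 2, max(slices) + dz / 2)
  )
  act <- rasterize_activity(
    spec, spacing = c(cfg$pixel_mm, cfg$pixel_mm, dz),
    supersample = supersample, extent = extent, allow_partial = TRUE
  )
  if (!is.null(spec$lung) && residual_fraction > 0) {
    xs <- axis_coords(act, 1); ys <- axis_coords(act, 2)
    lung <- outer(xs, ys, function(x, y) {
      sqrt(x^2 + y^2) < spec$lung$diameter / 2
    })
    add <- residual_fraction * spec$background_activity
    for (k in seq_len(dim(act$values)[3])) {
      act$values[, , k] <- act$values[, , k] + add * lung
    }
  }
  nz <- dim(act$values)[3]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (mode == "ideal") {
    if (is.null(noise_sd)) noise_sd <- 0.05 * spec$background_activity
    out <- act$values
    for (k in seq_len(nz)) {
      sl <- blur_gaussian_2d(act$values[, , k], cfg$psf_fwhm_mm, cfg$pixel_mm)
      if (noise_sd > 0) {
        sl <- sl + matrix(rnorm(length(sl), sd = noise_sd), n, n)
      }
      out[, , k] <- sl
    }
    return(voxel_volume(out, act$spacing, act$origin, unit = "kBq_per_mL"))
  }
  gain <- if (uses_tof(cfg)) {
    tof_count_gain(spec$body$half_width + spec$body$half_height,
                   cfg$tof_resolution_ps)
  } else 1
  slice_seeds <- sample.int(.Machine$integer.max - 1L, nz)
  out <- array(0, dim = dim(act$values))
  for (k in seq_len(nz)) {
    sino <- forward_project(act$values[, , k], angle_count = angle_count,
                            pixel_mm = cfg$pixel_mm)
    noisy <- add_poisson_noise(sino, acq, seed = slice_seeds[k],
                               count_gain = gain)
    out[, , k] <- osem_reconstruct(noisy, cfg)
  }
  voxel_volume(out, act$spacing, act$origin, unit = "counts")
}

#' CT scan settings
#'
#' @param noise_sd Stationary Gaussian noise SD in HU (default 2.1, the
#'   centre of the background-SD band observed on the reference scanner).
#' @param slice_thickness_mm Slice thickness, mm (default 2).
#' @param pixel_mm In-plane pixel size, mm (default 2).
#' @param matrix Image matrix (default 512).
#' @param smoothing_fwhm_mm Optional in-plane Gaussian smoothing, mm
#'   (default 0).
#' @param seed Integer seed for the noise draw.
#' @return A `ct_scan_config` object.
#' @export
ct_scan_config <- function(noise_sd = 2.1, slice_thickness_mm = 2,
                           pixel_mm = 2, matrix = 512,
                           smoothing_fwhm_mm = 0, seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(noise_sd = noise_sd, slice_thickness_mm = slice_thickness_mm,
         pixel_mm = pixel_mm, matrix = as.integer(matrix)[1],
         smoothing_fwhm_mm = smoothing_fwhm_mm, seed = as.integer(seed)),
    class = "ct_scan_config"
  )
}

#' Simulate a CT volume of the phantom's CT module
#'
#' Rasterizes the Hounsfield map of the CT module ([rasterize_hu()]),
#' optionally smooths each slice with an in-plane Gaussian, and adds
#' stationary Gaussian noise of SD `cfg$noise_sd`. The noise model is
#' deliberately simple — all the CT metrics are ROI means and SDs — and is
#' documented as a limitation (no reconstruction-kernel texture or noise
#' correlation).
#'
#' @param spec A `phantom_spec` with a CT module.
#' @param cfg A [ct_scan_config()].
#' @return A [voxel_volume()] with unit `"HU"`.
#' @export
simulate_ct_volume <- function(spec, cfg = ct_scan_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$ct_module)) {
    abort("configuration error: phantom has no CT module")
  }
  m <- spec$ct_module
  half_fov <- cfg$matrix * cfg$pixel_mm / 2
  extent <- list(
    x = c(-1, 1) * half_fov, y = c(-1, 1) * half_fov,
    z = m$center_z + c(-1, 1) * m$thickness / 2
  )
  vol <- rasterize_hu(
    spec, spacing = c(cfg$pixel_mm, cfg$pixel_mm, cfg$slice_thickness_mm),
    supersample = 4, extent = extent
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  d <- dim(vol$values)
  for (k in seq_len(d[3])) {
    sl <- vol$values[, , k]
    if (cfg$smoothing_fwhm_mm > 0) {
      sl <- blur_gaussian_2d(sl, cfg$smoothing_fwhm_mm, cfg$pixel_mm)
    }
    if (cfg$noise_sd > 0) {
      sl <- sl + matrix(rnorm(length(sl), sd = cfg$noise_sd), d[1], d[2])
    }
    vol$values[, , k] <- sl
  }
  vol
}
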