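# shared fixtures, built once per test run and memoized

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  hit <- get0(key, envir = .fixture_cache)
  if (is.null(hit)) {
    hit <- fn()
    assign(key, hit, envir = .fixture_cache)
  }
  hit
}

# NIM phantom variant with every sphere hot (for hot-contrast-vs-size
# sweeps across the full 4-37 mm range)
all_hot_nim <- function() {
  sp <- sphere_ring(c(4, 7, 10, 13, 17, 22, 28, 37))
  sp$role <- "hot"
  build_nim_phantom(list(spheres = sp))
}

# ideal-mode simulation grid used by several metric tests
ideal_sim <- function(spec, psf = 8, noise = 0, seed = 7,
                      residual = 0.08, supersample = 3, key = NULL) {
  if (is.null(key)) {
    key <- paste("ideal", spec$name, psf, noise, seed, residual, supersample)
  }
  cached(key, function() {
    cfg <- recon_config(matrix = 128, pixel_mm = 2.6, slice_mm = 5,
                        psf_fwhm_mm = psf, seed = seed)
    simulate_pet_volume(spec, cfg = cfg, mode = "ideal", noise_sd = noise,
                        supersample = supersample,
                        residual_fraction = residual, seed = seed)
  })
}

# cheap constant image covering the ROI analysis range
bg_image <- function(spec, nz = 9) {
  cached(paste("bgimg", spec$name, nz), function() {
    vals <- array(1, dim = c(130, 100, nz))
    voxel_volume(vals, spacing = c(2.6, 2.6, 5),
                 origin = c(-129 * 2.6 / 2, -99 * 2.6 / 2, -(nz - 1) / 2 * 5),
                 unit = "kBq_per_mL")
  })
}

# single-slice recon-mode background variability at one ROI size,
# used by the TOF noise-reduction checks
recon_bv <- function(algorithm, seed, iterations = 2) {
  cached(paste("bv", algorithm, seed, iterations), function() {
    recon_bv_compute(algorithm, seed, iterations)
  })
}

recon_bv_compute <- function(algorithm, seed, iterations) {
  spec <- build_nim_phantom()
  cfg <- recon_config(algorithm = algorithm, matrix = 64, pixel_mm = 5.2,
                      slice_mm = 10, iterations = iterations, subsets = 8,
                      seed = seed)
  vol <- simulate_pet_volume(spec, acquisition_config(), cfg,
                             slices = 0, angle_count = 48, supersample = 2,
                             seed = seed)
  rois <- place_background_rois(spec, vol, offsets = 0)
  m <- measure_rois(vol, rois[rois$sphere_size == 37, ])
  background_variability(m$mean)
}
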