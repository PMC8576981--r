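test_that("ideal mode with no blur or noise returns the rasterized activity", {
  ph <- build_nim_phantom()
  cfg <- recon_config(matrix = 64, pixel_mm = 5.2, slice_mm = 10,
                      psf_fwhm_mm = 0)
  vol <- simulate_pet_volume(ph, cfg = cfg, mode = "ideal", noise_sd = 0,
                             residual_fraction = 0, supersample = 2,
                             slices = c(-10, 0, 10))
  ref <- rasterize_activity(
    ph, spacing = c(5.2, 5.2, 10), supersample = 2,
    extent = list(x = c(-166.4, 166.4), y = c(-166.4, 166.4),
                  z = c(-15, 15)),
    allow_partial = TRUE
  )
  expect_equal(vol$values, ref$values, tolerance = 1e-6)
})

test_that("blur spreads small spheres: hot contrast rises with diameter", {
  ph <- all_hot_nim()
  vol <- ideal_sim(ph, psf = 8, noise = 0, seed = 7, key = "allhot-blur")
  res <- analyze_pet(vol, ph)
  hot <- res$measured_contrast[order(res$sphere_size)]
  expect_true(all(diff(hot) > 0))  # strictly increasing 4 -> 37 mm
})

test_that("end-to-end simulation with a fixed seed is reproducible", {
  ph <- build_nim_phantom()
  cfg <- recon_config(matrix = 128, pixel_mm = 2.6, slice_mm = 5,
                      psf_fwhm_mm = 6, seed = 5)
  v1 <- simulate_pet_volume(ph, cfg = cfg, mode = "ideal", supersample = 2,
                            seed = 5)
  v2 <- simulate_pet_volume(ph, cfg = cfg, mode = "ideal", supersample = 2,
                            seed = 5)
  expect_identical(v1$values, v2$values)
  r1 <- analyze_pet(v1, ph); r2 <- analyze_pet(v2, ph)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(attr(r1, "residual_error"), attr(r2, "residual_error"))
  v3 <- simulate_pet_volume(ph, cfg = cfg, mode = "ideal", supersample = 2,
                            seed = 6)
  expect_false(identical(v1$values, v3$values))
})

test_that("recon-mode simulation produces a usable, deterministic volume", {
  ph <- build_nim_phantom()
  cfg <- recon_config(matrix = 64, pixel_mm = 5.2, slice_mm = 10,
                      iterations = 2, subsets = 8, seed = 3)
  v1 <- simulate_pet_volume(ph, acquisition_config(), cfg, slices = 0,
                            angle_count = 48, supersample = 2, seed = 3)
  v2 <- simulate_pet_volume(ph, acquisition_config(), cfg, slices = 0,
                            angle_count = 48, supersample = 2, seed = 3)
  expect_identical(v1$values, v2$values)
  expect_true(all(v1$values >= 0))
  # the hottest reconstructed in-body voxel should sit in a hot sphere
  xs <- petctiq:::axis_coords(v1, 1); ys <- petctiq:::axis_coords(v1, 2)
  peak <- which(v1$values[, , 1] == max(v1$values[, , 1]), arr.ind = TRUE)
  px <- xs[peak[1, 1]]; py <- ys[peak[1, 2]]
  hot <- ph$spheres[ph$spheres$role == "hot", ]
  dmin <- min(sqrt((hot$x - px)^2 + (hot$y - py)^2) - hot$diameter / 2)
  expect_lt(dmin, 10)
})

test_that("TOF count gain lowers reconstructed background variability", {
  seeds <- 101:112
  bv_osem <- vapply(seeds, function(s) recon_bv("OSEM", s), numeric(1))
  bv_tof <- vapply(seeds, function(s) recon_bv("OSEM_TOF", s), numeric(1))
  expect_gt(mean(bv_osem - bv_tof), 0)
  expect_gte(sum(bv_tof < bv_osem), 9)  # at least 9 of 12 seeds
  expect_lt(t.test(bv_osem, bv_tof, paired = TRUE,
                   alternative = "greater")$p.value, 0.01)
})

test_that("CT simulation recovers the HU map and its noise model", {
  ph <- build_nim_phantom()
  cfg0 <- ct_scan_config(matrix = 120, pixel_mm = 1.4, noise_sd = 0, seed = 1)
  v0 <- simulate_ct_volume(ph, cfg0)
  ref <- rasterize_hu(ph, spacing = c(1.4, 1.4, 2), supersample = 4,
                      extent = list(x = c(-84, 84), y = c(-84, 84),
                                    z = 100 + c(-10, 10)))
  expect_identical(v0$values, ref$values)

  cfg1 <- ct_scan_config(matrix = 120, pixel_mm = 1.4, noise_sd = 2.1,
                         seed = 9)
  v1 <- simulate_ct_volume(ph, cfg1)
  expect_identical(v1$values, simulate_ct_volume(ph, cfg1)$values)
  # background SD over a large ROI in the sampling band (ROIs sit in the
  # insert-free directions of the module)
  roi <- tibble::tibble(x = 0, y = -40, z = 100, diameter = 40)
  m <- measure_rois(v1, roi)
  expect_gt(m$n_voxels, 500)
  expect_gt(m$sd, 1.8); expect_lt(m$sd, 2.4)

  # stationarity: disjoint equal ROIs agree within the chi-square band
  roiB <- tibble::tibble(x = 40 * cos(pi / 6), y = 40 * sin(pi / 6),
                         z = 100, diameter = 40)
  mB <- measure_rois(v1, roiB)
  ratio <- m$sd^2 / mB$sd^2
  n <- m$n_voxels
  band <- stats::qf(c(0.001, 0.999), n - 1, mB$n_voxels - 1)
  expect_gt(ratio, band[1]); expect_lt(ratio, band[2])

  # insert means within 3 sd / sqrt(n)
  ins <- ph$ct_module$inserts
  for (i in 1:3) {
    r <- measure_rois(v1, tibble::tibble(x = ins$x[i], y = ins$y[i],
                                         z = 100,
                                         diameter = ins$diameter[i] - 2 *
                                           2 * 1.4))
    expect_lt(abs(r$mean - ins$hu_delta[i]), 3 * 2.1 / sqrt(r$n_voxels) + 0.05)
  }
})
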