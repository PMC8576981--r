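test_that("the background grid is 12 ROIs x 5 slices = 60 per size", {
  ph <- build_nim_phantom()
  img <- bg_image(ph)
  rois <- place_background_rois(ph, img)
  r37 <- rois[rois$sphere_size == 37, ]
  expect_equal(nrow(r37), 60)
  expect_equal(as.integer(table(r37$slice)), rep(12L, 5))
  expect_equal(length(unique(r37$slice)), 5)
  # slices nearest 0, +/-10, +/-20 mm
  expect_setequal(unique(round(r37$z)), c(0, -10, 10, -20, 20))
  # every sphere size is served: 4..28 concentric + the 37 mm parents
  expect_setequal(unique(rois$sphere_size), c(4, 7, 10, 13, 17, 22, 28, 37))
  expect_equal(nrow(rois), 60 * 8)
})

test_that("smaller background ROIs are concentric with their 37 mm parents", {
  ph <- build_nim_phantom()
  rois <- place_background_rois(ph, bg_image(ph))
  parents <- rois[rois$sphere_size == 37, c("x", "y", "slice")]
  for (s in c(4, 10, 28)) {
    child <- rois[rois$sphere_size == s, c("x", "y", "slice")]
    expect_equal(child, parents, ignore_attr = TRUE)
  }
})

test_that("the packing honours the NEMA margin rule geometrically", {
  ph <- build_nim_phantom()
  rois <- place_background_rois(ph, bg_image(ph))
  r37 <- rois[rois$sphere_size == 37 & rois$slice == rois$slice[1], ]
  b <- ph$body
  # >= 15 mm from the boundary (ROI edge): signed distance <= -(18.5 + 15)
  sdf <- petctiq:::sdf_rounded_rect(r37$x, r37$y, b$half_width,
                                    b$half_height, b$corner_radius)
  expect_true(all(sdf <= -(18.5 + 15) + 1e-9))
  # >= 15 mm from every sphere surface
  for (i in seq_len(nrow(ph$spheres))) {
    d <- sqrt((r37$x - ph$spheres$x[i])^2 + (r37$y - ph$spheres$y[i])^2)
    expect_true(all(d >= ph$spheres$diameter[i] / 2 + 15 + 18.5 - 1e-9))
  }
  # clear of the lung insert and pairwise non-overlapping
  expect_true(all(sqrt(r37$x^2 + r37$y^2) >= 25 + 15 + 18.5 - 1e-9))
  dm <- as.matrix(dist(cbind(r37$x, r37$y))); diag(dm) <- Inf
  expect_true(all(dm >= 37 - 1e-9))
})

test_that("placement is deterministic and fails loudly when it cannot fit", {
  ph <- build_nim_phantom()
  img <- bg_image(ph)
  r1 <- place_background_rois(ph, img)
  r2 <- place_background_rois(ph, img)
  expect_identical(r1, r2)
  expect_error(place_background_rois(ph, img, margin = 60),
               "placement error")
  # image too short axially for the +/- 20 mm slices
  short <- voxel_volume(array(1, dim = c(130, 100, 2)),
                        spacing = c(2.6, 2.6, 5),
                        origin = c(-169, -128.7, 0), unit = "kBq_per_mL")
  expect_error(place_background_rois(ph, short), "analysis slices")
})

test_that("sphere and lung ROIs sit on the sphere centres and lung axis", {
  ph <- build_nim_phantom()
  img <- bg_image(ph)
  rois <- place_sphere_and_lung_rois(ph, img)
  sph <- rois[rois$label == "sphere", ]
  expect_equal(nrow(sph), 8)
  expect_setequal(sph$diameter, c(4, 7, 10, 13, 17, 22, 28, 37))
  ord <- match(sph$diameter, ph$spheres$diameter)
  expect_equal(sph$x, ph$spheres$x[ord])
  expect_equal(sph$y, ph$spheres$y[ord])
  lung <- rois[rois$label == "lung", ]
  expect_equal(nrow(lung), 5)
  expect_true(all(lung$diameter == 30))
  expect_true(all(lung$x == 0 & lung$y == 0))
})

test_that("ROI measurement follows the voxel-centre rule", {
  vals <- array(3.5, dim = c(21, 21, 3))
  img <- voxel_volume(vals, spacing = c(2, 2, 2), origin = c(-20, -20, -2),
                      unit = "counts")
  m <- measure_rois(img, tibble::tibble(x = 0, y = 0, z = 0, diameter = 12))
  expect_equal(m$mean, 3.5)
  expect_equal(m$sd, 0)

  # one-voxel ROI
  img$values[11, 11, 2] <- 9
  m1 <- measure_rois(img, tibble::tibble(x = 0, y = 0, z = 0, diameter = 1.5))
  expect_equal(m1$n_voxels, 1)
  expect_equal(m1$mean, 9)

  # half 0 / half 2 disk averages to ~1 by symmetry
  vals2 <- array(0, dim = c(41, 41, 1))
  vals2[, 22:41, 1] <- 2
  img2 <- voxel_volume(vals2, spacing = c(1, 1, 1), origin = c(-20, -20, 0),
                       unit = "counts")
  m2 <- measure_rois(img2, tibble::tibble(x = 0, y = 0.5, z = 0,
                                          diameter = 30))
  expect_equal(m2$mean, 1, tolerance = 0.05)

  # degenerate/outside ROIs error
  expect_error(
    measure_rois(img2, tibble::tibble(x = 100, y = 0, z = 0, diameter = 2)),
    "no voxel centres"
  )
})
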