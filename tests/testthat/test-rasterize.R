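test_that("background-only phantom rasterizes to a constant interior fill", {
  ph <- build_nema_iec_phantom(list(spheres = sphere_ring(numeric(0)),
                                    lung = NULL))
  vol <- rasterize_activity(ph, spacing = 6, supersample = 2)
  # voxels well inside the body (10 mm margin) are exactly background
  xs <- petctiq:::axis_coords(vol, 1); ys <- petctiq:::axis_coords(vol, 2)
  zs <- petctiq:::axis_coords(vol, 3)
  b <- ph$body
  inside <- outer(
    petctiq:::sdf_rounded_rect(rep(xs, length(ys)),
                               rep(ys, each = length(xs)),
                               b$half_width, b$half_height,
                               b$corner_radius) < -10,
    abs(zs) < b$length / 2 - 10,
    `&`
  )
  inside <- array(inside, dim = dim(vol$values))
  expect_true(all(vol$values[inside] == 6.6))
  # and air is zero
  expect_equal(vol$values[1, 1, 1], 0)
})

test_that("rasterized 37 mm sphere volume matches the analytic volume", {
  ph <- build_nim_phantom()
  s37 <- ph$spheres[ph$spheres$diameter == 37, ]
  pad <- 4
  ext <- list(x = s37$x + c(-1, 1) * (18.5 + pad),
              y = s37$y + c(-1, 1) * (18.5 + pad),
              z = c(-1, 1) * (18.5 + pad))
  vol <- rasterize_activity(ph, spacing = 1, supersample = 4, extent = ext,
                            allow_partial = TRUE)
  # inside this sub-grid the only non-background structure is the sphere;
  # cold spheres have activity 0, so occupancy = (bg - act) / bg
  occ <- (ph$background_activity - vol$values) / ph$background_activity
  v_meas <- sum(occ) * prod(vol$spacing)
  v_true <- 4 / 3 * pi * 18.5^3
  expect_equal(v_meas, v_true, tolerance = 0.01)
  expect_equal(v_true, 26521.8, tolerance = 1e-4)
})

test_that("cold spheres rasterize to zero activity inside", {
  ph <- build_nim_phantom()
  s28 <- ph$spheres[ph$spheres$diameter == 28, ]
  ext <- list(x = s28$x + c(-10, 10), y = s28$y + c(-10, 10),
              z = c(-10, 10))
  vol <- rasterize_activity(ph, spacing = 2, supersample = 2, extent = ext,
                            allow_partial = TRUE)
  xs <- petctiq:::axis_coords(vol, 1); ys <- petctiq:::axis_coords(vol, 2)
  zs <- petctiq:::axis_coords(vol, 3)
  d2 <- outer(outer((xs - s28$x)^2, (ys - s28$y)^2, `+`), zs^2, `+`)
  core <- d2 < (14 - 3)^2   # fully interior voxels
  expect_gt(sum(core), 100)
  expect_equal(mean(vol$values[core]), 0)
})

test_that("rasterization is deterministic and conserves total activity", {
  ph <- build_nema_iec_phantom()
  v1 <- rasterize_activity(ph, spacing = 5, supersample = 2)
  v2 <- rasterize_activity(ph, spacing = 5, supersample = 2)
  expect_identical(v1$values, v2$values)

  truth <- analytic_total_activity(ph)
  err <- vapply(c(1, 4), function(ss) {
    v <- rasterize_activity(ph, spacing = 5, supersample = ss)
    abs(sum(v$values) * prod(v$spacing) / 1000 - truth)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2] / truth, 0.005)
})

test_that("supersampling strictly improves the 4 mm sphere volume", {
  ph <- build_nim_phantom()
  s4 <- ph$spheres[ph$spheres$diameter == 4, ]
  ext <- list(x = s4$x + c(-6, 6), y = s4$y + c(-6, 6), z = c(-6, 6))
  v_true <- 4 / 3 * pi * 2^3
  err <- vapply(c(1, 2, 4), function(ss) {
    vol <- rasterize_activity(ph, spacing = 2, supersample = ss,
                              extent = ext, allow_partial = TRUE)
    occ <- (vol$values - ph$background_activity) /
      (ph$hot_activity - ph$background_activity)
    abs(sum(occ) * prod(vol$spacing) - v_true)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("HU rasterization maps inserts, water, lung and air correctly", {
  ph <- build_nim_phantom()
  vol <- rasterize_hu(ph, spacing = c(1, 1, 2), supersample = 2)
  m <- ph$ct_module
  xs <- petctiq:::axis_coords(vol, 1); ys <- petctiq:::axis_coords(vol, 2)
  kz <- petctiq:::nearest_slice(vol, m$center_z)
  sl <- vol$values[, , kz]
  for (i in seq_len(nrow(m$inserts))) {
    core <- outer((xs - m$inserts$x[i])^2, (ys - m$inserts$y[i])^2, `+`) <
      (m$inserts$diameter[i] / 2 - 2)^2
    expect_equal(mean(sl[core]), m$inserts$hu_delta[i], tolerance = 1e-12)
  }
  # water background between the inserts and the rim
  r2 <- outer(xs^2, ys^2, `+`)
  bgpix <- r2 > 58^2 & r2 < 68^2
  expect_equal(mean(sl[bgpix]), 0, tolerance = 1e-12)
  expect_equal(sl[1, 1], -1000)
  expect_error(rasterize_hu(build_nema_iec_phantom()), "CT module")
})

test_that("lung insert maps to the density-derived HU", {
  ph <- build_nim_phantom()
  ext <- list(x = c(-10, 10), y = c(-10, 10), z = c(-10, 10))
  vol <- rasterize_hu(ph, spacing = 2, supersample = 1, extent = ext)
  expect_equal(unique(as.vector(vol$values)), 1000 * (0.3 - 1))
})

test_that("a grid that cannot contain the phantom raises an extent error", {
  ph <- build_nema_iec_phantom()
  ext <- list(x = c(-50, 50), y = c(-50, 50), z = c(-50, 50))
  expect_error(rasterize_activity(ph, spacing = 5, extent = ext),
               "extent error")
  expect_silent(rasterize_activity(ph, spacing = 5, extent = ext,
                                   allow_partial = TRUE))
})
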