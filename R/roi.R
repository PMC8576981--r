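#' NEMA-style region-of-interest placement
#'
#' `place_background_rois()` lays out the standard background grid: twelve
#' 37 mm circular ROIs per slice on the five analysis slices (central slice
#' and the slices nearest +/- 10 and +/- 20 mm), i.e. 60 background ROIs,
#' with concentric smaller ROIs of every other sphere size at the same
#' centres. Placement honours the NEMA margin rule: every ROI edge at
#' least `margin` mm from the phantom boundary and from every sphere
#' surface (in-plane, central-slice layout shared across slices), the lung
#' insert avoided, and the twelve 37 mm ROIs pairwise non-overlapping.
#' Positions are found by a deterministic farthest-point packing over a
#' candidate grid, so the same phantom always yields the same layout.
#'
#' `place_sphere_and_lung_rois()` returns one ROI per sphere (diameter
#' equal to the sphere's inner diameter, centred on the sphere, on the
#' slice through the sphere centres) plus a 30 mm lung ROI on the lung
#' axis of each analysis slice.
#'
#' @param spec A `phantom_spec`.
#' @param image A [voxel_volume()] the ROIs are to be measured on.
#' @param central_z z of the sphere plane in mm (default 0).
#' @param offsets Axial offsets of the analysis slices, mm
#'   (default `c(0, -10, 10, -20, 20)`).
#' @param margin NEMA margin in mm (default 15).
#' @param n_rois Background ROIs per slice (default 12).
#' @param include_micro If `TRUE` (default), concentric background ROIs are
#'   also produced for sphere sizes below 10 mm when the phantom carries
#'   such spheres.
#' @param lung_diameter Lung ROI diameter, mm (default 30).
#' @param grid_step Candidate-grid step for the packing search, mm.
#' @return A tibble of ROIs with columns `roi_id`, `label` (`"background"`,
#'   `"sphere"`, `"lung"`), `sphere_size` (the sphere size the ROI serves,
#'   mm), `x`, `y`, `z`, `diameter`, `slice`.
#' @name roi_placement
NULL

roi_tibble <- function(label, sphere_size, x, y, z, diameter, slice) {
  tibble(
    roi_id = seq_along(x), label = label, sphere_size = sphere_size,
    x = x, y = y, z = z, diameter = diameter, slice = slice
  )
}

# deterministic farthest-point packing of n_rois circle centres
pack_background_centers <- function(spec, roi_d, margin, n_rois, grid_step) {
  b <- spec$body
  roi_r <- roi_d / 2
  er <- roi_r + margin
  xs <- seq(-(b$half_width - er), b$half_width - er, by = grid_step)
  ys <- seq(-(b$half_height - er), b$half_height - er, by = grid_step)
  cand <- expand.grid(x = xs, y = ys)
  keep <- sdf_rounded_rect(cand$x, cand$y, b$half_width, b$half_height,
                           b$corner_radius) <= -er
  sp <- spec$spheres
  for (i in seq_len(nrow(sp))) {
    keep <- keep & sqrt((cand$x - sp$x[i])^2 + (cand$y - sp$y[i])^2) >=
      sp$diameter[i] / 2 + margin + roi_r
  }
  if (!is.null(spec$lung)) {
    keep <- keep & sqrt(cand$x^2 + cand$y^2) >=
      spec$lung$diameter / 2 + margin + roi_r
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    abort(sprintf(
      "placement error: no admissible centre for %.0f mm background ROIs (margin %.0f mm)",
      roi_d, margin
    ))
  }
  pts <- as.matrix(cand)
  sel <- pts[which.max(pts[, 1]^2 + pts[, 2]^2), , drop = FALSE]
  while (nrow(sel) < n_rois) {
    dmin <- rep(Inf, nrow(pts))
    for (r in seq_len(nrow(sel))) {
      dmin <- pmin(dmin, sqrt((pts[, 1] - sel[r, 1])^2 +
                                (pts[, 2] - sel[r, 2])^2))
    }
    i <- which.max(dmin)
    if (dmin[i] < roi_d) {
      abort(sprintf(
        paste0("placement error: only %d of %d non-overlapping %.0f mm ",
               "background ROIs fit (margin %.0f mm, %d candidate centres)"),
        nrow(sel), n_rois, roi_d, margin, nrow(pts)
      ))
    }
    sel <- rbind(sel, pts[i, ])
  }
  unname(sel)
}

#' @rdname roi_placement
#' @export
place_background_rois <- function(spec, image, central_z = 0,
                                  offsets = c(0, -10, 10, -20, 20),
                                  margin = 15, n_rois = 12,
                                  include_micro = TRUE, grid_step = 2) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(image, "voxel_volume"))
  zc <- axis_coords(image, 3)
  if (max(abs(offsets)) > 0 &&
      (min(zc) > central_z + min(offsets) ||
       max(zc) < central_z + max(offsets))) {
    abort("placement error: image does not cover the analysis slices")
  }
  sizes <- sort(unique(c(spec$spheres$diameter, 37)))
  sizes <- sizes[sizes <= 37]
  if (!include_micro) sizes <- sizes[sizes >= 10]
  centers <- pack_background_centers(spec, 37, margin, n_rois, grid_step)
  slice_idx <- vapply(central_z + offsets, function(z) nearest_slice(image, z),
                      integer(1))
  out <- list()
  for (k in seq_along(slice_idx)) {
    z <- zc[slice_idx[k]]
    for (s in sizes) {
      out[[length(out) + 1]] <- roi_tibble(
        "background", s, centers[, 1], centers[, 2], rep(z, n_rois),
        rep(s, n_rois), rep(slice_idx[k], n_rois)
      )
    }
  }
  res <- bind_rows(out)
  res$roi_id <- seq_len(nrow(res))
  check_rois_inside(res, image)
  res
}

#' @rdname roi_placement
#' @export
place_sphere_and_lung_rois <- function(spec, image, central_z = 0,
                                       offsets = c(0, -10, 10, -20, 20),
                                       lung_diameter = 30) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(image, "voxel_volume"))
  zc <- axis_coords(image, 3)
  sp <- spec$spheres
  out <- list()
  if (nrow(sp) > 0) {
    k <- nearest_slice(image, central_z)
    out[[1]] <- roi_tibble("sphere", sp$diameter, sp$x, sp$y,
                           rep(zc[k], nrow(sp)), sp$diameter,
                           rep(k, nrow(sp)))
  }
  if (!is.null(spec$lung)) {
    slice_idx <- vapply(central_z + offsets,
                        function(z) nearest_slice(image, z), integer(1))
    out[[length(out) + 1]] <- roi_tibble(
      "lung", NA_real_, rep(0, length(slice_idx)), rep(0, length(slice_idx)),
      zc[slice_idx], rep(lung_diameter, length(slice_idx)), slice_idx
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(res)
  res$roi_id <- seq_len(nrow(res))
  check_rois_inside(res, image)
  res
}

check_rois_inside <- function(rois, image) {
  xr <- range(axis_coords(image, 1)) + c(-0.5, 0.5) * image$spacing[1]
  yr <- range(axis_coords(image, 2)) + c(-0.5, 0.5) * image$spacing[2]
  bad <- rois$x - rois$diameter / 2 < xr[1] |
    rois$x + rois$diameter / 2 > xr[2] |
    rois$y - rois$diameter / 2 < yr[1] |
    rois$y + rois$diameter / 2 > yr[2]
  if (any(bad)) {
    abort(sprintf("placement error: %d ROI(s) extend outside the image",
                  sum(bad)))
  }
  invisible(rois)
}

#' Measure circular ROIs on a voxel volume
#'
#' The mean and sample standard deviation over all voxels whose centres
#' lie within the ROI circle on the ROI's slice (voxel-centre-in-circle
#' rule, no partial weighting).
#'
#' @param image A [voxel_volume()].
#' @param rois A tibble of ROIs as returned by the placement functions
#'   (columns `x`, `y`, `diameter` and either `slice` or `z`).
#' @param roi A single ROI (one-row tibble or list).
#' @return `measure_rois()`: the ROI tibble with `mean`, `sd`, `n_voxels`
#'   appended. `measure_roi()`: a one-row tibble.
#' @export
measure_rois <- function(image, rois) {
  stopifnot(inherits(image, "voxel_volume"))
  xs <- axis_coords(image, 1)
  ys <- axis_coords(image, 2)
  slice <- if ("slice" %in% names(rois) && !all(is.na(rois$slice))) {
    as.integer(rois$slice)
  } else {
    vapply(rois$z, function(z) nearest_slice(image, z), integer(1))
  }
  res <- pmap(
    list(rois$x, rois$y, rois$diameter, slice),
    function(cx, cy, d, k) {
      m <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= (d / 2)^2
      v <- image$values[, , k][m]
      if (length(v) == 0) {
        abort("measurement error: ROI contains no voxel centres")
      }
      tibble(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
             n_voxels = length(v))
    }
  )
  bind_cols(rois, bind_rows(res))
}

#' @rdname measure_rois
#' @export
measure_roi <- function(image, roi) {
  roi <- as_tibble(as.list(roi[c("x", "y", "diameter",
                                 intersect(names(roi), c("slice", "z")))]))
  measure_rois(image, roi)
}
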