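#' Voxel volumes
#'
#' A `voxel_volume` is a 3D scalar grid with voxel spacing and origin in mm.
#' The array is stored column-major in (x, y, z) order; `origin` is the mm
#' coordinate of the centre of voxel `[1, 1, 1]`, and voxel values live at
#' voxel centres. `unit` records the physical meaning of the values
#' (`"kBq_per_mL"`, `"HU"` or `"counts"`).
#'
#' @param values Numeric 3D array.
#' @param spacing Numeric length-3, mm per voxel, strictly positive.
#' @param origin Numeric length-3, mm coordinate of the first voxel centre.
#' @param unit One of `"kBq_per_mL"`, `"HU"`, `"counts"`.
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(values, spacing, origin,
                         unit = c("kBq_per_mL", "HU", "counts")) {
  unit <- match.arg(unit)
  if (length(dim(values)) != 3) abort("values must be a 3D array")
  if (any(dim(values) < 1)) abort("grid dimensions must be >= 1 in each axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("spacing must be a strictly positive length-3 vector")
  }
  if (length(origin) != 3) abort("origin must be a length-3 vector")
  structure(
    list(values = values, spacing = spacing, origin = origin, unit = unit),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_volume %d x %d x %d, spacing %.3g x %.3g x %.3g mm, unit %s>\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit
  ))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# mm coordinates of voxel centres along one axis
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

# index of the slice whose centre is nearest to z (ties toward lower z,
# i.e. the phantom head end)
nearest_slice <- function(vol, z) {
  zc <- axis_coords(vol, 3)
  d <- abs(zc - z)
  which(d == min(d))[1]
}

voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

# build a centred grid: n voxels per axis, centres symmetric about 0
centered_grid <- function(n, spacing) {
  list(
    n = n, spacing = spacing,
    origin = -(n - 1) / 2 * spacing
  )
}
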