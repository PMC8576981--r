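#' Sinograms and parallel-beam forward projection
#'
#' The simulator uses a 2D parallel-beam slice-wise system model: a
#' pixel-driven discrete Radon transform in which each pixel's value is
#' spread over the two nearest radial bins by linear interpolation, scaled
#' by `pixel_area / radial_spacing` so that sinogram values are line
#' integrals in activity-mm. The same sparse system matrix (and its
#' transpose) drives forward projection and OSEM backprojection, so the
#' operator pair is exactly matched.
#'
#' @param values Matrix `n_angles x n_radial` of line integrals (or counts
#'   after [add_poisson_noise()]).
#' @param angles Projection angles in radians.
#' @param radial_spacing Radial bin width, mm.
#' @param pixel_mm Image pixel size, mm, of the image the sinogram was
#'   projected from.
#' @param expected_counts Total expected counts (`NA` until a count level
#'   is set).
#' @return A `sinogram` object.
#' @export
sinogram <- function(values, angles, radial_spacing, pixel_mm,
                     expected_counts = NA_real_) {
  if (!is.matrix(values)) abort("sinogram values must be a matrix")
  if (nrow(values) != length(angles)) {
    abort("nrow(values) must equal length(angles)")
  }
  if (length(angles) < 1) abort("need at least one projection angle")
  structure(
    list(values = values, angles = angles, radial_spacing = radial_spacing,
         pixel_mm = pixel_mm, expected_counts = expected_counts),
    class = "sinogram"
  )
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf(
    "<sinogram %d angles x %d radial bins, bin %.3g mm, expected counts %s>\n",
    nrow(x$values), ncol(x$values), x$radial_spacing,
    if (is.na(x$expected_counts)) "unset" else
      format(x$expected_counts, big.mark = ",")
  ))
  invisible(x)
}

# sparse system matrix: rows ordered radial-fastest within angle blocks,
# columns are image pixels (x fastest, column-major). Memoized per geometry.
radon_system_matrix <- function(n_pix, pixel_mm, angles, n_radial,
                                radial_mm) {
  key <- paste("A", n_pix, pixel_mm, n_radial, radial_mm,
               paste(signif(angles, 12), collapse = ","), sep = "|")
  hit <- get0(key, envir = .petctiq_cache)
  if (!is.null(hit)) return(hit)
  centers <- (seq_len(n_pix) - (n_pix + 1) / 2) * pixel_mm
  px <- rep(centers, times = n_pix)
  py <- rep(centers, each = n_pix)
  npx <- n_pix^2
  scale <- pixel_mm^2 / radial_mm
  ii <- vector("list", length(angles))
  jj <- vector("list", length(angles))
  xx <- vector("list", length(angles))
  for (a in seq_along(angles)) {
    s <- px * cos(angles[a]) + py * sin(angles[a])
    pos <- s / radial_mm + (n_radial + 1) / 2
    lo <- floor(pos)
    w <- pos - lo
    row0 <- (a - 1L) * n_radial
    ok_lo <- lo >= 1 & lo <= n_radial
    ok_hi <- (lo + 1) >= 1 & (lo + 1) <= n_radial
    ii[[a]] <- c(row0 + lo[ok_lo], row0 + lo[ok_hi] + 1L)
    jj[[a]] <- c(which(ok_lo), which(ok_hi))
    xx[[a]] <- c((1 - w[ok_lo]) * scale, w[ok_hi] * scale)
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(length(angles) * n_radial, npx)
  )
  assign(key, A, envir = .petctiq_cache)
  A
}

#' Forward projection of a single slice
#'
#' @param slice_image Square numeric matrix of activity values (finite,
#'   non-negative), pixels `pixel_mm` on a side.
#' @param angle_count Number of projection angles, evenly spaced over
#'   `[0, pi)`.
#' @param radial_bins Number of radial bins (default: image width plus
#'   enough margin to cover the pixel grid diagonal).
#' @param pixel_mm Pixel size in mm.
#' @param radial_mm Radial bin width in mm (default `pixel_mm`).
#' @return A [sinogram()] of line integrals (activity-mm).
#' @export
forward_project <- function(slice_image, angle_count = 180,
                            radial_bins = NULL, pixel_mm = 2,
                            radial_mm = pixel_mm) {
  if (!is.matrix(slice_image) || nrow(slice_image) != ncol(slice_image)) {
    abort("slice_image must be a square matrix")
  }
  if (any(!is.finite(slice_image))) abort("slice_image must be finite")
  if (any(slice_image < 0)) {
    abort("validation error: slice_image must be non-negative")
  }
  if (angle_count < 1) abort("angle_count must be >= 1")
  n <- nrow(slice_image)
  if (is.null(radial_bins)) {
    radial_bins <- 2L * as.integer(ceiling(n / sqrt(2))) + 3L
  }
  angles <- (seq_len(angle_count) - 1) * pi / angle_count
  A <- radon_system_matrix(n, pixel_mm, angles, radial_bins, radial_mm)
  y <- as.numeric(A %*% as.vector(slice_image))
  sinogram(
    values = t(matrix(y, nrow = radial_bins)),
    angles = angles, radial_spacing = radial_mm, pixel_mm = pixel_mm
  )
}

#' Acquisition settings for the count model
#'
#' `sensitivity` is the calibration constant converting activity to
#' detected coincidences: expected total counts for a slice equal
#' `sensitivity * slice_activity_kBq * scan_time_seconds`, where the slice
#' activity is recovered from the sinogram's line-integral mass and the
#' slice thickness.
#'
#' @param scan_time_min PET acquisition time in minutes (default 8).
#' @param sensitivity Counts per (kBq s) (default 2).
#' @param slice_thickness_mm Axial extent represented by one slice, mm.
#' @return An `acquisition_config` object.
#' @export
acquisition_config <- function(scan_time_min = 8, sensitivity = 2,
                               slice_thickness_mm = 3.66) {
  if (scan_time_min <= 0) abort("scan_time_min must be > 0")
  if (sensitivity <= 0) abort("sensitivity must be > 0")
  structure(
    list(scan_time_min = scan_time_min, sensitivity = sensitivity,
         slice_thickness_mm = slice_thickness_mm),
    class = "acquisition_config"
  )
}

#' Poisson counting noise on a sinogram
#'
#' Scales the noise-free sinogram so its total equals the expected count
#' level implied by the acquisition settings (optionally multiplied by
#' `count_gain`, e.g. a time-of-flight effective-count gain), then replaces
#' every bin by an independent Poisson draw. With a fixed seed the draw is
#' reproducible.
#'
#' @param sino A [sinogram()] of line integrals.
#' @param acq An [acquisition_config()].
#' @param seed Integer seed for the draw.
#' @param count_gain Effective-count multiplier (default 1); see
#'   [tof_count_gain()].
#' @return A `sinogram` whose values are counts; `expected_counts` records
#'   the pre-noise total.
#' @export
add_poisson_noise <- function(sino, acq, seed, count_gain = 1) {
  stopifnot(inherits(sino, "sinogram"), inherits(acq, "acquisition_config"))
  if (any(sino$values < 0)) abort("sinogram must be non-negative")
  tot <- sum(sino$values)
  if (tot == 0) {
    out <- sino
    out$expected_counts <- 0
    return(out)
  }
  # line-integral mass per angle = image mass (kBq/mL * mm^2); slice
  # activity in kBq = mass * thickness / 1000 (mm^3 -> mL)
  mass <- tot * sino$radial_spacing / length(sino$angles)
  slice_kbq <- mass * acq$slice_thickness_mm / 1000
  expected <- acq$sensitivity * slice_kbq * acq$scan_time_min * 60 * count_gain
  lambda <- sino$values * (expected / tot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  noisy <- matrix(rpois(length(lambda), lambda), nrow = nrow(lambda))
  out <- sino
  out$values <- noisy
  out$expected_counts <- expected
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
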