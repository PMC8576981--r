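#' Read and write voxel volumes as NIfTI-1
#'
#' Volumes round-trip through NIfTI-1 with spacing and origin preserved
#' (origin via the sform translation; any scale slope/intercept stored in
#' the file is applied on read by RNifti). DICOM series are not supported
#' by this build; requesting `format = "dicom_series"` raises an error.
#'
#' @param vol A [voxel_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param format Input format; only `"nifti"` is available.
#' @param unit Unit to stamp on the volume read from disk.
#' @return `read_volume()` a `voxel_volume`; `write_volume()` the path,
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::asNifti(img, reference = list(
    qform_code = 1L,
    qoffset_x = -vol$origin[1], qoffset_y = -vol$origin[2],
    qoffset_z = vol$origin[3]
  ))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series"),
                        unit = c("kBq_per_mL", "HU", "counts")) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (format == "dicom_series") {
    abort("format error: DICOM series are not supported by this build; use NIfTI")
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("format error: missing or invalid voxel spacing")
  }
  origin <- c(-hdr$qoffset_x, -hdr$qoffset_y, hdr$qoffset_z)
  vals <- array(as.numeric(img), dim = dim(img))
  voxel_volume(vals, spacing, origin, unit = unit)
}

#' Run configuration files
#'
#' A run configuration is a YAML file with sections `phantom` (preset name
#' plus overrides), `acquisition`, `reconstruction`, `ct_scan`, `analysis`
#' and `seed`. Unknown top-level keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A named list with validated sections and objects
#'   (`phantom` as a `phantom_spec`, `acquisition` as an
#'   [acquisition_config()], `reconstruction` as a [recon_config()],
#'   `ct_scan` as a [ct_scan_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  obj <- yaml::read_yaml(path)
  known <- c("phantom", "acquisition", "reconstruction", "ct_scan",
             "analysis", "seed")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  ph <- obj$phantom %||% list(preset = "nim_petct")
  preset <- ph$preset %||% "nim_petct"
  overrides <- ph$overrides
  phantom <- switch(preset,
    nim_petct = build_nim_phantom(overrides),
    nema_iec = build_nema_iec_phantom(overrides),
    abort(paste0("unknown phantom preset: ", preset))
  )
  list(
    phantom = phantom,
    acquisition = do.call(acquisition_config, obj$acquisition %||% list()),
    reconstruction = do.call(recon_config, obj$reconstruction %||% list()),
    ct_scan = do.call(ct_scan_config, obj$ct_scan %||% list()),
    analysis = obj$analysis %||% list(),
    seed = as.integer(obj$seed %||% 1L)
  )
}
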