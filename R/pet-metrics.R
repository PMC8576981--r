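#' PET image-quality metrics
#'
#' The four standard NEMA-style metrics, each a pure function of ROI means:
#'
#' * `hot_contrast()` — percent contrast recovery of a hot sphere:
#'   `Q_H = 100 * (C_H / C_B - 1) / (R - 1)`, where `R` is the true
#'   sphere-to-background activity ratio.
#' * `cold_contrast()` — percent contrast recovery of a cold sphere:
#'   `Q_C = 100 * (1 - C_C / C_B)`.
#' * `background_variability()` — percent coefficient of variation of the
#'   background ROI means at one ROI size:
#'   `N_j = 100 * SD(means) / mean(means)` (sample SD, n - 1 denominator,
#'   across the 60 ROI means under the standard protocol).
#' * `residual_error()` — percent of counts misplaced into the
#'   zero-activity lung insert after attenuation/scatter correction:
#'   per slice `dC_i = 100 * C_lung_i / C_B_37mm` with `C_B_37mm` the mean
#'   of all 37 mm background ROI means; the summary is the unweighted mean
#'   over the analysed slices.
#'
#' All four are invariant under a global rescaling of the image.
#'
#' @param c_h,c_c Mean counts in the hot / cold sphere ROI.
#' @param c_b Mean counts in the matched-size background ROIs.
#' @param R True sphere-to-background activity concentration ratio (> 1).
#' @param means Background ROI means at one ROI size (length >= 2).
#' @param lung_means Lung-ROI mean per analysed slice.
#' @param c_b_37 Mean of the 37 mm background ROI means (> 0).
#' @return `hot_contrast()`, `cold_contrast()`,
#'   `background_variability()`: a percentage. `residual_error()`: a list
#'   with `per_slice` (percent per slice) and `summary` (their mean).
#' @examples
#' hot_contrast(20, 10, R = 4)      # 33.33
#' cold_contrast(2.5, 10)           # 75
#' background_variability(c(8, 10, 12))  # 20
#' residual_error(c(4, 5), 50)$summary   # 9
#' @name pet_metrics
NULL

#' @rdname pet_metrics
#' @export
hot_contrast <- function(c_h, c_b, R) {
  if (any(R <= 1)) abort("validation error: R must be > 1")
  if (any(c_b <= 0)) abort("validation error: background mean must be > 0")
  (c_h / c_b - 1) / (R - 1) * 100
}

#' @rdname pet_metrics
#' @export
cold_contrast <- function(c_c, c_b) {
  if (any(c_b <= 0)) abort("validation error: background mean must be > 0")
  (1 - c_c / c_b) * 100
}

#' @rdname pet_metrics
#' @export
background_variability <- function(means) {
  if (length(means) < 2) abort("need >= 2 background ROI means")
  if (all(means == 0)) abort("validation error: all background means zero")
  sd(means) / mean(means) * 100
}

#' @rdname pet_metrics
#' @export
residual_error <- function(lung_means, c_b_37) {
  if (c_b_37 <= 0) abort("validation error: background mean must be > 0")
  per_slice <- lung_means / c_b_37 * 100
  list(per_slice = per_slice, summary = mean(per_slice))
}

#' Full PET image-quality analysis of a phantom image
#'
#' Runs the complete protocol on a reconstructed (or simulated) volume:
#' background, sphere and lung ROI placement, ROI measurement, and the
#' metrics of [pet_metrics]. Hot spheres whose measured contrast does not
#' exceed `detect_factor` times the background variability at their size
#' are reported as not detected (contrast set to `NA`), mirroring how small
#' spheres drop out of scanner reports; the raw measured value is kept in
#' `measured_contrast`.
#'
#' @param image A [voxel_volume()] (reconstructed PET or ideal-mode
#'   simulation).
#' @param spec The `phantom_spec` that was imaged (provides sphere centres,
#'   sizes, roles and the true ratio R).
#' @param central_z,offsets,margin,include_micro,lung_diameter Passed to
#'   the ROI placement functions.
#' @param detect_factor Detectability floor multiplier (default 2);
#'   applies to hot spheres only.
#' @param label Free-text label stored in the result (phantom / system /
#'   algorithm).
#' @return A `pet_iq_result`: a tibble with one row per sphere
#'   (`sphere_size`, `role`, `contrast`, `measured_contrast`,
#'   `background_variability`, `detected`) carrying attributes
#'   `residual_error` (summary percent), `residual_per_slice`,
#'   `background_means` (the measured background ROI tibble) and `meta`.
#'   [tidy()] returns the sphere table, [glance()] a one-row summary.
#' @export
analyze_pet <- function(image, spec, central_z = 0,
                        offsets = c(0, -10, 10, -20, 20), margin = 15,
                        include_micro = TRUE, lung_diameter = 30,
                        detect_factor = 2, label = spec$name) {
  bg <- place_background_rois(spec, image, central_z = central_z,
                              offsets = offsets, margin = margin,
                              include_micro = include_micro)
  sl <- place_sphere_and_lung_rois(spec, image, central_z = central_z,
                                   offsets = offsets,
                                   lung_diameter = lung_diameter)
  bg_m <- measure_rois(image, bg)
  sl_m <- measure_rois(image, sl)

  bg_stats <- bg_m |>
    group_by(.data$sphere_size) |>
    summarise(
      c_b = mean(.data$mean),
      n_j = background_variability(.data$mean),
      n_rois = dplyr::n(),
      .groups = "drop"
    )
  R <- activity_ratio(spec)
  spheres <- sl_m |>
    filter(.data$label == "sphere") |>
    left_join(bg_stats, by = "sphere_size") |>
    mutate(
      role = spec$spheres$role[match(.data$sphere_size,
                                     spec$spheres$diameter)],
      measured_contrast = ifelse(
        .data$role == "hot",
        hot_contrast(.data$mean, .data$c_b, R),
        cold_contrast(.data$mean, .data$c_b)
      ),
      detected = .data$role == "cold" |
        .data$measured_contrast > detect_factor * .data$n_j,
      contrast = ifelse(.data$detected, .data$measured_contrast, NA_real_)
    ) |>
    arrange(desc(.data$sphere_size)) |>
    select(sphere_size = "sphere_size", role = "role",
           contrast = "contrast", measured_contrast = "measured_contrast",
           background_variability = "n_j", detected = "detected")

  res_attr <- list(per_slice = numeric(0), summary = NA_real_)
  if (!is.null(spec$lung)) {
    c_b_37 <- bg_stats$c_b[bg_stats$sphere_size == 37]
    lung_means <- sl_m$mean[sl_m$label == "lung"]
    res_attr <- residual_error(lung_means, c_b_37)
  }
  structure(
    spheres,
    residual_error = res_attr$summary,
    residual_per_slice = res_attr$per_slice,
    background_means = bg_m,
    meta = list(label = label, R = R, unit = image$unit,
                n_background_rois = sum(bg_stats$n_rois[
                  bg_stats$sphere_size == 37]),
                detect_factor = detect_factor),
    class = c("pet_iq_result", class(spheres))
  )
}

#' @export
print.pet_iq_result <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("PET image-quality result: %s (R = %.2f)\n", meta$label,
              meta$R))
  print(as_tibble(x), n = nrow(x))
  cat(sprintf("Residual lung error: %.2f %%\n", attr(x, "residual_error")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pet_iq_result <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.pet_iq_result <- function(x, ...) {
  meta <- attr(x, "meta")
  tibble(
    label = meta$label,
    n_spheres = nrow(x),
    n_detected = sum(x$detected),
    max_hot_contrast = suppressWarnings(
      max(x$contrast[x$role == "hot"], na.rm = TRUE)),
    residual_error = attr(x, "residual_error"),
    n_background_rois = meta$n_background_rois
  )
}

#' Convert a PET IQ result to a comparison metric table
#' @param x A `pet_iq_result`.
#' @return A [metric_table()].
#' @export
as_metric_table <- function(x) {
  stopifnot(inherits(x, "pet_iq_result"))
  metric_table(
    tibble(
      sphere_size = x$sphere_size,
      contrast = x$contrast,
      background_variability = x$background_variability
    ),
    label = attr(x, "meta")$label,
    residual_error = attr(x, "residual_error")
  )
}
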