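#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: for a
#' `pet_iq_result`, contrast and background variability against sphere
#' size (the standard presentation of phantom IQ results); for a
#' `ct_iq_result`, measured mean delta-CT against the nominal insert HU
#' plus the CNR per insert. `plot_metric_tables()` overlays several
#' metric tables (e.g. algorithms or systems) the same way.
#'
#' @param object A result object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name petctiq-plots
NULL

#' @rdname petctiq-plots
#' @exportS3Method ggplot2::autoplot
autoplot.pet_iq_result <- function(object, ...) {
  df <- tidy(object) |>
    select("sphere_size", "contrast", "background_variability") |>
    pivot_longer(-"sphere_size", names_to = "metric", values_to = "value") |>
    mutate(metric = recode(.data$metric, contrast = "Contrast (%)",
                           background_variability =
                             "Background variability (%)"))
  ggplot(df, aes(.data$sphere_size, .data$value)) +
    geom_line(na.rm = TRUE) +
    geom_point(na.rm = TRUE) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Sphere inner diameter (mm)", y = NULL,
         title = attr(object, "meta")$label) +
    theme_minimal()
}

#' @rdname petctiq-plots
#' @exportS3Method ggplot2::autoplot
autoplot.ct_iq_result <- function(object, ...) {
  df <- tidy(object) |>
    pivot_longer(c("mean_delta_ct", "cnr"), names_to = "metric",
                 values_to = "value") |>
    mutate(metric = recode(.data$metric, mean_delta_ct = "Mean delta CT (HU)",
                           cnr = "CNR"))
  ggplot(df, aes(factor(.data$contrast_pct), .data$value)) +
    geom_col(width = 0.6) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Low-contrast resolution (%)", y = NULL,
         title = object$meta$label) +
    theme_minimal()
}

#' @rdname petctiq-plots
#' @param tables Named list of [metric_table()]s.
#' @param metric `"contrast"` or `"background_variability"`.
#' @export
plot_metric_tables <- function(tables,
                               metric = c("contrast",
                                          "background_variability")) {
  metric <- match.arg(metric)
  df <- imap(tables, function(t, nm) {
    tibble(label = attr(t, "label") %||% nm, sphere_size = t$sphere_size,
           value = t[[metric]])
  }) |> list_rbind()
  ylab <- if (metric == "contrast") "Contrast (%)" else
    "Background variability (%)"
  ggplot(df, aes(.data$sphere_size, .data$value, colour = .data$label)) +
    geom_line(na.rm = TRUE) +
    geom_point(na.rm = TRUE) +
    labs(x = "Sphere inner diameter (mm)", y = ylab, colour = NULL) +
    theme_minimal()
}
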