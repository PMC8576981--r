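#' Metric tables and cross-phantom / cross-system / cross-algorithm
#' comparison arithmetic
#'
#' A `metric_table` holds one column of PET image-quality results: per
#' sphere size, contrast (%) and background variability (%), plus an
#' optional scalar residual lung error (%). Missing entries (spheres the
#' scanner could not measure) are `NA` and are skipped — and reported — by
#' the comparison operations.
#'
#' @param data Data frame with columns `sphere_size`, `contrast`,
#'   `background_variability` (sphere sizes unique; `NA` marks a sphere
#'   that could not be measured).
#' @param label Label of the measurement (phantom / system / algorithm).
#' @param residual_error Scalar residual lung error in percent, or `NA`.
#' @return A `metric_table` (a tibble subclass with `label` and
#'   `residual_error` attributes).
#' @export
metric_table <- function(data, label, residual_error = NA_real_) {
  data <- as_tibble(data)
  need <- c("sphere_size", "contrast", "background_variability")
  if (!all(need %in% names(data))) {
    abort(paste0("metric_table needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(data$sphere_size)) {
    abort("sphere sizes must be unique")
  }
  structure(
    arrange(data[need], desc(.data$sphere_size)),
    label = label, residual_error = residual_error,
    class = c("metric_table", class(data))
  )
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("Metric table: %s (residual error %s %%)\n", attr(x, "label"),
              format(attr(x, "residual_error"))))
  NextMethod()
}

metric_column <- function(tab, metric) {
  metric <- match.arg(metric, c("contrast", "background_variability"))
  setNames(tab[[metric]], tab$sphere_size)
}

#' Maximum absolute deviation between two metric tables
#'
#' `max_abs_deviation()` compares one metric across two tables over a set
#' of sphere sizes and returns the largest absolute difference and the
#' size attaining it (ties broken toward the largest size). Sizes at which
#' either side is missing are skipped and listed in `skipped`.
#' `scalar_deviation()` is the same for the scalar residual error.
#' `algorithm_improvement()` returns the per-size contrast change
#' `variant - base` and the size with the largest increase.
#'
#' @param a,b,base,variant `metric_table` objects.
#' @param metric `"contrast"` or `"background_variability"`.
#' @param sizes Sphere sizes to compare (default: all sizes present in
#'   both tables).
#' @return `max_abs_deviation()`: list with `value`, `sphere_size`,
#'   `skipped`. `scalar_deviation()`: a number.
#'   `algorithm_improvement()`: tibble of per-size deltas with attributes
#'   `max_increase` and `at_size`.
#' @examples
#' tabs <- reference_tables()$phantom_comparison
#' max_abs_deviation(tabs$nim_petct, tabs$nema_iec, "contrast")
#' @export
max_abs_deviation <- function(a, b, metric = "contrast", sizes = NULL) {
  va <- metric_column(a, metric); vb <- metric_column(b, metric)
  common <- intersect(names(va), names(vb))
  if (!is.null(sizes)) {
    want <- as.character(sizes)
    missing_sizes <- setdiff(want, common)
    if (length(missing_sizes) > 0) {
      abort(paste0("requested sizes absent from both tables: ",
                   paste(missing_sizes, collapse = ", ")))
    }
    common <- want
  }
  if (length(common) == 0) abort("validation error: no common sphere sizes")
  ok <- !is.na(va[common]) & !is.na(vb[common])
  skipped <- as.numeric(common[!ok])
  common <- common[ok]
  if (length(common) == 0) abort("validation error: no comparable entries")
  d <- abs(va[common] - vb[common])
  best <- max(d)
  at <- max(as.numeric(common[d == best]))  # tie-break to largest size
  list(value = unname(best), sphere_size = at, skipped = skipped)
}

#' @rdname max_abs_deviation
#' @export
scalar_deviation <- function(a, b) {
  ra <- attr(a, "residual_error"); rb <- attr(b, "residual_error")
  if (is.na(ra) || is.na(rb)) {
    abort("validation error: residual error missing from a table")
  }
  abs(ra - rb)
}

#' @rdname max_abs_deviation
#' @export
algorithm_improvement <- function(base, variant) {
  vb <- metric_column(base, "contrast"); vv <- metric_column(variant, "contrast")
  if (!setequal(names(vb), names(vv))) {
    abort("validation error: sphere keys of the two tables do not align")
  }
  sizes <- names(vb)
  delta <- vv[sizes] - vb[sizes]
  out <- tibble(
    sphere_size = as.numeric(sizes),
    base = unname(vb[sizes]), variant = unname(vv[sizes]),
    delta = unname(delta)
  ) |> arrange(desc(.data$sphere_size))
  ok <- !is.na(out$delta)
  if (!any(ok)) abort("validation error: no comparable entries")
  best <- max(out$delta[ok])
  at <- max(out$sphere_size[ok][out$delta[ok] == best])
  structure(out, max_increase = best, at_size = at,
            labels = c(attr(base, "label"), attr(variant, "label")))
}

#' Render results as a document
#'
#' Deterministic serialization of one or more analysis results
#' (`pet_iq_result`, `ct_iq_result`, `metric_table`, or comparison output)
#' as CSV, JSON or markdown. The same input always yields byte-identical
#' output; a metadata block records labels.
#'
#' @param results A single result or a list of results.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param path Optional output file; the document is also returned.
#' @return The document as a single string, invisibly if `path` is given.
#' @export
render_report <- function(results, format = c("csv", "json", "markdown"),
                          path = NULL) {
  format <- match.arg(format)
  if (inherits(results, c("pet_iq_result", "ct_iq_result", "metric_table"))) {
    results <- list(results)
  }
  if (!is.list(results) || length(results) == 0) {
    abort("validation error: empty result list")
  }
  parts <- imap(results, function(r, nm) {
    df <- report_frame(r)
    title <- report_title(r, nm)
    switch(format,
      csv = paste0("# ", title, "\n",
                   paste(utils::capture.output(
                     utils::write.csv(df, row.names = FALSE)), collapse = "\n")),
      json = NULL,  # handled jointly below
      markdown = paste0("## ", title, "\n\n", markdown_table(df))
    )
  })
  doc <- if (format == "json") {
    jsonlite::toJSON(
      lapply(seq_along(results), function(i) {
        list(title = report_title(results[[i]], names(results)[i] %||% ""),
             table = report_frame(results[[i]]))
      }),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null"
    )
  } else {
    paste(unlist(parts), collapse = "\n\n")
  }
  doc <- paste0(doc, "\n")
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

report_frame <- function(r) {
  if (inherits(r, "pet_iq_result")) {
    df <- as.data.frame(tidy(r)[c("sphere_size", "contrast",
                                  "background_variability")])
    names(df) <- c("Sphere size (mm)", "Contrast (%)",
                   "Background variability (%)")
    df[["Residual error (%)"]] <- c(round2(attr(r, "residual_error")),
                                    rep(NA, nrow(df) - 1))
    df[, 2] <- round2(df[, 2]); df[, 3] <- round2(df[, 3])
    df
  } else if (inherits(r, "ct_iq_result")) {
    df <- as.data.frame(tidy(r))
    names(df) <- c("Low-contrast resolution (%)", "Nominal delta (HU)",
                   "Insert CT value (HU)", "Mean delta CT (HU)", "CNR")
    df[, 3:5] <- lapply(df[, 3:5], round2)
    df
  } else if (inherits(r, "metric_table")) {
    df <- as.data.frame(r)
    names(df) <- c("Sphere size (mm)", "Contrast (%)",
                   "Background variability (%)")
    df
  } else if (is.list(r) && all(c("value", "sphere_size") %in% names(r))) {
    data.frame(`Max deviation` = round2(r$value),
               `At sphere size (mm)` = r$sphere_size, check.names = FALSE)
  } else if (is.data.frame(r)) {
    as.data.frame(r)
  } else {
    abort("unknown result type in render_report()")
  }
}

report_title <- function(r, nm) {
  if (!is.null(nm) && nzchar(nm)) return(nm)
  if (inherits(r, "pet_iq_result")) {
    paste0("PET image quality: ", attr(r, "meta")$label)
  } else if (inherits(r, "ct_iq_result")) {
    paste0("CT low-contrast results: ", r$meta$label)
  } else if (inherits(r, "metric_table")) {
    paste0("Metric table: ", attr(r, "label"))
  } else "Comparison"
}

# round half away from zero at 2 dp (printed-table convention)
round2 <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

markdown_table <- function(df) {
  fmt <- function(v) {
    ifelse(is.na(v), "-",
           ifelse(vapply(v, is.numeric, logical(1)) | is.numeric(v),
                  format(v, trim = TRUE), as.character(v)))
  }
  cells <- vapply(df, function(col) fmt(col), character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
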