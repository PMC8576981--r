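#' Reference image-quality measurements
#'
#' The package ships, as plain CSV under `inst/extdata`, the published
#' clinical-scanner measurements from the NIM PET/CT phantom's validation
#' study: the NIM vs NEMA IEC phantom comparison, the three-system (A/B/C)
#' comparison, the four reconstruction-algorithm comparison
#' (OSEM / OSEM-PSF / OSEM-TOF / OSEM-PSF-TOF), the CT low-contrast ROI
#' values, the boundary-noise SDs and the uniformity ROI values. They are
#' the inputs to the comparison arithmetic ([max_abs_deviation()] and
#' friends) and to the CT metric functions; the acquisitions behind them
#' are real scans and are not reproduced by the simulator.
#'
#' @return A list:
#' \describe{
#'   \item{phantom_comparison}{named list of two [metric_table()]s
#'     (`nim_petct`, `nema_iec`) with residual errors attached.}
#'   \item{system_comparison}{named list of three `metric_table`s
#'     (`A`, `B`, `C`).}
#'   \item{algorithm_comparison}{named list of four `metric_table`s keyed
#'     by algorithm.}
#'   \item{ct_low_contrast}{tibble `contrast_pct`, `roi`, `ct`, `sd`.}
#'   \item{ct_boundary_noise}{tibble `roi`, `sd`.}
#'   \item{ct_uniformity}{tibble `mode`, `roi`, `ct`.}
#' }
#' @examples
#' tabs <- reference_tables()
#' tabs$phantom_comparison$nim_petct
#' @export
reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "petctiq",
                                  mustWork = TRUE)
  rd <- function(f) readr::read_csv(path(f), show_col_types = FALSE,
                                    progress = FALSE)
  res <- rd("pet_iq_residual_errors.csv")
  split_tables <- function(df, table_name) {
    labs <- unique(df$label)
    setNames(lapply(labs, function(l) {
      r <- res$residual_error[res$table == table_name & res$label == l]
      metric_table(df[df$label == l,
                      c("sphere_size", "contrast", "background_variability")],
                   label = l,
                   residual_error = if (length(r)) r else NA_real_)
    }), labs)
  }
  list(
    phantom_comparison = split_tables(rd("pet_iq_phantom_comparison.csv"),
                                      "phantom_comparison"),
    system_comparison = split_tables(rd("pet_iq_system_comparison.csv"),
                                     "system_comparison"),
    algorithm_comparison = split_tables(rd("pet_iq_algorithm_comparison.csv"),
                                        "algorithm_comparison"),
    ct_low_contrast = rd("ct_low_contrast.csv"),
    ct_boundary_noise = rd("ct_boundary_noise.csv"),
    ct_uniformity = rd("ct_uniformity.csv")
  )
}

#' Read/write a metric table as CSV
#'
#' The CSV carries the data columns plus a one-line header comment
#' encoding the label and residual error, so a table round-trips.
#'
#' @param tab A [metric_table()].
#' @param path File path.
#' @export
write_metric_table <- function(tab, path) {
  stopifnot(inherits(tab, "metric_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label: %s; residual_error: %s", attr(tab, "label"),
                     format(attr(tab, "residual_error"))), con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1)
  label <- "table"; res <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("label:\\s*([^;]+);\\s*residual_error:\\s*(\\S+)",
                                   first))[[1]]
    if (length(m) == 3) {
      label <- trimws(m[2])
      res <- suppressWarnings(as.numeric(m[3]))
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  metric_table(df, label = label, residual_error = res)
}
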