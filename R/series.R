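#' Lysis time series
#'
#' A thin data-frame container for a tumor decay record: a time grid in
#' hours and the tumor cell count at each time (optionally also the immune
#' cell count, for cellular-automaton runs).
#'
#' @param time_hr Numeric vector of times, hours, non-decreasing.
#' @param tumor_cells Tumor cell counts, same length, >= 0.
#' @param immune_cells Optional immune cell counts.
#' @param truncated Logical flag: `TRUE` if a step cap was reached before
#'   tumor extinction.
#' @return A data frame of class `lysis_series`.
#' @export
lysis_series <- function(time_hr, tumor_cells, immune_cells = NULL,
                         truncated = FALSE) {
  stopifnot(is.numeric(time_hr), is.numeric(tumor_cells),
            length(time_hr) == length(tumor_cells))
  if (any(tumor_cells < 0)) stop("tumor counts must be non-negative",
                                 call. = FALSE)
  if (any(diff(time_hr) < 0)) stop("time must be non-decreasing",
                                   call. = FALSE)
  df <- data.frame(time_hr = as.numeric(time_hr),
                   tumor_cells = as.numeric(tumor_cells))
  if (!is.null(immune_cells)) {
    stopifnot(length(immune_cells) == length(time_hr))
    df$immune_cells <- as.numeric(immune_cells)
  }
  class(df) <- c("lysis_series", "data.frame")
  attr(df, "truncated") <- isTRUE(truncated)
  df
}

#' @export
print.lysis_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Lysis series: %d records over %.1f hr; tumor %g -> %g cells%s\n",
              n, x$time_hr[n] - x$time_hr[1], x$tumor_cells[1],
              x$tumor_cells[n],
              if (isTRUE(attr(x, "truncated"))) " [truncated]" else ""))
  NextMethod()
}

#' Write a lysis series to CSV
#'
#' Two (or three) column CSV with header `time_hr, tumor_cells
#' [, immune_cells]`.
#'
#' @param series A [lysis_series] (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lysis_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a lysis series from CSV
#'
#' @param path CSV with columns `time_hr`, `tumor_cells` and optionally
#'   `immune_cells`.
#' @return A [lysis_series].
#' @export
read_lysis_series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_hr", "tumor_cells") %in% names(df)))
    stop("CSV must have columns 'time_hr' and 'tumor_cells'", call. = FALSE)
  lysis_series(df$time_hr, df$tumor_cells, df$immune_cells)
}
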