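#' Read a head-capsule-width measurement table
#'
#' Reads a delimited text file of per-larva head-capsule widths (HCW) and
#' returns a validated tibble. Widths are kept in micrometres; an explicit
#' `unit = "mm"` converts millimetre readings by multiplying by 1000. No unit
#' is ever inferred from column headers.
#'
#' Rows whose width is missing, non-numeric, non-finite, or not strictly
#' positive are invalid. With `strict = TRUE` (the default) any invalid row
#' aborts with a message naming the offending rows; with `strict = FALSE`
#' invalid rows are dropped with a warning.
#'
#' @param path Path to a delimited text file with one header row.
#' @param column Name (or 1-based index) of the column holding the widths.
#' @param delimiter Single-character field delimiter; `","` for CSV,
#'   `"\t"` for TSV.
#' @param unit Unit of the stored widths: `"um"` (default) or `"mm"`.
#' @param strict If `TRUE`, invalid rows are fatal; if `FALSE`, they are
#'   dropped with a warning.
#'
#' @return A tibble with columns `id` (taken from an `id` column when the
#'   file has one, otherwise the data row number as a character) and
#'   `hcw_um` (positive double, micrometres). Any `true_instar` column in
#'   the file (written by [write_fixture()]) is carried through.
#' @seealso [write_hcw_table()], [make_histogram()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("hcw_um", "300", "400", "650"), f)
#' read_hcw_table(f)
read_hcw_table <- function(path, column = "hcw_um", delimiter = ",",
                           unit = c("um", "mm"), strict = TRUE) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (nchar(delimiter) != 1L) {
    stop("`delimiter` must be a single character", call. = FALSE)
  }
  # columns come in as text and are converted by as.numeric(): R's strtod
  # is correctly rounded, so written doubles round-trip exactly
  raw <- readr::read_delim(path, delim = delimiter,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (is.numeric(column)) {
    if (column < 1L || column > ncol(raw)) {
      stop("column index ", column, " out of range (file has ",
           ncol(raw), " columns)", call. = FALSE)
    }
    column <- names(raw)[column]
  }
  if (!column %in% names(raw)) {
    stop("column '", column, "' not found; available: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(raw[[column]]))
  bad <- which(is.na(vals) | !is.finite(vals) | vals <= 0)
  if (length(bad) > 0L) {
    msg <- paste0("invalid head-capsule width in data row(s) ",
                  paste(utils::head(bad, 10L), collapse = ", "),
                  if (length(bad) > 10L) ", ..." else "",
                  " (must be finite and > 0)")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropping ", length(bad), " row(s)", call. = FALSE)
  }
  keep <- setdiff(seq_along(vals), bad)
  if (length(keep) == 0L) {
    stop("no valid rows in '", path, "'", call. = FALSE)
  }
  ids <- if ("id" %in% names(raw)) as.character(raw$id) else as.character(seq_along(vals))
  out <- tibble::tibble(
    id = ids[keep],
    hcw_um = vals[keep] * if (unit == "mm") 1000 else 1
  )
  if ("true_instar" %in% names(raw)) {
    out$true_instar <- as.integer(raw$true_instar[keep])
  }
  attr(out, "source") <- path
  out
}

#' Write a head-capsule-width table
#'
#' Serialises a HCW tibble back to delimited text so that
#' [read_hcw_table()] reproduces the values exactly.
#'
#' @param data A data frame with at least a `hcw_um` column.
#' @param path Output file path.
#' @param delimiter Single-character field delimiter.
#' @return `path`, invisibly.
#' @export
write_hcw_table <- function(data, path, delimiter = ",") {
  stopifnot(is.data.frame(data), "hcw_um" %in% names(data))
  out <- data
  # 17 significant digits make the double -> text -> double trip lossless
  out$hcw_um <- sprintf("%.17g", data$hcw_um)
  readr::write_delim(out, path, delim = delimiter)
  invisible(path)
}

#' Bin head-capsule widths into a frequency histogram
#'
#' Builds the frequency-distribution histogram of head-capsule widths on
#' which the multi-peak normal fit is visualised. Bins are half-open
#' `[start, end)` except the last, which is closed so the maximum value is
#' counted. The bin origin is anchored at the minimum observed value rounded
#' down to a multiple of the bin width, making the grid independent of row
#' order.
#'
#' With `bin_width = "auto"` the Freedman-Diaconis rule
#' (2 IQR / n^(1/3)) is applied with a 5 micrometre floor.
#'
#' @param data Data frame of measurements.
#' @param column Name of the width column, in micrometres.
#' @param bin_width Positive bin width in micrometres, or `"auto"`.
#' @return A tibble with columns `bin_start`, `bin_end`, `mid`, `count`;
#'   the chosen bin width is stored in attribute `bin_width`.
#' @export
#' @examples
#' d <- tibble::tibble(hcw_um = c(350, 350, 360))
#' make_histogram(d, bin_width = 25)
make_histogram <- function(data, column = "hcw_um", bin_width = "auto") {
  stopifnot(is.data.frame(data))
  x <- data[[column]]
  if (is.null(x) || length(x) == 0L) {
    stop("no values to bin in column '", column, "'", call. = FALSE)
  }
  if (identical(bin_width, "auto")) {
    bin_width <- fd_bin_width(x)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be a positive number or \"auto\"", call. = FALSE)
  }
  origin <- floor(min(x) / bin_width) * bin_width
  m <- max(1L, ceiling((max(x) - origin) / bin_width))
  edges <- origin + bin_width * (0:m)
  # last bin closed: a value exactly on the last edge belongs to bin m
  idx <- pmin(floor((x - origin) / bin_width) + 1L, m)
  counts <- tabulate(idx, nbins = m)
  out <- tibble::tibble(
    bin_start = edges[-(m + 1L)],
    bin_end = edges[-1L],
    mid = (edges[-(m + 1L)] + edges[-1L]) / 2,
    count = counts
  )
  attr(out, "bin_width") <- bin_width
  out
}

# Freedman-Diaconis width with a 5 um floor (instrument-scale lower bound).
fd_bin_width <- function(x) {
  iqr <- stats::IQR(x)
  w <- 2 * iqr / length(x)^(1 / 3)
  if (!is.finite(w) || w <= 0) w <- diff(range(x)) / max(1, ceiling(sqrt(length(x))))
  max(w, 5)
}

#' Export a histogram as two-column TSV
#'
#' @param histogram A tibble from [make_histogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(histogram, path) {
  readr::write_tsv(histogram[, c("bin_start", "count")], path)
  invisible(path)
}
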