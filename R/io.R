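# On-disk formats: labelled TSV time series, labelled CSV matrices, edge-list
# TSV, JSON reports. Readers locate malformed input by line and column
# instead of silently misreading.

split_table_lines <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2)
    stop(sprintf("%s: expected a header and at least one data row", path),
         call. = FALSE)
  strsplit(lines, sep, fixed = TRUE)
}

parse_numeric_table <- function(path, sep, skip_first_field = FALSE) {
  fields <- split_table_lines(path, sep)
  header <- fields[[1]]
  n_col <- length(header)
  body <- fields[-1]
  vals <- matrix(NA_real_, length(body), n_col - skip_first_field)
  row_labels <- character(length(body))
  for (r in seq_along(body)) {
    f <- body[[r]]
    if (length(f) != n_col)
      stop(sprintf("%s: line %d has %d fields, expected %d", path, r + 1,
                   length(f), n_col), call. = FALSE)
    if (skip_first_field) {
      row_labels[r] <- f[1]
      f <- f[-1]
    }
    num <- suppressWarnings(as.numeric(f))
    if (anyNA(num)) {
      col <- which(is.na(num))[1]
      stop(sprintf("%s: non-numeric value at line %d, column %d", path,
                   r + 1, col + skip_first_field), call. = FALSE)
    }
    vals[r, ] <- num
  }
  colnames(vals) <- if (skip_first_field) header[-1] else header
  if (skip_first_field) rownames(vals) <- row_labels
  vals
}

#' Write / read an ROI time-series TSV
#'
#' One header row of ROI labels, then `T` tab-separated numeric rows.
#'
#' @param series A [roi_time_series()], [clean_series()] or matrix.
#' @param path File path.
#' @return `read_series_tsv` returns the numeric matrix with column labels.
#' @export
write_series_tsv <- function(series, path) {
  x <- series_values(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = "\t"), con)
  utils::write.table(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  parse_numeric_table(path, "\t")
}

#' Write / read a labelled square matrix CSV
#'
#' First column holds row labels; header holds column labels.
#'
#' @param mat Labelled numeric matrix.
#' @param path File path.
#' @return `read_matrix_csv` returns the labelled matrix.
#' @export
write_matrix_csv <- function(mat, path) {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)))
    rownames(mat) <- colnames(mat) %||% paste0("V", seq_len(nrow(mat)))
  df <- cbind(roi = rownames(mat),
              as.data.frame(format(mat, digits = 15, trim = TRUE,
                                   scientific = FALSE)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  vals <- parse_numeric_table(path, ",", skip_first_field = TRUE)
  if (nrow(vals) != ncol(vals))
    stop(sprintf("%s: matrix is not square (%d x %d)", path, nrow(vals),
                 ncol(vals)), call. = FALSE)
  vals
}

#' Write / read a posterior edge list TSV
#'
#' Columns: source, target, probability, expected_partial; one row per
#' unordered ROI pair.
#'
#' @param summary A [run_mcmc()] posterior summary.
#' @param path File path.
#' @return `read_edge_list_tsv` returns the data frame.
#' @export
write_edge_list_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "posterior_summary"))
  idx <- which(upper.tri(summary$edge_probability), arr.ind = TRUE)
  df <- data.frame(source = summary$roi_labels[idx[, 1]],
                   target = summary$roi_labels[idx[, 2]],
                   probability = summary$edge_probability[idx],
                   expected_partial = summary$expected_partials[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list_tsv
#' @export
read_edge_list_tsv <- function(path) {
  fields <- split_table_lines(path, "\t")
  header <- fields[[1]]
  expect <- c("source", "target", "probability", "expected_partial")
  if (!identical(header, expect))
    stop(sprintf("%s: unexpected edge-list header", path), call. = FALSE)
  body <- fields[-1]
  out <- data.frame(source = character(length(body)),
                    target = character(length(body)),
                    probability = numeric(length(body)),
                    expected_partial = numeric(length(body)))
  for (r in seq_along(body)) {
    f <- body[[r]]
    if (length(f) != 4)
      stop(sprintf("%s: line %d has %d fields, expected 4", path, r + 1,
                   length(f)), call. = FALSE)
    num <- suppressWarnings(as.numeric(f[3:4]))
    if (anyNA(num))
      stop(sprintf("%s: non-numeric value at line %d", path, r + 1),
           call. = FALSE)
    out[r, ] <- list(f[1], f[2], num[1], num[2])
  }
  out
}

#' Write / read a JSON report
#'
#' @param x A list of plain values.
#' @param path File path.
#' @return `read_json_report` returns the parsed list.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_report
#' @export
read_json_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
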