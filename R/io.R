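#' Read a labeled numeric matrix from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the extension:
#' `.csv` is comma-separated, anything else tab-separated) whose first row
#' holds column labels and first column holds row labels.  Four kinds of
#' matrix are understood:
#'
#' * `"response"` — cell lines in rows, drugs in columns; empty cells,
#'   `"NA"` or `"NaN"` (case-insensitive) mark unobserved entries, which
#'   become `NA` in the returned matrix.
#' * `"expression"` — genes in rows, cell lines in columns; must be fully
#'   numeric.
#' * `"fingerprint"` — drugs in rows, fingerprint bits in columns; every
#'   entry must be 0 or 1.
#' * `"similarity"` — square and symmetric (within 1e-8), labels on both
#'   axes identical.
#'
#' @param path Path to the file.
#' @param kind One of `"response"`, `"expression"`, `"fingerprint"`,
#'   `"similarity"`.
#' @return A numeric matrix with `dimnames`; unobserved response entries
#'   are `NA`.
#' @seealso [write_labeled_matrix()], [align_inputs()]
#' @export
read_labeled_matrix <- function(path,
                                kind = c("response", "expression",
                                         "fingerprint", "similarity")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) {
    stop("file has no data columns: ", path, call. = FALSE)
  }
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  .check_unique_labels(row_ids, "row", path)
  .check_unique_labels(col_ids, "column", path)

  vals <- as.matrix(raw[, -1L, drop = FALSE])
  dimnames(vals) <- list(row_ids, col_ids)
  out <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))

  missing_tok <- c("", "na", "nan")
  cell <- trimws(vals)
  is_missing <- tolower(cell) %in% missing_tok | is.na(cell)
  dim(is_missing) <- dim(cell)
  num <- suppressWarnings(as.numeric(cell))
  dim(num) <- dim(cell)
  bad <- !is_missing & !is.finite(num) &
    !(tolower(cell) %in% c("inf", "-inf"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 row_ids[idx[1L]], col_ids[idx[2L]], path), call. = FALSE)
  }
  out[!is_missing] <- num[!is_missing]

  if (kind != "response" && any(is_missing)) {
    idx <- which(is_missing, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value not allowed for kind '%s': row '%s', column '%s'",
                 kind, row_ids[idx[1L]], col_ids[idx[2L]]), call. = FALSE)
  }
  if (kind == "fingerprint") {
    nb <- !(out %in% c(0, 1))
    if (any(nb)) {
      dim(nb) <- dim(out)
      idx <- which(nb, arr.ind = TRUE)[1L, ]
      stop(sprintf("fingerprint entries must be 0/1; found %g at row '%s', column '%s'",
                   out[idx[1L], idx[2L]], row_ids[idx[1L]], col_ids[idx[2L]]),
           call. = FALSE)
    }
  }
  if (kind == "similarity") {
    if (nrow(out) != ncol(out) || !identical(rownames(out), colnames(out))) {
      stop("similarity matrix must be square with identical row/column labels",
           call. = FALSE)
    }
    if (max(abs(out - t(out))) > 1e-8) {
      stop("similarity matrix is not symmetric (tolerance 1e-8)",
           call. = FALSE)
    }
  }
  out
}

#' Write a labeled numeric matrix to delimited text
#'
#' Inverse of [read_labeled_matrix()]: values are printed with 17
#' significant digits so that read-after-write is floating-point exact;
#' `NA` entries are written as the literal `NA`.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- matrix(sprintf("%.17g", x), nrow(x))
  fmt[is.na(x)] <- "NA"
  lines <- c(paste(c("", colnames(x)), collapse = sep),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], fmt[i, ]), collapse = sep)
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

.check_unique_labels <- function(ids, what, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s label(s) in %s: %s", what, path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Align response, expression and fingerprint matrices by label
#'
#' Restricts the three inputs to the shared cell lines (response rows
#' intersected with expression columns) and shared drugs (response columns
#' intersected with fingerprint rows), keeping the response matrix's
#' ordering.  Dropped labels are reported via `message()`.  Either feature
#' matrix may be `NULL`, in which case only the other axis is aligned.
#'
#' @param response Cell-line x drug response matrix (`NA` = unobserved).
#' @param expression Genes x cell-lines matrix, or `NULL`.
#' @param fingerprints Drugs x bits binary matrix, or `NULL`.
#' @param quiet Suppress the dropped-label messages.
#' @return A list with elements `response`, `expression`, `fingerprints`.
#' @export
align_inputs <- function(response, expression = NULL, fingerprints = NULL,
                         quiet = FALSE) {
  stopifnot(is.matrix(response))
  cells <- rownames(response)
  drugs <- colnames(response)
  if (!is.null(expression)) {
    keep <- cells[cells %in% colnames(expression)]
    if (!length(keep)) stop("no cell lines shared between response and expression",
                            call. = FALSE)
    .report_drop(setdiff(cells, keep), "cell line", quiet)
    .report_drop(setdiff(colnames(expression), keep), "expression column", quiet)
    cells <- keep
    expression <- expression[, cells, drop = FALSE]
  }
  if (!is.null(fingerprints)) {
    keep <- drugs[drugs %in% rownames(fingerprints)]
    if (!length(keep)) stop("no drugs shared between response and fingerprints",
                            call. = FALSE)
    .report_drop(setdiff(drugs, keep), "drug", quiet)
    .report_drop(setdiff(rownames(fingerprints), keep), "fingerprint row", quiet)
    drugs <- keep
    fingerprints <- fingerprints[drugs, , drop = FALSE]
  }
  response <- response[cells, drugs, drop = FALSE]
  if (!any(is.finite(response))) {
    stop("aligned response matrix has no observed entries", call. = FALSE)
  }
  list(response = response, expression = expression,
       fingerprints = fingerprints)
}

.report_drop <- function(labels, what, quiet) {
  if (length(labels) && !quiet) {
    message(sprintf("dropping %d %s label(s) absent from the intersection: %s",
                    length(labels), what,
                    paste(utils::head(labels, 10L), collapse = ", ")))
  }
  invisible(NULL)
}
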