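#' Read a spike-count matrix from delimited text
#'
#' Expected layout: a header row whose first field is a cell-id column name
#' and whose remaining fields are the ILD levels in dB; one row per cell.
#' A level-descending header is accepted and reordered to ascending.
#'
#' @param path file path.
#' @param sep field separator; `""` sniffs tab vs comma from the header line.
#' @return an [ild_dataset].
#' @export
read_ild_matrix <- function(path, sep = "") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (identical(sep, "")) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expected a cell-id column plus at least 2 levels")
  cell_id <- as.character(df[[1]])
  levels <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(levels)) {
    stop(sprintf("header column %d ('%s') is not a numeric ILD level",
                 which(is.na(levels))[1] + 1, colnames(df)[-1][which(is.na(levels))[1]]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
    stop(sprintf("non-numeric value at row %d (cell '%s'), level %s",
                 bad[1, 1], cell_id[bad[1, 1]], colnames(df)[-1][bad[1, 2]]))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d (cell '%s'), level %s",
                 bad[1], cell_id[bad[1]], colnames(df)[-1][bad[2]]))
  }
  if (all(diff(levels) < 0)) {        # descending header: flip to ascending
    levels <- rev(levels)
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  validate_axis(levels)
  ild_dataset(m, levels, cell_id = cell_id)
}

#' Write a spike-count matrix as delimited text
#'
#' Inverse of [read_ild_matrix()]; `read_ild_matrix(write_ild_matrix(x, f))`
#' reproduces `x` exactly (values are written at full precision).
#'
#' @param x an [ild_dataset] or numeric matrix.
#' @param path output path.
#' @param sep field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_ild_matrix <- function(x, path, sep = "\t") {
  counts <- as_counts(x)
  levels <- if (inherits(x, "ild_dataset")) x$axis else as.numeric(colnames(counts))
  df <- data.frame(cell_id = rownames(counts), counts, check.names = FALSE)
  colnames(df) <- c("cell_id", as.character(levels))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read cluster labels as two-column delimited text
#' @param labels integer vector named by cell id (or unnamed).
#' @param path file path.
#' @rdname labels-io
#' @export
write_labels <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_along(labels))
  utils::write.table(data.frame(cell_id = ids, group = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname labels-io
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$group), df$cell_id)
}
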