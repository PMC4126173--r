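#' Construct an ILD axis
#'
#' An ILD (interaural level difference) axis is the ordered set of dB levels
#' at which a neuron's spike count was sampled. Positive ILDs follow the
#' convention that the sound is louder in the contralateral ear. The default
#' axis spans -30 to +30 dB in 5 dB steps (13 levels).
#'
#' @param lo_db,hi_db range endpoints in dB; both are included.
#' @param step_db level spacing in dB, must divide `hi_db - lo_db`.
#' @return numeric vector of levels with class `"ild_axis"`.
#' @examples
#' ild_axis()            # 13 levels, -30 ... +30
#' ild_axis(0, 10, 10)   # just the endpoints
#' @export
ild_axis <- function(lo_db = -30, hi_db = 30, step_db = 5) {
  stopifnot(is.numeric(lo_db), is.numeric(hi_db), is.numeric(step_db))
  if (!(lo_db < hi_db)) stop("`lo_db` must be strictly less than `hi_db`")
  if (step_db <= 0) stop("`step_db` must be positive")
  n_steps <- (hi_db - lo_db) / step_db
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop(sprintf("range %g..%g dB is not divisible by step %g dB",
                 lo_db, hi_db, step_db))
  }
  levels <- seq(lo_db, hi_db, by = step_db)
  structure(levels, class = "ild_axis", step_db = step_db)
}

#' Bundle a spike-count matrix with its ILD axis
#'
#' The central container of the package: one row per cell, one column per
#' ILD level, entries are spike counts per stimulus (non-negative).
#'
#' @param counts numeric matrix (or coercible), N cells x L levels.
#' @param axis `ild_axis` (or numeric levels) of length `ncol(counts)`.
#' @param cell_id optional character vector of row identifiers.
#' @return list with elements `counts`, `axis`, class `"ild_dataset"`.
#' @export
ild_dataset <- function(counts, axis = ild_axis(), cell_id = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(axis) != ncol(counts)) {
    stop(sprintf("axis has %d levels but counts has %d columns",
                 length(axis), ncol(counts)))
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %d", bad[1], bad[2]))
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative spike count at row %d, column %d", bad[1], bad[2]))
  }
  if (is.null(cell_id)) {
    cell_id <- rownames(counts)
    if (is.null(cell_id)) cell_id <- sprintf("cell_%03d", seq_len(nrow(counts)))
  }
  rownames(counts) <- cell_id
  colnames(counts) <- as.character(as.numeric(axis))
  structure(list(counts = counts, axis = as.numeric(axis)),
            class = "ild_dataset")
}

#' @export
print.ild_dataset <- function(x, ...) {
  cat(sprintf("ILD dataset: %d cells x %d levels (%g to %g dB)\n",
              nrow(x$counts), length(x$axis), min(x$axis), max(x$axis)))
  cat(sprintf("spike counts in [%g, %g]\n", min(x$counts), max(x$counts)))
  invisible(x)
}

#' @export
dim.ild_dataset <- function(x) dim(x$counts)

as_counts <- function(x) {
  if (inherits(x, "ild_dataset")) x$counts else as.matrix(x)
}

validate_axis <- function(levels) {
  if (length(levels) < 2) stop("an ILD axis needs at least 2 levels")
  d <- diff(levels)
  if (any(d <= 0)) stop("ILD levels must be strictly increasing")
  if (max(d) - min(d) > 1e-8 * max(abs(levels), 1)) {
    stop("ILD levels must be uniformly spaced")
  }
  invisible(levels)
}
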