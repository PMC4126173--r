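## Seven data-normalization methods and the prototype test bench that
## scores them. All per-vector statistics (mean, SD, sum, max) are taken
## over one cell's L-level curve; only the global-max method uses a
## matrix-wide reference.

#' The normalization method table
#'
#' @return data.frame with columns `id` (1-7), `name`, `scope`
#'   ("vector" statistics, "global" reference, or "constant").
#' @export
norm_methods <- function() {
  data.frame(
    id = 1:7,
    name = c("mean_correction", "global_max", "vector_max", "vector_sd",
             "log2_mean", "utpm", "zscore"),
    scope = c("vector", "global", "vector", "vector",
              "vector", "vector", "vector"),
    stringsAsFactors = FALSE
  )
}

resolve_method <- function(method) {
  tab <- norm_methods()
  if (is.numeric(method)) {
    i <- match(as.integer(method), tab$id)
  } else {
    i <- match(as.character(method), tab$name)
  }
  if (is.na(i)) stop(sprintf("unknown normalization method: %s", method))
  tab[i, ]
}

#' Normalize a spike-count matrix
#'
#' Implements the seven normalization methods compared on the prototype
#' test bench. With `V` the normalized and `X` the raw value of cell `n`
#' at level `j`, and per-cell mean/SD/sum/max written `mu_n`, `sigma_n`,
#' `sum_n`, `max_n`:
#'
#' 1. `mean_correction`: `V = X - mu_n`
#' 2. `global_max`:      `V = X / max(X over the whole matrix)`
#' 3. `vector_max`:      `V = X / max_n`
#' 4. `vector_sd`:       `V = X / sigma_n`
#' 5. `log2_mean`:       `V = log2(X) - log2(mu_n)` (requires `X > 0`)
#' 6. `utpm`:            `V = X * mu_n / sum_n` — unit total probability
#'    mass; with per-cell `mu_n = sum_n / L` this is exactly `X / L`, a
#'    uniform rescaling that preserves every curve shape and the relative
#'    amplitudes across cells.
#' 7. `zscore`:          `V = (X - mu_n) / sigma_n`
#'
#' @param x an [ild_dataset] or numeric matrix (cells x levels).
#' @param method method id (1-7) or name, see [norm_methods()].
#' @param utpm_mu `"vector"` (default) uses each cell's own mean in the
#'   UTPM formula; `"grand"` uses the grand mean of the matrix.
#' @param log_eps offset added inside the log for method 5 (default 0:
#'   non-positive values are a hard error naming the row).
#' @return numeric matrix of normalized values, same shape and dimnames as
#'   the input counts; attribute `"norm_method"` records the method name.
#' @export
normalize <- function(x, method = "utpm", utpm_mu = c("vector", "grand"),
                      log_eps = 0) {
  utpm_mu <- match.arg(utpm_mu)
  m <- as_counts(x)
  meth <- resolve_method(method)
  if (nrow(m) < 1) stop("empty dataset")
  mu <- rowMeans(m)
  out <- switch(meth$name,
    mean_correction = m - mu,
    global_max = m / max(m),
    vector_max = {
      mx <- apply(m, 1, max)
      if (any(mx == 0)) stop(sprintf("zero maximum in row %d", which(mx == 0)[1]))
      m / mx
    },
    vector_sd = {
      s <- apply(m, 1, stats::sd)
      if (any(s == 0)) stop(sprintf("zero standard deviation in row %d",
                                    which(s == 0)[1]))
      m / s
    },
    log2_mean = {
      if (any(m + log_eps <= 0)) {
        bad <- which(rowSums(m + log_eps <= 0) > 0)[1]
        stop(sprintf("non-positive value in row %d: logarithmic normalization undefined",
                     bad))
      }
      log2(m + log_eps) - log2(mu + log_eps)
    },
    utpm = {
      sm <- rowSums(m)
      if (any(sm == 0)) stop(sprintf("zero row sum in row %d", which(sm == 0)[1]))
      mu_used <- if (utpm_mu == "vector") mu else mean(m)
      m * (mu_used / sm)
    },
    zscore = {
      s <- apply(m, 1, stats::sd)
      if (any(s == 0)) stop(sprintf("zero standard deviation in row %d",
                                    which(s == 0)[1]))
      (m - mu) / s
    }
  )
  structure(out, norm_method = meth$name, norm_id = meth$id)
}

#' Score the seven normalizations on the prototype bench
#'
#' Applies each method to every perturbed prototype panel and records, per
#' (method, panel): the min and max normalized value, a shape-preservation
#' score (the Pearson correlation between the panel's normalized and raw
#' values, stacked over all the panel's curves, so that distortion of
#' relative amplitudes across curves is penalised as well as within-curve
#' distortion), and the dynamic-range compression ratio
#' (normalized max / raw max). Methods that error on a panel (e.g. the
#' logarithmic method on zeros) are recorded as failed for that panel.
#'
#' @param protos an `"ild_prototypes"` object (perturb with [perturb_ild()]
#'   first for the realistic bench).
#' @param methods method ids or names to evaluate (default all seven).
#' @param perturb if `TRUE` (default), apply the standard +/-6% perturbation
#'   before scoring.
#' @param seed seed for the perturbation draw.
#' @return object of class `"ild_bench"`: data.frame `table` with one row
#'   per method x panel, plus the `selected` method name.
#' @export
bench_evaluate <- function(protos, methods = 1:7, perturb = TRUE, seed = NULL) {
  if (length(methods) < 1) stop("no methods to evaluate")
  tab <- norm_methods()
  meths <- do.call(rbind, lapply(methods, resolve_method))
  panels <- protos$panels
  if (perturb) {
    if (!is.null(seed)) set.seed(seed)
    panels <- lapply(panels, perturb_ild, fraction = 0.06,
                     m = protos$m_max, floor = 0.1)
  }
  rows <- list()
  for (k in seq_len(nrow(meths))) {
    for (p in names(panels)) {
      raw <- panels[[p]]
      rec <- data.frame(method = meths$name[k], id = meths$id[k], panel = p,
                        min = NA_real_, max = NA_real_, shape_r = NA_real_,
                        compression = NA_real_, failed = FALSE,
                        stringsAsFactors = FALSE)
      norm <- tryCatch(normalize(raw, meths$id[k]), error = function(e) e)
      if (inherits(norm, "error")) {
        rec$failed <- TRUE
      } else {
        rec$min <- min(norm); rec$max <- max(norm)
        # NA when the method collapses a non-constant panel to a constant
        rec$shape_r <- suppressWarnings(stats::cor(as.vector(raw), as.vector(norm)))
        rec$compression <- max(abs(norm)) / max(abs(raw))
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  table <- do.call(rbind, rows)
  res <- structure(list(table = table), class = "ild_bench")
  res$selected <- select_method(res)
  res
}

#' Select the preferred normalization from a bench report
#'
#' Lexicographic rule: (a) keep methods with no failed panel and a
#' shape-preservation score of at least `shape_min` on every panel (the
#' normalization must not distort curve shapes or relative amplitudes);
#' (b) among those, prefer methods whose reference is local to each cell's
#' vector (or a constant) over methods coupled to the whole matrix, since a
#' single extreme cell must not rescale every other cell; (c) then prefer
#' the strongest dynamic-range compression (smallest worst-case normalized
#' magnitude); (d) remaining ties go to the lower method id.
#'
#' @param report an `"ild_bench"` object.
#' @param shape_min minimum acceptable shape score (default 0.999).
#' @return the selected method name.
#' @export
select_method <- function(report, shape_min = 0.999) {
  tab <- report$table
  if (is.null(tab) || nrow(tab) == 0) stop("empty bench report")
  scope <- stats::setNames(norm_methods()$scope, norm_methods()$name)
  per <- do.call(rbind, lapply(split(tab, tab$method), function(d) {
    data.frame(method = d$method[1], id = d$id[1],
               ok = !any(d$failed) && !anyNA(d$shape_r) &&
                 all(d$shape_r >= shape_min),
               local = unname(scope[d$method[1]]) != "global",
               worst_mag = max(abs(c(d$min, d$max)), na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (nrow(per) == 1) return(per$method)
  cand <- per[per$ok, , drop = FALSE]
  if (nrow(cand) == 0) cand <- per              # nothing passes: fall through
  if (any(cand$local)) cand <- cand[cand$local, , drop = FALSE]
  cand <- cand[order(cand$worst_mag, cand$id), , drop = FALSE]
  cand$method[1]
}

#' @export
print.ild_bench <- function(x, ...) {
  cat("Normalization bench (", length(unique(x$table$panel)), "panels x",
      length(unique(x$table$method)), "methods )\n")
  cat("selected:", x$selected, "\n")
  invisible(x)
}
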