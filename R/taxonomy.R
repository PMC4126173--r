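## Cluster templates and their classification against the four canonical
## ILD function types.

ILD_CLASSES <- c("SIGMOID_EI", "SIGMOID_IE", "PEAKED", "INSENSITIVE",
                 "TRANSITION_PEAK_SIGMOID", "TRANSITION_PEAK_FLAT",
                 "TRANSITION_OTHER")

#' Classification rule parameters
#'
#' Numeric thresholds for [classify_ild_function()]. All thresholds are
#' relative (fractions), so classification is invariant to uniform
#' positive scaling of a curve.
#'
#' @param insensitive_depth modulation-depth cutoff: curves with
#'   `(max - min)/max` below it are INSENSITIVE (default 0.25).
#' @param monotone_frac minimum fraction of direction-consistent
#'   consecutive steps for a sigmoidal call (default 0.9); steps smaller
#'   than 5% of the curve's range count as consistent with either
#'   direction, so the flat tails of a sigmoid do not break monotonicity.
#' @param peak_prominence minimum drop on each flank of an interior
#'   maximum, as a fraction of the curve's range (default 0.5): a genuine
#'   peak must fall at least half-way back on both sides, while a peak
#'   riding on a one-sided high shoulder falls through to the
#'   transitional rules.
#' @param transition_min_cor minimum correlation with the best-matching
#'   transitional reference shape; below it the curve is
#'   TRANSITION_OTHER (default 0.7).
#' @return list of class `"ild_class_rules"`.
#' @export
class_rule_params <- function(insensitive_depth = 0.25, monotone_frac = 0.9,
                              peak_prominence = 0.5, transition_min_cor = 0.7) {
  vals <- c(insensitive_depth, monotone_frac, peak_prominence, transition_min_cor)
  if (any(vals <= 0 | vals >= 1)) stop("all rule thresholds must lie in (0, 1)")
  structure(list(insensitive_depth = insensitive_depth,
                 monotone_frac = monotone_frac,
                 peak_prominence = peak_prominence,
                 transition_min_cor = transition_min_cor),
            class = "ild_class_rules")
}

#' Classify one ILD function
#'
#' Assigns a curve to one of the canonical ILD classes. Order of rules:
#' INSENSITIVE when the modulation depth `(max - min)/max` is below
#' threshold; SIGMOID when the fraction of consecutive steps sharing one
#' sign is high, with the EI/IE side given by the direction of change — an
#' EI cell (excited by the ipsilateral ear, inhibited by the contralateral)
#' responds most at negative ILDs, where the ipsilateral ear is louder, so
#' a decreasing curve is SIGMOID_EI and an increasing one SIGMOID_IE;
#' PEAKED when an interior maximum drops by a sufficient fraction of the
#' range on both flanks; otherwise a TRANSITION label by correlation with
#' peak-to-sigmoid and peak-to-flat reference blends.
#'
#' @param curve numeric vector of spike counts.
#' @param levels ILD levels matching `curve` (default the standard axis).
#' @param params an [class_rule_params()] list.
#' @return a single class label (character).
#' @export
classify_ild_function <- function(curve, levels = ild_axis(),
                                  params = class_rule_params()) {
  x <- as.numeric(levels)
  if (length(curve) != length(x)) stop("curve and axis lengths differ")
  if (all(curve == 0)) {
    warning("all-zero curve: classified INSENSITIVE")
    return("INSENSITIVE")
  }
  rng <- max(curve) - min(curve)
  if (rng / max(curve) < params$insensitive_depth) return("INSENSITIVE")

  d <- diff(curve)
  tol <- 0.05 * rng                  # deadband: near-flat steps are neutral
  mono_frac <- max(sum(d >= -tol), sum(d <= tol)) / length(d)
  if (mono_frac >= params$monotone_frac) {
    return(if (sum(d) >= 0) "SIGMOID_IE" else "SIGMOID_EI")
  }

  imax <- which.max(curve)
  if (imax > 1 && imax < length(curve)) {
    left_drop <- max(curve) - min(curve[1:imax])
    right_drop <- max(curve) - min(curve[imax:length(curve)])
    if (left_drop >= params$peak_prominence * rng &&
        right_drop >= params$peak_prominence * rng) {
      return("PEAKED")
    }
  }

  refs <- list(
    TRANSITION_PEAK_SIGMOID = 0.5 * ild_peak(x, x0 = 0, w = 10) +
      0.5 * ild_sigmoid(x, x0 = 0, s = 5, direction = 1),
    TRANSITION_PEAK_SIGMOID_m = 0.5 * ild_peak(x, x0 = 0, w = 10) +
      0.5 * ild_sigmoid(x, x0 = 0, s = 5, direction = -1),
    TRANSITION_PEAK_FLAT = 0.5 * ild_peak(x, x0 = 0, w = 8) +
      0.5 * ild_flat(x, m = 50)
  )
  r <- vapply(refs, function(ref) suppressWarnings(stats::cor(curve, ref)), 0)
  r[is.na(r)] <- -1
  best <- names(refs)[which.max(r)]
  if (max(r) < params$transition_min_cor) return("TRANSITION_OTHER")
  if (best == "TRANSITION_PEAK_SIGMOID_m") best <- "TRANSITION_PEAK_SIGMOID"
  best
}

#' Per-cluster mean templates
#'
#' Averages the member curves of every cluster into a template ILD
#' function, the per-cluster representative used for downstream modelling.
#'
#' @param dataset an [ild_dataset].
#' @param solution an `"ild_clusters"` object (or bare integer labels)
#'   covering every row of `dataset`.
#' @param params classification rule thresholds.
#' @return object of class `"ild_templates"`: `templates` (k x L matrix of
#'   mean spike counts), `counts` (members per cluster), `classes`
#'   (per-template label), `axis`.
#' @export
cluster_templates <- function(dataset, solution, params = class_rule_params()) {
  labels <- if (inherits(solution, "ild_clusters")) solution$labels else as.integer(solution)
  m <- as_counts(dataset)
  if (length(labels) != nrow(m)) stop("labels do not cover all rows")
  ids <- sort(unique(labels))
  if (!identical(ids, seq_len(max(ids)))) stop("cluster ids must be 1..k with no gaps")
  templates <- do.call(rbind, lapply(ids, function(g) colMeans(m[labels == g, , drop = FALSE])))
  rownames(templates) <- sprintf("cluster_%d", ids)
  axis <- if (inherits(dataset, "ild_dataset")) dataset$axis else as.numeric(colnames(m))
  classes <- apply(templates, 1, classify_ild_function, levels = axis, params = params)
  structure(list(templates = templates,
                 counts = as.integer(table(factor(labels, levels = ids))),
                 classes = unname(classes), axis = axis),
            class = "ild_templates")
}

#' @export
print.ild_templates <- function(x, ...) {
  k <- nrow(x$templates)
  cat(sprintf("%d templates (%s members): %s\n", k,
              paste(x$counts, collapse = "/"),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Assemble the taxonomy report
#'
#' Gathers the headline result of one pipeline run into a single
#' JSON-serializable structure: the normalization used, the variance
#' percentages and retained component count, the selected metric/linkage
#' pair with its CCC, the flat clustering with membership counts, the
#' per-cluster templates and class labels, and the retained PC scores for
#' external scatter plotting.
#'
#' @param templates an `"ild_templates"` object.
#' @param grid an `"ild_ccc_grid"` object.
#' @param pca an `"ild_pca"` object.
#' @param solution an `"ild_clusters"` object.
#' @param normalization normalization method name used.
#' @param n_pc number of retained components.
#' @return list of class `"ild_report"`.
#' @export
build_report <- function(templates, grid, pca, solution,
                         normalization = "utpm", n_pc = 3) {
  n <- length(solution$labels)
  if (ncol(pca$scores) != n) stop("PCA and clustering cover different cell counts")
  if (sum(templates$counts) != n) stop("template member counts do not sum to N")
  structure(list(
    n_cells = n,
    normalization = normalization,
    variance_pct = as.numeric(pca$variance_pct),
    n_components = as.integer(n_pc),
    metric = grid$best_metric,
    linkage = grid$best_linkage,
    ccc = grid$best_ccc,
    ccc_grid = grid$grid,
    k = solution$k,
    counts = solution$counts,
    labels = solution$labels,
    classes = templates$classes,
    templates = templates$templates,
    axis = templates$axis,
    scores = pca$scores[seq_len(n_pc), , drop = FALSE],
    pct_non_insensitive =
      100 * sum(solution$counts[templates$classes != "INSENSITIVE"]) / n
  ), class = "ild_report")
}

#' @export
print.ild_report <- function(x, ...) {
  cat(sprintf("ILD taxonomy report: %d cells, %s normalization\n",
              x$n_cells, x$normalization))
  cat(sprintf("  PC1-%d explain %.3f%% (%s)\n", x$n_components,
              sum(x$variance_pct[seq_len(x$n_components)]),
              paste(sprintf("%.3f", x$variance_pct[seq_len(x$n_components)]),
                    collapse = " / ")))
  cat(sprintf("  clustering: %s + %s, CCC = %.5f\n", x$metric, x$linkage, x$ccc))
  cat(sprintf("  k = %d clusters, counts %s\n", x$k,
              paste(x$counts, collapse = "/")))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  %.1f%% of cells in non-insensitive clusters\n",
              x$pct_non_insensitive))
  invisible(x)
}

#' Write / read a taxonomy report as JSON
#'
#' The on-disk form is plain JSON; `read_report()` restores the matrices
#' and the class attribute so a round trip is lossless.
#'
#' @param report an `"ild_report"`.
#' @param path file path.
#' @rdname report-io
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$ccc_grid <- list(values = unname(out$ccc_grid),
                       metrics = rownames(out$ccc_grid),
                       linkages = colnames(out$ccc_grid))
  out$templates <- list(values = unname(out$templates),
                        names = rownames(out$templates))
  out$scores <- list(values = unname(out$scores),
                     cells = colnames(out$scores))
  out$labels <- list(values = unname(out$labels), cells = names(out$labels))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname report-io
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ccc_grid <- matrix(unlist(x$ccc_grid$values), length(x$ccc_grid$metrics),
                       byrow = FALSE,
                       dimnames = list(x$ccc_grid$metrics, x$ccc_grid$linkages))
  x$templates <- matrix(unlist(x$templates$values), length(x$templates$names),
                        dimnames = list(x$templates$names,
                                        as.character(x$axis)))
  sc <- x$scores
  x$scores <- matrix(unlist(sc$values), ncol = length(sc$cells),
                     dimnames = list(sprintf("PC%d", seq_len(x$n_components)),
                                     sc$cells))
  x$labels <- stats::setNames(as.integer(x$labels$values), x$labels$cells)
  x$counts <- as.integer(x$counts)
  structure(x, class = "ild_report")
}
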