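## Agglomerative clustering: linkage trees, cophenetic correlation over the
## metric x linkage grid, the inconsistency coefficient, and dendrogram
## cutting by cluster count or inconsistency threshold.

ILD_LINKAGES <- c("single", "average", "complete", "ward")

hclust_method <- function(linkage) {
  switch(match.arg(linkage, ILD_LINKAGES),
         single = "single", average = "average", complete = "complete",
         ward = "ward.D2")   # Lance-Williams on squared distances, sqrt heights
}

#' Build an agglomerative linkage tree
#'
#' Merges the N items in N-1 agglomerative steps using the requested
#' linkage (`single`, `average`, `complete`, `ward`). Ward linkage is
#' applied through the Lance-Williams update on squared dissimilarities
#' with square-root heights, the convention of the legacy clustering
#' toolboxes; it accepts any dissimilarity, including cosine.
#'
#' @param dm a `stats::dist` object (see [pairwise_distances()]).
#' @param linkage linkage method name.
#' @return object of class `"ild_linkage"`: the underlying `hclust` fit
#'   plus a `merges` data.frame (`left`, `right`, `height`, `size`) in
#'   which leaves are numbered `1..N` and internal nodes `N+1..2N-1` in
#'   merge order.
#' @export
linkage <- function(dm, linkage = "ward") {
  n <- attr(dm, "Size")
  if (is.null(n) || n < 2) stop("need a dist object over at least 2 items")
  hc <- stats::hclust(dm, method = hclust_method(linkage))
  merges <- hclust_merge_table(hc)
  structure(list(hclust = hc, merges = merges, n = as.integer(n),
                 linkage = match.arg(linkage, ILD_LINKAGES),
                 metric = attr(dm, "metric")),
            class = "ild_linkage")
}

# hclust merge matrix (negative = leaf) -> flat node table with leaves 1..N,
# internal nodes N+1..2N-1 in merge order.
hclust_merge_table <- function(hc) {
  n <- length(hc$height) + 1L
  conv <- function(v) ifelse(v < 0, -v, v + n)
  sizes <- integer(n - 1L)
  node_size <- function(id) if (id <= n) 1L else sizes[id - n]
  left <- conv(hc$merge[, 1]); right <- conv(hc$merge[, 2])
  for (k in seq_len(n - 1L)) sizes[k] <- node_size(left[k]) + node_size(right[k])
  data.frame(left = left, right = right, height = hc$height, size = sizes)
}

#' @export
print.ild_linkage <- function(x, ...) {
  cat(sprintf("linkage tree: %d items, %d merges, %s linkage%s\n",
              x$n, nrow(x$merges), x$linkage,
              if (is.null(x$metric)) "" else paste0(" on ", x$metric, " distances")))
  invisible(x)
}

#' Cophenetic distances and correlation
#'
#' The cophenetic distance of a pair of items is the height of the lowest
#' merge joining them; the cophenetic correlation coefficient (CCC) is the
#' Pearson correlation between the original and the cophenetic condensed
#' distances, and measures how faithfully a dendrogram preserves the
#' pairwise dissimilarities.
#'
#' @param tree an `"ild_linkage"` object.
#' @param dm the `dist` the tree was built from.
#' @return list with `ccc` and `cophenetic` (a `dist`).
#' @export
cophenetic_ccc <- function(tree, dm) {
  if (attr(dm, "Size") != tree$n) stop("tree and distance matrix sizes differ")
  coph <- stats::cophenetic(tree$hclust)
  if (stats::sd(coph) == 0 || stats::sd(dm) == 0) {
    # degenerate case: with no spread the correlation is 0/0; report a
    # perfect score when the tree reproduces the distances exactly
    if (max(abs(coph - dm)) <= 1e-10 * max(abs(dm), 1)) {
      return(list(ccc = 1, cophenetic = coph))
    }
    warning("zero variance in distances: CCC undefined")
    return(list(ccc = NA_real_, cophenetic = coph))
  }
  list(ccc = stats::cor(as.vector(coph), as.vector(dm)), cophenetic = coph)
}

#' Cophenetic correlation over the 6 x 4 metric-linkage grid
#'
#' Evaluates all 24 combinations of the six distance metrics and four
#' linkage methods and records the CCC of each; the maximizing pair is the
#' recommended clustering algorithm. Combinations that fail (e.g. a
#' degenerate metric) are recorded as `NA` with the error message kept in
#' attribute `"failures"`. Ties on the maximum go to the earliest pair in
#' the documented metric-then-linkage order.
#'
#' @param x observation matrix (rows = items), e.g. `t(project(pca, 3))`.
#' @param metrics,linkages subsets of the metric / linkage names.
#' @param p Minkowski order.
#' @return object of class `"ild_ccc_grid"`: `grid` (metrics x linkages
#'   matrix of CCCs), `best_metric`, `best_linkage`, `best_ccc`.
#' @export
ccc_grid <- function(x, metrics = ILD_METRICS, linkages = ILD_LINKAGES, p = 2) {
  m <- as_counts(x)
  grid <- matrix(NA_real_, length(metrics), length(linkages),
                 dimnames = list(metrics, linkages))
  failures <- list()
  for (met in metrics) {
    dm <- tryCatch(pairwise_distances(m, met, p = p), error = function(e) e)
    if (inherits(dm, "error")) {
      failures[[met]] <- conditionMessage(dm)
      next
    }
    for (lnk in linkages) {
      val <- tryCatch(cophenetic_ccc(linkage(dm, lnk), dm)$ccc,
                      error = function(e) e)
      if (inherits(val, "error")) {
        failures[[paste(met, lnk, sep = "/")]] <- conditionMessage(val)
      } else {
        grid[met, lnk] <- val
      }
    }
  }
  if (all(is.na(grid))) stop("no metric/linkage combination succeeded")
  best <- which(grid == max(grid, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(grid = grid,
                 best_metric = metrics[best[1]],
                 best_linkage = linkages[best[2]],
                 best_ccc = grid[best[1], best[2]]),
            failures = failures, class = "ild_ccc_grid")
}

#' @export
print.ild_ccc_grid <- function(x, ...) {
  print(round(x$grid, 5))
  cat(sprintf("best: %s + %s (CCC = %.5f)\n",
              x$best_metric, x$best_linkage, x$best_ccc))
  invisible(x)
}

#' Inconsistency coefficient of every merge
#'
#' For each merge, collects the heights of all links within `depth` levels
#' below it (the link itself at level 1, its child links at level 2, and so
#' on) and reports the z-score of the link's height against that window:
#' `(height - mean) / sd`. A window of a single link, or one with zero
#' height spread, yields a coefficient of 0.
#'
#' @param tree an `"ild_linkage"` object.
#' @param depth window depth in levels (default 3).
#' @return data.frame with one row per merge: `height`, `mean`, `sd`,
#'   `n_links`, `coefficient`.
#' @export
inconsistency <- function(tree, depth = 3) {
  stopifnot(depth >= 1)
  mt <- tree$merges
  n <- tree$n
  nm <- nrow(mt)
  window_heights <- function(node, d) {
    if (node <= n || d < 1) return(numeric(0))
    k <- node - n
    c(mt$height[k],
      window_heights(mt$left[k], d - 1L),
      window_heights(mt$right[k], d - 1L))
  }
  out <- data.frame(height = mt$height, mean = NA_real_, sd = NA_real_,
                    n_links = NA_integer_, coefficient = NA_real_)
  for (k in seq_len(nm)) {
    h <- window_heights(n + k, depth)
    mu <- mean(h); s <- stats::sd(h)
    out$mean[k] <- mu
    out$sd[k] <- if (length(h) > 1) s else 0
    out$n_links[k] <- length(h)
    out$coefficient[k] <- if (length(h) > 1 && s > 0) (mt$height[k] - mu) / s else 0
  }
  out
}

#' Cut a linkage tree into flat clusters
#'
#' Exactly one of `k` and `inconsistency_threshold` must be supplied.
#' With `k`, the tree is cut to yield exactly `k` clusters. With a
#' threshold, clusters are the maximal subtrees none of whose internal
#' links has an inconsistency coefficient above the threshold; links more
#' inconsistent than the threshold are treated as boundaries between
#' natural groups.
#'
#' @param tree an `"ild_linkage"` object.
#' @param k desired number of clusters.
#' @param inconsistency_threshold coefficient cutoff.
#' @param depth inconsistency window depth (default 3).
#' @return object of class `"ild_clusters"`: integer `labels` (1..k, named
#'   by item when the tree has labels; cluster ids ordered by first member
#'   appearance), `k`, and `counts`.
#' @export
cut_tree <- function(tree, k = NULL, inconsistency_threshold = NULL, depth = 3) {
  if (is.null(k) == is.null(inconsistency_threshold)) {
    stop("supply exactly one of `k` and `inconsistency_threshold`")
  }
  n <- tree$n
  if (!is.null(k)) {
    stopifnot(k >= 1, k <= n)
    raw <- stats::cutree(tree$hclust, k = k)
  } else {
    coef <- inconsistency(tree, depth)$coefficient
    mt <- tree$merges
    ok <- logical(nrow(mt))           # subtree entirely below threshold?
    node_ok <- function(node) if (node <= n) TRUE else ok[node - n]
    for (j in seq_len(nrow(mt))) {    # children precede parents in merge order
      ok[j] <- coef[j] <= inconsistency_threshold &&
        node_ok(mt$left[j]) && node_ok(mt$right[j])
    }
    raw <- integer(n)
    nxt <- 0L
    leaves_under <- function(node) {
      if (node <= n) return(node)
      j <- node - n
      c(leaves_under(mt$left[j]), leaves_under(mt$right[j]))
    }
    assign_node <- function(node) {
      if (node <= n) {
        nxt <<- nxt + 1L
        raw[node] <<- nxt
      } else if (ok[node - n]) {
        nxt <<- nxt + 1L
        raw[leaves_under(node)] <<- nxt
      } else {
        j <- node - n
        assign_node(mt$left[j]); assign_node(mt$right[j])
      }
    }
    assign_node(n + nrow(mt))
  }
  # relabel 1..k by first appearance for determinism
  first <- match(unique(raw), raw)
  labels <- match(raw, raw[sort(first)])
  names(labels) <- tree$hclust$labels
  structure(list(labels = labels, k = max(labels),
                 counts = as.integer(table(labels))),
            class = "ild_clusters")
}

#' @export
print.ild_clusters <- function(x, ...) {
  cat(sprintf("%d clusters over %d items; counts: %s\n",
              x$k, length(x$labels), paste(x$counts, collapse = "/")))
  invisible(x)
}

#' Export a linkage tree
#'
#' `write_merge_table()` writes the 4-column merge record (left, right,
#' height, size; leaves `1..N`, internal nodes `N+1..2N-1`) as delimited
#' text, bit-exact. `write_newick()` writes the dendrogram in Newick form
#' with branch lengths equal to merge-height differences.
#'
#' @param tree an `"ild_linkage"` object.
#' @param path output path.
#' @rdname tree-export
#' @export
write_merge_table <- function(tree, path) {
  df <- tree$merges
  df$height <- sprintf("%.17g", df$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tree-export
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
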