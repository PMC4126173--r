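## End-to-end orchestration of the three-step classification:
## normalize -> PCA/project -> CCC grid/linkage -> cut -> templates/report.

#' Run the full ILD classification pipeline
#'
#' Executes the three-step flow on a spike-count dataset: (1) normalization
#' (a fixed method, or bench-selected from the prototype test bench);
#' (2) covariance PCA with a fixed or rule-selected component count, and
#' projection onto the retained components; (3) pairwise distances and
#' agglomerative linkage, with the metric/linkage pair either fixed or
#' selected by cophenetic correlation over the 6 x 4 grid, followed by a
#' dendrogram cut by cluster count or by inconsistency threshold;
#' finally per-cluster templates are averaged and classified. Identical
#' config and seed give identical output.
#'
#' @param dataset an [ild_dataset] (e.g. from [read_ild_matrix()] or
#'   [simulate_survey()]).
#' @param normalization method id/name, or `"bench"` to run the prototype
#'   test bench and use its selected method.
#' @param n_pc number of components to retain, or `NULL` to apply
#'   `pc_rule`.
#' @param pc_rule,pc_threshold component-count rule and its threshold,
#'   see [select_n_components()].
#' @param metric,linkage_method fixed distance/linkage pair; both `"ccc"`
#'   (default) selects the pair maximizing the cophenetic correlation.
#' @param k cluster count for the cut; set `NULL` and give
#'   `inconsistency_threshold` to cut by inconsistency instead.
#' @param inconsistency_threshold optional coefficient cutoff.
#' @param depth inconsistency window depth (default 3).
#' @param cluster_on `"scores"` (default: cluster the retained PC scores)
#'   or `"curves"` (cluster normalized curves directly).
#' @param seed integer seed covering every stochastic step (the bench
#'   perturbation).
#' @param out_dir optional directory; when given, every intermediate is
#'   written there as delimited text / JSON.
#' @param verbose print stage-by-stage headline numbers.
#' @return an `"ild_report"` (see [build_report()]).
#' @export
run_pipeline <- function(dataset,
                         normalization = "utpm",
                         n_pc = 3, pc_rule = "explained_variance",
                         pc_threshold = 95,
                         metric = "ccc", linkage_method = "ccc",
                         k = 7, inconsistency_threshold = NULL, depth = 3,
                         cluster_on = c("scores", "curves"),
                         seed = NULL, out_dir = NULL, verbose = FALSE) {
  cluster_on <- match.arg(cluster_on)
  if (!is.null(seed)) set.seed(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  # stage 1: normalization --------------------------------------------------
  norm_name <- normalization
  if (identical(normalization, "bench")) {
    bench <- bench_evaluate(make_prototypes())
    norm_name <- bench$selected
    say("stage 1: bench selected '%s'", norm_name)
    if (!is.null(out_dir)) {
      utils::write.csv(bench$table, file.path(out_dir, "bench_report.csv"),
                       row.names = FALSE)
    }
  }
  normed <- tryCatch(
    normalize(dataset, norm_name),
    error = function(e) stop("stage 1 (normalization): ", conditionMessage(e),
                             call. = FALSE))
  norm_name <- attr(normed, "norm_method")
  say("stage 1: normalized %d cells with '%s'", nrow(normed), norm_name)
  if (!is.null(out_dir)) write_ild_matrix(normed, file.path(out_dir, "normalized.tsv"))

  # stage 2: PCA ------------------------------------------------------------
  pca <- fit_pca(normed)
  if (is.null(n_pc)) {
    n_pc <- select_n_components(pca, rule = pc_rule, threshold = pc_threshold)
  }
  scores <- project(pca, n_pc)
  say("stage 2: PC1-%d explain %.3f%% (%s)", n_pc,
      sum(pca$variance_pct[seq_len(n_pc)]),
      paste(sprintf("%.3f", pca$variance_pct[seq_len(n_pc)]), collapse = " / "))
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(component = seq_along(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues,
                                variance_pct = pca$variance_pct),
                     file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
    utils::write.csv(t(scores), file.path(out_dir, "pc_scores.csv"))
  }

  # stage 3: clustering -----------------------------------------------------
  items <- if (cluster_on == "scores") t(scores) else normed
  if (identical(metric, "ccc") || identical(linkage_method, "ccc")) {
    grid <- ccc_grid(items)
  } else {
    dm0 <- pairwise_distances(items, metric)
    grid <- structure(list(
      grid = matrix(cophenetic_ccc(linkage(dm0, linkage_method), dm0)$ccc,
                    1, 1, dimnames = list(metric, linkage_method)),
      best_metric = metric, best_linkage = linkage_method,
      best_ccc = NA_real_), class = "ild_ccc_grid")
    grid$best_ccc <- grid$grid[1, 1]
  }
  say("stage 3: %s + %s (CCC = %.5f)",
      grid$best_metric, grid$best_linkage, grid$best_ccc)
  dm <- pairwise_distances(items, grid$best_metric)
  tree <- linkage(dm, grid$best_linkage)
  solution <- cut_tree(tree, k = k,
                       inconsistency_threshold = inconsistency_threshold,
                       depth = depth)
  say("stage 3: k = %d, counts %s", solution$k,
      paste(solution$counts, collapse = "/"))
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(grid$grid), file.path(out_dir, "ccc_grid.csv"))
    write_merge_table(tree, file.path(out_dir, "merges.tsv"))
    write_newick(tree, file.path(out_dir, "dendrogram.nwk"))
    utils::write.csv(inconsistency(tree, depth),
                     file.path(out_dir, "inconsistency.csv"), row.names = FALSE)
    write_labels(solution$labels, file.path(out_dir, "labels.tsv"))
  }

  # taxonomy ----------------------------------------------------------------
  templates <- cluster_templates(dataset, solution)
  report <- build_report(templates, grid, pca, solution,
                         normalization = norm_name, n_pc = n_pc)
  say("taxonomy: %s", paste(templates$classes, collapse = ", "))
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(cluster = rownames(templates$templates),
                                class = templates$classes,
                                members = templates$counts,
                                templates$templates, check.names = FALSE),
                     file.path(out_dir, "templates.csv"), row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}
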