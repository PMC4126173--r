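test_that("distance metrics match their defining formulas", {
  m <- rbind(c(0, 0), c(3, 4))
  expect_equal(as.numeric(pairwise_distances(m, "euclidean")), 5)
  expect_equal(as.numeric(pairwise_distances(m, "cityblock")), 7)

  # cosine: zero against positive multiples of the same vector
  m2 <- rbind(c(1, 2, 3), c(2, 4, 6), c(-1, -2, -3))
  dc <- as.matrix(pairwise_distances(m2, "cosine"))
  expect_equal(dc[1, 2], 0, tolerance = 1e-12)
  expect_equal(dc[1, 3], 2, tolerance = 1e-12)
  expect_error(pairwise_distances(rbind(c(0, 0), c(1, 1)), "cosine"),
               "zero-norm row 1")

  # minkowski p = 2 equals euclidean; both match a double-loop oracle
  set.seed(11)
  r <- matrix(stats::rnorm(8 * 5), 8, 5)
  expect_equal(as.numeric(pairwise_distances(r, "minkowski", p = 2)),
               as.numeric(pairwise_distances(r, "euclidean")), tolerance = 1e-12)
  expect_equal(as.numeric(pairwise_distances(r, "minkowski", p = 3)),
               as.numeric(brute_minkowski(r, 3)), tolerance = 1e-12)

  # seuclidean standardizes by per-dimension unbiased variance
  v <- apply(r, 2, stats::var)
  expect_equal(as.numeric(pairwise_distances(r, "seuclidean")),
               as.numeric(stats::dist(sweep(r, 2, sqrt(v), "/"))),
               tolerance = 1e-12)

  # mahalanobis reduces to euclidean for identity covariance (whitened data)
  set.seed(12)
  w <- matrix(stats::rnorm(200 * 3), 200, 3)
  w <- w %*% solve(chol(stats::cov(w)))    # exact identity sample covariance
  expect_equal(as.numeric(pairwise_distances(w, "mahalanobis")),
               as.numeric(pairwise_distances(w, "euclidean")), tolerance = 1e-6)
  expect_warning(pairwise_distances(cbind(r, r[, 1]), "mahalanobis"),
                 "pseudo-inverse")
})

test_that("3-point single linkage matches exhaustive enumeration", {
  # d(a,b) = 1, d(a,c) = 2, d(b,c) = 3: of the three possible first merges,
  # (a,b) at height 1 is minimal, then c joins at min(d(a,c), d(b,c)) = 2
  d <- stats::as.dist(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
  tree <- linkage(d, "single")
  expect_equal(nrow(tree$merges), 2)
  expect_equal(sort(c(tree$merges$left[1], tree$merges$right[1])), c(1, 2))
  expect_equal(tree$merges$height, c(1, 2))
  expect_equal(tree$merges$size, c(2L, 3L))
})

test_that("linkage produces N-1 monotone merges for all four methods", {
  set.seed(13)
  m <- matrix(stats::rnorm(40 * 3), 40, 3)
  dm <- pairwise_distances(m, "euclidean")
  for (lnk in c("single", "average", "complete", "ward")) {
    tree <- linkage(dm, lnk)
    expect_equal(nrow(tree$merges), 39)
    expect_true(all(diff(tree$merges$height) >= -1e-12))
    expect_equal(tree$merges$size[39], 40L)   # root holds everything
  }
  expect_error(linkage(stats::dist(1), "single"), "at least 2")
})

test_that("cophenetic distances match the lowest-common-merge oracle and are ultrametric", {
  set.seed(14)
  for (trial in 1:5) {
    n <- sample(4:8, 1)
    m <- matrix(stats::rnorm(n * 3), n, 3)
    dm <- pairwise_distances(m, "euclidean")
    for (lnk in c("single", "average", "complete", "ward")) {
      tree <- linkage(dm, lnk)
      got <- cophenetic_ccc(tree, dm)
      oracle <- brute_cophenetic(tree)
      expect_equal(as.numeric(got$cophenetic), as.numeric(oracle),
                   tolerance = 1e-10)
      expect_equal(got$ccc, stats::cor(as.numeric(dm), as.numeric(oracle)),
                   tolerance = 1e-10)
      expect_true(got$ccc >= -1 && got$ccc <= 1)
      expect_ultrametric(got$cophenetic)
    }
  }
})

test_that("single-linkage cophenetic distances equal minimax path distances", {
  set.seed(15)
  m <- matrix(stats::rnorm(8 * 4), 8, 4)
  dm <- pairwise_distances(m, "euclidean")
  tree <- linkage(dm, "single")
  expect_equal(as.numeric(cophenetic_ccc(tree, dm)$cophenetic),
               as.numeric(brute_minimax(dm)), tolerance = 1e-10)
})

test_that("equidistant points are already ultrametric: CCC is 1", {
  d <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  tree <- linkage(d, "average")
  expect_equal(cophenetic_ccc(tree, d)$ccc, 1)
})

test_that("the CCC grid covers 24 combinations and is permutation-stable", {
  sim <- simulate_survey(n_cells = 60, proportions = c(18, 5, 10, 7, 6, 4, 10),
                         seed = 16)
  scores <- t(project(fit_pca(normalize(sim$dataset, "utpm")), 3))
  grid <- ccc_grid(scores)
  expect_equal(dim(grid$grid), c(6L, 4L))
  expect_true(all(grid$grid >= -1 & grid$grid <= 1, na.rm = TRUE))
  expect_equal(grid$best_ccc, max(grid$grid, na.rm = TRUE))

  # restricting to one combination reproduces the direct computation
  g1 <- ccc_grid(scores, metrics = "cosine", linkages = "ward")
  dm <- pairwise_distances(scores, "cosine")
  direct <- cophenetic_ccc(linkage(dm, "ward"), dm)$ccc
  expect_equal(g1$grid[1, 1], direct)
  expect_equal(g1$best_metric, "cosine")

  # row permutation must not change the argmax or the clustering (up to labels)
  set.seed(17)
  perm <- sample(nrow(scores))
  grid_p <- ccc_grid(scores[perm, ])
  expect_equal(grid_p$best_metric, grid$best_metric)
  expect_equal(grid_p$best_linkage, grid$best_linkage)
  cut_o <- cut_tree(linkage(pairwise_distances(scores, grid$best_metric),
                            grid$best_linkage), k = 7)
  cut_p <- cut_tree(linkage(pairwise_distances(scores[perm, ], grid$best_metric),
                            grid$best_linkage), k = 7)
  expect_equal(ari(cut_o$labels[perm], cut_p$labels), 1)
})

test_that("inconsistency matches a hand computation and zeroes degenerate windows", {
  # points on a line at 0, 1, 3, 10; single linkage merges at heights 1, 2, 7
  d <- stats::dist(c(0, 1, 3, 10))
  tree <- linkage(d, "single")
  expect_equal(tree$merges$height, c(1, 2, 7))
  inc <- inconsistency(tree, depth = 2)
  # windows: {1}; {2,1}; {7,2} -> z-scores 0, (2-1.5)/sd(c(2,1)), (7-4.5)/sd(c(7,2))
  expect_equal(inc$coefficient,
               c(0, (2 - 1.5) / stats::sd(c(2, 1)), (7 - 4.5) / stats::sd(c(7, 2))))
  expect_equal(inc$n_links, c(1L, 2L, 2L))
  # depth 3 widens the last window to {7, 2, 1}
  inc3 <- inconsistency(tree, depth = 3)
  expect_equal(inc3$coefficient[3], (7 - mean(c(7, 2, 1))) / stats::sd(c(7, 2, 1)))

  # equal-height tree: every coefficient is zero
  de <- stats::as.dist(matrix(1, 4, 4) - diag(4))
  te <- linkage(de, "single")
  expect_true(all(inconsistency(te, depth = 3)$coefficient == 0))
})

test_that("tree cutting respects k and the inconsistency threshold", {
  set.seed(18)
  m <- rbind(matrix(stats::rnorm(20 * 2, 0), 20, 2),
             matrix(stats::rnorm(20 * 2, 8), 20, 2),
             matrix(stats::rnorm(20 * 2, 16), 20, 2))
  dm <- pairwise_distances(m, "euclidean")
  tree <- linkage(dm, "ward")
  expect_error(cut_tree(tree), "exactly one")
  expect_error(cut_tree(tree, k = 3, inconsistency_threshold = 1), "exactly one")

  expect_equal(cut_tree(tree, k = 1)$counts, 60L)
  expect_equal(sort(unique(cut_tree(tree, k = 60)$labels)), 1:60)
  for (k in c(2, 3, 7, 25)) {
    sol <- cut_tree(tree, k = k)
    expect_equal(sol$k, k)
    expect_equal(sum(sol$counts), 60L)
    expect_true(all(sol$counts > 0))
  }
  sol3 <- cut_tree(tree, k = 3)
  truth <- rep(1:3, each = 20)
  expect_equal(ari(sol3$labels, truth), 1)

  # an aggressive threshold keeps everything together; a permissive one
  # splits at the inconsistent (between-blob) links
  all_one <- cut_tree(tree, inconsistency_threshold = 1e6)
  expect_equal(all_one$k, 1L)
  split <- cut_tree(tree, inconsistency_threshold = 1.0, depth = 3)
  expect_gte(split$k, 3L)
  expect_equal(sum(split$counts), 60L)
})

test_that("merge tables and Newick exports are faithful", {
  set.seed(19)
  m <- matrix(stats::rnorm(10 * 3), 10, 3)
  rownames(m) <- letters[1:10]
  dm <- pairwise_distances(m, "euclidean")
  tree <- linkage(dm, "average")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_merge_table(tree, f)
  back <- utils::read.table(f, header = TRUE)
  expect_equal(back$height, tree$merges$height, tolerance = 0)  # bit-exact
  expect_equal(back$left, tree$merges$left)

  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  phy <- ape::read.tree(nwk)
  expect_equal(sort(phy$tip.label), sort(letters[1:10]))
  # leaf-to-leaf path length equals the cophenetic merge height
  coph <- as.matrix(cophenetic_ccc(tree, dm)$cophenetic)
  pd <- ape::cophenetic.phylo(phy)[rownames(coph), colnames(coph)]
  expect_equal(pd, coph, tolerance = 1e-6)
})
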