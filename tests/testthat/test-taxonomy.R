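ax <- ild_axis()
x <- as.numeric(ax)

test_that("canonical curves receive their canonical labels", {
  expect_equal(classify_ild_function(ild_flat(x, 40), ax), "INSENSITIVE")
  expect_warning(lab <- classify_ild_function(rep(0, 13), ax), "all-zero")
  expect_equal(lab, "INSENSITIVE")

  # increasing = IE (contralateral ear excitatory, louder at positive ILDs)
  expect_equal(classify_ild_function(ild_sigmoid(x, direction = 1), ax),
               "SIGMOID_IE")
  expect_equal(classify_ild_function(ild_sigmoid(x, direction = -1), ax),
               "SIGMOID_EI")
  expect_equal(classify_ild_function(ild_peak(x, w = 8), ax), "PEAKED")
  expect_equal(classify_ild_function(ild_peak(x, x0 = 10, w = 5), ax), "PEAKED")

  # transitional: peak with a high one-sided shoulder
  blend <- 0.5 * ild_peak(x, x0 = -5, w = 10) +
    0.5 * ild_sigmoid(x, x0 = 0, s = 5, direction = -1)
  expect_equal(classify_ild_function(blend, ax), "TRANSITION_PEAK_SIGMOID")

  expect_error(classify_ild_function(1:5, ax), "lengths differ")
})

test_that("rule thresholds are validated and labels stay in the class set", {
  expect_error(class_rule_params(insensitive_depth = 0), "in \\(0, 1\\)")
  expect_error(class_rule_params(peak_prominence = 1.2), "in \\(0, 1\\)")
  set.seed(21)
  for (i in 1:25) {
    curve <- pmax(stats::runif(13, 0, 100), 0.1)
    lab <- classify_ild_function(curve, ax)
    expect_true(lab %in% c("SIGMOID_EI", "SIGMOID_IE", "PEAKED", "INSENSITIVE",
                           "TRANSITION_PEAK_SIGMOID", "TRANSITION_PEAK_FLAT",
                           "TRANSITION_OTHER"))
  }
})

test_that("classification is invariant to uniform scaling and mirrors EI/IE", {
  curves <- list(sig_up = ild_sigmoid(x), sig_dn = ild_sigmoid(x, direction = -1),
                 peak = ild_peak(x, w = 8), flat = ild_flat(x, 30),
                 blend = 0.5 * ild_peak(x, x0 = -5, w = 10) +
                   0.5 * ild_sigmoid(x, direction = -1))
  swap <- c(SIGMOID_EI = "SIGMOID_IE", SIGMOID_IE = "SIGMOID_EI",
            PEAKED = "PEAKED", INSENSITIVE = "INSENSITIVE",
            TRANSITION_PEAK_SIGMOID = "TRANSITION_PEAK_SIGMOID",
            TRANSITION_PEAK_FLAT = "TRANSITION_PEAK_FLAT",
            TRANSITION_OTHER = "TRANSITION_OTHER")
  for (cv in curves) {
    base <- classify_ild_function(cv, ax)
    for (s in c(0.2, 3, 41.7)) {
      expect_equal(classify_ild_function(s * cv, ax), base)
    }
    expect_equal(classify_ild_function(rev(cv), ax), unname(swap[base]))
  }
})

test_that("templates average members and respect their envelope", {
  sim <- simulate_survey(n_cells = 30, proportions = c(8, 4, 5, 4, 3, 2, 4),
                         seed = 22)
  ts <- cluster_templates(sim$dataset, sim$labels)
  expect_equal(nrow(ts$templates), 7)
  expect_equal(sum(ts$counts), 30)
  m <- sim$dataset$counts
  for (g in 1:7) {
    members <- m[sim$labels == g, , drop = FALSE]
    expect_equal(unname(ts$templates[g, ]), unname(colMeans(members)))
    expect_true(all(ts$templates[g, ] >= apply(members, 2, min) - 1e-12))
    expect_true(all(ts$templates[g, ] <= apply(members, 2, max) + 1e-12))
  }
  # singleton and duplicate clusters
  two <- ild_dataset(rbind(ild_peak(x), ild_peak(x), ild_flat(x, 20)), ax)
  ts2 <- cluster_templates(two, c(1L, 1L, 2L))
  expect_equal(unname(ts2$templates[1, ]), ild_peak(x))
  expect_equal(unname(ts2$templates[2, ]), ild_flat(x, 20))
  expect_error(cluster_templates(two, c(1L, 3L, 3L)), "1..k")
  expect_error(cluster_templates(two, c(1L, 2L)), "labels do not cover")
})

test_that("the taxonomy report assembles and round-trips through JSON", {
  sim <- simulate_survey(n_cells = 52, proportions = c(15, 5, 9, 6, 5, 3, 9),
                         seed = 23)
  rep <- run_pipeline(sim$dataset, k = 7)
  expect_s3_class(rep, "ild_report")
  expect_equal(sum(rep$counts), 52)
  expect_equal(length(rep$classes), rep$k)
  expect_equal(dim(rep$scores), c(3L, 52L))

  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- read_report(f)
  for (field in c("n_cells", "normalization", "variance_pct", "n_components",
                  "metric", "linkage", "ccc", "k", "counts",
                  "pct_non_insensitive")) {
    expect_equal(back[[field]], rep[[field]], tolerance = 1e-12, label = field)
  }
  expect_equal(back$ccc_grid, rep$ccc_grid, tolerance = 1e-12)
  expect_equal(unname(back$templates), unname(rep$templates), tolerance = 1e-12)
  expect_equal(back$labels, rep$labels)
  expect_equal(back$scores, rep$scores, tolerance = 1e-12)

  # component mismatch is refused
  other <- fit_pca(matrix(stats::runif(10 * 13), 10, 13))
  expect_error(build_report(cluster_templates(sim$dataset, sim$labels),
                            ccc_grid(t(project(other, 3))), other,
                            structure(list(labels = rep$labels, k = 7L,
                                           counts = rep$counts),
                                      class = "ild_clusters")),
               "different cell counts")
})
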