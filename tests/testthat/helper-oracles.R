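# Independent brute-force oracles used to cross-check the clustering code.
# These deliberately avoid stats::hclust / stats::cophenetic internals: they
# work directly from pairwise loops and the exported merge table.

# Cophenetic distance by lowest-common-merge lookup: for every pair of
# leaves, walk the merge table and take the height of the first merge whose
# subtree contains both.
brute_cophenetic <- function(tree) {
  mt <- tree$merges
  n <- tree$n
  members <- vector("list", n + nrow(mt))
  for (i in seq_len(n)) members[[i]] <- i
  for (k in seq_len(nrow(mt))) {
    members[[n + k]] <- c(members[[mt$left[k]]], members[[mt$right[k]]])
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (k in seq_len(nrow(mt))) {
        if (i %in% members[[n + k]] && j %in% members[[n + k]]) {
          out[i, j] <- out[j, i] <- mt$height[k]
          break
        }
      }
    }
  }
  stats::as.dist(out)
}

# Minimax path distance on the complete graph: single-linkage cophenetic
# distances must equal the smallest possible maximum edge over all paths.
brute_minimax <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  mm <- d
  for (k in seq_len(n)) {        # Floyd-Warshall with max-edge composition
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        mm[i, j] <- min(mm[i, j], max(mm[i, k], mm[k, j]))
      }
    }
  }
  stats::as.dist(mm)
}

# Double-loop Minkowski distance, independent of stats::dist.
brute_minkowski <- function(m, p) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sum(abs(m[i, ] - m[j, ])^p)^(1 / p)
    }
  }
  stats::as.dist(out)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_ultrametric <- function(coph) {
  cm <- as.matrix(coph)
  n <- nrow(cm)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      for (c in seq_len(n)) {
        expect_lte(cm[a, c], max(cm[a, b], cm[b, c]) + 1e-10)
      }
    }
  }
}
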