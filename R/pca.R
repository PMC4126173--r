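## Covariance PCA of the L ILD-level variables across N cells, with the
## component-count selection rules (scree elbow, Kaiser, Horn, explained
## variance).

#' Fit PCA to an ILD matrix
#'
#' Computes the L x L covariance of the ILD-level variables across cells
#' with 1/N scaling, `A = (1/N) * sum_k (x_k - mu)(x_k - mu)^T`,
#' eigen-decomposes it, and projects the centered data onto the
#' eigenvectors, `y = V^T (x - mu)`. Eigenvalue order is descending;
#' each eigenvector's sign is fixed so its largest-magnitude loading is
#' positive, making score files reproducible.
#'
#' @param x an [ild_dataset], a normalized matrix, or any numeric matrix
#'   with cells in rows and variables in columns.
#' @return object of class `"ild_pca"` with elements `mean` (per-variable
#'   mean), `eigenvalues` (descending), `eigenvectors` (orthonormal columns),
#'   `scores` (L x N projection), `variance_pct`, `n`, `col_var` (unbiased
#'   per-variable variances, used by Horn's procedure), and `constant`
#'   (TRUE when the input had zero covariance).
#' @export
fit_pca <- function(x) {
  m <- as_counts(x)
  n <- nrow(m)
  if (n < 2) stop("PCA needs at least 2 rows")
  if (anyNA(m)) stop("PCA input contains missing values")
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  A <- crossprod(xc) / n                     # 1/N covariance
  e <- eigen(A, symmetric = TRUE)
  lambda <- pmax(e$values, 0)                # clip numerical negatives
  V <- e$vectors
  for (j in seq_len(ncol(V))) {             # deterministic sign convention
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  constant <- sum(lambda) <= 1e-12 * max(1, sum(mu^2))
  if (constant) {
    warning("constant input matrix: all eigenvalues are zero")
    pct <- rep(0, length(lambda))
  } else {
    pct <- variance_percentages(lambda)
  }
  scores <- t(V) %*% t(xc)                   # L x N
  dimnames(scores) <- list(sprintf("PC%d", seq_len(nrow(scores))), rownames(m))
  structure(list(mean = mu, eigenvalues = lambda, eigenvectors = V,
                 scores = scores, variance_pct = pct, n = n,
                 col_var = apply(m, 2, stats::var), constant = constant),
            class = "ild_pca")
}

#' @export
print.ild_pca <- function(x, ...) {
  cat(sprintf("PCA: %d variables, %d cells\n", length(x$eigenvalues), x$n))
  cat("variance explained (%):",
      paste(sprintf("%.3f", utils::head(x$variance_pct, 4)), collapse = " "),
      "...\n")
  invisible(x)
}

#' Variance percentages from eigenvalues
#'
#' Each eigenvalue as a percentage of the eigenvalue total,
#' `100 * lambda_i / sum(lambda)`; order preserved. Scale-invariant:
#' multiplying all eigenvalues by a positive constant leaves the
#' percentages unchanged.
#'
#' @param eigenvalues non-negative numeric vector, not all zero.
#' @return numeric vector of percentages summing to 100.
#' @export
variance_percentages <- function(eigenvalues) {
  if (any(eigenvalues < -1e-12)) stop("eigenvalues must be non-negative")
  s <- sum(eigenvalues)
  if (s <= 0) stop("all eigenvalues are zero: percentages undefined")
  100 * eigenvalues / s
}

#' Choose the number of principal components
#'
#' Four selection rules:
#' * `"explained_variance"`: smallest k whose cumulative variance
#'   percentage reaches `threshold` (default 95%).
#' * `"kaiser"`: count of eigenvalues above the cutoff. For covariance PCA
#'   the classical "greater than one" rule is scale-dependent, so the
#'   default cutoff is the mean eigenvalue (`kaiser_cutoff = "mean"`);
#'   `"one"` gives the classical rule.
#' * `"scree_elbow"`: the elbow index, located as the position of the
#'   largest second difference of the descending eigenvalue sequence.
#' * `"horn"`: parallel analysis — count of eigenvalues exceeding the
#'   `percentile`-th percentile of eigenvalues of `reps` i.i.d. Gaussian
#'   null matrices matched in shape and per-variable variance.
#'
#' @param result an `"ild_pca"` object.
#' @param rule one of `"explained_variance"`, `"kaiser"`, `"scree_elbow"`,
#'   `"horn"`.
#' @param threshold cumulative percentage for `"explained_variance"`,
#'   in (0, 100].
#' @param kaiser_cutoff `"mean"` or `"one"`.
#' @param reps,percentile,seed Horn settings (defaults 200 replicates,
#'   95th percentile).
#' @return integer k between 1 and the number of variables.
#' @export
select_n_components <- function(result,
                                rule = c("explained_variance", "kaiser",
                                         "scree_elbow", "horn"),
                                threshold = 95,
                                kaiser_cutoff = c("mean", "one"),
                                reps = 200, percentile = 95, seed = NULL) {
  rule <- match.arg(rule)
  lambda <- result$eigenvalues
  L <- length(lambda)
  k <- switch(rule,
    explained_variance = {
      stopifnot(threshold > 0, threshold <= 100)
      cum <- cumsum(result$variance_pct)
      which(cum >= threshold - 1e-9)[1]
    },
    kaiser = {
      cutoff <- switch(match.arg(kaiser_cutoff), mean = mean(lambda), one = 1)
      sum(lambda > cutoff)
    },
    scree_elbow = {
      if (L < 3) return(1L)
      d2 <- diff(diff(lambda))               # second difference at 2..L-1
      which.max(d2) + 1L
    },
    horn = {
      if (!is.null(seed)) set.seed(seed)
      n <- result$n
      null_ev <- matrix(0, reps, L)
      sds <- sqrt(result$col_var)
      for (r in seq_len(reps)) {
        z <- matrix(stats::rnorm(n * L), n, L) %*% diag(sds, L)
        zc <- sweep(z, 2, colMeans(z))
        null_ev[r, ] <- eigen(crossprod(zc) / n, symmetric = TRUE,
                              only.values = TRUE)$values
      }
      thr <- apply(null_ev, 2, stats::quantile, probs = percentile / 100)
      sum(lambda > thr)
    }
  )
  max(1L, min(as.integer(k), L))
}

#' Project onto the first k principal components
#'
#' @param result an `"ild_pca"` object.
#' @param k number of components, between 1 and the number of variables.
#' @return k x N score matrix.
#' @export
project <- function(result, k) {
  L <- length(result$eigenvalues)
  if (!(k >= 1 && k <= L)) stop(sprintf("k must be in [1, %d]", L))
  result$scores[seq_len(k), , drop = FALSE]
}

#' Reconstruct data from k components
#'
#' With `k = L` this recovers the original matrix up to numerical precision.
#'
#' @param result an `"ild_pca"` object.
#' @param k number of components.
#' @return N x L matrix on the original scale.
#' @export
reconstruct <- function(result, k = length(result$eigenvalues)) {
  y <- project(result, k)
  xc <- t(result$eigenvectors[, seq_len(k), drop = FALSE] %*% y)
  sweep(xc, 2, result$mean, "+")
}
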