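## Pairwise dissimilarities for the six metrics compared in the CCC grid.

ILD_METRICS <- c("euclidean", "seuclidean", "minkowski", "mahalanobis",
                 "cityblock", "cosine")

#' Condensed pairwise distances
#'
#' Computes the lower-triangle ("condensed") dissimilarity vector between
#' the rows of `x` for one of six metrics: `euclidean`, `seuclidean`
#' (Euclidean after standardizing each dimension by its unbiased variance),
#' `minkowski` (order `p`), `mahalanobis` (full-sample covariance, with a
#' pseudo-inverse fallback and warning when singular), `cityblock`, and
#' `cosine` (`1 - u.v / (|u||v|)`).
#'
#' @param x numeric matrix, observations in rows (e.g. a t() of the k x N
#'   PC score matrix), or an [ild_dataset].
#' @param metric one of `"euclidean"`, `"seuclidean"`, `"minkowski"`,
#'   `"mahalanobis"`, `"cityblock"`, `"cosine"`.
#' @param p Minkowski order (default 2).
#' @return a `stats::dist` object with attribute `"metric"`.
#' @export
pairwise_distances <- function(x, metric = "euclidean", p = 2) {
  m <- as_counts(x)
  metric <- match.arg(metric, ILD_METRICS)
  d <- switch(metric,
    euclidean = stats::dist(m, method = "euclidean"),
    cityblock = stats::dist(m, method = "manhattan"),
    minkowski = stats::dist(m, method = "minkowski", p = p),
    seuclidean = {
      v <- apply(m, 2, stats::var)          # unbiased per-dimension variance
      if (any(v == 0)) stop(sprintf("zero variance in dimension %d", which(v == 0)[1]))
      stats::dist(sweep(m, 2, sqrt(v), "/"), method = "euclidean")
    },
    mahalanobis = {
      S <- stats::cov(m)
      Sinv <- tryCatch(solve(S), error = function(e) {
        warning("singular covariance: using Moore-Penrose pseudo-inverse")
        MASS::ginv(S)
      })
      Sinv <- (Sinv + t(Sinv)) / 2
      e <- eigen(Sinv, symmetric = TRUE)
      W <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), ncol(m))
      stats::dist(m %*% W, method = "euclidean")
    },
    cosine = {
      nrm <- sqrt(rowSums(m^2))
      if (any(nrm == 0)) stop(sprintf("zero-norm row %d: cosine distance undefined",
                                      which(nrm == 0)[1]))
      sim <- tcrossprod(m / nrm)
      d0 <- stats::as.dist(1 - sim)
      d0[d0 < 0] <- 0                        # clip numerical negatives
      d0
    }
  )
  attr(d, "metric") <- metric
  d
}
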