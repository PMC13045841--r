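# Embedding-quality diagnostics: clustering-tendency statistics (Hopkins
# score and the cluster tendency score) and internal cluster-validity
# indices (silhouette, Calinski-Harabasz), plus a bundle that runs seeded
# k-means (k = 2) the way the embedding analyses do.

# Nearest-neighbor distance from each row of `from` to rows of `data`,
# excluding `exclude[i]` (an index into `data`) from the search for row i.
nn_dist <- function(from, data, exclude = NULL, squared = FALSE) {
  d2 <- outer(rowSums(from^2), rowSums(data^2), "+") - 2 * tcrossprod(from, data)
  d2[d2 < 0] <- 0
  if (!is.null(exclude)) {
    d2[cbind(seq_len(nrow(from)), exclude)] <- Inf
  }
  mins <- apply(d2, 1, min)
  if (squared) mins else sqrt(mins)
}

hopkins_ratio <- function(points, n_test, seed, squared) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n_test < 1L || n < n_test + 1L) {
    stop("need at least `n_test` + 1 points", call. = FALSE)
  }
  with_seed(seed, {
    test_idx <- sample.int(n, n_test)
    lo <- apply(points, 2, min)
    hi <- apply(points, 2, max)
    U <- matrix(stats::runif(n_test * ncol(points)), n_test) *
      rep(hi - lo, each = n_test) + rep(lo, each = n_test)
  })
  d_t <- sum(nn_dist(points[test_idx, , drop = FALSE], points,
                     exclude = test_idx, squared = squared))
  d_r <- sum(nn_dist(U, points, squared = squared))
  if (d_t + d_r == 0) {
    warning("degenerate data: all points identical; returning 1")
    return(1)
  }
  d_r / (d_r + d_t)
}

#' Hopkins clustering-tendency score
#'
#' Samples `n_test` real points (without replacement); `D_T` is the sum of
#' each one's Euclidean distance to its nearest neighbor among the remaining
#' data. `n_test` uniform reference points are drawn from the data's
#' axis-aligned bounding box; `D_R` is the sum of their nearest-data
#' distances. Returns `D_R / (D_R + D_T)`: about 0.5 for uniformly
#' distributed data, approaching 1 for strongly clustered data.
#'
#' @param points Numeric matrix, one row per point.
#' @param n_test Number of test points. Default `min(100, floor(0.1 n))`
#'   with a floor of 10.
#' @param seed Seed for the test-point and reference draws.
#' @return Scalar in `[0, 1]`.
#' @export
hopkins_score <- function(points, n_test = NULL, seed = 1L) {
  points <- as.matrix(points)
  n_test <- n_test %||% max(10L, min(100L, floor(0.1 * nrow(points))))
  hopkins_ratio(points, n_test, seed, squared = FALSE)
}

#' Cluster tendency score
#'
#' Same construction as [hopkins_score()] but with squared Euclidean
#' nearest-neighbor distances, normalized as
#' `CTS = 2 max(D_R / (D_R + D_T) - 0.5, 0)`, so uniformly distributed
#' points score near 0 and strongly clustered points near 1.
#'
#' @inheritParams hopkins_score
#' @return Scalar in `[0, 1]`.
#' @export
cluster_tendency_score <- function(points, n_test = NULL, seed = 1L) {
  points <- as.matrix(points)
  n_test <- n_test %||% max(10L, min(100L, floor(0.1 * nrow(points))))
  2 * max(hopkins_ratio(points, n_test, seed, squared = TRUE) - 0.5, 0)
}

#' Silhouette index
#'
#' For each point, `a(i)` is its mean distance to the other members of its
#' cluster and `b(i)` the smallest mean distance to any other cluster;
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Singleton clusters score 0, as
#' does the degenerate 0/0 case of coincident points. Returns the mean over
#' all points.
#'
#' @param points Numeric matrix.
#' @param labels Cluster assignment (>= 2 distinct values).
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("need at least 2 clusters", call. = FALSE)
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster
  md <- sapply(seq_len(k), function(cl) rowSums(D[, labels == cl, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    if (sizes[cl] == 1L) { s[i] <- 0; next }
    a <- md[i, cl] / (sizes[cl] - 1L)
    b <- min(md[i, -cl] / sizes[-cl])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' Variance-ratio criterion `(B / (K - 1)) / (W / (N - K))`, with
#' between-cluster dispersion `B = sum n_k ||c_k - c||^2` and within-cluster
#' dispersion `W = sum_k sum_{i in C_k} ||x_i - c_k||^2`, centroids being
#' arithmetic means. When `W = 0` (coincident within-cluster points) the
#' index is unbounded and a large finite sentinel is returned with attribute
#' `degenerate = TRUE`.
#'
#' @inheritParams silhouette_index
#' @return Non-negative scalar.
#' @export
calinski_harabasz <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(points)
  if (k < 2L || k >= n) stop("need 2 <= K < N clusters", call. = FALSE)
  c_all <- colMeans(points)
  B <- 0
  W <- 0
  for (cl in seq_len(k)) {
    P <- points[labels == cl, , drop = FALSE]
    ck <- colMeans(P)
    B <- B + nrow(P) * sum((ck - c_all)^2)
    W <- W + sum(sweep(P, 2, ck)^2)
  }
  if (W == 0) {
    return(structure(.Machine$double.xmax / 2, degenerate = TRUE))
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Embedding diagnostics bundle
#'
#' Runs seeded k-means (k clusters, multiple restarts) on the embeddings and
#' reports the silhouette and Calinski-Harabasz indices of the fitted
#' partition, together with the Hopkins score and cluster tendency score of
#' the raw point cloud.
#'
#' @param points Numeric matrix of embeddings.
#' @param k Number of k-means clusters (2 in the standard analysis).
#' @param n_test Test-point count for the tendency statistics.
#' @param seed Seed covering the k-means restarts and tendency draws.
#' @param nstart k-means restarts.
#' @return List of class `embedding_diagnostics` with elements `hopkins`,
#'   `cts`, `silhouette`, `chi`, `n_points`, `n_test`, `seed`.
#' @export
embedding_diagnostics <- function(points, k = 2L, n_test = NULL, seed = 1L,
                                  nstart = 5L) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("`points` must be finite", call. = FALSE)
  n_test <- n_test %||% max(10L, min(100L, floor(0.1 * nrow(points))))
  km <- with_seed(seed, stats::kmeans(points, centers = k, nstart = nstart))
  structure(
    list(hopkins = hopkins_score(points, n_test, seed),
         cts = cluster_tendency_score(points, n_test, seed),
         silhouette = silhouette_index(points, km$cluster),
         chi = as.numeric(calinski_harabasz(points, km$cluster)),
         n_points = nrow(points), n_test = n_test, seed = as.integer(seed)),
    class = "embedding_diagnostics"
  )
}

#' @export
print.embedding_diagnostics <- function(x, ...) {
  cat("Embedding diagnostics (n = ", x$n_points, ", n_test = ", x$n_test,
      ", seed = ", x$seed, ")\n", sep = "")
  cat(sprintf("  Hopkins score        %.3f\n", x$hopkins))
  cat(sprintf("  Cluster tendency     %.3f\n", x$cts))
  cat(sprintf("  Silhouette index     %.3f\n", x$silhouette))
  cat(sprintf("  Calinski-Harabasz    %.2f\n", x$chi))
  invisible(x)
}
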