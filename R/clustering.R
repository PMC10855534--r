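# Coordinates may arrive as the data.frame from embed_samples() (sample_id
# column + U columns) or as a plain numeric matrix.
as_points <- function(points) {
  if (is.data.frame(points)) {
    ids <- if ("sample_id" %in% names(points)) points$sample_id else
      rownames(points)
    m <- as.matrix(points[, setdiff(names(points), "sample_id"), drop = FALSE])
    rownames(m) <- ids
    m
  } else {
    as.matrix(points)
  }
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center with probability proportional to squared distance to the
# nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j + 1], ], "-")^2))
  }
  x[centers, , drop = FALSE]
}

#' k-means clustering of the fused embedding
#'
#' Lloyd's algorithm with k-means++ seeding, best of `restarts` runs by
#' within-cluster sum of squares (inertia). Deterministic given `seed`.
#' Connectivity and silhouette validity scores are computed on the same
#' points.
#'
#' @param points samples-x-k coordinates ([embed_samples()] output or a
#'   numeric matrix).
#' @param n_clusters number of clusters, in `[2, n_samples]`.
#' @param restarts number of seeded restarts (default 50).
#' @param seed integer seed.
#' @param n_neighbors neighbors used by the connectivity score.
#' @return object of class `cluster_solution`: `labels` (named integer
#'   vector in 1..k), `k`, `connectivity`, `silhouette`, `inertia`,
#'   `centers`, `seed`.
#' @export
kmeans_cluster <- function(points, n_clusters, restarts = 50, seed = 1L,
                           n_neighbors = 10) {
  x <- as_points(points)
  n <- nrow(x)
  if (n_clusters < 2 || n_clusters > n) stop("n_clusters must be in [2, n_samples]")
  if (nrow(unique(x)) < n_clusters)
    stop("fewer distinct points than clusters: a cluster would be empty")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- kmeanspp_centers(x, n_clusters)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = cen, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  labels <- stats::setNames(as.integer(best$cluster), rownames(x))
  structure(list(
    labels = labels, k = n_clusters,
    connectivity = connectivity_index(x, labels,
                                      n_neighbors = min(n_neighbors, n - 1)),
    silhouette = if (length(unique(labels)) >= 2)
      silhouette_index(x, labels) else NA_real_,
    inertia = best$tot.withinss, centers = best$centers, seed = seed),
    class = "cluster_solution")
}

#' Connectivity cluster-validity index
#'
#' For each sample, its `n_neighbors` nearest neighbors (Euclidean, distance
#' ties broken by sample index) contribute `1/j` when the j-th neighbor lies
#' in a different cluster. Lower is better; 0 means no sample has a
#' near neighbor from another cluster.
#'
#' @param points samples-x-k coordinates.
#' @param labels per-sample cluster labels.
#' @param n_neighbors number of ranked neighbors (default 10).
#' @return non-negative scalar.
#' @export
connectivity_index <- function(points, labels, n_neighbors = 10) {
  x <- as_points(points)
  n <- nrow(x)
  if (n_neighbors >= n) stop("n_neighbors must be < n_samples")
  d <- as.matrix(stats::dist(x))
  total <- 0
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])  # tie-break by sample index
    nb <- (seq_len(n)[-i])[ord][seq_len(n_neighbors)]
    mismatch <- labels[nb] != labels[i]
    total <- total + sum(mismatch / seq_len(n_neighbors))
  }
  total
}

#' Mean silhouette width
#'
#' Per sample: `(b - a) / max(a, b)` with `a` the mean distance to the other
#' members of its own cluster and `b` the smallest mean distance to another
#' cluster; samples in singleton clusters score 0. Returns the mean over
#' samples.
#'
#' @param points samples-x-k coordinates.
#' @param labels per-sample cluster labels (>= 2 clusters).
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_index <- function(points, labels) {
  x <- as_points(points)
  labels <- as.vector(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(c2)
      mean(d[i, labels == c2]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters by connectivity and silhouette
#'
#' Runs [kmeans_cluster()] for each k in `k_range` and reports a validity
#' table (connectivity and silhouette per k). The chosen k minimizes the sum
#' of the connectivity rank (ascending: low connectivity is good) and the
#' silhouette rank (descending), restricted to ks whose silhouette lies
#' within `tol_sil` of the maximum; the smallest such k wins ties. The full
#' table is always returned so the user can override.
#'
#' A precomputed validity table (data.frame with columns `k`,
#' `connectivity`, `silhouette`) may be passed as `points` with
#' `k_range = NULL`, in which case only the selection rule is applied.
#'
#' @param points samples-x-k coordinates, or a precomputed validity table.
#' @param k_range integer vector of candidate k (subset of
#'   `[2, n_samples - 1]`), or NULL when `points` is a validity table.
#' @param seed integer seed forwarded to [kmeans_cluster()].
#' @param tol_sil silhouette tolerance band (default 0.1; wide enough that
#'   a clearly lower-connectivity solution wins against a marginally better
#'   silhouette, the trade-off uveal-melanoma risk-class discovery needs).
#' @param restarts restarts per k.
#' @return list with `k` (chosen) and `table` (one row per candidate k with
#'   connectivity and silhouette).
#' @export
select_k <- function(points, k_range = 2:6, seed = 1L, tol_sil = 0.1,
                     restarts = 50) {
  if (is.null(k_range)) {
    tab <- as.data.frame(points)
    stopifnot(all(c("k", "connectivity", "silhouette") %in% names(tab)))
  } else {
    x <- as_points(points)
    if (any(k_range < 2 | k_range > nrow(x) - 1))
      stop("k_range must lie in [2, n_samples - 1]")
    sols <- lapply(k_range, function(k)
      kmeans_cluster(x, k, restarts = restarts, seed = seed))
    tab <- data.frame(k = k_range,
                      connectivity = vapply(sols, `[[`, numeric(1), "connectivity"),
                      silhouette = vapply(sols, `[[`, numeric(1), "silhouette"))
  }
  conn_rank <- rank(tab$connectivity, ties.method = "min")
  sil_rank <- rank(-tab$silhouette, ties.method = "min")
  score <- conn_rank + sil_rank
  eligible <- tab$silhouette >= max(tab$silhouette) - tol_sil
  pool <- which(eligible & score == min(score[eligible]))
  chosen <- tab$k[pool[which.min(tab$k[pool])]]
  list(k = chosen, table = tab)
}
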