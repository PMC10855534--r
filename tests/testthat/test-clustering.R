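test_that("two well-separated blobs are recovered exactly", {
  b <- make_blobs(15, rbind(c(0, 0), c(10, 10)), seed = 1)
  sol <- kmeans_cluster(b$x, 2, seed = 1)
  expect_equal(adjusted_rand_index(sol$labels, b$labels), 1)
  expect_gt(sol$silhouette, 0.9)
  expect_equal(sol$connectivity, 0)
})

test_that("as many clusters as points gives zero inertia", {
  set.seed(2)
  x <- matrix(rnorm(12), 6, 2)
  sol <- kmeans_cluster(x, 6, seed = 1)
  expect_equal(sol$inertia, 0)
})

test_that("small planted instances match the exhaustive best partition", {
  b <- make_blobs(3, rbind(c(0, 0), c(4, 0), c(0, 4)), sd = 0.6, seed = 3)
  x <- b$x  # 9 points, 3 blobs
  sol <- kmeans_cluster(x, 3, restarts = 100, seed = 1)
  # brute force over all 3^9 assignments with non-empty clusters
  best <- Inf
  for (code in 0:(3^9 - 1)) {
    lab <- (code %/% 3^(0:8)) %% 3
    if (length(unique(lab)) < 3) next
    inertia <- 0
    for (c2 in 0:2) {
      pts <- x[lab == c2, , drop = FALSE]
      inertia <- inertia + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    best <- min(best, inertia)
  }
  expect_equal(sol$inertia, best, tolerance = 1e-10)
})

test_that("connectivity matches the brute-force neighbor enumeration", {
  # line example: perfectly split labels score zero
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  expect_equal(connectivity_index(x, c(1, 1, 1, 2, 2, 2), n_neighbors = 2), 0)
  # shifted boundary: the point at 2 sees neighbors 1 (1/1) and 0 (1/2)
  lab <- c(1, 1, 2, 2, 2, 2)
  expect_equal(connectivity_index(x, lab, n_neighbors = 2),
               oracle_connectivity(x, lab, 2))
  # point at 2: ranks 1 and 2 both cross (1 + 1/2); points 0 and 1 each see
  # the point at 2 as their rank-2 neighbor (1/2 each)
  expect_equal(oracle_connectivity(x, lab, 2), (1 + 1 / 2) + 1 / 2 + 1 / 2)
  # random fixtures
  for (s in 1:5) {
    set.seed(s)
    xr <- matrix(rnorm(20), 10, 2)
    lr <- sample(1:3, 10, replace = TRUE)
    expect_equal(connectivity_index(xr, lr, n_neighbors = 4),
                 oracle_connectivity(xr, lr, 4))
  }
})

test_that("merging two distant blobs never decreases connectivity", {
  b <- make_blobs(6, rbind(c(0, 0), c(8, 0), c(0, 8)), seed = 4)
  three <- connectivity_index(b$x, b$labels, n_neighbors = 3)
  merged <- ifelse(b$labels == 3, 2, b$labels)
  expect_gte(connectivity_index(b$x, merged, n_neighbors = 3), three)
})

test_that("silhouette equals the pairwise-distance oracle", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  # closed form: a = 1, b = (10 + sqrt(101)) / 2 for every point
  b_exact <- (10 + sqrt(101)) / 2
  expect_equal(silhouette_index(x, lab), (b_exact - 1) / b_exact)
  expect_equal(silhouette_index(x, lab), oracle_silhouette(x, lab))
  for (s in 1:5) {
    set.seed(s)
    xr <- matrix(rnorm(24), 12, 2)
    lr <- sample(1:3, 12, replace = TRUE)
    if (length(unique(lr)) < 2) next
    expect_equal(silhouette_index(xr, lr), oracle_silhouette(xr, lr))
  }
})

test_that("silhouette agrees with the cluster package on fixtures", {
  skip_if_not_installed("cluster")
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(30), 15, 2)
    lab <- sample(1:3, 15, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ref <- mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
    expect_equal(silhouette_index(x, lab), ref, tolerance = 1e-10)
  }
})

test_that("random labels on one blob give silhouette near zero", {
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(40), 20, 2)
    silhouette_index(x, rep(1:2, 10))
  }, numeric(1))
  expect_lt(max(abs(vals)), 0.15)
})

test_that("the validity selection rule reproduces the published pattern", {
  tab <- data.frame(k = c(2, 3, 4),
                    connectivity = c(2.25, 6.27, 15.66),
                    silhouette = c(0.45, 0.51, 0.52))
  expect_equal(select_k(tab, k_range = NULL)$k, 2)
})

test_that("three planted blobs select k = 3; ties select the smallest k", {
  b <- make_blobs(10, rbind(c(0, 0), c(6, 0), c(0, 6)), sd = 0.4, seed = 6)
  sel <- select_k(b$x, k_range = 2:5, seed = 1)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$table), 4)
  flat <- data.frame(k = 2:4, connectivity = c(1, 1, 1),
                     silhouette = c(0.5, 0.5, 0.5))
  expect_equal(select_k(flat, k_range = NULL)$k, 2)
})

test_that("labels are invariant to rotation and translation of the points", {
  b <- make_blobs(8, rbind(c(0, 0), c(5, 5)), seed = 7)
  sol1 <- kmeans_cluster(b$x, 2, seed = 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  x2 <- b$x %*% R + 100
  sol2 <- kmeans_cluster(x2, 2, seed = 3)
  expect_equal(adjusted_rand_index(sol1$labels, sol2$labels), 1)
})

test_that("degenerate clustering inputs are rejected", {
  x <- matrix(rep(c(0, 1), each = 4), 4, 2)
  expect_error(kmeans_cluster(x, 3, seed = 1), "distinct points")
  expect_error(connectivity_index(matrix(rnorm(8), 4, 2), rep(1, 4),
                                  n_neighbors = 4), "n_neighbors")
  expect_error(silhouette_index(matrix(rnorm(8), 4, 2), rep(1, 4)),
               "2 clusters")
})
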