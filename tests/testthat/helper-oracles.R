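# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with naive loops/closed forms so they share no code
# with the package implementations they check.

toy_matrix <- function(nr, nc, kind = "expression_normalized", seed = 1,
                       gen = function(n) rnorm(n)) {
  set.seed(seed)
  omics_matrix(matrix(gen(nr * nc), nr, nc,
                      dimnames = list(sprintf("g%03d", seq_len(nr)),
                                      sprintf("s%03d", seq_len(nc)))),
               kind)
}

# connectivity: double loop over samples and ranked neighbors
oracle_connectivity <- function(x, labels, L) {
  n <- nrow(x)
  total <- 0
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
    ord <- setdiff(order(d, seq_len(n)), i)[seq_len(L)]
    for (j in seq_len(L))
      if (labels[ord[j]] != labels[i]) total <- total + 1 / j
  }
  total
}

# silhouette: textbook formula from the full pairwise distance matrix
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (c2 in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, which(labels == c2)]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# AUC: concordant-pair counting with half credit for ties
oracle_auc <- function(pred, labels) {
  pos <- pred[labels == 1]; neg <- pred[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# SAM: exhaustive-permutation d statistics and q-values, naive loops
oracle_sam <- function(x, labels, s0) {
  d_of <- function(lab) {
    i1 <- which(lab == 0); i2 <- which(lab == 1)
    sapply(seq_len(nrow(x)), function(g) {
      a <- x[g, i1]; b <- x[g, i2]
      sp <- sqrt((1 / length(a) + 1 / length(b)) *
                   (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                   (length(a) + length(b) - 2))
      (mean(b) - mean(a)) / (sp + s0)
    })
  }
  d_obs <- d_of(labels)
  n2 <- sum(labels == 1)
  combos <- utils::combn(length(labels), n2)
  d_null <- sapply(seq_len(ncol(combos)), function(b) {
    lab <- rep(0L, length(labels)); lab[combos[, b]] <- 1L
    d_of(lab)
  })
  q <- sapply(seq_len(nrow(x)), function(g) {
    t <- abs(d_obs[g])
    obs_ex <- sum(abs(d_obs) >= t)
    null_ex <- median(apply(d_null, 2, function(col) sum(abs(col) >= t)))
    min(1, null_ex / obs_ex)
  })
  list(d = d_obs, q = q)
}

# Welch t-test from the closed form
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# BH step-up from the textbook definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  cummin_rev <- Inf
  for (i in n:1) {
    cummin_rev <- min(cummin_rev, p[o[i]] * n / i)
    adj[o[i]] <- min(1, cummin_rev)
  }
  adj
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# small two-blob / three-blob point sets
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}
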