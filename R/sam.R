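# SAM-style two-class permutation differential analysis.
#
# d_i = (mean2_i - mean1_i) / (s_i + s0), with s_i the two-class pooled
# standard error and s0 a "fudge factor" chosen as the percentile of {s_i}
# minimizing the coefficient of variation of d across windows of s. The null
# distribution comes from balanced label permutations; features are called by
# the delta-band rule against the mean-ordered null statistics, and per-
# feature q-values are estimated from exceedance counts.

sam_d_stat <- function(x, labels, s0) {
  g1 <- x[, labels == 0, drop = FALSE]
  g2 <- x[, labels == 1, drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  ss1 <- rowSums((g1 - m1)^2)
  ss2 <- rowSums((g2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(d = (m2 - m1) / (s + s0), s = s, diff = m2 - m1)
}

# Tusher-style fudge factor: among the 0,5,...,100 percentiles of s, pick the
# one minimizing the coefficient of variation of the window-wise MAD of d.
sam_s0 <- function(s, diff) {
  qs <- stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE, type = 7)
  # windows of s for the dispersion profile: s-quantile bins
  br <- unique(stats::quantile(s, seq(0, 1, length.out = 21), names = FALSE))
  if (length(br) < 3) return(stats::median(s))
  bin <- cut(s, br, include.lowest = TRUE)
  cvs <- vapply(qs, function(s0c) {
    d <- diff / (s + s0c)
    mads <- tapply(d, bin, function(v) stats::mad(v))
    mads <- mads[!is.na(mads)]
    if (mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  qs[which.min(cvs)]
}

# All balanced relabelings of a binary vector (as a matrix, one per column),
# or n_perm random ones when more than n_perm exist.
balanced_permutations <- function(labels, n_perm) {
  n <- length(labels)
  n2 <- sum(labels == 1)
  total <- choose(n, n2)
  if (total <= n_perm) {
    idx <- utils::combn(n, n2)
    apply(idx, 2, function(j) {
      l <- integer(n); l[j] <- 1L; l
    })
  } else {
    vapply(seq_len(n_perm), function(b) {
      l <- integer(n); l[sample.int(n, n2)] <- 1L; l
    }, integer(n))
  }
}

#' SAM two-class differential analysis
#'
#' Computes the SAM d-statistic per feature, builds the null from balanced
#' label permutations (all of them when no more than `n_perm` exist,
#' otherwise `n_perm` random ones), calls features by the delta-band rule
#' against the mean-ordered null statistics, and estimates per-feature
#' q-values as the median permutation exceedance count divided by the
#' observed exceedance count, capped at 1.
#'
#' @param m [omics_matrix()] on a roughly variance-stabilized scale
#'   (normalized expression, or beta values — optionally logit-transformed
#'   via `logit_beta`).
#' @param labels binary per-sample class labels (0/1, or a 2-level vector);
#'   both classes need >= 2 samples. `d > 0` means higher in the class coded
#'   1 (class 2).
#' @param n_perm permutation budget (default 1000).
#' @param delta half-width of the delta band, or `"auto"` to pick the
#'   smallest delta whose estimated FDR is at most `fdr_target`.
#' @param fdr_target FDR target used when `delta = "auto"` (default 0.05).
#' @param seed integer seed for random permutations.
#' @param s0 optional fixed fudge factor; by default chosen by the
#'   CV-minimizing percentile rule.
#' @param logit_beta if TRUE and `m` holds beta values, analyze
#'   `log(beta/(1-beta))` instead.
#' @return object of class `sam_result`: data.frame `table` (feature, d, s,
#'   q-value, significant flag, direction), plus `s0`, `delta`, `n_perm`,
#'   `d_bar` (mean-ordered null), `cutlow`/`cutup`, `seed`.
#' @export
sam_two_class <- function(m, labels, n_perm = 1000, delta = "auto",
                          fdr_target = 0.05, seed = 1L, s0 = NULL,
                          logit_beta = FALSE) {
  x <- if (inherits(m, "omics_matrix")) m$values else as.matrix(m)
  labels <- as.integer(factor(labels)) - 1L
  if (length(unique(labels)) != 2 || !all(labels %in% c(0L, 1L)))
    stop("labels must have exactly 2 levels")
  if (min(table(labels)) < 2) stop("both classes need at least 2 samples")
  if (logit_beta) {
    xc <- pmin(pmax(x, 0.001), 0.999)
    x <- log(xc / (1 - xc))
  }
  set.seed(seed)

  obs0 <- sam_d_stat(x, labels, s0 = 0)
  if (is.null(s0)) s0 <- sam_s0(obs0$s, obs0$diff)
  if (s0 == 0 && all(obs0$s == 0))
    stop("all features have zero pooled variance and s0 = 0; ",
         "supply a positive s0 or check the fudge-factor rule")
  obs <- sam_d_stat(x, labels, s0 = s0)

  perms <- balanced_permutations(labels, n_perm)
  B <- ncol(perms)
  d_null <- vapply(seq_len(B), function(b)
    sam_d_stat(x, perms[, b], s0 = s0)$d, numeric(nrow(x)))

  p <- nrow(x)
  ord <- order(obs$d)
  d_sorted <- obs$d[ord]
  d_bar <- rowMeans(apply(d_null, 2, sort))  # mean-ordered null statistics

  # delta-band cutoffs: walking out from the centre, the first sorted d whose
  # deviation from d_bar exceeds delta fixes the cut; everything beyond is
  # significant.
  cuts_for_delta <- function(dl) {
    dev <- d_sorted - d_bar
    up_idx <- which(dev >= dl & seq_len(p) > which.min(abs(d_bar)))
    cutup <- if (length(up_idx) > 0) d_sorted[min(up_idx)] else Inf
    low_idx <- which(dev <= -dl & seq_len(p) < which.min(abs(d_bar)))
    cutlow <- if (length(low_idx) > 0) d_sorted[max(low_idx)] else -Inf
    c(cutlow, cutup)
  }
  called_fdr <- function(dl) {
    cuts <- cuts_for_delta(dl)
    n_called <- sum(obs$d >= cuts[2] | obs$d <= cuts[1])
    if (n_called == 0) return(list(fdr = 0, cuts = cuts, n = 0))
    null_called <- apply(d_null, 2, function(dn)
      sum(dn >= cuts[2] | dn <= cuts[1]))
    list(fdr = min(1, stats::median(null_called) / n_called),
         cuts = cuts, n = n_called)
  }
  if (identical(delta, "auto")) {
    cand <- sort(unique(c(0, abs(d_sorted - d_bar))))
    delta <- cand[length(cand)]
    for (dl in cand) {
      if (called_fdr(dl)$fdr <= fdr_target) { delta <- dl; break }
    }
  }
  cf <- called_fdr(delta)
  sig <- obs$d >= cf$cuts[2] | obs$d <= cf$cuts[1]

  # per-feature q-value from two-sided exceedance counts
  abs_obs <- abs(obs$d)
  obs_exceed <- vapply(abs_obs, function(t) sum(abs_obs >= t), numeric(1))
  null_exceed <- vapply(seq_len(p), function(i)
    stats::median(colSums(abs(d_null) >= abs_obs[i])), numeric(1))
  q <- pmin(1, null_exceed / obs_exceed)

  feature_ids <- if (inherits(m, "omics_matrix")) m$feature_ids else
    rownames(x) %||% paste0("f", seq_len(p))
  tab <- data.frame(feature = feature_ids, d = obs$d, s = obs$s, q = q,
                    significant = sig,
                    direction = ifelse(obs$d > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, s0 = s0, delta = delta,
                 estimated_fdr = cf$fdr, n_called = cf$n,
                 n_perm = B, d_bar = d_bar,
                 cutlow = cf$cuts[1], cutup = cf$cuts[2], seed = seed),
            class = "sam_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Significant gene set of a SAM result
#' @param res a [sam_two_class()] result.
#' @return character vector of significant feature IDs.
#' @export
sam_significant <- function(res) {
  res$table$feature[res$table$significant]
}
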