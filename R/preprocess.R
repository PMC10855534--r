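#' Remove count outlier genes
#'
#' Drops genes whose total raw count over all samples is below `min_total` or
#' above `max_total`. Both bounds are strict: totals equal to either bound are
#' retained.
#'
#' @param m [omics_matrix()] of kind `expression_counts`.
#' @param min_total,max_total total-count bounds (defaults 100 and 1e6).
#' @return filtered [omics_matrix()]; warns (does not error) when no gene
#'   survives.
#' @export
filter_count_outliers <- function(m, min_total = 100, max_total = 1e6) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$kind != "expression_counts")
    stop("filter_count_outliers expects expression_counts, got ", m$kind)
  totals <- rowSums(m$values)
  keep <- totals >= min_total & totals <= max_total
  if (!any(keep)) warning("no gene passes the count-outlier filter")
  subset_omics(m, features = which(keep))
}

#' Median-of-ratios normalization of counts
#'
#' Computes per-sample size factors by the median-of-ratios method over genes
#' with all-positive counts (each sample's counts divided by the per-gene
#' geometric mean; size factor = median of those ratios) and returns
#' `log2(count / size_factor + 1)`, an approximately variance-stabilized,
#' monotone transform. A pre-transformed matrix of kind
#' `expression_normalized` may be supplied anywhere the pipeline expects one,
#' bypassing this step.
#'
#' @param m [omics_matrix()] of kind `expression_counts`, >= 2 samples.
#' @return [omics_matrix()] of kind `expression_normalized` with the size
#'   factors attached as attribute `size_factors`.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$kind != "expression_counts")
    stop("normalize_counts expects expression_counts, got ", m$kind)
  if (ncol(m$values) < 2) stop("need at least 2 samples")
  zero_samp <- colSums(m$values) == 0
  if (any(zero_samp))
    stop("all-zero counts in sample(s): ",
         paste(m$sample_ids[zero_samp], collapse = ", "),
         " (size factor undefined)")
  pos <- rowSums(m$values > 0) == ncol(m$values)
  if (!any(pos)) stop("no gene has all-positive counts; size factors undefined")
  logv <- log(m$values[pos, , drop = FALSE])
  loggeo <- rowMeans(logv)
  sf <- apply(logv, 2, function(col) exp(stats::median(col - loggeo)))
  norm <- log2(sweep(m$values, 2, sf, "/") + 1)
  out <- omics_matrix(norm, "expression_normalized",
                      feature_annot = m$feature_annot)
  attr(out, "size_factors") <- sf
  out
}

# MAD / variance per feature with lexicographic-ID deterministic tie-break.
rank_features_desc <- function(score, ids) {
  order(-score, ids)
}

#' Keep the n features with largest MAD
#'
#' Median absolute deviation across samples, ties broken by lexicographic
#' feature ID so the selection is deterministic across platforms.
#'
#' @param m [omics_matrix()].
#' @param n number of features to keep (default 1500).
#' @return [omics_matrix()] with `n` features, in the original feature order.
#' @export
select_top_mad <- function(m, n = 1500) {
  stopifnot(inherits(m, "omics_matrix"))
  if (n > nrow(m$values))
    stop("n = ", n, " exceeds the number of features (", nrow(m$values), ")")
  mads <- apply(m$values, 1, stats::mad)
  keep <- sort(rank_features_desc(mads, m$feature_ids)[seq_len(n)])
  subset_omics(m, features = keep)
}

#' Keep the most variable fraction of features
#'
#' Keeps `ceil(frac * n_features)` features with the largest sample variance
#' (lexicographic-ID tie-break). Features with any missing value are dropped
#' first; their count is attached as attribute `n_dropped_na`.
#'
#' @param m [omics_matrix()].
#' @param frac fraction in (0, 1\]; default 0.01.
#' @return [omics_matrix()].
#' @export
select_top_variance_fraction <- function(m, frac = 0.01) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!(frac > 0 && frac <= 1)) stop("frac must be in (0, 1]")
  complete <- rowSums(is.na(m$values)) == 0
  n_dropped <- sum(!complete)
  m2 <- if (n_dropped > 0) subset_omics(m, features = which(complete)) else m
  n <- ceiling(frac * nrow(m2$values))
  vars <- apply(m2$values, 1, stats::var)
  keep <- sort(rank_features_desc(vars, m2$feature_ids)[seq_len(n)])
  out <- subset_omics(m2, features = keep)
  attr(out, "n_dropped_na") <- n_dropped
  out
}
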