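#' Fit a multivariate Cox multi-gene signature
#'
#' Standardizes the candidate genes' expression (z-score per gene), fits a
#' multivariate Cox proportional-hazards model on overall survival (Breslow
#' tie handling), and keeps the genes whose Wald p-value is below `p_keep`.
#' The signature weights are the retained coefficients: positive beta means
#' high expression shortens survival.
#'
#' @param expr [omics_matrix()] of kind `expression_normalized`.
#' @param clinical a [clinical_table()] covering `expr`'s samples.
#' @param candidate_genes genes to enter the model (must be in `expr`).
#' @param p_keep Wald retention threshold (default 0.05).
#' @return object of class `gene_signature`: `genes`, `weights` (named),
#'   `source` = "data_fusion" by default, plus the full `fit` and the
#'   per-gene coefficient table `coef_table`.
#' @export
fit_cox_mgs <- function(expr, clinical, candidate_genes, p_keep = 0.05) {
  stopifnot(inherits(expr, "omics_matrix"))
  missing <- setdiff(candidate_genes, expr$feature_ids)
  if (length(missing) > 0)
    stop("candidate genes absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  clinical <- as.data.frame(clinical)
  idx <- match(expr$sample_ids, clinical$sample_id)
  if (anyNA(idx)) stop("clinical table does not cover all samples")
  clin <- clinical[idx, ]
  if (sum(clin$os_event) == 0) stop("no events in the clinical table")
  z <- t(scale(t(expr$values[candidate_genes, , drop = FALSE])))
  keep <- apply(z, 1, function(r) all(is.finite(r)))
  z <- z[keep, , drop = FALSE]
  if (nrow(z) == 0) stop("all candidate genes are constant")
  df <- data.frame(t(z), check.names = FALSE)
  surv <- survival::Surv(clin$os_time, clin$os_event)
  fit <- survival::coxph(surv ~ ., data = df, ties = "breslow")
  if (!is.null(fit$info) && any(!is.finite(stats::coef(fit))))
    stop("Cox fit did not converge; inspect collinearity among candidates")
  sm <- summary(fit)
  ct <- data.frame(gene = rownames(sm$coefficients),
                   beta = sm$coefficients[, "coef"],
                   se = sm$coefficients[, "se(coef)"],
                   p = sm$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  kept <- ct[!is.na(ct$p) & ct$p < p_keep, , drop = FALSE]
  gene_signature(genes = kept$gene,
                 weights = stats::setNames(kept$beta, kept$gene),
                 source = "data_fusion",
                 extra = list(fit = fit, coef_table = ct))
}

#' Construct a gene signature
#'
#' @param genes character vector, no duplicates.
#' @param weights optional named numeric weights (Cox coefficients); an
#'   unweighted signature carries `weights = NULL`.
#' @param source method tag: one of `data_fusion`, `igc_gain`, `igc_loss`,
#'   `cnape`, `methylmix`.
#' @param extra optional list of additional fields kept on the object.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(genes, weights = NULL,
                           source = c("data_fusion", "igc_gain", "igc_loss",
                                      "cnape", "methylmix"),
                           extra = NULL) {
  source <- match.arg(source)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in signature")
  if (!is.null(weights)) {
    if (!all(is.finite(weights))) stop("signature weights must be finite")
    weights <- weights[genes]
  }
  structure(c(list(genes = genes, weights = weights, source = source),
              extra),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d gene(s)%s\n", x$source,
              length(x$genes),
              if (is.null(x$weights)) " (unweighted)" else ""))
  invisible(x)
}

#' Multi-gene score
#'
#' `score_s = sum_g beta_g * z_gs` on per-gene standardized expression.
#'
#' @param sig a weighted [gene_signature()].
#' @param expr [omics_matrix()] containing the signature genes.
#' @param allow_missing if TRUE, genes absent from `expr` are dropped and
#'   the score is computed on the available genes; if FALSE (default) a
#'   missing gene is an error.
#' @return named numeric vector of per-sample scores.
#' @export
multi_gene_score <- function(sig, expr, allow_missing = FALSE) {
  stopifnot(inherits(sig, "gene_signature"), inherits(expr, "omics_matrix"))
  if (is.null(sig$weights)) stop("multi_gene_score needs a weighted signature")
  genes <- sig$genes
  missing <- setdiff(genes, expr$feature_ids)
  if (length(missing) > 0) {
    if (!allow_missing)
      stop("signature genes missing from expression matrix: ",
           paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
    if (length(genes) == 0) stop("no signature gene available")
  }
  z <- t(scale(t(expr$values[genes, , drop = FALSE])))
  z[!is.finite(z)] <- 0  # constant gene: no contribution
  drop(crossprod(z, sig$weights[genes]))[expr$sample_ids]
}

#' Kaplan-Meier split and log-rank test on a score
#'
#' Dichotomizes at the median score (ties go to the low group), draws the
#' two Kaplan-Meier curves and tests their difference with the two-group
#' log-rank test.
#'
#' @param scores named per-sample scores.
#' @param clinical a [clinical_table()].
#' @param split only `"median"` is supported.
#' @return list: `group` (factor high/low per sample), `logrank_chisq`,
#'   `logrank_p`, `km` (a `survfit` object), `fit` (the `survdiff` object).
#' @export
km_logrank_split <- function(scores, clinical, split = "median") {
  split <- match.arg(split, "median")
  if (length(unique(scores)) < 2) stop("constant scores: no split possible")
  clinical <- as.data.frame(clinical)
  idx <- match(names(scores), clinical$sample_id)
  if (anyNA(idx)) stop("clinical table does not cover all scored samples")
  clin <- clinical[idx, ]
  group <- factor(ifelse(scores > stats::median(scores), "high", "low"),
                  levels = c("low", "high"))
  if (length(unique(group)) < 2) stop("median split produced one group")
  surv <- survival::Surv(clin$os_time, clin$os_event)
  sd_ <- survival::survdiff(surv ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  km <- survival::survfit(surv ~ group)
  list(group = stats::setNames(group, names(scores)),
       logrank_chisq = unname(sd_$chisq), logrank_p = p, km = km, fit = sd_)
}

#' Rank-based single-sample signature score
#'
#' Per sample, all genes are ranked ascending by expression (mean rank for
#' ties); the raw score is the mean rank of the signature genes divided by
#' the number of genes, then normalized to the attainable range for a set of
#' size m among n genes: min `(m+1)/(2n)`, max `(2n-m+1)/(2n)`. The result
#' is 0 when the set occupies the bottom ranks and 1 at the top, and is
#' invariant to any monotone transform of a sample's expression values.
#'
#' @param expr [omics_matrix()].
#' @param genes non-empty unweighted gene set, subset of the features.
#' @return named numeric vector of per-sample normalized scores.
#' @export
simple_score <- function(expr, genes) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (length(genes) == 0) stop("empty gene set")
  missing <- setdiff(genes, expr$feature_ids)
  if (length(missing) > 0)
    stop("genes not in matrix: ", paste(missing, collapse = ", "))
  n <- nrow(expr$values)
  m <- length(genes)
  lo <- (m + 1) / (2 * n)
  hi <- (2 * n - m + 1) / (2 * n)
  raw <- apply(expr$values, 2, function(col) {
    mean(rank(col, ties.method = "average")[match(genes, expr$feature_ids)]) / n
  })
  if (hi == lo) return(raw * 0 + 0.5)  # full gene set: range degenerates
  (raw - lo) / (hi - lo)
}

#' Min-max rescale to \[0, 1\]
#'
#' `(x - min) / (max - min)`; affine-invariant and idempotent.
#'
#' @param scores numeric vector with >= 2 distinct values.
#' @return rescaled vector attaining 0 and 1 exactly.
#' @export
minmax_rescale <- function(scores) {
  rng <- range(scores)
  if (diff(rng) == 0) stop("constant scores cannot be rescaled")
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' ROC curve and AUC of a signature score
#'
#' The predictor is `1 - score` when `invert` (the default for every method
#' except the gain-direction CNA signature, whose high score already tracks
#' the positive class), else the score itself. The ROC is a threshold sweep;
#' the AUC is the Mann-Whitney concordance probability with the usual 1/2
#' tie credit.
#'
#' @param scores per-sample scores in \[0, 1\] (or any numeric scores).
#' @param labels binary labels (1 = positive class: M3 or metastasis).
#' @param invert whether to use `1 - score` as predictor (default TRUE).
#' @return list: `auc`, `roc` (data.frame `fpr`, `tpr`, `threshold`),
#'   `predictor`.
#' @export
roc_auc <- function(scores, labels, invert = TRUE) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2) stop("both label classes must be present")
  pred <- if (invert) 1 - scores else scores
  # Mann-Whitney with tie correction via midranks
  r <- rank(pred, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # threshold sweep: step function from (0,0) to (1,1)
  thr <- c(Inf, sort(unique(pred), decreasing = TRUE))
  roc <- t(vapply(thr, function(t) {
    called <- pred >= t
    c(fpr = sum(called & labels == 0) / n0,
      tpr = sum(called & labels == 1) / n1)
  }, numeric(2)))
  list(auc = auc,
       roc = data.frame(fpr = roc[, "fpr"], tpr = roc[, "tpr"],
                        threshold = thr),
       predictor = pred)
}

#' Evaluate a signature against a clinical label
#'
#' Convenience wrapper: [simple_score()] on the signature genes, min-max
#' rescale, ROC/AUC against the chosen clinical label (score inversion for
#' every source except `igc_gain`), and a KM/log-rank median split.
#'
#' @param sig a [gene_signature()].
#' @param expr [omics_matrix()].
#' @param clinical a [clinical_table()].
#' @param label `"m3"` or `"metastasis"`.
#' @param allow_missing drop signature genes absent from `expr`.
#' @return list of class `signature_evaluation`: `score` (raw),
#'   `score_rescaled`, `auc`, `roc`, `km`, `label`, `source`.
#' @export
evaluate_signature <- function(sig, expr, clinical,
                               label = c("m3", "metastasis"),
                               allow_missing = FALSE) {
  stopifnot(inherits(sig, "gene_signature"))
  label <- match.arg(label)
  genes <- sig$genes
  if (allow_missing) genes <- intersect(genes, expr$feature_ids)
  sc <- simple_score(expr, genes)
  scr <- minmax_rescale(sc)
  clinical <- as.data.frame(clinical)
  y <- clinical[[label]][match(names(scr), clinical$sample_id)]
  ra <- roc_auc(scr, y, invert = sig$source != "igc_gain")
  km <- km_logrank_split(scr, clinical)
  structure(list(score = sc, score_rescaled = scr, auc = ra$auc,
                 roc = ra$roc, km = km, label = label, source = sig$source),
            class = "signature_evaluation")
}
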