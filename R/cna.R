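#' Classify genes by copy-number alteration pattern
#'
#' Per sample and gene, a discrete code > 0 is a gain event, < 0 a loss
#' event, 0 neutral (codes +/-2 are pooled with +/-1: any nonzero is an
#' event). Genes altered in fewer than `min_altered` samples are dropped.
#' A kept gene is classified `gain` when the fraction of gain samples is at
#' least `gain_prop`, `loss` when the loss fraction is at least `loss_prop`,
#' `both` when both hold, `none` otherwise. Thresholds are inclusive.
#'
#' @param cna [omics_matrix()] of kind `cna_discrete`.
#' @param gain_prop,loss_prop classification fractions (default 0.2).
#' @param min_altered minimum number of altered samples (default 4).
#' @return data.frame, one row per retained gene: `gene`, `cna_class`,
#'   `n_gain`, `n_loss`, `n_neutral`.
#' @export
classify_gene_cna <- function(cna, gain_prop = 0.2, loss_prop = 0.2,
                              min_altered = 4) {
  stopifnot(inherits(cna, "omics_matrix"))
  if (cna$kind != "cna_discrete")
    stop("classify_gene_cna expects cna_discrete, got ", cna$kind)
  v <- cna$values
  if (any(v != round(v))) stop("CNA codes must be integers")
  n <- ncol(v)
  n_gain <- rowSums(v > 0)
  n_loss <- rowSums(v < 0)
  altered <- n_gain + n_loss
  keep <- altered >= min_altered
  gain <- n_gain[keep] / n >= gain_prop
  loss <- n_loss[keep] / n >= loss_prop
  cls <- ifelse(gain & loss, "both",
                ifelse(gain, "gain", ifelse(loss, "loss", "none")))
  data.frame(gene = cna$feature_ids[keep], cna_class = cls,
             n_gain = n_gain[keep], n_loss = n_loss[keep],
             n_neutral = n - altered[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' CNA-expression association (IGC-style)
#'
#' For each classified gene and each direction it carries (gain, loss, or
#' both), a Welch two-sample t-test compares normalized expression in event
#' samples against neutral samples (two-sided). P-values are
#' Benjamini-Hochberg adjusted within each direction across genes; a test is
#' kept when its FDR is below `fdr_threshold`.
#'
#' @param expr [omics_matrix()] of kind `expression_normalized`.
#' @param cna [omics_matrix()] of kind `cna_discrete`, same genes/samples.
#' @param classes optional precomputed [classify_gene_cna()] table; computed
#'   from `cna` when NULL.
#' @param fdr_threshold FDR cut (default 0.05).
#' @param ... forwarded to [classify_gene_cna()].
#' @return data.frame, one row per gene x tested direction: `gene`,
#'   `direction`, `cna_class`, `n_event`, `n_neutral`, `t`, `p`, `fdr`,
#'   `kept`, `skipped` (TRUE when a direction had < 2 event or < 2 neutral
#'   samples).
#' @export
cna_expression_test <- function(expr, cna, classes = NULL,
                                fdr_threshold = 0.05, ...) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (expr$kind != "expression_normalized")
    stop("cna_expression_test expects expression_normalized, got ", expr$kind)
  if (is.null(classes)) classes <- classify_gene_cna(cna, ...)
  genes <- intersect(classes$gene[classes$cna_class != "none"],
                     expr$feature_ids)
  samples <- intersect(expr$sample_ids, cna$sample_ids)
  if (length(samples) < 4) stop("expr and cna share too few samples")
  ev <- expr$values[, samples, drop = FALSE]
  cv <- cna$values[, samples, drop = FALSE]

  rows <- list()
  for (g in genes) {
    cls <- classes$cna_class[classes$gene == g]
    dirs <- if (cls == "both") c("gain", "loss") else cls
    for (dir in dirs) {
      event <- if (dir == "gain") cv[g, ] > 0 else cv[g, ] < 0
      neutral <- cv[g, ] == 0
      skipped <- sum(event) < 2 || sum(neutral) < 2
      if (skipped) {
        tt <- list(statistic = NA_real_, p.value = NA_real_)
      } else {
        tt <- stats::t.test(ev[g, event], ev[g, neutral],
                            var.equal = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, direction = dir, cna_class = cls,
        n_event = sum(event), n_neutral = sum(neutral),
        t = unname(tt$statistic), p = tt$p.value, skipped = skipped,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), direction = character(),
                      cna_class = character(), n_event = integer(),
                      n_neutral = integer(), t = numeric(), p = numeric(),
                      fdr = numeric(), kept = logical(), skipped = logical()))
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (dir in unique(out$direction)) {
    sel <- out$direction == dir & !out$skipped
    out$fdr[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$kept <- !out$skipped & out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}

#' Penalized-logistic prediction of chromosome-3 monosomy (CNAPE-style)
#'
#' Fits an elastic-net logistic regression of a binary arm-level copy-number
#' label (M3) on standardized gene expression, with L1 mixing
#' `mixing = 0.1` and the penalty strength chosen by `n_folds`-fold
#' cross-validated deviance at its minimum. The genes with nonzero
#' coefficients at the chosen penalty are the selected predictor set.
#'
#' @param expr [omics_matrix()] of kind `expression_normalized`.
#' @param label binary per-sample label (chromosome-3 monosomy), named by
#'   sample ID or in `expr` sample order.
#' @param mixing elastic-net mixing parameter alpha (default 0.1).
#' @param n_folds cross-validation folds (default 20).
#' @param seed integer seed (fold assignment).
#' @param lambda_rule `"min"` (CV-deviance minimum, default) or `"1se"`.
#' @return object of class `penalized_model`: `coefficients` (named,
#'   original scale, incl. `(Intercept)`), `selected_genes`, `lambda`,
#'   `cv_curve` (data.frame lambda/deviance), `mixing`, `n_folds`, `seed`,
#'   and the underlying `fit` (a `cv.glmnet` object).
#' @export
cnape_model <- function(expr, label, mixing = 0.1, n_folds = 20, seed = 1L,
                        lambda_rule = c("min", "1se")) {
  stopifnot(inherits(expr, "omics_matrix"))
  lambda_rule <- match.arg(lambda_rule)
  x <- t(expr$values)  # samples x genes
  if (!is.null(names(label))) label <- label[rownames(x)]
  y <- as.integer(label)
  if (length(unique(y)) < 2) stop("label must contain both classes")
  if (length(y) != nrow(x)) stop("label length does not match samples")
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(x)))
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = mixing,
                           foldid = foldid, standardize = TRUE,
                           type.measure = "deviance")
  lam <- if (lambda_rule == "min") fit$lambda.min else fit$lambda.1se
  beta <- as.matrix(stats::coef(fit, s = lam))[, 1]
  selected <- setdiff(names(beta)[beta != 0], "(Intercept)")
  structure(list(coefficients = beta, selected_genes = selected,
                 lambda = lam,
                 cv_curve = data.frame(lambda = fit$lambda,
                                       deviance = fit$cvm),
                 mixing = mixing, n_folds = n_folds, seed = seed,
                 fit = fit),
            class = "penalized_model")
}

#' @export
print.penalized_model <- function(x, ...) {
  cat(sprintf("<penalized_model> alpha = %g, lambda = %.4g, %d genes selected\n",
              x$mixing, x$lambda, length(x$selected_genes)))
  invisible(x)
}
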