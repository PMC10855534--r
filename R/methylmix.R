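#' Screen for transcriptionally predictive methylation-driven genes
#'
#' MethylMix-style procedure, per gene: (i) fit univariate Gaussian mixtures
#' with 1..`max_components` components to the cancer-group methylation
#' (beta values clipped to \[0.001, 0.999\]) and pick the component count by
#' BIC; (ii) compute the differential methylation value DM of each component
#' (component mean minus the control-group mean) and keep the gene when at
#' least one |DM| reaches `dm_threshold`; (iii) regress the cancer-group
#' expression of the gene on its methylation; the gene is transcriptionally
#' predictive when the fit reaches `r2_min` and the F-test p-value is at
#' most `p_max` — and, under the default inverse-only policy, the slope is
#' negative. Only predictive genes are returned.
#'
#' The control group is typically the low-risk fused cluster (the pipeline
#' wires cluster 2 in as control), but any control matrix can be supplied.
#'
#' @param met_cancer [omics_matrix()] of gene-level methylation (cancer
#'   group).
#' @param ge_cancer [omics_matrix()] of normalized expression, same samples
#'   as `met_cancer`; genes are matched by feature ID.
#' @param met_normal [omics_matrix()] of gene-level methylation for the
#'   control group.
#' @param dm_threshold minimum |DM| (default 0.10).
#' @param r2_min minimum regression R-squared (default 0.1).
#' @param p_max maximum F-test p-value (default 0.001).
#' @param max_components maximum mixture components (default 3).
#' @param inverse_only if TRUE (default), require a negative
#'   methylation-expression slope.
#' @return data.frame, one row per predictive gene: `gene`, `n_components`,
#'   `component_means`, `component_weights`, `dm` (comma-separated per
#'   component), `max_abs_dm`, `slope`, `r2`, `p`.
#' @export
methylmix_screen <- function(met_cancer, ge_cancer, met_normal,
                             dm_threshold = 0.10, r2_min = 0.1,
                             p_max = 0.001, max_components = 3,
                             inverse_only = TRUE) {
  stopifnot(inherits(met_cancer, "omics_matrix"),
            inherits(ge_cancer, "omics_matrix"),
            inherits(met_normal, "omics_matrix"))
  genes <- Reduce(intersect, list(met_cancer$feature_ids,
                                  ge_cancer$feature_ids,
                                  met_normal$feature_ids))
  samples <- intersect(met_cancer$sample_ids, ge_cancer$sample_ids)
  if (length(genes) == 0) stop("no shared genes between inputs")
  if (length(samples) < 4) stop("too few shared cancer samples")

  clip <- function(v) pmin(pmax(v, 0.001), 0.999)
  rows <- list()
  for (g in genes) {
    met <- clip(met_cancer$values[g, samples])
    ctrl_mean <- mean(clip(met_normal$values[g, ]))
    if (stats::sd(met) < 1e-8) next  # constant methylation: never differential
    fit <- fit_beta_mixture(met, max_components)
    dm <- fit$means - ctrl_mean
    if (max(abs(dm)) < dm_threshold) next
    ge <- ge_cancer$values[g, samples]
    reg <- stats::lm(ge ~ met)
    sm <- summary(reg)
    slope <- unname(stats::coef(reg)[2])
    r2 <- sm$r.squared
    pf <- sm$fstatistic
    p <- if (is.null(pf)) NA_real_ else
      stats::pf(pf[1], pf[2], pf[3], lower.tail = FALSE)
    if (is.na(p) || r2 < r2_min || p > p_max) next
    if (inverse_only && slope >= 0) next
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, n_components = length(fit$means),
      component_means = paste(signif(fit$means, 4), collapse = ","),
      component_weights = paste(signif(fit$weights, 4), collapse = ","),
      dm = paste(signif(dm, 4), collapse = ","),
      max_abs_dm = max(abs(dm)), slope = slope, r2 = r2, p = unname(p),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), n_components = integer(),
                      component_means = character(),
                      component_weights = character(), dm = character(),
                      max_abs_dm = numeric(), slope = numeric(),
                      r2 = numeric(), p = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Univariate Gaussian mixture on (clipped) beta values, component count by
# BIC over 1..max_components. Equal-variance and varying-variance models are
# both tried; mclust's BIC is maximized.
#' @importFrom mclust Mclust mclustBIC
fit_beta_mixture <- function(v, max_components = 3) {
  gmax <- min(max_components, length(unique(v)))
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(v, G = seq_len(gmax),
                                    modelNames = c("E", "V"),
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(means = mean(v), weights = 1, n = 1L))
  list(means = unname(fit$parameters$mean),
       weights = unname(fit$parameters$pro),
       n = fit$G)
}
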