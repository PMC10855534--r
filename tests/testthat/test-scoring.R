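# Table of multi-gene-score weights used in the published uveal-melanoma
# signature; two entries exercise the sign convention checks.
mgs_weights <- c(ROBO1 = -0.241, ROPN1 = 0.312)

test_that("null survival retains almost no candidate genes", {
  kept <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    x <- matrix(rnorm(20 * n), 20, n,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
    expr <- omics_matrix(x, "expression_normalized")
    surv <- simulate_survival(rep(0, n), 1 / 1000, censor_rate = 0.3)
    clin <- clinical_table(data.frame(
      sample_id = colnames(x), os_time = surv$time, os_event = surv$event,
      metastasis = 0, m3 = 0, molecular_class = 1))
    length(fit_cox_mgs(expr, clin, rownames(x))$genes)
  }, numeric(1))
  # calibrated Wald retention keeps ~ Binomial(20, 0.05) genes per seed
  expect_lte(mean(kept), 2)
  expect_lte(median(kept), 1)
})

test_that("Cox coefficients cover the truth at the stated rate", {
  covered <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 250
    z <- matrix(rnorm(2 * n), 2, n,
                dimnames = list(c("gA", "gB"), paste0("s", 1:n)))
    beta_true <- c(0.8, -0.8)
    surv <- simulate_survival(drop(crossprod(z, beta_true)), 1 / 1000,
                              censor_rate = 0.2)
    clin <- clinical_table(data.frame(
      sample_id = colnames(z), os_time = surv$time, os_event = surv$event,
      metastasis = 0, m3 = 0, molecular_class = 1))
    expr <- omics_matrix(z, "expression_normalized")
    sig <- fit_cox_mgs(expr, clin, c("gA", "gB"), p_keep = 1)
    ct <- sig$coef_table
    # covariates enter z-scored; rescale the truth by each gene's sd
    sds <- apply(z, 1, sd)
    all(abs(ct$beta - beta_true * sds[ct$gene]) <= 1.96 * ct$se)
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("a gene that shortens survival gets a positive coefficient", {
  set.seed(60)
  n <- 200
  z <- matrix(rnorm(n), 1, n, dimnames = list("gRISK", paste0("s", 1:n)))
  surv <- simulate_survival(drop(z) * 1.0, 1 / 800, censor_rate = 0.2)
  clin <- clinical_table(data.frame(
    sample_id = colnames(z), os_time = surv$time, os_event = surv$event,
    metastasis = 0, m3 = 0, molecular_class = 1))
  sig <- fit_cox_mgs(omics_matrix(z, "expression_normalized"), clin, "gRISK")
  expect_gt(sig$weights[["gRISK"]], 0)
})

test_that("the multi-gene score is the weighted sum of z-scores", {
  sig <- gene_signature(names(mgs_weights), mgs_weights, "data_fusion")
  set.seed(61)
  n <- 40
  v <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(names(mgs_weights), paste0("s", 1:n)))
  expr <- omics_matrix(v, "expression_normalized")
  sc <- multi_gene_score(sig, expr)
  z <- t(scale(t(v)))
  expect_equal(unname(sc), unname(drop(crossprod(z, mgs_weights))),
               tolerance = 1e-12)
  # a sample at z = +1 on ROBO1 and 0 elsewhere contributes -0.241
  expect_equal(unname(sum(c(1, 0) * mgs_weights)), -0.241)
  # linearity and weight equivariance
  sig2 <- gene_signature(names(mgs_weights), 2 * mgs_weights, "data_fusion")
  expect_equal(unname(multi_gene_score(sig2, expr)), unname(2 * sc),
               tolerance = 1e-12)
  expect_error(multi_gene_score(sig, omics_matrix(v[1, , drop = FALSE],
                                                  "expression_normalized")),
               "ROPN1")
})

test_that("log-rank median split: type-I error, power, and the O-E oracle", {
  # identical generators: uniform p, bounded rejection
  rej <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 40
    surv <- simulate_survival(rep(0, n), 1 / 500, censor_rate = 0.2)
    clin <- clinical_table(data.frame(
      sample_id = paste0("s", 1:n), os_time = surv$time,
      os_event = surv$event, metastasis = 0, m3 = 0, molecular_class = 1))
    sc <- setNames(rnorm(n), paste0("s", 1:n))
    km_logrank_split(sc, clin)$logrank_p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.08)

  # hazard ratio 3, scores = true class: strong rejection
  set.seed(62)
  n <- 100
  cls <- rep(c(0, 1), each = n / 2)
  surv <- simulate_survival(cls * log(3), 1 / 500, censor_rate = 0.2)
  clin <- clinical_table(data.frame(
    sample_id = paste0("s", 1:n), os_time = surv$time,
    os_event = surv$event, metastasis = 0, m3 = 0, molecular_class = 1))
  km <- km_logrank_split(setNames(cls + rnorm(n, 0, 1e-6), paste0("s", 1:n)),
                         clin)
  expect_lt(km$logrank_p, 0.001)

  # 6-patient hand example: all events, groups A = {1,3,5}, B = {2,4,6}
  clin6 <- clinical_table(data.frame(
    sample_id = paste0("p", 1:6), os_time = c(1, 2, 3, 4, 5, 6),
    os_event = 1, metastasis = 0, m3 = 0, molecular_class = 1))
  sc6 <- setNames(c(0, 1, 0, 1, 0, 1), paste0("p", 1:6))
  km6 <- km_logrank_split(sc6, clin6)
  # textbook O-E: at each event time, E_high = n_high / n_total
  at_risk_high <- c(3, 3, 2, 2, 1, 1)
  at_risk_tot <- 6:1
  events_high <- c(0, 1, 0, 1, 0, 1)
  E <- sum(at_risk_high / at_risk_tot)
  V <- sum((at_risk_high / at_risk_tot) * (1 - at_risk_high / at_risk_tot))
  chisq_hand <- (sum(events_high) - E)^2 / V
  expect_equal(km6$logrank_chisq, chisq_hand, tolerance = 1e-10)
  expect_error(km_logrank_split(setNames(rep(1, 6), paste0("p", 1:6)), clin6),
               "constant")
})

test_that("rank-based signature scores match hand enumeration", {
  v <- matrix(c(1, 2, 3, 4, 5), 5, 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  expr <- omics_matrix(v, "expression_normalized")
  # top-2 genes: mean rank 4.5, raw 0.9 = the attainable max -> score 1
  expect_equal(unname(simple_score(expr, c("g4", "g5"))), 1)
  # bottom-2 genes: mean rank 1.5, raw 0.3 = attainable min -> score 0
  expect_equal(unname(simple_score(expr, c("g1", "g2"))), 0)
  # middle set: raw 0.6 -> (0.6 - 0.3) / (0.9 - 0.3)
  expect_equal(unname(simple_score(expr, c("g2", "g4"))),
               (0.6 - 0.3) / (0.9 - 0.3))
  # the whole gene set scores identically for every sample
  m <- toy_matrix(10, 5, seed = 63)
  all_sc <- simple_score(m, m$feature_ids)
  expect_equal(diff(range(all_sc)), 0)
  expect_error(simple_score(m, character(0)), "empty")
})

test_that("signature scores are invariant to monotone per-sample transforms", {
  m <- toy_matrix(30, 8, seed = 64)
  genes <- m$feature_ids[c(3, 10, 22)]
  s1 <- simple_score(m, genes)
  warped <- omics_matrix(exp(m$values / 2), "expression_normalized")
  expect_equal(s1, simple_score(warped, genes), tolerance = 1e-12)
  # raising a set gene's rank never lowers the score
  v <- m$values
  v[genes[1], 1] <- max(v[, 1]) + 1
  s2 <- simple_score(omics_matrix(v, "expression_normalized"), genes)
  expect_gte(s2[[1]], s1[[1]])
})

test_that("min-max rescaling is exact, affine-invariant, and idempotent", {
  expect_equal(minmax_rescale(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(65)
  x <- rnorm(20)
  r <- minmax_rescale(x)
  expect_equal(range(r), c(0, 1))
  expect_equal(minmax_rescale(3 * x + 7), r, tolerance = 1e-12)
  expect_equal(minmax_rescale(r), r, tolerance = 1e-12)
  expect_error(minmax_rescale(rep(1, 5)), "constant")
})

test_that("AUC equals the pair-counting oracle, including ties", {
  out <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), invert = FALSE)
  expect_equal(out$auc, oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  for (s in 1:10) {
    set.seed(s)
    sc <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # many ties
    lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    out <- roc_auc(sc, lab, invert = FALSE)
    expect_equal(out$auc, oracle_auc(sc, lab))
    # ROC endpoints
    expect_equal(out$roc$fpr[1], 0); expect_equal(out$roc$tpr[1], 0)
    expect_equal(out$roc$fpr[nrow(out$roc)], 1)
    expect_equal(out$roc$tpr[nrow(out$roc)], 1)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  sc <- rnorm(50); lab <- rbinom(50, 1, 0.4)
  ours <- roc_auc(sc, lab, invert = FALSE)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("perfect separation and label swaps behave canonically", {
  sc <- c(0.9, 0.8, 0.2, 0.1)
  lab <- c(1, 1, 0, 0)
  expect_equal(roc_auc(sc, lab, invert = FALSE)$auc, 1)
  expect_equal(roc_auc(sc, lab, invert = TRUE)$auc, 0)
  set.seed(67)
  sc <- runif(20); lab <- rbinom(20, 1, 0.5)
  if (length(unique(lab)) >= 2) {
    a <- roc_auc(sc, lab, invert = FALSE)$auc
    b <- roc_auc(sc, 1 - lab, invert = FALSE)$auc
    expect_equal(a, 1 - b, tolerance = 1e-12)
  }
  expect_error(roc_auc(sc, rep(1, 20)), "both label classes")
})
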