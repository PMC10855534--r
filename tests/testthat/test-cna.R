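cna_fixture <- function(codes, ids = NULL) {
  v <- do.call(rbind, codes)
  rownames(v) <- ids %||% paste0("g", seq_along(codes))
  colnames(v) <- paste0("s", seq_len(ncol(v)))
  omics_matrix(v, "cna_discrete")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("genes below the minimum altered-sample count are dropped", {
  m <- cna_fixture(list(c(rep(-1, 3), rep(0, 7)),      # 3 altered: dropped
                        c(rep(-1, 4), rep(0, 6))))     # 4 altered: kept
  out <- classify_gene_cna(m)
  expect_equal(out$gene, "g2")
  expect_equal(out$cna_class, "loss")
})

test_that("the classification fraction is inclusive at the threshold", {
  m <- cna_fixture(list(c(rep(1, 4), rep(0, 16))))  # 4/20 = 0.20 exactly
  out <- classify_gene_cna(m)
  expect_equal(out$cna_class, "gain")
})

test_that("mixed and sub-threshold patterns classify correctly", {
  m <- cna_fixture(list(
    c(rep(1, 5), rep(-1, 5), rep(0, 10)),   # both at 0.25/0.25
    c(rep(1, 3), rep(-1, 2), rep(0, 15)),   # 5 altered, both fracs < 0.2
    c(rep(2, 3), rep(1, 2), rep(0, 15))))   # codes +/-2 pool with +/-1
  out <- classify_gene_cna(m)
  expect_equal(out$cna_class[out$gene == "g1"], "both")
  expect_equal(out$cna_class[out$gene == "g2"], "none")
  expect_equal(out$cna_class[out$gene == "g3"], "gain")
})

test_that("classification matches a brute-force counting oracle", {
  set.seed(20)
  v <- matrix(sample(-2:2, 40 * 25, replace = TRUE,
                     prob = c(0.05, 0.15, 0.6, 0.15, 0.05)), 40, 25,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:25)))
  m <- omics_matrix(v, "cna_discrete")
  out <- classify_gene_cna(m, gain_prop = 0.2, loss_prop = 0.2,
                           min_altered = 4)
  for (g in rownames(v)) {
    ng <- 0; nl <- 0
    for (s in colnames(v)) {
      if (v[g, s] > 0) ng <- ng + 1
      if (v[g, s] < 0) nl <- nl + 1
    }
    if (ng + nl < 4) {
      expect_false(g %in% out$gene)
    } else {
      cls <- "none"
      if (ng / 25 >= 0.2 && nl / 25 >= 0.2) cls <- "both"
      else if (ng / 25 >= 0.2) cls <- "gain"
      else if (nl / 25 >= 0.2) cls <- "loss"
      expect_equal(out$cna_class[out$gene == g], cls)
    }
  }
})

test_that("the Welch test equals the closed-form oracle", {
  expr_v <- rbind(g1 = c(1, 2, 3, 6, 7, 8, 9))
  colnames(expr_v) <- paste0("s", 1:7)
  expr <- omics_matrix(expr_v, "expression_normalized")
  cna <- cna_fixture(list(c(-1, -1, -1, 0, 0, 0, 0)), ids = "g1")
  out <- cna_expression_test(expr, cna, min_altered = 3, loss_prop = 0.2)
  o <- oracle_welch(c(1, 2, 3), c(6, 7, 8, 9))
  expect_equal(out$t, o$t, tolerance = 1e-12)
  expect_equal(out$p, o$p, tolerance = 1e-12)
})

test_that("per-direction BH adjustment matches the textbook step-up rule", {
  set.seed(21)
  n <- 30
  v <- lapply(1:n, function(i) {
    x <- rep(0, 40); x[sample(40, 10)] <- -1; x
  })
  cna <- cna_fixture(v)
  ev <- matrix(rnorm(n * 40), n, 40,
               dimnames = list(paste0("g", 1:n), paste0("s", 1:40)))
  expr <- omics_matrix(ev, "expression_normalized")
  out <- cna_expression_test(expr, cna)
  loss <- out[out$direction == "loss" & !out$skipped, ]
  expect_equal(loss$fdr, oracle_bh(loss$p), tolerance = 1e-12)
})

test_that("null CNA-expression associations are rarely kept", {
  kept_frac <- vapply(1:10, function(s) {
    set.seed(s)
    v <- lapply(1:60, function(i) {
      x <- rep(0, 50); x[sample(50, 12)] <- sample(c(-1, 1), 1); x
    })
    cna <- cna_fixture(v)
    ev <- matrix(rnorm(60 * 50), 60, 50,
                 dimnames = list(paste0("g", 1:60), paste0("s", 1:50)))
    expr <- omics_matrix(ev, "expression_normalized")
    out <- cna_expression_test(expr, cna)
    mean(out$kept)
  }, numeric(1))
  expect_lte(mean(kept_frac), 2 * 0.05)
})

test_that("a planted dosage gene is kept as loss with small FDR", {
  set.seed(22)
  n_s <- 55
  cn <- c(rep(-1, 15), rep(0, 40))
  # log2-scale noise sd ~ 0.6, typical of bulk expression at NB dispersion 0.2
  noise <- matrix(rnorm(20 * n_s, sd = 0.6), 20, n_s)
  noise[1, ] <- noise[1, ] + 1.0 * cn  # delta_cna = 1 on the planted gene
  rownames(noise) <- paste0("g", 1:20)
  colnames(noise) <- paste0("s", 1:n_s)
  codes <- rbind(cn, matrix(0, 19, n_s))
  # give the null genes some alterations so they are tested too
  for (i in 2:20) codes[i, sample(n_s, 12)] <- -1
  rownames(codes) <- rownames(noise); colnames(codes) <- colnames(noise)
  out <- cna_expression_test(omics_matrix(noise, "expression_normalized"),
                             omics_matrix(codes, "cna_discrete"))
  g1 <- out[out$gene == "g1", ]
  expect_true(g1$kept)
  expect_equal(g1$direction, "loss")
  expect_lt(g1$fdr, 0.01)
})

test_that("directions with too few samples are skipped and recorded", {
  expr <- omics_matrix(matrix(rnorm(20), 1, 20,
                              dimnames = list("g1", paste0("s", 1:20))),
                       "expression_normalized")
  cna <- cna_fixture(list(c(rep(1, 19), 0)), ids = "g1")
  out <- cna_expression_test(expr, cna)
  expect_true(out$skipped[1])
  expect_false(out$kept[1])
})

test_that("a perfectly separating gene dominates the penalized model", {
  set.seed(23)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:n)))
  x[7, ] <- y * 4 + rnorm(n, sd = 0.1)
  expr <- omics_matrix(x, "expression_normalized")
  fit <- cnape_model(expr, setNames(y, colnames(x)), seed = 1)
  co <- fit$coefficients[setdiff(names(fit$coefficients), "(Intercept)")]
  expect_equal(names(which.max(abs(co))), "g7")
  expect_true("g7" %in% fit$selected_genes)
})

test_that("permuted labels collapse the selected set", {
  set.seed(24)
  n <- 50
  x <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:n)))
  expr <- omics_matrix(x, "expression_normalized")
  n_null <- vapply(1:8, function(s) {
    set.seed(100 + s)
    y <- sample(rep(c(0, 1), each = n / 2))
    length(suppressWarnings(
      cnape_model(expr, setNames(y, colnames(x)), seed = s,
                  lambda_rule = "1se"))$selected_genes)
  }, numeric(1))
  # under the null the parsimonious rule mostly returns an empty model;
  # CV noise occasionally admits an interior lambda with tiny coefficients
  expect_lte(median(n_null), 2)
  # a planted signal selects a large share of the panel by contrast
  x2 <- x
  y2 <- rep(c(0, 1), each = n / 2)
  x2[1:10, ] <- x2[1:10, ] + matrix(rep(y2 * 1.5, each = 10), 10, n)
  fit <- suppressWarnings(  # 20 folds on 50 samples: glmnet notes small folds
    cnape_model(omics_matrix(x2, "expression_normalized"),
                setNames(y2, colnames(x2)), seed = 1))
  expect_gte(mean(paste0("g", 1:10) %in% fit$selected_genes), 0.8)
})

test_that("the coefficient path shrinks monotonically with the penalty", {
  set.seed(25)
  co <- generate_cohort(cohort_config(n_samples_per_class = c(low = 20, high = 20),
                                      n_genes = 100, n_probes = 100,
                                      n_de_genes = 10, n_dosage_genes = 10,
                                      n_meth_driver_genes = 5, seed = 25))
  norm <- normalize_counts(co$expression_counts)
  m3 <- setNames(co$clinical$m3, co$clinical$sample_id)
  fit <- suppressWarnings(cnape_model(norm, m3, seed = 1))
  beta_l1 <- colSums(abs(as.matrix(fit$fit$glmnet.fit$beta)))
  lam <- fit$fit$glmnet.fit$lambda  # decreasing
  expect_true(all(diff(beta_l1) >= -1e-8))  # ||beta||_1 grows as lambda drops
  expect_error(cnape_model(norm, setNames(rep(1, 40), norm$sample_ids)),
               "both classes")
})
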