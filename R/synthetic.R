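#' Configuration of a synthetic multi-omics cohort
#'
#' Defines the coupled structure the generator plants: two risk classes
#' (low/high), negative-binomial expression with class-shifted means for DE
#' genes and copy-scaled means for dosage genes on chromosome arms 3p/3q,
#' logit-normal methylation with bimodal class-shifted modes for
#' methylation-driver genes inversely coupled to their expression, exponential
#' survival with a class hazard ratio and independent censoring, and a
#' chromosome-3 monosomy (M3) flag drawn per class.
#'
#' Defaults mirror a TCGA-UVM-sized cohort: 80 patients in two classes of 40,
#' strong M3 enrichment in the high-risk class, a five-year follow-up horizon.
#'
#' @param n_samples_per_class named integer vector `c(low = , high = )`.
#' @param n_genes,n_probes matrix sizes (genes and methylation probes).
#' @param n_de_genes number of differentially expressed genes; `delta_expr`
#'   is their log2 mean shift in the high class (random sign per gene).
#' @param n_dosage_genes number of dosage genes placed on arms 3p/3q;
#'   `delta_cna` is the per-copy log2 expression effect.
#' @param p_m3_high,p_m3_low probability of chromosome-3 loss per class.
#' @param n_meth_driver_genes genes with bimodal hypermethylation in the high
#'   class; `gamma_meth` is the (negative) log2-expression-per-beta slope
#'   coupling methylation to expression.
#' @param baseline_hazard exponential event rate per day in the low class;
#'   `log_hr` the log hazard ratio of the high class.
#' @param censor_rate target fraction of censored observations.
#' @param followup_days administrative follow-up horizon; the metastasis
#'   indicator is an event time before this horizon.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param bg_cna_rate per-sample rate of background copy-number noise on
#'   genes outside chromosome 3 (alterations with no expression effect).
#' @param partial_deletion if TRUE, each M3 event deletes only a random
#'   contiguous stretch of chromosome-3 genes instead of the whole arm pair.
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples_per_class = c(low = 40, high = 40),
                          n_genes = 1000, n_probes = 1000,
                          n_de_genes = 50, delta_expr = 1.5,
                          n_dosage_genes = 40, delta_cna = 1.0,
                          p_m3_high = 0.9, p_m3_low = 0.1,
                          n_meth_driver_genes = 30, gamma_meth = -3,
                          baseline_hazard = 1 / 4000, log_hr = log(3),
                          censor_rate = 0.3, followup_days = 1825,
                          dispersion = 0.2, bg_cna_rate = 0.05,
                          partial_deletion = FALSE, seed = 1L) {
  cfg <- list(n_samples_per_class = n_samples_per_class,
              n_genes = n_genes, n_probes = n_probes,
              n_de_genes = n_de_genes, delta_expr = delta_expr,
              n_dosage_genes = n_dosage_genes, delta_cna = delta_cna,
              p_m3_high = p_m3_high, p_m3_low = p_m3_low,
              n_meth_driver_genes = n_meth_driver_genes,
              gamma_meth = gamma_meth,
              baseline_hazard = baseline_hazard, log_hr = log_hr,
              censor_rate = censor_rate, followup_days = followup_days,
              dispersion = dispersion, bg_cna_rate = bg_cna_rate,
              partial_deletion = partial_deletion, seed = as.integer(seed))
  probs <- c(cfg$p_m3_high, cfg$p_m3_low, cfg$censor_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
  if (any(!is.finite(c(cfg$delta_expr, cfg$delta_cna, cfg$gamma_meth,
                       cfg$log_hr))))
    stop("effect sizes must be finite")
  if (any(cfg$n_samples_per_class < 1))
    stop("each class needs at least one sample")
  if (cfg$n_de_genes + cfg$n_dosage_genes + cfg$n_meth_driver_genes >
      cfg$n_genes)
    stop("planted gene roles exceed n_genes")
  if (cfg$n_probes < cfg$n_dosage_genes + cfg$n_de_genes +
      cfg$n_meth_driver_genes)
    stop("n_probes too small to cover the planted methylation-driver genes")
  class(cfg) <- "cohort_config"
  cfg
}

# Chromosome arms used for feature annotation; chr3 arms carry the planted
# dosage genes, the rest of the genome is spread over the UM-relevant arms.
.arms <- c("1p", "1q", "3p", "3q", "6p", "6q", "8p", "8q", "16p", "16q", "other")

#' Simulate exponential survival with independent censoring
#'
#' Event times are exponential with rate `baseline_hazard * exp(lp)`;
#' censoring times are exponential with a rate chosen so that roughly
#' `censor_rate` of baseline-class observations are censored.
#'
#' @param lp per-sample linear predictor (log hazard ratio scale).
#' @param baseline_hazard event rate per day at `lp = 0`.
#' @param censor_rate target censoring fraction.
#' @return data.frame with `time`, `event` (1 = observed), and the latent
#'   uncensored `event_time`.
#' @export
simulate_survival <- function(lp, baseline_hazard, censor_rate = 0.3) {
  n <- length(lp)
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(lp))
  if (censor_rate <= 0) {
    return(data.frame(time = t_event, event = 1L, event_time = t_event))
  }
  cens_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
  t_cens <- stats::rexp(n, rate = cens_rate)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             event_time = t_event)
}

#' Generate a coupled synthetic cohort
#'
#' Draws expression counts, methylation beta values, discrete copy-number
#' calls and a clinical table with the planted structure described in
#' [cohort_config()], plus per-gene truth labels
#' (`de` / `dosage` / `meth_driver` / `null`) and the true class per sample.
#'
#' @param cfg a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements
#'   `expression_counts`, `methylation_beta`, `cna_discrete`
#'   (all [omics_matrix()]), `clinical` ([clinical_table()]) and `truth`
#'   (list with `gene_roles` data.frame and `true_class` vector).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n_low <- cfg$n_samples_per_class[["low"]]
  n_high <- cfg$n_samples_per_class[["high"]]
  n <- n_low + n_high
  true_class <- rep(c("low", "high"), c(n_low, n_high))
  high <- as.integer(true_class == "high")
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))

  # gene roles: disjoint planted sets, remainder null
  role <- rep("null", cfg$n_genes)
  idx_dosage <- seq_len(cfg$n_dosage_genes)
  idx_de <- seq_len(cfg$n_de_genes) + cfg$n_dosage_genes
  idx_meth <- seq_len(cfg$n_meth_driver_genes) + cfg$n_dosage_genes +
    cfg$n_de_genes
  role[idx_dosage] <- "dosage"
  role[idx_de] <- "de"
  role[idx_meth] <- "meth_driver"

  # arm annotation: dosage genes split over 3p/3q, others over remaining arms
  arm <- rep(NA_character_, cfg$n_genes)
  arm[idx_dosage] <- rep(c("3p", "3q"), length.out = cfg$n_dosage_genes)
  other_arms <- setdiff(.arms, c("3p", "3q"))
  rest <- setdiff(seq_len(cfg$n_genes), idx_dosage)
  arm[rest] <- sample(other_arms, length(rest), replace = TRUE)
  annot <- data.frame(symbol = gene_ids, arm = arm,
                      chromosome = sub("[pq]$", "", sub("other", "0", arm)),
                      cytoband = arm, stringsAsFactors = FALSE)

  # chromosome-3 monosomy events and CNA matrix
  p_m3 <- ifelse(high == 1, cfg$p_m3_high, cfg$p_m3_low)
  m3 <- stats::rbinom(n, 1, p_m3)
  cna <- matrix(0L, cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))
  chr3 <- which(arm %in% c("3p", "3q"))
  for (s in which(m3 == 1)) {
    if (cfg$partial_deletion && length(chr3) > 2) {
      len <- sample(seq(2, length(chr3)), 1)
      start <- sample(seq_len(length(chr3) - len + 1), 1)
      cna[chr3[start:(start + len - 1)], s] <- -1L
    } else {
      cna[chr3, s] <- -1L
    }
  }
  if (cfg$bg_cna_rate > 0) {
    # passenger alterations with no expression effect: a tenth of the
    # non-chr3 genes are recurrently altered (rate 0.25, gene-consistent
    # sign, enough to be tested by the association stage), the rest carry
    # sporadic noise at bg_cna_rate
    nonchr3 <- setdiff(seq_len(cfg$n_genes), chr3)
    recurrent <- stats::rbinom(length(nonchr3), 1, 0.1) == 1
    rate <- ifelse(recurrent, 0.25, cfg$bg_cna_rate)
    sign_g <- sample(c(-1L, 1L), length(nonchr3), replace = TRUE)
    noise <- matrix(stats::rbinom(length(nonchr3) * n, 1, rep(rate, n)),
                    length(nonchr3), n) * sign_g
    cna[nonchr3, ] <- noise
  }

  # methylation: probe i <= n_genes maps to gene i; extra probes re-sample genes
  probe_gene <- c(seq_len(min(cfg$n_probes, cfg$n_genes)),
                  if (cfg$n_probes > cfg$n_genes)
                    sample(cfg$n_genes, cfg$n_probes - cfg$n_genes,
                           replace = TRUE))
  probe_ids <- sprintf("cg%06d", seq_len(cfg$n_probes))
  base_mode <- stats::runif(cfg$n_probes, 0.1, 0.9)
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  mu_logit <- matrix(rep(logit(base_mode), n), cfg$n_probes, n)
  hyper <- matrix(0L, cfg$n_probes, n)  # latent hypermethylation state
  for (p in which(probe_gene %in% idx_meth)) {
    mu_logit[p, ] <- logit(0.2)
    hi_state <- stats::rbinom(n, 1, ifelse(high == 1, 0.7, 0.05))
    hyper[p, ] <- hi_state
    mu_logit[p, hi_state == 1] <- logit(0.7)
  }
  beta <- inv_logit(mu_logit +
                      matrix(stats::rnorm(cfg$n_probes * n, 0, 0.4),
                             cfg$n_probes, n))
  dimnames(beta) <- list(probe_ids, sample_ids)
  meth_annot <- data.frame(symbol = gene_ids[probe_gene],
                           arm = arm[probe_gene], stringsAsFactors = FALSE)

  # gene-level methylation seen by expression coupling (first probe per gene)
  gene_beta <- beta[match(seq_len(cfg$n_genes),
                          probe_gene)[seq_len(cfg$n_genes)], , drop = FALSE]

  # expression: NB with class / copy-number / methylation effects + depth
  base_mu <- stats::rlnorm(cfg$n_genes, meanlog = log(200), sdlog = 1)
  de_sign <- ifelse(stats::rbinom(cfg$n_genes, 1, 0.5) == 1, 1, -1)
  log2mu <- matrix(rep(log2(base_mu), n), cfg$n_genes, n)
  log2mu[idx_de, ] <- log2mu[idx_de, ] +
    outer(cfg$delta_expr * de_sign[idx_de], high)
  # only the planted chr3 dosage genes respond to copy number; background
  # passenger alterations elsewhere leave expression untouched
  log2mu[chr3, ] <- log2mu[chr3, ] +
    cfg$delta_cna * cna[chr3, , drop = FALSE]
  log2mu[idx_meth, ] <- log2mu[idx_meth, ] +
    cfg$gamma_meth * (gene_beta[idx_meth, , drop = FALSE] - 0.2)
  depth <- stats::rlnorm(n, 0, 0.2)
  mu <- sweep(2^log2mu, 2, depth, "*")
  counts <- matrix(stats::rnbinom(cfg$n_genes * n, mu = mu,
                                  size = 1 / cfg$dispersion),
                   cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))

  # survival: class hazard ratio, exponential censoring, follow-up horizon
  surv <- simulate_survival(cfg$log_hr * high, cfg$baseline_hazard,
                            cfg$censor_rate)
  metastasis <- as.integer(surv$event_time <= cfg$followup_days)
  molecular_class <- ifelse(high == 1,
                            ifelse(m3 == 1, 4L, 3L),
                            ifelse(m3 == 1, 2L, 1L))
  clin <- clinical_table(data.frame(
    sample_id = sample_ids,
    os_time = round(surv$time, 1), os_event = surv$event,
    metastasis = metastasis, m3 = m3,
    molecular_class = molecular_class, stringsAsFactors = FALSE))

  truth <- list(
    gene_roles = data.frame(gene = gene_ids, role = role,
                            de_sign = ifelse(role == "de", de_sign, 0),
                            arm = arm, stringsAsFactors = FALSE),
    true_class = stats::setNames(true_class, sample_ids),
    probe_gene = stats::setNames(gene_ids[probe_gene], probe_ids))

  structure(list(
    expression_counts = omics_matrix(counts, "expression_counts",
                                     feature_annot = annot),
    methylation_beta = omics_matrix(beta, "methylation_beta",
                                    feature_annot = meth_annot),
    cna_discrete = omics_matrix(cna, "cna_discrete", feature_annot = annot),
    clinical = clin, truth = truth, config = cfg),
    class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Writes the four TSV tables plus a JSON truth file, mirroring the on-disk
#' layout the pipeline reads.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$expression_counts, file.path(dir, "expression_counts.tsv"))
  write_matrix(cohort$methylation_beta, file.path(dir, "methylation_beta.tsv"))
  write_matrix(cohort$cna_discrete, file.path(dir, "cna_discrete.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_manifest(list(config = unclass(cohort$config),
                      gene_roles = cohort$truth$gene_roles,
                      true_class = as.list(cohort$truth$true_class)),
                 file.path(dir, "truth.json"))
  invisible(dir)
}
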