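---
title: "Methods: multi-omics fusion and gene prioritization for uveal melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics fusion and gene prioritization for uveal melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`umfuse` analyzes matched expression, methylation and copy-number profiles of
a uveal-melanoma cohort to discover risk classes and prioritize genes. This
vignette is the package's account of the science: the models, their
assumptions, the tunable parameters, and the numerical choices, so a reader
can judge what the methods do and do not show.

## The data model

All stages consume `omics_matrix` objects: features × samples, with a
declared kind that fixes the validation rules (counts non-negative; beta
values in [0, 1]; copy-number codes integers in −2..2, with ±2 pooled with
±1 throughout — the analyses treat any non-zero code as an event). The
clinical table carries overall survival (days, with an event indicator), a
metastasis indicator, the chromosome-3 monosomy flag (M3) and the molecular
risk class 1–4 used in uveal melanoma. Gene identity across engines is the
feature ID (upper-cased symbol when lists are compared).

## Preprocessing

* **Count filter.** Genes with a total raw count below 100 or above 10^6
  across all samples are removed; both bounds are inclusive (a total of
  exactly 100 or 10^6 is retained). The bounds are literal: they drop
  never-expressed genes and saturated outliers, nothing more.
* **Normalization.** Median-of-ratios size factors (computed over genes with
  all-positive counts) followed by `log2(count/size_factor + 1)`. This is an
  approximately variance-stabilizing, monotone transform; any pre-transformed
  matrix of kind `expression_normalized` can be supplied instead, so users
  preferring a spline-based variance-stabilizing transform can plug one in.
* **Feature reduction.** Expression: the 1500 genes with the highest median
  absolute deviation (MAD). Methylation: the most variable 1% of probes;
  probes with any missing value are dropped first and their count recorded.
  Both selections break ties by lexicographic feature ID so results are
  identical across platforms. The defaults (1500, 1%) assume genome-scale
  input; on the desk-scale synthetic cohorts used by the test-suite we pass
  300 genes and 10% of probes through the run configuration, keeping the
  selected fraction of the matrix comparable.

## Joint SVD

The fusion model factorizes each domain matrix (samples × features, so the
shared factor lives on the sample side) as

$$A_i \approx U\,\mathrm{diag}(\sigma_i)\,V_i^{\top},\qquad
U^\top U = I_k,\quad V_i^\top V_i = I_k,$$

minimizing $\sum_i \lVert A_i - U\,\mathrm{diag}(\sigma_i)V_i^\top\rVert_F^2$
over the product of Stiefel manifolds. $U$ (default $k = 3$) is the fused
patient embedding used for clustering. For one matrix this is exactly the
rank-k truncated SVD, which gives the package a sharp correctness oracle
(the Eckart–Young optimum), exercised in the tests at relative tolerance
1e−8.

**Solver.** Given $U, V_i$, each $\sigma_i$ has the closed form
$\mathrm{diag}(U^\top A_i V_i)$; eliminating it leaves a maximization of
$\sum_{i,j} (u_j^\top A_i v_{ij})^2$. The default solver alternates exact
per-block minimizers: $V_i \leftarrow \mathrm{polar}(A_i^\top U \Sigma_i)$
and $U \leftarrow \mathrm{polar}(\sum_i A_i V_i \Sigma_i)$, each a Procrustes
step that cannot increase the objective, so the objective trace is
monotonically non-increasing. Iteration stops when the norm of the gradient
projected onto the tangent space of the product manifold drops below 1e−12
(the `grad_tol` default). A first-order Riemannian projected-gradient solver
with QR retraction and Armijo backtracking is included as an independent
route; the tests require the two to agree within 1e−6 on shared fixtures. We
chose the alternating scheme over a trust-region method because its steps
are closed-form, it is monotone by construction, and at these problem sizes
(tens to hundreds of samples) it reaches the 1e−12 gradient tolerance in a
few thousand cheap iterations; the projected-gradient solver guards against
a block scheme converging to a non-stationary point.

**Numerical choices.** Initialization is deterministic: $U$ from the top-k
left singular vectors of the column-concatenation $[A_1|A_2|\dots]$, $V_i$
from per-matrix polar factors given $U$; random orthonormal restarts are
available behind a seed and reach the same objective on the test fixtures.
Rank-deficient polar factors (e.g. all-zero inputs) complete the basis from
the previous iterate, deterministically. On return, signs are absorbed into
$V_i$ so $\sigma_i \ge 0$, and columns are sorted by total explained
$\sum_i \sigma_{ij}^2$ — a canonicalization that makes factor output unique
up to exact ties. Inputs are used exactly as preprocessing produced them (no
per-domain rescaling); an optional flag rescales each matrix to unit
Frobenius norm when domains have grossly different scales.

## Cluster discovery and validity

k-means on the embedding uses Lloyd's algorithm with k-means++ seeding, best
of 50 restarts by inertia, deterministic given a seed. Two validity scores
select the number of clusters:

* **Connectivity** (lower is better): each sample's j-th nearest neighbor
  (Euclidean; distance ties broken by sample index) adds $1/j$ when it sits
  in a different cluster, over the `n_neighbors = 10` nearest neighbors.
* **Silhouette** (higher is better): mean of $(b-a)/\max(a,b)$ with $a$ the
  mean intra-cluster distance and $b$ the best alternative cluster's mean
  distance; singleton clusters score 0.

The selection rule ranks candidate k by the sum of the connectivity rank and
the silhouette rank, restricted to k whose silhouette lies within `tol_sil`
of the maximum, smallest k winning ties; the full validity table is always
reported so the user can override. `tol_sil` defaults to 0.1: the trade-off
this rule encodes is that a clearly lower-connectivity solution should win
against a marginally better silhouette. On the published UM validity table
(connectivity 2.25/6.27/15.66, silhouette 0.45/0.51/0.52 for k = 2/3/4) the
rule selects k = 2, and on well-separated three-blob data it selects k = 3;
a tighter band (e.g. 0.05) would flip the first case to k = 3 because the
0.07 silhouette gap exceeds the band, which is why 0.1 is the default.

Downstream two-class stages (differential analysis, the methylation screen's
cancer/control split) always use the k = 2 solution on the embedding, with
the higher-M3-fraction cluster as the high-risk class; the model-selected k
is reported alongside.

## SAM-style differential analysis

For feature $i$, $d_i = (\bar x_{2i} - \bar x_{1i})/(s_i + s_0)$ with $s_i$
the two-class pooled standard error and the fudge factor $s_0$ chosen among
the 0, 5, …, 100 percentiles of $\{s_i\}$ to minimize the coefficient of
variation of the window-wise MAD of $d$ across s-quantile windows — the
standard stabilization that stops low-variance features from dominating.
The null distribution comes from class-size-preserving label permutations:
all of them when at most `n_perm` exist (a 3-vs-3 design has 20 and is
enumerated exactly, which the tests exploit with an independent brute-force
oracle), otherwise `n_perm` random draws. Calls use the delta-band rule
against the mean-ordered null statistics; with `delta = "auto"` the smallest
delta whose estimated FDR (median permutation call count over observed call
count) is at most `fdr_target` is used. Per-feature q-values are the median
null exceedance count over the observed exceedance count, capped at 1, with
no additional multiplicity layer on top. Beta values can be analyzed as-is
or after a logit transform (`logit_beta`).

## CNA–expression association

Per gene, samples split into gain (> 0), loss (< 0) and neutral (0). Genes
altered in fewer than 4 samples are dropped; a gene is classified gain/loss
when the corresponding fraction reaches 0.2 (inclusive, so 4 of 20 samples
counts), `both` when both do. For each classified direction a Welch t-test
compares expression in event versus neutral samples (two-sided), and
Benjamini–Hochberg FDR is applied within each direction across genes; tests
with fewer than 2 event or 2 neutral samples are skipped and recorded.
`both` genes are tested in both directions and can be kept in either.

## Penalized-logistic M3 prediction

Elastic-net logistic regression of the M3 flag on standardized expression
with mixing α = 0.1 and the penalty chosen by 20-fold cross-validated
deviance at its minimum (folds seeded); the nonzero-coefficient genes at the
chosen penalty are the selected predictor panel. The α = 0.1 penalty is
ridge-heavy: it spreads weight across correlated arm-3 genes (good for
sensitivity — the planted-truth tests require ≥ 0.8 of arm-3 dosage genes
selected) but under a null label CV noise can park the optimum at an
interior penalty and admit many tiny coefficients, so null-label selection
is only *usually* empty, not always. The one-standard-error rule
(`lambda_rule = "1se"`) is available and markedly more parsimonious under
the null.

## Methylation–expression screen

Per gene: univariate Gaussian mixtures with 1–3 components are fitted to
the cancer-group beta values (clipped to [0.001, 0.999]) and the count
chosen by BIC; the differential-methylation value of each component is its
mean minus the control-group mean, and genes need at least one |DM| ≥ 0.10;
finally the gene's cancer-group expression is regressed on its methylation,
and transcriptionally predictive genes require R² ≥ 0.1, F-test p ≤ 0.001
and — by default — a negative slope (`inverse_only = FALSE` admits both
signs). Thresholds follow the published defaults of the mixture-screen
approach; the control group is the low-risk fused cluster by design, but any
user-supplied control matrix works. Gaussian mixtures on beta values (not
beta-distributed mixtures) keep the model identical to the screen this stage
mirrors; the clipping bounds keep logits finite.

## Survival scoring and signature evaluation

The multi-gene score (MGS) is a multivariate Cox fit on z-scored candidate
expression (Breslow ties), retaining genes with Wald p < 0.05; the score is
$\sum_g \beta_g z_{gs}$, so positive weights mark risk genes. When no
candidate passes the Wald cut — common at n = 80 with collinear candidates
sharing one class signal — the pipeline falls back to the single smallest-p
gene so the split stages still run, and flags this in the manifest. The KM
split dichotomizes at the median score; the log-rank statistic is the
textbook O−E form, verified against a hand-enumerated example.

Rank-based signature scores rank all genes within a sample (mean rank for
ties), take the mean rank of the signature genes divided by the gene count,
and normalize by the attainable range for a set of size m among n genes
(min $(m+1)/2n$, max $(2n-m+1)/2n$); the score is invariant to any monotone
per-sample transform. The degenerate full-gene-set signature has an empty
attainable range and scores 0.5 for every sample. Scores are min–max
rescaled to [0, 1] for report comparability (the ROC is invariant to this
rescale). For ROC/AUC the predictor is `1 − score` for every engine except
the gain-direction CNA signature, whose high score already tracks risk; the
AUC is the Mann–Whitney concordance probability with half-credit for ties,
tested against a pair-counting oracle and an established ROC package.

## Synthetic cohorts: what they emulate, and what they do not

`generate_cohort()` plants every structure the pipeline assumes, at the
scale of the TCGA uveal-melanoma cohort (80 patients, two risk classes of
40). Defaults, chosen once as the package's study conditions:

* **Expression**: negative binomial, dispersion 0.2 (typical bulk RNA-seq
  overdispersion), lognormal baseline means, lognormal library-depth factors
  (sd 0.2 on the log scale). 50 differential genes at log2 effect 1.5
  (random sign); 1000 genes total.
* **Copy number**: chromosome-3 loss arm-wide with probability 0.9 in the
  high-risk class and 0.1 in the low-risk class (a partial-deletion mode
  restricts each event to a random contiguous stretch); 40 dosage genes on
  3p/3q whose expression scales by 2^(copy change) per the per-copy log2
  effect 1.0. Background passenger alterations elsewhere have no expression
  effect: a tenth of non-chr3 genes are recurrently altered (rate 0.25,
  gene-consistent sign) so the association engine has genuinely null tested
  genes, the rest carry sporadic noise (rate 0.05).
* **Methylation**: logit-normal beta values (logit sd 0.4); 30 driver genes
  are bimodal in the high-risk class (modes 0.2/0.7, hypermethylated state
  probability 0.7 vs 0.05) and couple into expression with slope −3 log2
  units per beta unit; 1000 probes, probe i mapping to gene i.
* **Survival**: exponential with baseline hazard 1/4000 per day and hazard
  ratio 3 for the high-risk class; independent exponential censoring
  targeting 30%; metastasis is an (uncensored) event time within a 1825-day
  administrative horizon, mirroring the fact that M3 status is certain at
  diagnosis while metastases may appear after follow-up ends — which is also
  why M3 AUCs exceed metastasis AUCs on these cohorts.

The generator reproduces the *structural* assumptions only. It does not
model batch effects, probe-level 450K structure, copy-number magnitudes
beyond event/no-event, gene–gene correlation beyond the planted classes, or
the marginal distributions of any real cohort. Passing planted-truth tests
therefore shows the engines detect the signal classes they target at
realistic effect sizes and cohort sizes — not that real-data performance
will match.

## Problem sizes and determinism

The test-suite and the acceptance script run cohorts of 1000 genes × 1000
probes × 80 samples, fuse 300 MAD-selected genes with 100 top-variance
probes at k = 3, and use 200–300 permutations for the differential stage and
50 replicates for the Monte-Carlo properties (Cox coverage, null
calibration); these sizes make every stage's statistical target measurable
while keeping a full run in seconds. Every stochastic step — cohort
generation, k-means restarts, permutation draws, CV fold assignment — is
seeded, and a repeated run with the same seed reproduces gene lists and
manifests byte-for-byte.

## Known limitations

* The fused embedding is linear; classes separated only by nonlinear
  structure will not separate in U.
* The alternating solver converges linearly; extremely tight gradient
  tolerances on large, gap-free spectra can require many (cheap) iterations.
* The q-value machinery of the differential stage estimates FDR without a
  null-proportion correction and can be conservative when many features are
  truly differential.
* With ridge-heavy mixing the penalized M3 predictor's selected panel is
  sensitive to CV noise under weak signal; use `lambda_rule = "1se"` when
  parsimony matters more than sensitivity.
* The Cox stage assumes proportional hazards and reports no diagnostics
  beyond convergence; at small n with collinear candidates the retained
  signature can legitimately be empty (the pipeline then falls back to the
  single best gene and says so).
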