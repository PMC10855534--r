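#' Omics matrix container
#'
#' A lightweight features-by-samples matrix with per-feature annotation and a
#' declared kind. All pipeline stages consume and produce this container.
#' Rows are features (genes or probes), columns are samples; the fused patient
#' embedding produced later is samples-by-k.
#'
#' @param values numeric matrix, features in rows, samples in columns. Row and
#'   column names are used as feature/sample IDs when `feature_ids` /
#'   `sample_ids` are not given.
#' @param kind one of `"expression_counts"`, `"expression_normalized"`,
#'   `"methylation_beta"`, `"cna_discrete"`. Value ranges are validated per
#'   kind: counts must be non-negative, beta values in \[0, 1\], CNA codes
#'   integers in \{-2, -1, 0, 1, 2\}.
#' @param feature_ids,sample_ids character vectors; must be unique.
#' @param feature_annot optional data.frame of per-feature annotation
#'   (e.g. columns `symbol`, `chromosome`, `arm`, `cytoband`), one row per
#'   feature.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, kind,
                         feature_ids = rownames(values),
                         sample_ids = colnames(values),
                         feature_annot = NULL) {
  kind <- match.arg(kind, c("expression_counts", "expression_normalized",
                            "methylation_beta", "cna_discrete"))
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be a numeric matrix")
  if (is.null(feature_ids)) feature_ids <- sprintf("f%d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length does not match the number of rows")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match the number of columns")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature_ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  validate_values_kind(values, kind)
  if (!is.null(feature_annot)) {
    feature_annot <- as.data.frame(feature_annot)
    if (nrow(feature_annot) != nrow(values))
      stop("feature_annot must have one row per feature")
    rownames(feature_annot) <- feature_ids
  }
  structure(list(values = values, kind = kind,
                 feature_ids = feature_ids, sample_ids = sample_ids,
                 feature_annot = feature_annot),
            class = "omics_matrix")
}

validate_values_kind <- function(values, kind) {
  finite <- is.finite(values)
  if (kind == "expression_counts") {
    bad <- which(finite & values < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("negative count %g at feature '%s', sample '%s'",
                   values[bad[1, 1], bad[1, 2]],
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  } else if (kind == "methylation_beta") {
    bad <- which(finite & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("beta value %g outside [0,1] at feature '%s', sample '%s'",
                   values[bad[1, 1], bad[1, 2]],
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  } else if (kind == "cna_discrete") {
    bad <- which(finite & (values != round(values) | abs(values) > 2),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("CNA code %g not an integer in {-2..2} at feature '%s', sample '%s'",
                   values[bad[1, 1], bad[1, 2]],
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$feature_annot))
    cat("  annotation columns:", paste(names(x$feature_annot), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# Subset features/samples keeping annotation in step.
subset_omics <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  fa <- m$feature_annot
  if (!is.null(features)) {
    v <- v[features, , drop = FALSE]
    if (!is.null(fa)) fa <- fa[features, , drop = FALSE]
  }
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  omics_matrix(v, m$kind, feature_annot = fa)
}

#' Clinical table
#'
#' Validates a per-sample clinical table: overall survival time (days), event
#' indicator, metastasis indicator, chromosome-3 monosomy flag (M3), and the
#' molecular risk class 1-4 used in uveal melanoma.
#'
#' @param df data.frame with columns `sample_id`, `os_time`, `os_event`,
#'   `metastasis`, `m3`, `molecular_class`.
#' @return the validated data.frame with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "os_time", "os_event", "metastasis", "m3",
            "molecular_class")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(df$os_time < 0, na.rm = TRUE)) stop("os_time must be >= 0")
  for (col in c("os_event", "metastasis", "m3")) {
    if (!all(df[[col]] %in% c(0, 1)))
      stop(col, " must be binary 0/1")
  }
  if (!all(df$molecular_class %in% 1:4))
    stop("molecular_class must be in 1..4")
  class(df) <- c("clinical_table", "data.frame")
  df
}
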