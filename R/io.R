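#' Read an omics matrix from a TSV file
#'
#' Reads the tab-separated matrix dialects produced by the usual portals:
#' `"plain"` (first column feature IDs, header row sample IDs), `"firehose"`
#' (Broad GDAC Firehose RSEM style: composite `symbol|entrez` feature names,
#' split on `|`, the symbol kept as annotation and the composite retained as
#' the unique feature ID) and `"cbioportal"` (leading `Hugo_Symbol` and
#' optional `Entrez_Gene_Id` columns).
#'
#' @param path TSV file path.
#' @param kind matrix kind, see [omics_matrix()].
#' @param dialect one of `"plain"`, `"firehose"`, `"cbioportal"`.
#' @return a validated [omics_matrix()].
#' @export
read_matrix <- function(path, kind, dialect = c("plain", "firehose", "cbioportal")) {
  dialect <- match.arg(dialect)
  header <- readLines(path, n = 1L)
  if (!nzchar(header) || !grepl("\t", header))
    stop("malformed header in ", path, ": expected tab-separated columns")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed matrix file ", path, ": fewer than 2 columns")
  annot <- NULL
  if (dialect == "cbioportal") {
    if (!"Hugo_Symbol" %in% names(df))
      stop("cbioportal dialect requires a Hugo_Symbol column")
    idcols <- intersect(c("Hugo_Symbol", "Entrez_Gene_Id"), names(df))
    ids <- as.character(df$Hugo_Symbol)
    ids <- make.unique(ids)
    annot <- data.frame(symbol = as.character(df$Hugo_Symbol))
    vals <- as.matrix(df[, setdiff(names(df), idcols), drop = FALSE])
  } else {
    ids <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (dialect == "firehose") {
      sym <- vapply(strsplit(ids, "|", fixed = TRUE), `[`, character(1), 1L)
      annot <- data.frame(symbol = sym)
    }
  }
  storage.mode(vals) <- "numeric"
  rownames(vals) <- ids
  omics_matrix(vals, kind = kind, feature_annot = annot)
}

#' Write an omics matrix to a TSV file
#'
#' Plain dialect: first column `feature_id`, one column per sample.
#' `read_matrix(write_matrix(m), kind)` is the identity on the values.
#'
#' @param m an [omics_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  # %.17g round-trips doubles exactly
  vals <- apply(m$values, 2, function(col) sprintf("%.17g", col))
  if (nrow(m$values) == 1) vals <- matrix(vals, nrow = 1)
  df <- data.frame(feature_id = m$feature_ids, vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("feature_id", m$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' @param path TSV with named columns `sample_id`, `os_time`, `os_event`,
#'   `metastasis`, `m3`, `molecular_class`.
#' @return a validated [clinical_table()].
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a clinical table to TSV
#' @param clin a [clinical_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# JSON run manifest: parameters + seed of a pipeline stage or run.
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
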