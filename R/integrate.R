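#' Overlap of method gene lists
#'
#' Exact set arithmetic over the named gene lists (one per selection
#' method): the size of every non-empty Venn region (samples belonging to
#' exactly that combination of lists), plus pairwise Jaccard indices.
#'
#' @param lists named list of character vectors (>= 2); lists are
#'   deduplicated, gene symbols upper-cased and whitespace-stripped before
#'   comparison.
#' @return list: `regions` (data.frame `region` — method names joined by
#'   `&` — `size`, `genes`), `jaccard` (matrix), `union_size`.
#' @export
overlap_counts <- function(lists) {
  if (length(lists) < 2) stop("need at least 2 lists")
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("lists must be named")
  if (anyDuplicated(names(lists))) stop("list names must be unique")
  norm <- lapply(lists, function(g) unique(toupper(trimws(as.character(g)))))
  all_genes <- sort(unique(unlist(norm)))
  member <- vapply(norm, function(g) all_genes %in% g,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(norm)))
  key <- apply(member, 1, function(row)
    paste(names(norm)[row], collapse = "&"))
  sizes <- table(key)
  regions <- data.frame(region = names(sizes),
                        size = as.integer(sizes),
                        genes = vapply(names(sizes), function(k)
                          paste(all_genes[key == k], collapse = ","),
                          character(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  nm <- names(norm)
  jac <- matrix(1, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    u <- length(union(norm[[i]], norm[[j]]))
    jac[i, j] <- if (u == 0) 1 else
      length(intersect(norm[[i]], norm[[j]])) / u
  }
  list(regions = regions, jaccard = jac, union_size = length(all_genes))
}

# Chromosome arms reported in uveal melanoma cytogenetics.
.report_arms <- c("1p", "1q", "3p", "3q", "6p", "6q", "8p", "8q",
                  "16p", "16q", "other")

#' Chromosome-arm localization of a gene list
#'
#' Counts genes per chromosome arm among the arms relevant for uveal
#' melanoma cytogenetics (1p, 1q, 3p, 3q, 6p, 6q, 8p, 8q, 16p, 16q);
#' anything else — including genes missing from the annotation — falls under
#' `other`. The `total` row equals the list length.
#'
#' @param genes character vector of gene IDs.
#' @param annotation data.frame with columns `gene` (or rownames) and `arm`.
#' @return data.frame with columns `arm` and `count`, last row `total`.
#' @export
arm_localization <- function(genes, annotation) {
  annotation <- as.data.frame(annotation)
  if (!"arm" %in% names(annotation)) stop("annotation needs an 'arm' column")
  key <- if ("gene" %in% names(annotation)) annotation$gene else
    rownames(annotation)
  arm <- annotation$arm[match(genes, key)]
  arm[is.na(arm) | !(arm %in% .report_arms)] <- "other"
  counts <- vapply(.report_arms, function(a) sum(arm == a), integer(1))
  data.frame(arm = c(.report_arms, "total"),
             count = c(unname(counts), length(genes)),
             stringsAsFactors = FALSE)
}
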