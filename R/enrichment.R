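#' Read an annotation gene set
#'
#' Plain-text list, one gene symbol per line; blank lines and `#` comments
#' are ignored. Symbols are uppercased so matching against expression gene
#' ids is case-insensitive.
#'
#' @param path file path.
#' @param name set name (defaults to the file name).
#' @return list with `name` and the character set `genes`.
#' @export
read_annotation_set <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  genes <- unique(toupper(lines[nzchar(lines)]))
  if (length(genes) == 0) stopf("annotation set '%s' is empty", path)
  list(name = name %||% sub("\\.[^.]*$", "", basename(path)), genes = genes)
}

#' Count annotated members of a gene group
#'
#' @param group character vector of gene ids.
#' @param annotation an annotation set (see [read_annotation_set()]) or a
#'   character vector of symbols.
#' @return integer vector `c(annotated, total)`.
#' @export
annotate_group <- function(group, annotation) {
  ann <- if (is.list(annotation)) annotation$genes else annotation
  c(annotated = sum(toupper(group) %in% toupper(ann)),
    total = length(group))
}

#' Chi-square enrichment test across gene groups
#'
#' Builds the k x 2 table of annotated vs non-annotated counts per group and
#' applies the Pearson chi-square test (no continuity correction). Cells with
#' zero expected count leave the test flagged undefined.
#'
#' @param groups list of `c(annotated, total)` pairs (as from
#'   [annotate_group()]), or a 2-column matrix of them.
#' @return list with `chisq`, `df`, `p`, the assembled `table`, `defined`.
#' @export
enrichment_test <- function(groups) {
  m <- if (is.matrix(groups)) groups else do.call(rbind, groups)
  if (nrow(m) < 2) stopf("need at least 2 groups")
  if (any(m[, 2] <= 0)) stopf("group totals must be positive")
  if (any(m[, 1] < 0) || any(m[, 1] > m[, 2])) {
    stopf("annotated counts must lie in [0, total]")
  }
  tab <- cbind(annotated = m[, 1], not_annotated = m[, 2] - m[, 1])
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) {
    return(list(chisq = NA_real_, df = NA_integer_, p = NA_real_,
                table = tab, defined = FALSE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, table = tab, defined = TRUE)
}
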