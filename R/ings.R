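#' Correlate every gene with the anchor gene
#'
#' Pearson product-moment correlation of each gene's expression vector with
#' the anchor gene's, across all samples. Genes with zero variance (including
#' all-zero genes) have no defined correlation and are excluded; their ids are
#' returned in the `"excluded"` attribute.
#'
#' @param expr expression matrix (genes x samples).
#' @param anchor anchor gene id (default the pan-leukocyte marker `"PTPRC"`).
#' @return `data.frame` with columns `gene`, `r`, `r2`.
#' @export
correlate_with_anchor <- function(expr, anchor = "PTPRC") {
  if (!anchor %in% rownames(expr)) {
    stopf("anchor gene '%s' not found in the expression matrix", anchor)
  }
  if (ncol(expr) < 3) stopf("need at least 3 samples to correlate")
  a <- expr[anchor, ]
  if (stats::sd(a) == 0) stopf("anchor gene '%s' has zero variance", anchor)
  sds <- apply(expr, 1, stats::sd)
  ok <- sds > 0
  r <- as.vector(stats::cor(t(expr[ok, , drop = FALSE]), a))
  out <- data.frame(gene = rownames(expr)[ok], r = r, r2 = r^2,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- rownames(expr)[!ok]
  out
}

#' Select the provisional immune-normalizing gene set
#'
#' All genes whose squared correlation with the anchor strictly exceeds
#' `r2_threshold`. By default membership also requires a positive correlation:
#' a factor averaging genes that anticorrelate with immune content would not
#' track it. Set `require_positive = FALSE` for the literal r-squared-only
#' rule.
#'
#' @param correlations output of [correlate_with_anchor()].
#' @param r2_threshold strict lower bound on r-squared (default 0.5).
#' @param require_positive additionally require `r > 0` (default `TRUE`).
#' @return character vector of gene ids (anchor included), sorted.
#' @export
build_provisional_ings <- function(correlations, r2_threshold = 0.5,
                                   require_positive = TRUE) {
  if (nrow(correlations) == 0) stopf("empty correlation table")
  keep <- correlations$r2 > r2_threshold
  if (require_positive) keep <- keep & correlations$r > 0
  genes <- sort(correlations$gene[keep])
  if (length(genes) < 2) {
    stopf("provisional set has %d gene(s); at least 2 are needed for a leave-one-out normalization factor",
          length(genes))
  }
  genes
}

#' Refine the provisional set by CVR
#'
#' Each provisional gene is normalized by its leave-one-out factor built from
#' the provisional set, its coefficient-of-variation ratio
#' `CVR = CV(normalized) / CV(raw)` is computed, and genes with CVR above
#' `cvr_threshold` are omitted. A single pass is made by default; the anchor is
#' always retained. `iterate = TRUE` repeats the pass (recomputing factors from
#' the surviving set) until a fixed point.
#'
#' @param expr expression matrix.
#' @param provisional provisional gene set (character vector).
#' @param cvr_threshold genes with CVR strictly above this are dropped
#'   (default 0.8).
#' @param anchor anchor gene id, always kept.
#' @param correlations optional correlation table to carry per-gene `r`/`r2`
#'   into the result.
#' @param iterate repeat refinement to a fixed point (default `FALSE`,
#'   single pass).
#' @return an object of class `"ings"`: sorted member `genes`, the `anchor`,
#'   both thresholds, and `per_gene_stats` (`gene`, `r`, `r2`, `cvr`).
#' @export
refine_ings <- function(expr, provisional, cvr_threshold = 0.8,
                        anchor = "PTPRC", correlations = NULL,
                        iterate = FALSE) {
  if (length(provisional) < 2) stopf("provisional set must have >= 2 genes")
  missing <- setdiff(provisional, rownames(expr))
  if (length(missing) > 0) {
    stopf("provisional gene(s) missing from matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  current <- sort(provisional)
  repeat {
    fac <- compute_factors(expr, current)
    sub <- expr[current, , drop = FALSE]
    norm <- sub / fac$loo
    cv_raw <- apply(sub, 1, coefficient_of_variation)
    cv_norm <- apply(norm, 1, coefficient_of_variation)
    cvr <- cv_norm / cv_raw
    keep <- !is.na(cvr) & cvr <= cvr_threshold
    keep[current == anchor] <- TRUE
    refined <- current[keep]
    if (length(refined) < 2) {
      stopf("CVR refinement left %d gene(s); the normalization factor is undefined",
            length(refined))
    }
    if (!iterate || identical(refined, current)) {
      current <- refined
      cvr_kept <- cvr[keep]
      break
    }
    current <- refined
  }
  stats_df <- data.frame(gene = current, cvr = cvr_kept,
                         stringsAsFactors = FALSE)
  if (!is.null(correlations)) {
    i <- match(current, correlations$gene)
    stats_df$r <- correlations$r[i]
    stats_df$r2 <- correlations$r2[i]
    stats_df <- stats_df[, c("gene", "r", "r2", "cvr")]
  }
  rownames(stats_df) <- NULL
  structure(list(genes = current, anchor = anchor,
                 r2_threshold = NA_real_, cvr_threshold = cvr_threshold,
                 per_gene_stats = stats_df),
            class = "ings")
}

#' @export
print.ings <- function(x, ...) {
  cat(sprintf("Immune-normalizing gene set: %d genes (anchor %s)\n",
              length(x$genes), x$anchor))
  cat(sprintf("  thresholds: r2 > %s, CVR <= %s\n",
              format(x$r2_threshold), format(x$cvr_threshold)))
  cat("  members: ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Serialize / load an INGS
#'
#' The gene set is written as a small JSON artifact (members, anchor,
#' thresholds, per-gene statistics) so it can be reused across cohorts of the
#' same cancer type.
#'
#' @param ings an `"ings"` object.
#' @param path file path.
#' @return `write_ings` returns `path` invisibly; `read_ings` returns the
#'   `"ings"` object.
#' @export
write_ings <- function(ings, path) {
  payload <- list(genes = ings$genes, anchor = ings$anchor,
                  r2_threshold = ings$r2_threshold,
                  cvr_threshold = ings$cvr_threshold,
                  per_gene_stats = ings$per_gene_stats)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ings
#' @export
read_ings <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genes = as.character(payload$genes),
                 anchor = payload$anchor,
                 r2_threshold = as.numeric(payload$r2_threshold),
                 cvr_threshold = as.numeric(payload$cvr_threshold),
                 per_gene_stats = as.data.frame(payload$per_gene_stats)),
            class = "ings")
}
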