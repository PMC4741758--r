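#' Per-sample immune normalization factors
#'
#' The biopsy-specific factor `f(s)` is the arithmetic mean expression of the
#' INGS genes in sample `s` — a proxy for the immune-cell fraction of the
#' biopsy. For every INGS member `i` a leave-one-out factor `loo(i, s)` is
#' also computed, averaging the INGS without gene `i`, so members are never
#' normalized by themselves.
#'
#' @param expr expression matrix.
#' @param ings an `"ings"` object or character vector of INGS gene ids.
#' @return list with `sample_ids`, `genes`, `f` (named per-sample vector) and
#'   `loo` (|INGS| x n matrix, rows named by INGS gene).
#' @export
compute_factors <- function(expr, ings) {
  genes <- if (inherits(ings, "ings")) ings$genes else as.character(ings)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stopf("INGS gene(s) missing from matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  k <- length(genes)
  if (k < 2) stopf("INGS must have >= 2 genes")
  sub <- expr[genes, , drop = FALSE]
  f <- colMeans(sub)
  if (any(f == 0)) {
    stopf("normalization factor is zero for sample '%s' (all INGS genes zero)",
          colnames(expr)[which(f == 0)[1]])
  }
  # k*f = (k-1)*loo(i,) + expr(i,)  =>  loo(i,) = (k*f - expr(i,)) / (k-1)
  loo <- (matrix(k * f, nrow = k, ncol = ncol(sub), byrow = TRUE) - sub) /
    (k - 1)
  if (any(loo <= 0)) {
    bad <- which(loo <= 0, arr.ind = TRUE)[1, ]
    stopf("leave-one-out factor is nonpositive for gene '%s', sample '%s'",
          genes[bad[1]], colnames(expr)[bad[2]])
  }
  dimnames(loo) <- list(genes, colnames(expr))
  list(sample_ids = colnames(expr), genes = genes, f = f, loo = loo)
}

#' Normalize an expression matrix by the immune factor
#'
#' Divides every gene's expression in sample `s` by the per-sample factor
#' `f(s)`; INGS members are divided by their leave-one-out factor instead
#' (self-normalization avoided). Zero raw values stay zero; no pseudocounts
#' are added.
#'
#' @param expr expression matrix.
#' @param ings an `"ings"` object or character vector of INGS gene ids.
#' @param factors optional precomputed [compute_factors()] result.
#' @return normalized expression matrix, same dimensions and dimnames, with a
#'   `"provenance"` attribute recording the INGS size, anchor and thresholds.
#' @export
normalize_expression <- function(expr, ings, factors = NULL) {
  fac <- factors %||% compute_factors(expr, ings)
  out <- sweep(expr, 2, fac$f, "/")
  out[fac$genes, ] <- expr[fac$genes, , drop = FALSE] / fac$loo
  attr(out, "provenance") <- list(
    ings_size = length(fac$genes),
    anchor = if (inherits(ings, "ings")) ings$anchor else NA_character_,
    r2_threshold = if (inherits(ings, "ings")) ings$r2_threshold else NA_real_,
    cvr_threshold = if (inherits(ings, "ings")) ings$cvr_threshold else NA_real_,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out
}
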