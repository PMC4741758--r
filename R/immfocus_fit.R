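#' Fit an immune-normalization model to a cohort
#'
#' Derives the immune-normalizing gene set (INGS) from the expression matrix
#' and computes the per-sample normalization factors. The derivation has two
#' stages: (1) a provisional set of all genes whose expression is strongly
#' correlated with the anchor gene across samples (Pearson r-squared strictly
#' above `r2_threshold`, positive by default), and (2) a refinement pass that
#' drops provisional members whose coefficient of variation is not reduced by
#' the provisional leave-one-out normalization (CVR above `cvr_threshold`).
#' The per-sample factor `f` is the mean expression of the final INGS genes —
#' an estimate, up to scale, of the immune-cell fraction of each biopsy.
#'
#' @param expr expression matrix (genes x samples), linear scale; see
#'   [as_expression_matrix()].
#' @param anchor anchor gene id; the default `"PTPRC"` (CD45, leukocyte
#'   common antigen) is a pan-leukocyte marker.
#' @param r2_threshold provisional membership needs squared correlation with
#'   the anchor strictly above this (default 0.5).
#' @param cvr_threshold refinement keeps genes with CVR at or below this
#'   (default 0.8).
#' @param require_positive require positive correlation with the anchor
#'   (default `TRUE`); `FALSE` gives the literal r-squared-only rule.
#' @param iterate iterate the CVR refinement to a fixed point instead of the
#'   default single pass.
#' @param log2_transform work on `log2(x + 1)` values for the correlation
#'   stage (off by default; factors and normalization always use the linear
#'   scale).
#' @return an object of class `"immfocus"` with components `ings` (class
#'   `"ings"`), `factors` (see [compute_factors()]), `correlations`, the
#'   training matrix `expr`, and the matched `call`.
#' @seealso [predict.immfocus()] to obtain the normalized matrix,
#'   [compute_cvr_table()] and [gene_survival_scan()] for the downstream
#'   screens.
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 60, n_genes = 80,
#'                                   immune_block_size = 20,
#'                                   prognostic_immune_count = 4, seed = 7))
#' fit <- immfocus(sim$expr)
#' fit
#' norm <- predict(fit)
#' @export
immfocus <- function(expr, anchor = "PTPRC", r2_threshold = 0.5,
                     cvr_threshold = 0.8, require_positive = TRUE,
                     iterate = FALSE, log2_transform = FALSE) {
  expr <- as_expression_matrix(expr)
  corr_input <- if (log2_transform) log2(expr + 1) else expr
  correlations <- correlate_with_anchor(corr_input, anchor = anchor)
  provisional <- build_provisional_ings(correlations,
                                        r2_threshold = r2_threshold,
                                        require_positive = require_positive)
  ings <- refine_ings(expr, provisional, cvr_threshold = cvr_threshold,
                      anchor = anchor, correlations = correlations,
                      iterate = iterate)
  ings$r2_threshold <- r2_threshold
  factors <- compute_factors(expr, ings)
  structure(list(ings = ings, factors = factors,
                 correlations = correlations, provisional = provisional,
                 expr = expr, anchor = anchor,
                 call = match.call()),
            class = "immfocus")
}

#' @export
print.immfocus <- function(x, ...) {
  cat("Immune normalization fit\n")
  cat(sprintf("  cohort: %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  cat(sprintf("  anchor: %s; provisional set: %d genes; final INGS: %d genes\n",
              x$anchor, length(x$provisional), length(x$ings$genes)))
  f <- x$factors$f
  cat(sprintf("  per-sample factor f: median %.4g (range %.4g-%.4g)\n",
              stats::median(f), min(f), max(f)))
  invisible(x)
}

#' @export
summary.immfocus <- function(object, ...) {
  out <- list(
    n_genes = nrow(object$expr), n_samples = ncol(object$expr),
    anchor = object$anchor,
    n_provisional = length(object$provisional),
    n_ings = length(object$ings$genes),
    r2_threshold = object$ings$r2_threshold,
    cvr_threshold = object$ings$cvr_threshold,
    f_summary = summary(object$factors$f),
    per_gene_stats = object$ings$per_gene_stats)
  class(out) <- "summary.immfocus"
  out
}

#' @export
print.summary.immfocus <- function(x, ...) {
  cat("Immune normalization fit\n")
  cat(sprintf("  cohort: %d genes x %d samples; anchor %s\n",
              x$n_genes, x$n_samples, x$anchor))
  cat(sprintf("  provisional set (r2 > %s): %d genes\n",
              format(x$r2_threshold), x$n_provisional))
  cat(sprintf("  final INGS (CVR <= %s): %d genes\n",
              format(x$cvr_threshold), x$n_ings))
  cat("  per-sample factor f:\n")
  print(x$f_summary)
  cat("  INGS member statistics (first rows):\n")
  print(utils::head(x$per_gene_stats))
  invisible(x)
}

#' Per-sample normalization factors of a fit
#'
#' @param object an `"immfocus"` fit.
#' @param ... unused.
#' @return the named per-sample factor vector `f`.
#' @export
coef.immfocus <- function(object, ...) object$factors$f

#' Normalize expression with a fitted model
#'
#' Applies the fitted INGS to an expression matrix: every gene is divided by
#' the per-sample factor, INGS members by their leave-one-out factor. With
#' `newdata`, factors are recomputed on the new cohort from the same gene set
#' (the INGS is the portable object; the factors are cohort-specific).
#'
#' @param object an `"immfocus"` fit.
#' @param newdata optional expression matrix containing all INGS genes;
#'   defaults to the training matrix.
#' @param ... unused.
#' @return the normalized expression matrix.
#' @export
predict.immfocus <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    normalize_expression(object$expr, object$ings, factors = object$factors)
  } else {
    normalize_expression(as_expression_matrix(newdata), object$ings)
  }
}

#' Diagnostic plot of an immune-normalization fit
#'
#' Left: distribution of the per-sample factor `f` (relative immune content).
#' Right: anchor correlation (r-squared) against refinement CVR for the final
#' INGS members, with the thresholds drawn.
#'
#' @param x an `"immfocus"` fit.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.immfocus <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$factors$f, main = "Per-sample immune factor",
                 xlab = "f (mean INGS expression)", col = "grey85", ...)
  st <- x$ings$per_gene_stats
  if (!is.null(st$r2)) {
    graphics::plot(st$r2, st$cvr, xlab = expression(r^2 ~ "with anchor"),
                   ylab = "CVR", main = "Final INGS members", pch = 19,
                   col = "steelblue")
    graphics::abline(h = x$ings$cvr_threshold, v = x$ings$r2_threshold,
                     lty = 2, col = "grey50")
  }
  invisible(x)
}
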