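#' Stratify samples into bottom and top expression tertiles
#'
#' Samples are ranked ascending by expression (ties broken by sample id);
#' the low group is the first `floor(N/3)` samples, the high group the last
#' `floor(N/3)`. The middle tertile is unused. When all values are identical
#' the split is still made by rank order but flagged uninformative.
#'
#' @param values per-sample expression of one gene; names are the sample ids
#'   (or supply `sample_ids`).
#' @param sample_ids sample ids matching `values`.
#' @return list with `low` and `high` id vectors and an `uninformative` flag.
#' @export
stratify_by_tertiles <- function(values, sample_ids = names(values)) {
  if (is.null(sample_ids)) stopf("sample ids are required (names of values)")
  n <- length(values)
  if (n < 6) stopf("tertile stratification needs at least 6 samples")
  k <- floor(n / 3)
  ord <- order(values, sample_ids)
  ids <- sample_ids[ord]
  list(low = ids[seq_len(k)], high = ids[seq(n - k + 1, n)],
       uninformative = length(unique(values)) == 1)
}

#' Kaplan-Meier product-limit curve
#'
#' Thin interface over [survival::survfit()] restricted to the distinct event
#' times: at each, the number at risk, the number of events, and the
#' product-limit estimate `S(t)`.
#'
#' @param times follow-up times (days), nonnegative.
#' @param events event indicator per subject (1 = death observed,
#'   0 = censored).
#' @return object of class `"km_curve"`: `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(times, events) {
  if (length(times) != length(events)) stopf("times and events differ in length")
  if (any(times < 0)) stopf("negative follow-up time")
  if (sum(events) == 0) {
    warnf("no events: survival curve is identically 1")
    return(structure(list(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), surv = numeric(0)),
                     class = "km_curve"))
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep], surv = fit$surv[keep]),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d event times\n", length(x$time)))
  if (length(x$time) > 0) {
    print(utils::head(data.frame(time = x$time, n_risk = x$n_risk,
                                 n_event = x$n_event, surv = x$surv), 10))
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Unstratified Mantel-Haenszel log-rank test (hypergeometric variance, no
#' continuity correction), computed via [survival::survdiff()]: chi-square on
#' 1 degree of freedom, two-sided p. With zero events overall the test is
#' undefined and `p` is `NA` with a warning.
#'
#' @param times_a,events_a follow-up times and event indicators, group A.
#' @param times_b,events_b same for group B.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stopf("both groups must be nonempty")
  }
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  if (sum(events) == 0) {
    warnf("no events in either group: log-rank test undefined")
    return(list(chisq = NA_real_, df = 1L, p = NA_real_))
  }
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Log-odds of normalization effect on survival significance
#'
#' `LOD = ln(p_norm / p_raw)`: negative when normalization strengthened the
#' survival association (smaller p), positive when it weakened it. A value of
#' -2 corresponds to a more than 7-fold (e^2) drop in p. Inputs are floored
#' at `p_floor` before the ratio so that underflowing p-values never produce
#' log(0).
#'
#' @param p_norm log-rank p-value on normalized expression.
#' @param p_raw log-rank p-value on raw expression.
#' @param p_floor lower floor applied to both (default 1e-300).
#' @return `ln(p_norm / p_raw)` (vectorized).
#' @export
compute_lod <- function(p_norm, p_raw, p_floor = 1e-300) {
  if (any(is.na(p_norm)) || any(is.na(p_raw))) {
    stopf("LOD undefined for missing p-values")
  }
  if (any(p_norm < 0) || any(p_raw < 0) ||
      any(p_norm > 1) || any(p_raw > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  log(pmax(p_norm, p_floor) / pmax(p_raw, p_floor))
}

# +1 when the high-expression tertile survives longer than the low tertile
# (longer KM median, falling back to the final product-limit estimate when a
# median is not reached), -1 otherwise.
km_direction <- function(strat, clin) {
  i_low <- match(strat$low, clin$sample_id)
  i_high <- match(strat$high, clin$sample_id)
  med_or_final <- function(i) {
    if (sum(clin$event[i]) == 0) return(c(Inf, 1))
    fit <- survival::survfit(survival::Surv(clin$os_time[i],
                                            clin$event[i]) ~ 1)
    med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
    c(if (is.na(med)) Inf else med, min(fit$surv))
  }
  lo <- med_or_final(i_low)
  hi <- med_or_final(i_high)
  cmp <- if (hi[1] != lo[1]) hi[1] - lo[1] else hi[2] - lo[2]
  if (cmp >= 0) 1L else -1L
}

#' Genome-wide tertile-stratified survival scan
#'
#' For each gene, patients are stratified into bottom and top expression
#' tertiles — once on raw and once on normalized values (groups re-derived
#' from the normalized ranks) — and the two tertiles are compared by the
#' log-rank test. Significance is Bonferroni-adjusted: a gene is flagged when
#' its p-value falls below `alpha / n_tests` (or below its Benjamini-Hochberg
#' threshold with `adjust = "BH"`). The normalization effect per gene is
#' summarised by `lod = ln(p_norm / p_raw)`.
#'
#' @param raw raw expression matrix.
#' @param norm normalized expression matrix (same genes and samples).
#' @param clin clinical table aligned to the matrix columns.
#' @param genes gene ids to scan (default: all rows).
#' @param alpha family-wise significance level (default 0.05).
#' @param n_tests `"auto"` (the number of scanned genes with a defined test)
#'   or an integer.
#' @param adjust `"bonferroni"` (default) or `"BH"` for a
#'   false-discovery-rate flag instead.
#' @param regroup re-derive tertiles from normalized values for the
#'   normalized test (default `TRUE`); `FALSE` reuses the raw grouping.
#' @return `data.frame` per gene: `p_raw`, `p_norm`, `lod`, `sig_raw`,
#'   `sig_norm`, `direction` (+1 = high expression associated with longer
#'   survival on the data that produced the more significant test), `n_low`,
#'   `n_high`. The effective `n_tests` is attached as an attribute.
#' @export
gene_survival_scan <- function(raw, norm, clin, genes = NULL, alpha = 0.05,
                               n_tests = "auto",
                               adjust = c("bonferroni", "BH"),
                               regroup = TRUE) {
  adjust <- match.arg(adjust)
  genes <- genes %||% rownames(raw)
  missing <- setdiff(genes, intersect(rownames(raw), rownames(norm)))
  if (length(missing) > 0) {
    stopf("scan gene(s) missing from matrices: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  if (!identical(colnames(raw), clin$sample_id)) {
    stopf("clinical table is not aligned to the matrix columns (run align_cohort first)")
  }
  one_p <- function(strat) {
    i_low <- match(strat$low, clin$sample_id)
    i_high <- match(strat$high, clin$sample_id)
    if (sum(clin$event[c(i_low, i_high)]) == 0) return(NA_real_)
    logrank_test(clin$os_time[i_low], clin$event[i_low],
                 clin$os_time[i_high], clin$event[i_high])$p
  }
  res <- lapply(genes, function(g) {
    st_raw <- stratify_by_tertiles(raw[g, ], colnames(raw))
    st_norm <- if (regroup) stratify_by_tertiles(norm[g, ], colnames(norm))
    else st_raw
    p_raw <- one_p(st_raw)
    p_norm <- one_p(st_norm)
    dir <- if (!is.na(p_norm) && (is.na(p_raw) || p_norm <= p_raw)) {
      km_direction(st_norm, clin)
    } else if (!is.na(p_raw)) km_direction(st_raw, clin) else NA_integer_
    data.frame(gene = g, p_raw = p_raw, p_norm = p_norm,
               direction = dir, n_low = length(st_raw$low),
               n_high = length(st_raw$high), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  defined <- !is.na(out$p_raw) & !is.na(out$p_norm)
  out$lod <- NA_real_
  out$lod[defined] <- compute_lod(out$p_norm[defined], out$p_raw[defined])
  n_eff <- if (identical(n_tests, "auto")) sum(defined) else as.integer(n_tests)
  if (adjust == "bonferroni") {
    out$sig_raw <- !is.na(out$p_raw) & out$p_raw < alpha / n_eff
    out$sig_norm <- !is.na(out$p_norm) & out$p_norm < alpha / n_eff
  } else {
    out$sig_raw <- !is.na(out$p_raw) &
      stats::p.adjust(out$p_raw, "BH") < alpha
    out$sig_norm <- !is.na(out$p_norm) &
      stats::p.adjust(out$p_norm, "BH") < alpha
  }
  out <- out[, c("gene", "p_raw", "p_norm", "lod", "sig_raw", "sig_norm",
                 "direction", "n_low", "n_high")]
  attr(out, "n_tests") <- n_eff
  attr(out, "alpha") <- alpha
  out
}
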