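#' Yates chi-square on a 2x2 stage contingency table, with legacy adjustment
#'
#' Pearson chi-square with Yates continuity correction on a 2x2 table of
#' expression tertile (low/high rows) against combined pathological stage
#' (I+II vs III+IV columns), followed by Bonferroni adjustment. With
#' `legacy_rounding` the raw p is first rounded to 4 decimal places and then
#' multiplied by `n_tests` (capped at 1) — the convention that reproduces the
#' published per-gene stage tables; new analyses should leave it off.
#'
#' @param counts 2x2 integer matrix: rows low/high expression tertile,
#'   columns stage I+II / III+IV.
#' @param n_tests Bonferroni multiplier (default 1).
#' @param legacy_rounding round the raw p to 4 decimals before multiplying
#'   (default `FALSE`).
#' @return list with `chisq`, `p_raw`, `p_adjusted`, `counts`.
#' @export
stage_chisq_adjust <- function(counts, n_tests = 1, legacy_rounding = FALSE) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L))) stopf("counts must be a 2x2 table")
  if (any(counts < 0)) stopf("negative count")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stopf("empty row or column: test undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = TRUE))
  p_raw <- ht$p.value
  p_adj <- if (legacy_rounding) min(round(p_raw, 4) * n_tests, 1)
  else min(p_raw * n_tests, 1)
  list(chisq = unname(ht$statistic), p_raw = p_raw, p_adjusted = p_adj,
       counts = counts)
}

tertile_clin <- function(values, clin) {
  strat <- stratify_by_tertiles(values, names(values) %||% clin$sample_id)
  list(low = clin[match(strat$low, clin$sample_id), , drop = FALSE],
       high = clin[match(strat$high, clin$sample_id), , drop = FALSE])
}

#' Stage association of an expression-stratified cohort
#'
#' Splits patients into bottom/top expression tertiles of one gene, combines
#' pathological stages I+II and III+IV, and tests the 2x2 tertile-by-stage
#' table with a Yates-corrected chi-square (see [stage_chisq_adjust()]).
#' Patients with unknown stage are dropped from the table.
#'
#' @param values per-sample expression of one gene, named by sample id.
#' @param clin clinical table.
#' @inheritParams stage_chisq_adjust
#' @return as [stage_chisq_adjust()], with the assembled `counts`.
#' @export
stage_association <- function(values, clin, n_tests = 1,
                              legacy_rounding = FALSE) {
  tc <- tertile_clin(values, clin)
  count_row <- function(d) {
    known <- d$stage %in% c("I", "II", "III", "IV")
    c(sum(d$stage[known] %in% c("I", "II")),
      sum(d$stage[known] %in% c("III", "IV")))
  }
  counts <- rbind(low = count_row(tc$low), high = count_row(tc$high))
  colnames(counts) <- c("stage_I_II", "stage_III_IV")
  if (any(rowSums(counts) == 0)) {
    stopf("a tertile has no patients with known stage")
  }
  stage_chisq_adjust(counts, n_tests = n_tests,
                     legacy_rounding = legacy_rounding)
}

#' Age association of an expression-stratified cohort
#'
#' Two-sided two-sample Student t-test (pooled variance) comparing the ages
#' of the bottom and top expression tertiles. Unknown ages are dropped; with
#' fewer than two known ages in either tertile the test is undefined and
#' returned flagged.
#'
#' @param values per-sample expression of one gene, named by sample id.
#' @param clin clinical table.
#' @return list with `t`, `p`, `n_low`, `n_high`, `defined`.
#' @export
age_association <- function(values, clin) {
  tc <- tertile_clin(values, clin)
  a <- tc$low$age[!is.na(tc$low$age)]
  b <- tc$high$age[!is.na(tc$high$age)]
  if (length(a) < 2 || length(b) < 2) {
    return(list(t = NA_real_, p = NA_real_, n_low = length(a),
                n_high = length(b), defined = FALSE))
  }
  if (stats::sd(c(a, b)) == 0) {
    return(list(t = 0, p = 1, n_low = length(a), n_high = length(b),
                defined = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, n_low = length(a),
       n_high = length(b), defined = TRUE)
}

#' Gender association of an expression-stratified cohort
#'
#' Yates-corrected 2x2 chi-square of tertile (low/high) against gender
#' (male/female); unknown genders are dropped. A tertile with no known
#' genders leaves the test undefined (flagged).
#'
#' @param values per-sample expression of one gene, named by sample id.
#' @param clin clinical table.
#' @return list with `chisq`, `p`, `counts`, `defined`.
#' @export
gender_association <- function(values, clin) {
  tc <- tertile_clin(values, clin)
  count_row <- function(d) c(male = sum(d$gender == "male"),
                             female = sum(d$gender == "female"))
  counts <- rbind(low = count_row(tc$low), high = count_row(tc$high))
  if (any(rowSums(counts) == 0)) {
    return(list(chisq = NA_real_, p = NA_real_, counts = counts,
                defined = FALSE))
  }
  if (any(colSums(counts) == 0)) {
    # one gender absent everywhere: distributions identical by construction
    return(list(chisq = 0, p = 1, counts = counts, defined = TRUE))
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = TRUE))
  list(chisq = unname(ht$statistic), p = ht$p.value, counts = counts,
       defined = TRUE)
}
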