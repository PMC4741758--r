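#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. Defined
#' only for vectors of at least two values with a positive mean; a
#' nonpositive mean returns `NA` (the caller flags such genes as excluded).
#'
#' @param values numeric vector.
#' @return `sd(values) / mean(values)`, or `NA_real_` when the mean is not
#'   positive.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stopf("CV needs at least 2 values")
  m <- mean(values)
  if (is.na(m) || m <= 0) return(NA_real_)
  stats::sd(values) / m
}

#' Per-gene CV ratio table
#'
#' For every gene, the coefficient of variation across samples before
#' (`cv_raw`) and after (`cv_norm`) normalization, and their ratio
#' `cvr = cv_norm / cv_raw`. A CVR below 1 means normalization reduced the
#' gene's apparent between-sample variability. Genes with a nonpositive mean
#' or zero raw variance have no defined ratio; they are flagged `excluded`
#' and carry `NA` in `cvr`.
#'
#' @param raw raw expression matrix.
#' @param normalized normalized expression matrix over the same genes and
#'   samples (see [normalize_expression()]).
#' @return `data.frame` with columns `gene`, `cv_raw`, `cv_norm`, `cvr`,
#'   `excluded`.
#' @export
compute_cvr_table <- function(raw, normalized) {
  if (!identical(dim(raw), dim(normalized)) ||
      !identical(rownames(raw), rownames(normalized)) ||
      !identical(colnames(raw), colnames(normalized))) {
    stopf("raw and normalized matrices must share genes and samples")
  }
  cv_raw <- apply(raw, 1, coefficient_of_variation)
  cv_norm <- apply(normalized, 1, coefficient_of_variation)
  excluded <- is.na(cv_raw) | is.na(cv_norm) | cv_raw == 0
  cvr <- ifelse(excluded, NA_real_, cv_norm / cv_raw)
  data.frame(gene = rownames(raw), cv_raw = cv_raw, cv_norm = cv_norm,
             cvr = cvr, excluded = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the CVR_low / CVR_high / CVR_random gene groups
#'
#' `cvr_low` holds the `group_size` genes with the lowest CVR (the genes most
#' responsive to the normalization), `cvr_high` the highest, and `cvr_random`
#' a seeded uniform sample, without replacement, drawn from all rankable
#' genes regardless of CVR — it may therefore overlap the other two. Ties at
#' group boundaries are broken by gene id order.
#'
#' @param table a [compute_cvr_table()] result.
#' @param group_size genes per group (default 500).
#' @param seed integer seed for the random group (recorded in the result).
#' @return an object of class `"cvr_groups"`: `cvr_low`, `cvr_high`,
#'   `cvr_random` (character vectors), `group_size`, `seed`.
#' @export
select_cvr_groups <- function(table, group_size = 500, seed = 1) {
  rankable <- table[!table$excluded & !is.na(table$cvr), , drop = FALSE]
  if (nrow(rankable) < group_size) {
    stopf("only %d rankable genes; cannot form groups of %d",
          nrow(rankable), group_size)
  }
  ord <- order(rankable$cvr, rankable$gene)
  low <- rankable$gene[ord][seq_len(group_size)]
  high <- rankable$gene[ord][seq(nrow(rankable) - group_size + 1,
                                 nrow(rankable))]
  random <- with_seed(seed, sample(rankable$gene, group_size))
  structure(list(cvr_low = low, cvr_high = high, cvr_random = sort(random),
                 group_size = group_size, seed = seed),
            class = "cvr_groups")
}

#' @export
print.cvr_groups <- function(x, ...) {
  cat(sprintf("CVR gene groups (%d genes each; random seed %d)\n",
              x$group_size, x$seed))
  invisible(x)
}

#' Compare mean CVR across the gene groups
#'
#' Mean and sample standard deviation of CVR per group, plus two-sided
#' two-sample Student t-tests for every pair of groups. Pairs where both
#' groups have zero within-group variance are flagged `degenerate` (the t
#' statistic is undefined).
#'
#' @param groups a [select_cvr_groups()] result (or named list of gene id
#'   vectors).
#' @param table the [compute_cvr_table()] result the groups came from.
#' @return list with `stats` (`group`, `n`, `mean`, `sd`) and `pairwise`
#'   (`group_a`, `group_b`, `t`, `p`, `degenerate`).
#' @export
compare_group_cvr <- function(groups, table) {
  sets <- if (inherits(groups, "cvr_groups")) {
    groups[c("cvr_low", "cvr_high", "cvr_random")]
  } else groups
  vals <- lapply(sets, function(g) {
    missing <- setdiff(g, table$gene)
    if (length(missing) > 0) {
      stopf("group gene(s) not in CVR table: %s",
            paste(utils::head(missing, 3), collapse = ", "))
    }
    v <- table$cvr[match(g, table$gene)]
    v[!is.na(v)]
  })
  stats_df <- data.frame(group = names(sets),
                         n = vapply(vals, length, integer(1)),
                         mean = vapply(vals, mean, numeric(1)),
                         sd = vapply(vals, stats::sd, numeric(1)),
                         row.names = NULL, stringsAsFactors = FALSE)
  pairs <- utils::combn(names(sets), 2)
  pw <- apply(pairs, 2, function(ab) {
    a <- vals[[ab[1]]]; b <- vals[[ab[2]]]
    degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (degenerate || identical(a, b)) {
      tt <- if (identical(a, b)) list(statistic = 0, p.value = 1)
      else list(statistic = NA_real_, p.value = NA_real_)
    } else {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(group_a = ab[1], group_b = ab[2],
               t = tt$statistic, p = tt$p.value, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  list(stats = stats_df, pairwise = do.call(rbind, pw))
}
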