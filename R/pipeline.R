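#' Run the full immune-normalization pipeline
#'
#' Orchestrates the end-to-end analysis on one cohort: align expression and
#' clinical tables, derive the INGS and per-sample factors, normalize, build
#' the CVR table and the CVR_low / CVR_high / CVR_random groups, run the
#' tertile-stratified survival scan over the grouped genes on raw and
#' normalized data, test stage/age/gender association for the
#' normalization-responsive hits, and (when an annotation list is supplied)
#' test immune enrichment of the three groups. Every table is written to
#' `out_dir` along with a machine-readable `manifest.json` and a short
#' human-readable `summary.txt`. A failure at any stage leaves a `FAILED`
#' marker file naming the stage.
#'
#' @param expr expression matrix, or path to a merged TSV.
#' @param clinical clinical table `data.frame`, or path to a clinical file.
#' @param out_dir output directory (created if absent).
#' @param anchor,r2_threshold,cvr_threshold,require_positive passed to
#'   [immfocus()].
#' @param group_size CVR group size (default 500).
#' @param seed seed for the random CVR group (default 1).
#' @param alpha,n_tests,adjust passed to [gene_survival_scan()].
#' @param lod_cutoff survival-scan hits with `sig_norm` and `lod` at or below
#'   this enter the clinical-association table (default -2).
#' @param annotation optional annotation set (path or
#'   [read_annotation_set()] result) for the enrichment test.
#' @param primary_tumor_only passed to [align_cohort()].
#' @param legacy_rounding passed to [stage_association()].
#' @return invisibly, a list with the fit, tables and the manifest.
#' @export
run_pipeline <- function(expr, clinical, out_dir,
                         anchor = "PTPRC", r2_threshold = 0.5,
                         cvr_threshold = 0.8, require_positive = TRUE,
                         group_size = 500, seed = 1, alpha = 0.05,
                         n_tests = "auto", adjust = "bonferroni",
                         lod_cutoff = -2, annotation = NULL,
                         primary_tumor_only = FALSE,
                         legacy_rounding = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_name <- "setup"
  artifacts <- character(0)
  on_fail <- function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage_name,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stopf("pipeline failed at stage '%s': %s", stage_name,
          conditionMessage(e))
  }
  tryCatch({
    emit <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      artifacts <<- c(artifacts, name)
      path
    }

    stage_name <- "align"
    if (is.character(expr)) expr <- read_expression_matrix(expr)
    if (is.character(clinical)) clinical <- read_clinical_table(clinical)
    cohort <- align_cohort(expr, clinical,
                           primary_tumor_only = primary_tumor_only)
    expr <- cohort$expr
    clinical <- cohort$clinical

    stage_name <- "ings"
    fit <- immfocus(expr, anchor = anchor, r2_threshold = r2_threshold,
                    cvr_threshold = cvr_threshold,
                    require_positive = require_positive)
    write_ings(fit$ings, file.path(out_dir, "ings.json"))
    artifacts <- c(artifacts, "ings.json")
    emit(data.frame(sample_id = names(fit$factors$f), f = fit$factors$f),
         "normalization_factors.tsv")

    stage_name <- "normalize"
    norm <- predict(fit)
    write_expression_matrix(norm, file.path(out_dir,
                                            "normalized_expression.tsv"))
    artifacts <- c(artifacts, "normalized_expression.tsv")

    stage_name <- "cvr"
    cvr_tab <- compute_cvr_table(expr, norm)
    emit(cvr_tab, "cvr_table.tsv")
    groups <- select_cvr_groups(cvr_tab, group_size = group_size,
                                seed = seed)
    emit(data.frame(
      group = rep(c("cvr_low", "cvr_high", "cvr_random"),
                  each = group_size),
      gene = c(groups$cvr_low, groups$cvr_high, groups$cvr_random)),
      "cvr_groups.tsv")
    group_cmp <- compare_group_cvr(groups, cvr_tab)

    stage_name <- "survival_scan"
    scan_genes <- unique(c(groups$cvr_low, groups$cvr_high,
                           groups$cvr_random))
    scan <- gene_survival_scan(expr, norm, clinical, genes = scan_genes,
                               alpha = alpha, n_tests = n_tests,
                               adjust = adjust)
    scan$group_low <- scan$gene %in% groups$cvr_low
    scan$group_high <- scan$gene %in% groups$cvr_high
    scan$group_random <- scan$gene %in% groups$cvr_random
    emit(scan, "survival_scan.tsv")

    stage_name <- "clinical_association"
    hits <- scan$gene[scan$sig_norm & !is.na(scan$lod) &
                        scan$lod <= lod_cutoff]
    assoc <- lapply(hits, function(gg) {
      st <- stage_association(norm[gg, ], clinical, n_tests = length(hits),
                              legacy_rounding = legacy_rounding)
      ag <- age_association(norm[gg, ], clinical)
      gd <- gender_association(norm[gg, ], clinical)
      data.frame(gene = gg,
                 direction = scan$direction[scan$gene == gg],
                 low_stage12 = st$counts[1, 1], low_stage34 = st$counts[1, 2],
                 high_stage12 = st$counts[2, 1],
                 high_stage34 = st$counts[2, 2],
                 stage_p_adjusted = st$p_adjusted,
                 age_p = ag$p, gender_p = gd$p,
                 stringsAsFactors = FALSE)
    })
    assoc <- if (length(assoc) > 0) do.call(rbind, assoc) else
      data.frame(gene = character(0), direction = integer(0),
                 low_stage12 = integer(0), low_stage34 = integer(0),
                 high_stage12 = integer(0), high_stage34 = integer(0),
                 stage_p_adjusted = numeric(0), age_p = numeric(0),
                 gender_p = numeric(0), stringsAsFactors = FALSE)
    emit(assoc, "clinical_associations.tsv")

    stage_name <- "enrichment"
    if (!is.null(annotation)) {
      if (is.character(annotation)) {
        annotation <- read_annotation_set(annotation)
      }
      counts <- lapply(groups[c("cvr_low", "cvr_high", "cvr_random")],
                       annotate_group, annotation = annotation)
      enr <- enrichment_test(counts)
      enr_df <- data.frame(group = names(counts),
                           annotated = vapply(counts, `[`, numeric(1), 1),
                           total = vapply(counts, `[`, numeric(1), 2),
                           chisq = enr$chisq, p = enr$p)
    } else {
      enr <- NULL
      enr_df <- data.frame(group = character(0), annotated = integer(0),
                           total = integer(0), chisq = numeric(0),
                           p = numeric(0))
    }
    emit(enr_df, "enrichment.tsv")

    stage_name <- "manifest"
    manifest <- list(
      package = "immfocus",
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = list(anchor = anchor, r2_threshold = r2_threshold,
                    cvr_threshold = cvr_threshold,
                    require_positive = require_positive,
                    group_size = group_size, seed = seed, alpha = alpha,
                    n_tests = n_tests, adjust = adjust,
                    lod_cutoff = lod_cutoff,
                    legacy_rounding = legacy_rounding),
      cohort = list(n_genes = nrow(expr), n_samples = ncol(expr)),
      ings_size = length(fit$ings$genes),
      artifacts = artifacts)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    summary_lines <- c(
      sprintf("cohort: %d genes x %d samples", nrow(expr), ncol(expr)),
      sprintf("INGS: %d genes (anchor %s)", length(fit$ings$genes), anchor),
      sprintf("CVR group means: low %.3f, high %.3f, random %.3f",
              group_cmp$stats$mean[1], group_cmp$stats$mean[2],
              group_cmp$stats$mean[3]),
      sprintf("survival scan: %d genes; significant raw %d, normalized %d",
              nrow(scan), sum(scan$sig_raw), sum(scan$sig_norm)),
      sprintf("normalization-responsive hits (sig_norm & LOD <= %g): %d",
              lod_cutoff, length(hits)),
      if (!is.null(enr)) sprintf("enrichment chi-square p: %.3g", enr$p)
      else "enrichment: skipped (no annotation supplied)")
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))

    invisible(list(fit = fit, scan = scan, cvr_table = cvr_tab,
                   groups = groups, group_cvr = group_cmp,
                   associations = assoc, enrichment = enr,
                   manifest = manifest))
  }, error = on_fail)
}
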