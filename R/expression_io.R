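#' Construct and validate an expression matrix
#'
#' The cohort expression container is a plain numeric matrix with gene
#' identifiers as row names and sample identifiers as column names, on the
#' linear (RSEM-normalized-count style) scale. This constructor validates the
#' invariants every downstream step relies on: nonnegative finite values,
#' unique gene and sample identifiers, and dimensions matching the id lists.
#'
#' @param values numeric matrix (genes x samples).
#' @param gene_ids character vector of gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   `colnames(values)`.
#' @return a validated numeric matrix with dimnames set.
#' @export
as_expression_matrix <- function(values, gene_ids = rownames(values),
                                 sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("expression values must be a numeric matrix")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("gene and sample identifiers are required (row/column names)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stopf("gene id list length (%d) does not match row count (%d)",
          length(gene_ids), nrow(values))
  }
  if (length(sample_ids) != ncol(values)) {
    stopf("sample id list length (%d) does not match column count (%d)",
          length(sample_ids), ncol(values))
  }
  if (anyDuplicated(gene_ids)) {
    stopf("duplicated gene id: %s", gene_ids[duplicated(gene_ids)][1])
  }
  if (anyDuplicated(sample_ids)) {
    stopf("duplicated sample id: %s", sample_ids[duplicated(sample_ids)][1])
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("missing or non-finite expression value at gene '%s', sample '%s'",
          gene_ids[bad[1]], sample_ids[bad[2]])
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stopf("negative expression value (%g) at gene '%s', sample '%s'",
          values[bad[1], bad[2]], gene_ids[bad[1]], sample_ids[bad[2]])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

# "SYMBOL|entrez" -> SYMBOL; the raw id is kept for later duplicates so that
# symbol collisions never silently merge two genes.
canonicalize_gene_ids <- function(raw_ids) {
  symbols <- sub("\\|.*$", "", raw_ids)
  empty <- !nzchar(symbols) | symbols == "?"
  symbols[empty] <- raw_ids[empty]
  dup <- duplicated(symbols)
  symbols[dup] <- raw_ids[dup]
  attr(symbols, "raw_ids") <- raw_ids
  symbols
}

#' Read a gene x sample expression matrix
#'
#' Two layouts are supported: a single merged tab-delimited matrix (first
#' column gene id, header row of sample ids), and a directory of per-sample
#' two-column RSEM files (`*.rsem.gene.normalized_results` style: header line,
#' then gene id and normalized count per row), all sharing an identical gene
#' list. Identifiers of the form `"SYMBOL|entrez"` are reduced to the symbol;
#' the raw ids are preserved in the `"raw_ids"` attribute.
#'
#' @param path path to the merged TSV file, or to the directory of per-sample
#'   files.
#' @param format `"merged_tsv"` or `"rsem_per_sample_dir"`.
#' @param pattern filename glob used in directory mode (regular expression);
#'   the sample id is the file name with this suffix stripped.
#' @return a validated expression matrix (see [as_expression_matrix()]).
#' @export
read_expression_matrix <- function(path,
                                   format = c("merged_tsv",
                                              "rsem_per_sample_dir"),
                                   pattern = "\\.rsem\\.gene\\.normalized_results$|\\.txt$|\\.tsv$") {
  format <- match.arg(format)
  if (format == "merged_tsv") {
    if (!file.exists(path)) stopf("expression file not found: %s", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stopf("merged matrix needs a gene column plus samples")
    raw_ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    gene_ids <- canonicalize_gene_ids(raw_ids)
    out <- as_expression_matrix(values, gene_ids = gene_ids,
                                sample_ids = colnames(tab)[-1])
    attr(out, "raw_ids") <- attr(gene_ids, "raw_ids")
    return(out)
  }
  if (!dir.exists(path)) stopf("per-sample directory not found: %s", path)
  files <- list.files(path, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) stopf("no per-sample files matching '%s' in %s",
                                pattern, path)
  read_one <- function(f) {
    tab <- utils::read.delim(f, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stopf("per-sample file %s needs two columns", f)
    list(ids = as.character(tab[[1]]), values = as.numeric(tab[[2]]))
  }
  first <- read_one(files[1])
  sample_ids <- sub(pattern, "", basename(files))
  values <- matrix(NA_real_, nrow = length(first$ids), ncol = length(files))
  values[, 1] <- first$values
  if (length(files) > 1) {
    for (j in 2:length(files)) {
      cur <- read_one(files[j])
      if (!identical(cur$ids, first$ids)) {
        mism <- which(cur$ids != first$ids | is.na(cur$ids != first$ids))[1]
        stopf("gene list mismatch in %s at line %d ('%s' vs '%s' in %s)",
              basename(files[j]), mism, cur$ids[mism], first$ids[mism],
              basename(files[1]))
      }
      values[, j] <- cur$values
    }
  }
  gene_ids <- canonicalize_gene_ids(first$ids)
  out <- as_expression_matrix(values, gene_ids = gene_ids,
                              sample_ids = sample_ids)
  attr(out, "raw_ids") <- attr(gene_ids, "raw_ids")
  out
}

#' Write an expression matrix as a merged TSV
#'
#' Same dialect as the merged-matrix input: first column `gene_id`, one column
#' per sample. Values round-trip exactly (full double precision).
#'
#' @param expr expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_aliases <- list(
  sample_id = c("sample_id", "bcr_patient_barcode", "patient_id", "sample",
                "barcode", "id"),
  os_time = c("os_time", "os_days", "overall_survival_days", "time"),
  event = c("event", "os_event", "status"),
  days_to_death = c("days_to_death"),
  days_to_last_followup = c("days_to_last_followup", "days_to_last_follow_up",
                            "days_to_last_known_alive"),
  vital_status = c("vital_status"),
  age = c("age", "age_at_initial_pathologic_diagnosis", "age_at_diagnosis",
          "years_to_birth"),
  gender = c("gender", "sex"),
  stage = c("stage", "pathologic_stage", "pathological_stage",
            "ajcc_pathologic_stage", "tumor_stage")
)

find_alias <- function(cols, aliases) {
  hit <- match(aliases, tolower(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

normalize_stage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^STAGE\\s*", "", x)
  out <- rep("unknown", length(x))
  out[grepl("^IV", x)] <- "IV"
  out[grepl("^III", x) & !grepl("^IV", x)] <- "III"
  out[grepl("^II($|[^IV])", x)] <- "II"
  out[grepl("^I($|[^IV])", x)] <- "I"
  out[grepl("^4", x)] <- "IV"
  out[grepl("^3", x)] <- "III"
  out[grepl("^2", x)] <- "II"
  out[grepl("^1", x)] <- "I"
  out
}

normalize_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m")] <- "male"
  out[x %in% c("female", "f")] <- "female"
  out
}

#' Read a per-sample clinical table
#'
#' Reads a TSV/CSV clinical table and maps it onto the cohort clinical model:
#' `sample_id`, `os_time` (days), `event` (1 = death observed, 0 = censored),
#' `age` (years), `gender` (`male`/`female`/`unknown`) and `stage`
#' (`I`/`II`/`III`/`IV`/`unknown`). When a direct `os_time`/`event` pair is
#' absent, overall survival is derived from TCGA-style columns: vital status
#' "dead" gives `event = 1` with `os_time = days_to_death`, otherwise
#' `event = 0` with `os_time = days_to_last_followup`. Rows with no usable
#' survival time are dropped with a warning (the count is recorded in the
#' `"n_dropped"` attribute). Stage strings are prefix-matched, so
#' "Stage IIIa" maps to `III`.
#'
#' @param path clinical table path; the delimiter is inferred from the
#'   extension (`.csv` vs tab-delimited otherwise).
#' @return a `data.frame`, one row per sample.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stopf("clinical file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "[Not Available]",
                                          "[Not Applicable]", "null"))
  cols <- colnames(tab)
  pick <- function(field) {
    i <- find_alias(cols, clinical_aliases[[field]])
    if (is.na(i)) NULL else tab[[i]]
  }
  sample_id <- pick("sample_id")
  if (is.null(sample_id)) stopf("no sample id column found (aliases: %s)",
                                paste(clinical_aliases$sample_id,
                                      collapse = ", "))
  sample_id <- as.character(sample_id)

  os_time <- suppressWarnings(as.numeric(pick("os_time")))
  event <- suppressWarnings(as.numeric(pick("event")))
  if (is.null(os_time) || is.null(event) || all(is.na(os_time))) {
    dtd <- suppressWarnings(as.numeric(pick("days_to_death")))
    dtf <- suppressWarnings(as.numeric(pick("days_to_last_followup")))
    vs <- tolower(trimws(as.character(pick("vital_status") %||%
                                        rep(NA, length(sample_id)))))
    if (is.null(dtd) && is.null(dtf)) {
      stopf("no survival columns found (need os_time/event or days_to_death/days_to_last_followup + vital_status)")
    }
    dtd <- dtd %||% rep(NA_real_, length(sample_id))
    dtf <- dtf %||% rep(NA_real_, length(sample_id))
    dead <- vs %in% c("dead", "deceased")
    event <- ifelse(dead, 1, 0)
    os_time <- ifelse(dead, dtd, dtf)
    # dead but no recorded death time: fall back to last follow-up
    fix <- dead & is.na(os_time) & !is.na(dtf)
    os_time[fix] <- dtf[fix]
  }

  age <- suppressWarnings(as.numeric(pick("age") %||%
                                       rep(NA_real_, length(sample_id))))
  gender <- normalize_gender(pick("gender") %||% rep(NA, length(sample_id)))
  stage <- normalize_stage(pick("stage") %||% rep(NA, length(sample_id)))

  keep <- !is.na(os_time) & os_time >= 0 & !is.na(event)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warnf("dropped %d clinical row(s) without a usable survival time",
          n_dropped)
  }
  out <- data.frame(sample_id = sample_id, os_time = os_time,
                    event = as.integer(event), age = age, gender = gender,
                    stage = stage, stringsAsFactors = FALSE)[keep, ,
                                                             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

tcga_sample_type <- function(ids) {
  # TCGA barcodes: TCGA-XX-XXXX-01A-... ; field 4 starts with the 2-digit
  # sample-type code ("01" = primary solid tumor)
  parts <- strsplit(ids, "-", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) >= 4 && toupper(p[1]) == "TCGA") substr(p[4], 1, 2)
    else NA_character_
  }, character(1))
}

#' Align expression and clinical tables into one cohort
#'
#' Restricts both inputs to their shared sample ids, in sorted id order (the
#' fixed cohort order used by every downstream step). With
#' `primary_tumor_only = TRUE` and TCGA-style barcodes, only sample-type code
#' "01" (primary solid tumor) is retained before intersecting.
#'
#' @param expr expression matrix.
#' @param clin clinical `data.frame` as from [read_clinical_table()].
#' @param primary_tumor_only keep only primary-tumor barcodes when barcodes
#'   are TCGA-style.
#' @return `list(expr = , clinical = )`, both over the same ordered samples.
#' @export
align_cohort <- function(expr, clin, primary_tumor_only = FALSE) {
  expr_ids <- colnames(expr)
  if (primary_tumor_only) {
    st <- tcga_sample_type(expr_ids)
    if (any(!is.na(st))) expr_ids <- expr_ids[is.na(st) | st == "01"]
  }
  shared <- sort(intersect(expr_ids, clin$sample_id))
  if (length(shared) == 0) {
    stopf("no shared sample ids between expression and clinical tables")
  }
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr[, shared, drop = FALSE], clinical = clin2)
}
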