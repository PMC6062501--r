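# File formats: TSV expression matrices (first column gene id, remaining
# columns sample ids), TSV clinical tables, GMT gene sets, JSON run
# manifests. All readers validate and reject rather than silently coerce.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' duplicate gene ids and non-numeric body cells are rejected with
#' coordinates.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stopf("expression file needs a gene column plus samples")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("non-numeric cell at row %d (gene %s), column %d (%s)",
          bad[1, 1], genes[bad[1, 1]], bad[1, 2], colnames(body)[bad[1, 2]])
  }
  if (anyNA(num)) stopf("missing values in expression matrix")
  dimnames(num) <- list(genes, colnames(body))
  num
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CLINICAL_COLUMNS <- c("sample_id", "time", "event", "sex", "age",
                      "cytogenetics", "runx1_mutation", "fusion_t8_21")

#' Read a clinical table from TSV
#'
#' Validates the schema: required columns present; `time` numeric and
#' positive; `event` in \{0, 1\}; cytogenetic risk in
#' \{favorable, intermediate, adverse\}; alteration flags in
#' \{present, absent, missing\}. Missingness is preserved as the explicit
#' `"missing"` category, never imputed.
#'
#' @param path File path.
#' @return Data frame of validated clinical records.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing) > 0) {
    stopf("clinical schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  }
  check_values <- function(col, valid) {
    bad <- which(!df[[col]] %in% valid)
    if (length(bad) > 0) {
      stopf("invalid %s value '%s' at line %d", col, df[[col]][bad[1]],
            bad[1] + 1)
    }
  }
  if (!is.numeric(df$time) || any(is.na(df$time)) || any(df$time <= 0)) {
    bad <- which(is.na(df$time) | df$time <= 0)[1]
    stopf("invalid time value at line %d (must be numeric > 0)",
          (bad %||% 1) + 1)
  }
  check_values("event", c(0, 1))
  check_values("cytogenetics", c("favorable", "intermediate", "adverse"))
  check_values("runx1_mutation", c("present", "absent", "missing"))
  check_values("fusion_t8_21", c("present", "absent", "missing"))
  df
}

#' Write a clinical table to TSV
#' @param clinical Clinical data frame.
#' @param path Output path.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical[, CLINICAL_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then tab-separated gene ids (at least
#' one). Duplicate genes within a set are collapsed with a warning; an
#' empty file yields an empty collection with a warning.
#'
#' @param path File path.
#' @param universe Optional universe; defaults to the union of all sets.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warnf("empty GMT file: returning an empty collection")
    return(structure(list(sets = list(), universe = universe %||% character(0)),
                     class = "gene_set_collection"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("GMT parse error at line %d: expected at least 3 tab-separated fields", i)
    }
    genes <- fields[-(1:2)]
    uniq <- unique(genes)
    if (length(uniq) < length(genes)) {
      warnf("duplicate gene(s) within set '%s' collapsed", fields[1])
    }
    sets[[fields[1]]] <- uniq
  }
  gene_set_collection(sets, universe %||% unique(unlist(sets)))
}

#' Write gene sets to a GMT file
#' @param genesets A [gene_set_collection()].
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(genesets, path, description = "synthetic") {
  lines <- vapply(names(genesets$sets), function(nm) {
    paste(c(nm, description, genesets$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what a pipeline stage did -- tool version, a hash of the
#' configuration, the seeds used and per-stage row counts/statuses -- so any
#' output directory documents how to re-run it.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param config List of configuration values (hashed and embedded).
#' @param seeds Seed(s) used.
#' @param counts Named list/vector of row counts.
#' @param status Stage status string.
#' @export
write_run_manifest <- function(path, stage, config, seeds, counts = list(),
                               status = "ok") {
  manifest <- list(
    tool = "survmedscreen",
    version = as.character(utils::packageVersion("survmedscreen")),
    stage = stage,
    config_hash = config_hash(config),
    config = config,
    seeds = seeds,
    counts = counts,
    status = status,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# Deterministic hash of a configuration list (serialize canonically, then
# fold bytes; no external digest dependency).
config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 997)) %% 4294967291)
}
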