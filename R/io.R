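#' Read a gene-by-sample expression matrix from TSV
#'
#' The expected layout is a header row of sample identifiers, a first column of
#' gene identifiers, and a numeric body of normalized log2 intensities. The
#' dialect is strict — tab separated, `.` decimal, no quoting — so that
#' write/read round-trips are bit-exact.
#'
#' @param path path to a TSV file.
#' @return A numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stopf("expression file '%s' has no data rows", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample ID(s) in '%s': %s", path,
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    stopf("ragged row at line %d of '%s' (%d fields, expected %d)",
          bad + 1L, path, widths[bad], length(header))
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene ID(s) in '%s': %s", path,
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  vals <- vapply(body, function(row) {
    v <- suppressWarnings(as.numeric(row[-1]))
    v
  }, numeric(length(sample_ids)))
  mat <- if (length(sample_ids) == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1L, any))[1]
    stopf("non-numeric or missing cell at line %d of '%s' (gene %s)",
          bad_row + 1L, path, gene_ids[bad_row])
  }
  dimnames(mat) <- list(gene_ids, sample_ids)
  validate_expression(mat)
  mat
}

#' @param matrix numeric matrix with gene rownames and sample colnames.
#' @rdname read_expression
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix)
  header <- paste(c("gene", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i],
            format(matrix[i, ], digits = 15, scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

validate_expression <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stopf("expression matrix must carry gene rownames and sample colnames")
  }
  if (ncol(mat) < 2) stopf("expression matrix needs at least 2 samples")
  if (anyDuplicated(rownames(mat))) stopf("duplicate gene IDs in expression matrix")
  if (anyDuplicated(colnames(mat))) stopf("duplicate sample IDs in expression matrix")
  if (!all(is.finite(mat))) stopf("expression matrix contains non-finite values")
  invisible(mat)
}

#' Read and write per-sample metadata tables
#'
#' The sample table carries, per sample: cohort (`phenotype` or `development`),
#' genotype, developmental stage and age, treatment (`HGP`, `control`, `none`),
#' site, and the optional phenotypes ADG/kg liveweight (1/day) and intramuscular
#' fat percent.
#'
#' @param path path to a CSV file with a `sample_id` column.
#' @return A data.frame, one row per sample.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stopf("sample table '%s' lacks a sample_id column", path)
  if (anyDuplicated(tab$sample_id)) stopf("duplicate sample_id in '%s'", path)
  tab
}

#' @param table a sample data.frame.
#' @rdname read_sample_table
#' @export
write_sample_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set annotation file
#'
#' Standard GMT: one term per line, fields tab-separated — term ID, description,
#' then member genes. Members outside `universe` are dropped (with a message of
#' the dropped count); terms empty after filtering are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @param universe character vector of admissible gene IDs, or `NULL` to keep
#'   all members.
#' @return A named list of character vectors (members), with a `names` attribute
#'   per term stored as the `descriptions` attribute.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stopf("GMT line %d of '%s' has fewer than 3 fields", short[1], path)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  names(descs) <- ids
  if (!is.null(universe)) {
    n_before <- sum(lengths(members))
    members <- lapply(members, function(m) m[m %in% universe])
    dropped <- n_before - sum(lengths(members))
    if (dropped > 0) {
      message(sprintf("read_gmt: dropped %d gene(s) outside the universe", dropped))
    }
    empty <- lengths(members) == 0
    if (any(empty)) {
      warnf("read_gmt: dropped %d term(s) empty after universe filtering: %s",
            sum(empty), paste(ids[empty], collapse = ", "))
      members <- members[!empty]
      descs <- descs[!empty]
    }
  }
  structure(members, descriptions = descs, class = "gene_annotation")
}

#' @param annotation a named list of member-gene vectors (as from [read_gmt()]).
#' @rdname read_gmt
#' @export
write_gmt <- function(annotation, path) {
  descs <- attr(annotation, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(names(annotation), names(annotation))
  lines <- vapply(names(annotation), function(id) {
    paste(c(id, descs[[id]], annotation[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read the muscle cell-type marker table
#'
#' Parses a CSV of published marker genes for the major cellular components of
#' skeletal muscle (pericytes, satellite cells, endothelial cells,
#' fibro/adipogenic progenitors, preadipocytes, adipocytes, fibroblasts, ...).
#' Columns: `gene`, `cell_type`, `sign` (one of `+`, `-`, `+?`, `?`), `source`.
#' A transcription of this table for cattle longissimus muscle ships with the
#' package at `system.file("extdata", "muscle_cell_markers.csv", package =
#' "growthsets")`.
#'
#' @param path path to a marker CSV.
#' @return A data.frame with one row per (gene, cell type) report.
#' @export
read_marker_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "cell_type", "sign")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("marker table '%s' lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (anyDuplicated(tab[c("gene", "cell_type")])) {
    stopf("marker table '%s' has duplicate (gene, cell_type) rows", path)
  }
  bad <- setdiff(unique(tab$sign), c("+", "-", "+?", "?"))
  if (length(bad)) stopf("marker table '%s' has invalid sign value(s): %s", path,
                         paste(bad, collapse = ", "))
  tab
}

#' Validate an expression matrix against its sample table
#'
#' Report-only consistency check: sample ID agreement (presence and order),
#' presence of the phenotype required for the requested analysis, and stage
#' vocabulary. Never mutates or errors; all violations are listed.
#'
#' @param matrix expression matrix.
#' @param table sample table.
#' @param require_phenotype optional column name (e.g. `"adg_per_kg"`) that must
#'   be present and complete.
#' @param stage_levels optional ordered vocabulary the `stage` column must be
#'   drawn from.
#' @return Character vector of violation messages; empty when the cohort is
#'   consistent.
#' @export
validate_cohort <- function(matrix, table, require_phenotype = NULL,
                            stage_levels = NULL) {
  violations <- character(0)
  mat_ids <- colnames(matrix)
  tab_ids <- table$sample_id
  if (!setequal(mat_ids, tab_ids)) {
    only_m <- setdiff(mat_ids, tab_ids)
    only_t <- setdiff(tab_ids, mat_ids)
    if (length(only_m)) {
      violations <- c(violations, sprintf(
        "samples in matrix but not table: %s", paste(only_m, collapse = ", ")))
    }
    if (length(only_t)) {
      violations <- c(violations, sprintf(
        "samples in table but not matrix: %s", paste(only_t, collapse = ", ")))
    }
  } else if (!identical(mat_ids, tab_ids)) {
    violations <- c(violations, "sample order differs between matrix and table")
  }
  if (!is.null(require_phenotype)) {
    if (!require_phenotype %in% names(table)) {
      violations <- c(violations,
                      sprintf("required phenotype column '%s' missing", require_phenotype))
    } else if (anyNA(table[[require_phenotype]])) {
      violations <- c(violations,
                      sprintf("required phenotype '%s' has missing values", require_phenotype))
    }
  }
  if (!is.null(stage_levels) && "stage" %in% names(table)) {
    bad <- setdiff(unique(table$stage), stage_levels)
    if (length(bad)) {
      violations <- c(violations, sprintf(
        "stage label(s) outside the declared vocabulary: %s", paste(bad, collapse = ", ")))
    }
  }
  violations
}
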