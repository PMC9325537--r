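# Reading, validation and writing of count matrices and sample designs.
# Counts travel as a plain integer matrix (genes x samples, dimnames set);
# designs as a data.frame keyed by sample_id.

DESIGN_REQUIRED <- c("sample_id", "genotype", "environment", "batch")
DESIGN_OPTIONAL <- c("upper_genotype", "replicate_unit", "snp_group", "sv_group")

#' Read a gene-by-sample count matrix
#'
#' Expects a tab-separated table with a header row; the first column holds gene
#' identifiers and the remaining columns one sample each. Counts must be
#' nonnegative integers. Validation failures raise conditions of class
#' `grn_validation_error` naming the offending gene/sample.
#'
#' @param path Path to a tab-separated counts file.
#' @return Integer matrix, genes in rows, samples in columns.
#' @seealso [read_design()], [write_counts()], [normalize_counts()]
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) grn_stop("counts file needs a gene-id column plus >=1 sample column")
  gene_ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    grn_stop("count matrix must carry gene (row) and sample (column) identifiers")
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g)) grn_stop(sprintf("duplicate gene identifiers: %s",
                                      paste(utils::head(dup_g, 5), collapse = ", ")))
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s)) grn_stop(sprintf("duplicate sample identifiers: %s",
                                      paste(utils::head(dup_s, 5), collapse = ", ")))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    grn_stop(sprintf("missing count for gene '%s', sample '%s'",
                     rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    grn_stop(sprintf(
      "counts must be nonnegative integers; offending entry gene '%s', sample '%s' (value %g)",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], m[bad[1L, , drop = FALSE]]
    ))
  }
  invisible(m)
}

#' @rdname read_counts
#' @param counts Integer count matrix with gene/sample dimnames.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample design table
#'
#' The design is a tab-separated table with required columns `sample_id`,
#' `genotype`, `environment` (numeric) and `batch`, optional columns
#' `upper_genotype`, `replicate_unit`, `snp_group`, `sv_group`, and any number
#' of numeric fitness phenotypes in columns prefixed `fitness_`. Any other
#' column name is rejected.
#'
#' @param path Path to a tab-separated design file.
#' @return A validated `data.frame`, one row per sample.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_design_table(df)
}

validate_design_table <- function(df) {
  missing <- setdiff(DESIGN_REQUIRED, names(df))
  if (length(missing)) grn_stop(sprintf("design is missing required column(s): %s",
                                        paste(missing, collapse = ", ")))
  known <- c(DESIGN_REQUIRED, DESIGN_OPTIONAL)
  unknown <- setdiff(names(df), c(known, grep("^fitness_", names(df), value = TRUE)))
  if (length(unknown)) grn_stop(sprintf("unknown design column(s): %s",
                                        paste(unknown, collapse = ", ")))
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) grn_stop(sprintf("duplicate sample_id in design: %s",
                                    paste(dup, collapse = ", ")))
  env <- suppressWarnings(as.numeric(df$environment))
  if (anyNA(env)) grn_stop("design column 'environment' must be numeric")
  df$environment <- env
  for (col in intersect(c("genotype", "batch", "upper_genotype", "replicate_unit",
                          "snp_group", "sv_group"), names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in grep("^fitness_", names(df), value = TRUE)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (all(is.na(v)) && !all(is.na(df[[col]]))) {
      grn_stop(sprintf("fitness column '%s' must be numeric", col))
    }
    df[[col]] <- v
  }
  df
}

#' @rdname read_design
#' @param design Design data frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a count matrix with a sample design
#'
#' Samples are matched by identifier, never by position. Errors list unmatched
#' sample ids from either side.
#'
#' @param counts Count matrix (columns = samples).
#' @param design Design data frame with a `sample_id` column.
#' @return The design reordered to match the count-matrix columns.
#' @export
align_design <- function(counts, design) {
  unmatched <- setdiff(colnames(counts), design$sample_id)
  if (length(unmatched)) {
    grn_stop(sprintf("samples present in counts but absent from design: %s",
                     paste(unmatched, collapse = ", ")))
  }
  extra <- setdiff(design$sample_id, colnames(counts))
  if (length(extra)) {
    grn_stop(sprintf("samples present in design but absent from counts: %s",
                     paste(extra, collapse = ", ")))
  }
  out <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read counts stored as a MatrixMarket triplet plus identifier files
#'
#' Convenience reader for large sparse inputs: an `.mtx` triplet file with
#' companion one-column text files listing gene and sample identifiers.
#' Requires the Matrix package.
#'
#' @param mtx_path Path to the MatrixMarket file.
#' @param genes_path,samples_path One identifier per line, in matrix order.
#' @return Dense integer count matrix.
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    grn_stop("the Matrix package is required for MTX input", class = "grn_dependency_error")
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}
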