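#' Size-factor normalization and log2 counts-per-million
#'
#' Computes median-of-ratios size factors: each sample's factor is the median,
#' over reference genes (genes with no zero count in any sample), of the ratio
#' between its count and the gene's geometric mean across samples. Factors are
#' rescaled to geometric mean 1. Normalized expression is log2 counts-per-million
#' after size-factor correction, with a pseudocount added on the count scale:
#' `log2((count/sf + pseudocount) / L * 1e6)` where `L` is the mean
#' size-corrected library size.
#'
#' If no gene is free of zeros the function falls back to total-count size
#' factors with a warning of class `grn_norm_fallback`.
#'
#' @param counts Integer count matrix (genes x samples) as from [read_counts()].
#' @param pseudocount Count-scale offset stabilizing low counts; default 0.5.
#' @return An object of class `grn_norm`: list with `values` (log2 matrix, same
#'   dimnames as `counts`), `size_factors`, `lib_scale` (the mean corrected
#'   library size) and `pseudocount`.
#' @examples
#' counts <- matrix(rpois(60, 50), 10, 6,
#'                  dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' nm <- normalize_counts(counts)
#' range(nm$size_factors)
#' @export
normalize_counts <- function(counts, pseudocount = 0.5) {
  validate_counts(counts)
  if (pseudocount <= 0) grn_stop("pseudocount must be positive")
  m <- counts
  storage.mode(m) <- "double"
  if (!any(colSums(m) > 0)) grn_stop("all samples have zero total counts")

  ref <- rowSums(m == 0) == 0L
  if (any(ref)) {
    lg <- log(m[ref, , drop = FALSE])
    geo <- exp(rowMeans(lg))
    ratios <- m[ref, , drop = FALSE] / geo
    sf <- apply(ratios, 2L, stats::median)
  } else {
    grn_warn("no zero-free reference genes; falling back to total-count size factors",
             class = "grn_norm_fallback")
    sf <- colSums(m)
  }
  if (any(sf <= 0)) grn_stop("nonpositive size factor; check for empty samples")
  sf <- sf / exp(mean(log(sf)))

  corrected <- sweep(m, 2L, sf, "/")
  lib_scale <- mean(colSums(corrected))
  values <- log2((corrected + pseudocount) / lib_scale * 1e6)

  structure(
    list(values = values, size_factors = stats::setNames(sf, colnames(m)),
         lib_scale = lib_scale, pseudocount = pseudocount),
    class = "grn_norm"
  )
}

#' @export
print.grn_norm <- function(x, ...) {
  cat(sprintf("Normalized expression (log2 CPM): %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("size factors: %.3f - %.3f (geometric mean 1)\n",
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

#' PCA sanity plot of normalized samples
#'
#' First two principal components of the samples (genes as variables),
#' optionally coloured by a design factor — a quick check for batch artifacts
#' or swapped samples before any model fitting.
#'
#' @param x A `grn_norm` object.
#' @param design Optional design data frame (see [read_design()]).
#' @param colour_by Design column used for colouring (default `"genotype"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grn_norm <- function(x, design = NULL, colour_by = "genotype", ...) {
  keep <- apply(x$values, 1L, stats::var) > 1e-12
  pc <- stats::prcomp(t(x$values[keep, , drop = FALSE]), center = TRUE)
  pct <- 100 * pc$sdev[1:2]^2 / sum(pc$sdev^2)
  col <- 1
  if (!is.null(design) && colour_by %in% names(design)) {
    design <- align_design(x$values, design)
    f <- factor(design[[colour_by]])
    col <- grDevices::hcl.colors(max(3L, nlevels(f)), "Dark 3")[as.integer(f)]
  }
  graphics::plot(pc$x[, 1L], pc$x[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", pct[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", pct[2L]), ...)
  invisible(pc)
}

#' Write a normalized matrix in the counts-table dialect
#' @param norm A `grn_norm` object.
#' @param path Output path (tab-separated).
#' @export
write_normalized <- function(norm, path) {
  df <- data.frame(gene_id = rownames(norm$values), norm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Accept either a grn_norm or a bare log2 matrix wherever expression goes in.
as_norm_values <- function(object) {
  if (inherits(object, "grn_norm")) return(object$values)
  if (is.matrix(object)) {
    if (is.null(rownames(object))) rownames(object) <- paste0("gene", seq_len(nrow(object)))
    return(object)
  }
  grn_stop("expected a grn_norm object or a numeric matrix of log2 expression")
}
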