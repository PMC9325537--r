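# S3 methods for the fitted-model object.

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("Per-gene reaction-norm fit (%s model, %s environment coding)\n",
              x$spec$model, x$spec$env_coding))
  cat(sprintf("%d genes x %d samples; reference genotype '%s', reference environment %g\n",
              nrow(x$coefficients), nrow(x$design), x$reference_genotype, x$reference_env))
  cat(sprintf("residual df %d; %d flagged gene(s)", x$df_residual, sum(x$flagged)))
  if (length(x$aliased_terms)) {
    cat(sprintf("; aliased term(s): %s", paste(x$aliased_terms, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Summary of a per-gene reaction-norm fit
#'
#' @param object A `grn_fit` object.
#' @param alpha FDR threshold for the per-term significant-gene counts.
#' @param ... Unused.
#' @return Object of class `summary.grn_fit`: per-term counts of genes with
#'   q-value below `alpha`, plus fit dimensions.
#' @export
summary.grn_fit <- function(object, alpha = object$spec$alpha, ...) {
  counts <- vapply(object$tests, function(tt) sum(tt$q < alpha, na.rm = TRUE), integer(1))
  structure(
    list(term_counts = counts, alpha = alpha,
         n_genes = nrow(object$coefficients), n_samples = nrow(object$design),
         flagged = sum(object$flagged), aliased_terms = object$aliased_terms,
         model = object$spec$model),
    class = "summary.grn_fit"
  )
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  cat(sprintf("Reaction-norm fit (%s model): %d genes, %d samples\n",
              x$model, x$n_genes, x$n_samples))
  cat(sprintf("genes with term q < %g:\n", x$alpha))
  print(x$term_counts)
  if (x$flagged) cat(sprintf("%d gene(s) with undefined (constant) fits\n", x$flagged))
  if (length(x$aliased_terms)) {
    cat("aliased terms:", paste(x$aliased_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.grn_fit <- function(object, ...) object$coefficients

#' @export
fitted.grn_fit <- function(object, ...) object$fitted

#' @export
residuals.grn_fit <- function(object, ...) object$values - object$fitted

#' Predict expression at new design points
#'
#' Evaluates the fitted per-gene models on a new design (same factor levels;
#' aliased coefficients are treated as zero, matching the fitted values).
#'
#' @param object A `grn_fit` object.
#' @param newdata Design data frame with the columns the model was fitted on;
#'   defaults to the training design.
#' @param ... Unused.
#' @return Matrix of predicted log2 expression, genes x new samples.
#' @export
predict.grn_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- validate_design_table(newdata)
  bl <- build_blocks_like(object, newdata)
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(newdata))), bl))
  co <- object$coefficients
  co[is.na(co)] <- 0
  common <- intersect(colnames(X), colnames(co))
  if (!setequal(colnames(X), colnames(co))) {
    grn_stop("newdata produces a different model matrix (unseen factor levels?)")
  }
  out <- co[, common, drop = FALSE] %*% t(X[, common, drop = FALSE])
  colnames(out) <- newdata$sample_id
  out
}

# Rebuild the fitted model's blocks on new data, reusing stored references.
build_blocks_like <- function(fit, newdata) {
  spec <- fit$spec
  spec$reference_genotype <- fit$reference_genotype
  spec$reference_env <- fit$reference_env
  build_blocks(newdata, spec)$blocks
}

#' Simulate normalized-expression matrices from a fitted model
#'
#' Draws Gaussian residuals around the fitted values, gene by gene, with each
#' gene's estimated residual variance — a parametric-bootstrap generator on
#' the normalized (log2) scale.
#'
#' @param object A `grn_fit` object.
#' @param nsim Number of replicate matrices.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` matrices shaped like the input expression.
#' @export
simulate.grn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  gen <- function() {
    noise <- matrix(stats::rnorm(length(object$fitted), sd = sqrt(object$sigma2)),
                    nrow = nrow(object$fitted))
    object$fitted + noise
  }
  if (!is.null(seed)) with_seed(seed, replicate(nsim, gen(), simplify = FALSE))
  else replicate(nsim, gen(), simplify = FALSE)
}

#' Plot a gene's reaction norms
#'
#' Normalized expression against the environment, one colour per genotype,
#' with the fitted reaction-norm lines overlaid.
#'
#' @param x A `grn_fit` object.
#' @param gene Gene identifier (or row index).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grn_fit <- function(x, gene = 1L, ...) {
  if (is.numeric(gene)) gene <- rownames(x$values)[gene]
  y <- x$values[gene, ]
  env <- x$design$environment
  genos <- x$genotype_levels
  cols <- grDevices::hcl.colors(max(3L, length(genos)), "Dark 3")[seq_along(genos)]
  gi <- match(x$design$genotype, genos)
  graphics::plot(env, y, col = cols[gi], pch = 19,
                 xlab = "environment", ylab = "log2 normalized expression",
                 main = gene, ...)
  rns <- build_reaction_norms(x)
  if (!(gene %in% rownames(rns$slope))) return(invisible(x))
  ee <- seq(min(env), max(env), length.out = 50L)
  vals <- eval_norms(rns, gene, ee)
  for (k in seq_along(genos)) graphics::lines(ee, vals[, k], col = cols[k], lwd = 2)
  graphics::legend("topleft", legend = genos, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' @export
print.grn_rns <- function(x, ...) {
  cat(sprintf("Reaction norms: %d genes x %d genotypes over environment [%g, %g]\n",
              nrow(x$slope), ncol(x$slope), x$env_range[1L], x$env_range[2L]))
  cat(sprintf("reference genotype '%s' at environment %g\n",
              x$reference_genotype, x$reference_env))
  if (length(x$omitted)) cat(sprintf("%d gene(s) omitted (undefined fit)\n",
                                     length(x$omitted)))
  invisible(x)
}

#' @export
print.grn_findings <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("design check: no findings\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("[%s] %s: %s\n", x$level[i], x$field[i], x$message[i]))
    }
  }
  invisible(x)
}

#' Flatten a fit into the per-gene result table
#'
#' One row per gene with coefficient estimate/SE pairs, per-term F/p/q triples
#' and the degenerate-fit flag — the tab-separated export format.
#'
#' @param x A `grn_fit` object.
#' @param ... Unused.
#' @export
as.data.frame.grn_fit <- function(x, ...) {
  co <- x$coefficients; se <- x$se
  out <- data.frame(gene_id = rownames(co), stringsAsFactors = FALSE)
  for (j in colnames(co)) {
    nm <- gsub("[^A-Za-z0-9_]", "_", j)
    out[[paste0("est_", nm)]] <- co[, j]
    out[[paste0("se_", nm)]] <- se[, j]
  }
  for (tm in names(x$tests)) {
    out[[paste0("F_", tm)]] <- x$tests[[tm]]$F
    out[[paste0("p_", tm)]] <- x$tests[[tm]]$p
    out[[paste0("q_", tm)]] <- x$tests[[tm]]$q
  }
  out$flagged <- x$flagged
  rownames(out) <- NULL
  out
}

#' Write the per-gene fit table
#' @param fit A `grn_fit` object.
#' @param path Output path (tab-separated).
#' @export
write_fit_table <- function(fit, path) {
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
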