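# Dimension-reduced and fitness-linked follow-up analyses: co-expression
# module summaries that can be refit as reaction norms, and expression-fitness
# correlation with permutation inference at the genotype-unit level.

#' Summarize co-expression modules
#'
#' Clusters genes by average-linkage hierarchical clustering on the
#' correlation distance (1 - Pearson r) and cuts the tree into `k` modules.
#' Each module is summarized by the first principal-component score of its
#' genes' standardized expression (an eigengene), sign-oriented so that the
#' mean gene loading is nonnegative. Zero-variance genes go to an explicit
#' `"unassigned"` bucket. This is a deliberately simple stand-in for full
#' weighted co-expression network analysis: module summaries here exist to be
#' refit through [grn_fit()] as module-level reaction norms, not to describe
#' network topology.
#'
#' @param object A `grn_norm` object or log2 expression matrix.
#' @param k Number of modules (>= 2, < number of variable genes).
#' @param seed Accepted for interface uniformity; the procedure is
#'   deterministic.
#' @return Object of class `grn_modules`: `assignment` (named character,
#'   gene -> module id or "unassigned"), `summaries` (modules x samples score
#'   matrix, zero mean per module), `loadings` and `sizes`.
#' @examples
#' sim <- simulate_grn(grn_sim_config(n_genes = 30, seed = 4))
#' mods <- summarize_modules(normalize_counts(sim$counts), k = 3)
#' mods$sizes
#' @export
summarize_modules <- function(object, k, seed = 1L) {
  X <- as_norm_values(object)
  if (k <= 1L) grn_stop("k must be >= 2")
  v <- apply(X, 1L, stats::var)
  variable <- v > 1e-12
  if (sum(variable) <= k) grn_stop("k must be smaller than the number of variable genes")
  Xv <- X[variable, , drop = FALSE]

  d <- stats::as.dist(1 - stats::cor(t(Xv)))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  assignment <- stats::setNames(rep("unassigned", nrow(X)), rownames(X))
  assignment[rownames(Xv)] <- paste0("M", cl)

  Z <- t(scale(t(Xv)))   # standardized gene profiles
  summaries <- matrix(0, k, ncol(X), dimnames = list(paste0("M", seq_len(k)), colnames(X)))
  loadings <- vector("list", k)
  names(loadings) <- rownames(summaries)
  for (m in seq_len(k)) {
    Zm <- Z[cl == m, , drop = FALSE]
    pc <- stats::prcomp(t(Zm), center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1L]
    ld <- pc$rotation[, 1L]
    if (mean(ld) < 0) { sc <- -sc; ld <- -ld }
    summaries[m, ] <- sc
    loadings[[m]] <- stats::setNames(ld, rownames(Zm))
  }
  structure(
    list(assignment = assignment, summaries = summaries, loadings = loadings,
         sizes = stats::setNames(tabulate(cl, k), rownames(summaries))),
    class = "grn_modules"
  )
}

#' @export
print.grn_modules <- function(x, ...) {
  cat(sprintf("%d co-expression modules over %d samples\n",
              nrow(x$summaries), ncol(x$summaries)))
  print(x$sizes)
  un <- sum(x$assignment == "unassigned")
  if (un) cat(sprintf("(%d zero-variance gene(s) unassigned)\n", un))
  invisible(x)
}

#' Correlate an expression feature with fitness across genotype units
#'
#' Pearson correlation between a per-genotype-unit expression feature (mean
#' expression, reaction-norm slope, or DP magnitude) and a fitness phenotype,
#' with a permutation null built by shuffling the fitness labels. The p-value
#' is `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param feature Named numeric vector, one value per genotype unit.
#' @param fitness Named numeric vector over the same units.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for the permutation stream.
#' @param feature_id Optional identifier recorded in the output.
#' @param statistic Label for the feature statistic used.
#' @return One-row data frame: `feature_id`, `statistic`, `n_units`,
#'   `correlation`, `p_value`, `n_perm`. A constant feature or fitness vector
#'   yields `NA` correlation and p-value.
#' @export
correlate_fitness <- function(feature, fitness, n_perm = 1000L, seed = 1L,
                              feature_id = NA_character_,
                              statistic = "mean") {
  if (!is.null(names(feature)) && !is.null(names(fitness))) {
    units <- intersect(names(feature), names(fitness))
    feature <- feature[units]; fitness <- fitness[units]
  }
  ok <- stats::complete.cases(feature, fitness)
  feature <- feature[ok]; fitness <- fitness[ok]
  n <- length(feature)
  if (n < 3L) grn_stop("need >=3 genotype units with both feature and fitness values")
  out <- data.frame(feature_id = feature_id, statistic = statistic,
                    n_units = n, correlation = NA_real_, p_value = NA_real_,
                    n_perm = as.integer(n_perm), stringsAsFactors = FALSE)
  if (stats::sd(feature) < 1e-12 || stats::sd(fitness) < 1e-12) {
    return(out)  # correlation undefined; reported as NA
  }
  r_obs <- stats::cor(feature, fitness)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stats::cor(feature, sample(fitness)),
           numeric(1))
  })
  out$correlation <- r_obs
  out$p_value <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
  out
}

#' Per-genotype reaction-norm features for fitness analysis
#'
#' Extracts, for one gene (or module refit), the per-genotype feature to
#' correlate with fitness: environment-averaged mean expression, reaction-norm
#' slope, or DP magnitude (absolute slope difference from the reference
#' genotype).
#'
#' @param rns A `grn_rns` object.
#' @param gene Gene identifier.
#' @param what `"mean"`, `"slope"` or `"dp"`.
#' @return Named numeric vector over genotypes.
#' @export
reaction_norm_features <- function(rns, gene, what = c("mean", "slope", "dp")) {
  what <- match.arg(what)
  switch(what,
    mean = genotype_means(rns, gene),
    slope = rns$avg_slope[gene, ],
    dp = abs(rns$avg_slope[gene, ] - rns$avg_slope[gene, rns$reference_genotype])
  )
}
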