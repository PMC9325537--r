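# From per-gene fits to reaction norms, DE/DP directions and magnitudes under
# the model-intercept convention, the twelve-category classification, and the
# evolutionary-pattern sub-labels (genetic compensation, genetic assimilation,
# reversal).

#' Per-genotype reaction norms from a fitted model
#'
#' The reference genotype's intercept (log2 expression at the reference
#' environment) and slope are read directly from the coefficients; every other
#' genotype adds its offset terms. With quadratic environment coding a
#' curvature term is carried along, and an `avg_slope` (the chord slope over
#' the observed environment range) is provided for direction/DP summaries.
#' Only available for numeric environment codings.
#'
#' @param fit A [grn_fit()] object fitted with the basic model.
#' @return Object of class `grn_rns`: matrices `intercept`, `slope`
#'   (genes x genotypes; plus `curvature`, `avg_slope` if quadratic), the
#'   environment range, reference genotype/environment, and ids of genes
#'   omitted because their fit was undefined.
#' @export
build_reaction_norms <- function(fit) {
  stopifnot(inherits(fit, "grn_fit"))
  if (fit$spec$model != "basic") {
    grn_stop("reaction norms are built from the basic model; refit with model = 'basic'")
  }
  if (fit$spec$env_coding == "categorical") {
    grn_stop("reaction norms require a numeric environment coding (linear or quadratic)")
  }
  genos <- fit$genotype_levels            # reference first
  co <- fit$coefficients
  G <- length(genos)
  ngene <- nrow(co)

  intercept <- matrix(co[, "(Intercept)"], ngene, G)
  slope <- matrix(co[, "env"], ngene, G)
  quad <- fit$spec$env_coding == "quadratic"
  curvature <- if (quad) matrix(co[, "env2"], ngene, G) else NULL
  for (k in seq_len(G)[-1L]) {
    g <- genos[k]
    intercept[, k] <- intercept[, k] + co[, paste0("genotype", g)]
    slope[, k] <- slope[, k] + co[, paste0("genotype", g, ":env")]
    if (quad) curvature[, k] <- curvature[, k] + co[, paste0("genotype", g, ":env2")]
  }
  dimnames(intercept) <- dimnames(slope) <- list(rownames(co), genos)
  if (quad) dimnames(curvature) <- dimnames(intercept)

  omit <- fit$flagged | apply(is.na(intercept) | is.na(slope), 1L, any)
  if (any(omit)) {
    message(sprintf("omitting %d gene(s) with undefined fits from reaction norms",
                    sum(omit)))
  }
  rng <- fit$env_range - fit$reference_env   # centered observed range
  avg_slope <- if (quad) slope + curvature * (rng[1L] + rng[2L]) else slope

  structure(
    list(intercept = intercept[!omit, , drop = FALSE],
         slope = slope[!omit, , drop = FALSE],
         curvature = if (quad) curvature[!omit, , drop = FALSE] else NULL,
         avg_slope = avg_slope[!omit, , drop = FALSE],
         env_range = fit$env_range, reference_env = fit$reference_env,
         reference_genotype = fit$reference_genotype,
         env_col_means = fit$env_col_means,
         omitted = rownames(co)[omit]),
    class = "grn_rns"
  )
}

# Evaluate reaction norms at (uncentered) environment values.
eval_norms <- function(rns, gene, env) {
  ec <- env - rns$reference_env
  v <- outer(rep(1, length(env)), rns$intercept[gene, ]) +
    outer(ec, rns$slope[gene, ])
  if (!is.null(rns$curvature)) v <- v + outer(ec^2, rns$curvature[gene, ])
  rownames(v) <- as.character(env)
  v
}

# Environment-averaged mean expression per genotype, consistent with the
# centering used by the genotype main-effect test.
genotype_means <- function(rns, gene) {
  m <- rns$intercept[gene, ] + rns$slope[gene, ] * rns$env_col_means[["env"]]
  if (!is.null(rns$curvature)) {
    m <- m + rns$curvature[gene, ] * rns$env_col_means[["env2"]]
  }
  m
}

#' Direction and magnitude of differential expression and plasticity
#'
#' For a pair of genotypes under the model-intercept convention: differential
#' expression (DE) is the comparison genotype's environment-averaged mean
#' expression minus the reference's; differential plasticity (DP) is the
#' comparison slope minus the reference slope. Directions are signs,
#' magnitudes absolute values. With opposite-sign equal slopes +s/-s the DP
#' magnitude is 2s (twice each slope's magnitude); with same-sign slopes it is
#' the difference between the slope magnitudes.
#'
#' @param rns A `grn_rns` object from [build_reaction_norms()].
#' @param gene Gene identifier (or row index).
#' @param reference Reference ("model intercept") genotype; defaults to the
#'   fit's reference genotype.
#' @param comparison Comparison genotype; defaults to the first non-reference
#'   genotype.
#' @return List with `de_magnitude`, `de_direction`, `dp_magnitude`,
#'   `dp_direction` (`"+"`, `"-"` or `"none"`).
#' @export
compute_de_dp <- function(rns, gene, reference = rns$reference_genotype,
                          comparison = NULL) {
  stopifnot(inherits(rns, "grn_rns"))
  genos <- colnames(rns$slope)
  if (!(reference %in% genos)) {
    grn_stop(sprintf("reference genotype '%s' absent from reaction norms", reference))
  }
  comparison <- comparison %||% setdiff(genos, reference)[1L]
  if (is.na(comparison) || !(comparison %in% genos)) {
    grn_stop("comparison genotype absent from reaction norms")
  }
  means <- genotype_means(rns, gene)
  de <- means[[comparison]] - means[[reference]]
  dp <- rns$avg_slope[gene, comparison] - rns$avg_slope[gene, reference]
  list(de_magnitude = abs(de), de_direction = sign_chr(de),
       dp_magnitude = abs(dp), dp_direction = sign_chr(dp))
}

#' Assign one of the twelve expression-pattern categories
#'
#' The category is the cell of the grid {DE no/yes} x {DP no/yes} x
#' {mean environmental direction up/down/none}. The direction is the sign of
#' the across-genotype mean slope when the environment term is significant, or
#' when the gene is differentially plastic and its mean slope is nonzero
#' beyond a tolerance; otherwise `"none"`. At fitted (noisy) coefficients that
#' tolerance is taken as twice the mean slope's standard error, so genotypes
#' whose responses cancel are not handed a spurious direction.
#'
#' @param de_flag,dp_flag,e_flag Logical significance flags for the genotype,
#'   interaction and environment terms.
#' @param mean_slope Across-genotype mean slope.
#' @param mean_slope_se Standard error of `mean_slope` (0 for noise-free use).
#' @param tol Numeric floor below which a slope is treated as zero.
#' @return Category label (see [grn_categories()]); vectorized over genes.
#' @export
classify_gene <- function(de_flag, dp_flag, e_flag, mean_slope,
                          mean_slope_se = 0, tol = 1e-8) {
  n <- max(length(de_flag), length(dp_flag), length(e_flag), length(mean_slope))
  de_flag <- rep_len(de_flag, n); dp_flag <- rep_len(dp_flag, n)
  e_flag <- rep_len(e_flag, n); mean_slope <- rep_len(mean_slope, n)
  mean_slope_se <- rep_len(mean_slope_se, n)
  thr <- pmax(2 * mean_slope_se, tol)
  has_dir <- (e_flag & abs(mean_slope) > tol) | (dp_flag & abs(mean_slope) > thr)
  dir <- ifelse(!has_dir, "none", ifelse(mean_slope > 0, "up", "down"))
  category_label(de_flag, dp_flag, dir)
}

#' Evolutionary pattern of a differentially plastic gene pair
#'
#' Compares a derived genotype's reaction norm against a designated
#' ancestral-proxy genotype. *Reversal*: the two slopes have strictly opposite
#' signs (both non-negligible). *Genetic assimilation*: the derived genotype
#' has lost the plastic response (near-zero slope) and constitutively
#' expresses the level the ancestral norm reaches at the derived-environment
#' end of the gradient. *Genetic compensation*: the derived genotype has lost
#' the response but holds the ancestral level at the ancestral-environment end
#' (its intercept offset opposes the plastic direction). Anything else is
#' `"none"`.
#'
#' These quantitative rules are this package's operationalization of
#' qualitative concepts; the tolerance `tau` (log2 units) defaults to 25% of
#' the ancestral plastic change over the observed range, and slopes are
#' compared against `tau / range`.
#'
#' @param ancestral,derived Numeric `c(intercept, slope)` pairs, intercepts at
#'   the low-environment end.
#' @param env_range Observed environment range `c(lo, hi)`.
#' @param tau Expression-scale tolerance; default
#'   `0.25 * |ancestral slope| * (hi - lo)`.
#' @return One of `"reversal"`, `"assimilation"`, `"compensation"`, `"none"`.
#' @examples
#' classify_evo_pattern(c(5, 1), c(6, 0), c(0, 1))  # assimilation
#' classify_evo_pattern(c(5, 1), c(5, 0), c(0, 1))  # compensation
#' classify_evo_pattern(c(5, 1), c(6, -1), c(0, 1)) # reversal
#' @export
classify_evo_pattern <- function(ancestral, derived, env_range, tau = NULL) {
  rng <- diff(range(env_range))
  if (rng <= 0) grn_stop("env_range must span a positive interval")
  a_A <- ancestral[[1L]]; s_A <- ancestral[[2L]]
  a_D <- derived[[1L]]; s_D <- derived[[2L]]
  tau <- tau %||% (0.25 * abs(s_A) * rng)
  if (tau <= 0) return("none")
  slope_tol <- tau / rng
  if (sign(s_A) * sign(s_D) < 0 && abs(s_A) > slope_tol && abs(s_D) > slope_tol) {
    return("reversal")
  }
  if (abs(s_D) < slope_tol) {
    m_D <- a_D + s_D * rng / 2               # derived (near-flat) mean level
    d_assim <- abs(m_D - (a_A + s_A * rng))  # ancestral norm, derived end
    d_comp <- abs(m_D - a_A)                 # ancestral norm, ancestral end
    if (d_assim < tau || d_comp < tau) {
      if (d_assim < d_comp) return("assimilation")
      if (d_comp < d_assim) return("compensation")
      return("none")
    }
  }
  "none"
}

#' Classify every gene of a fitted model
#'
#' Combines significance flags (term q-values below `alpha`), reaction-norm
#' directions and magnitudes into the per-gene category table. DE/DP
#' directions and magnitudes are averages of the pairwise comparisons of each
#' non-reference genotype against the reference (for two genotypes this is
#' exactly the pairwise definition). When `ancestral` is given, differentially
#' plastic genes additionally receive an evolutionary-pattern label computed
#' against the derived genotype.
#'
#' @param fit A [grn_fit()] object (basic model, numeric environment coding).
#' @param alpha FDR threshold for the significance flags; defaults to the
#'   model spec's alpha.
#' @param ancestral Optional genotype label serving as ancestral proxy.
#' @param derived Optional derived genotype; defaults to the single other
#'   genotype in two-genotype designs.
#' @param tau Tolerance passed to [classify_evo_pattern()].
#' @return Data frame of class `grn_categories`, one row per classified gene:
#'   flags, directions, magnitudes, `category` and (if requested)
#'   `evo_pattern`. Genes with undefined fits are omitted.
#' @export
grn_classify <- function(fit, alpha = NULL, ancestral = NULL, derived = NULL,
                         tau = NULL) {
  stopifnot(inherits(fit, "grn_fit"))
  alpha <- alpha %||% fit$spec$alpha
  rns <- build_reaction_norms(fit)
  genes <- rownames(rns$slope)
  keep <- genes
  qde <- fit$tests$G[keep, "q"]
  qe <- fit$tests$E[keep, "q"]
  qdp <- fit$tests$GxE[keep, "q"]
  de_flag <- !is.na(qde) & qde < alpha
  e_flag <- !is.na(qe) & qe < alpha
  dp_flag <- !is.na(qdp) & qdp < alpha

  ms <- rowMeans(rns$avg_slope)
  ms_se <- mean_slope_se(fit)[keep]
  category <- classify_gene(de_flag, dp_flag, e_flag, ms, ms_se)
  dir <- grn_category_info()$direction[match(category, grn_category_info()$category)]

  ref <- rns$reference_genotype
  others <- setdiff(colnames(rns$slope), ref)
  means <- rns$intercept + rns$slope * rns$env_col_means[["env"]]
  if (!is.null(rns$curvature)) {
    means <- means + rns$curvature * rns$env_col_means[["env2"]]
  }
  de_delta <- rowMeans(means[, others, drop = FALSE] - means[, ref])
  dp_delta <- rowMeans(rns$avg_slope[, others, drop = FALSE] - rns$avg_slope[, ref])

  out <- data.frame(
    gene_id = genes,
    de_flag = de_flag, plastic_flag = e_flag, dp_flag = dp_flag,
    de_direction = sign_chr(de_delta), de_magnitude = abs(de_delta),
    mean_env_direction = dir,
    dp_direction = sign_chr(dp_delta), dp_magnitude = abs(dp_delta),
    category = category,
    stringsAsFactors = FALSE
  )

  if (!is.null(ancestral)) {
    genos <- colnames(rns$slope)
    if (!(ancestral %in% genos)) {
      grn_stop(sprintf("ancestral genotype '%s' absent from the design", ancestral))
    }
    derived <- derived %||% if (length(genos) == 2L) setdiff(genos, ancestral) else NULL
    if (is.null(derived)) {
      grn_stop("designate a derived genotype when more than two genotypes are present")
    }
    evo <- rep("none", nrow(out))
    for (i in which(dp_flag)) {
      evo[i] <- classify_evo_pattern(
        c(rns$intercept[i, ancestral], rns$slope[i, ancestral]),
        c(rns$intercept[i, derived], rns$slope[i, derived]),
        rns$env_range, tau = tau
      )
    }
    out$evo_pattern <- evo
  } else if (!is.null(derived) || !is.null(tau)) {
    grn_warn("no ancestral genotype designated; evolutionary-pattern column omitted",
             class = "grn_no_ancestral")
  }
  class(out) <- c("grn_categories", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "omitted") <- rns$omitted
  out
}

# SE of the across-genotype mean slope, from the coefficient covariance of
# the full model: mean slope = env coefficient + mean of interaction offsets.
mean_slope_se <- function(fit) {
  cn <- colnames(fit$coefficients)
  genos <- fit$genotype_levels
  w <- stats::setNames(numeric(length(cn)), cn)
  w["env"] <- 1
  int_cols <- paste0("genotype", genos[-1L], ":env")
  int_cols <- intersect(int_cols, cn)
  w[int_cols] <- 1 / length(genos)
  keep <- setdiff(cn, fit$aliased)
  XtXinv <- chol2inv(chol(crossprod(fit$X[, keep, drop = FALSE])))
  wk <- w[keep]
  vfac <- drop(t(wk) %*% XtXinv %*% wk)
  stats::setNames(sqrt(vfac * fit$sigma2), rownames(fit$coefficients))
}

#' @export
print.grn_categories <- function(x, ...) {
  cat(sprintf("Gene categories (alpha = %g): %d genes\n", attr(x, "alpha"), nrow(x)))
  print(table(factor(x$category, levels = grn_categories())))
  if ("evo_pattern" %in% names(x)) {
    cat("evolutionary patterns among DP genes:\n")
    print(table(x$evo_pattern[x$dp_flag]))
  }
  invisible(x)
}

#' Per-category gene counts
#' @param object A `grn_categories` table.
#' @param ... Unused.
#' @return Data frame with `category` and `n_genes` covering all 12 categories.
#' @export
summary.grn_categories <- function(object, ...) {
  tab <- table(factor(object$category, levels = grn_categories()))
  data.frame(category = names(tab), n_genes = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Write a category table (and its per-category summary)
#' @param categories A `grn_categories` table.
#' @param path Output path for the per-gene table; the summary is written next
#'   to it with suffix `_summary.tsv`.
#' @export
write_categories <- function(categories, path) {
  utils::write.table(categories, path, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- sub("\\.tsv$", "_summary.tsv", path)
  if (identical(spath, path)) spath <- paste0(path, "_summary.tsv")
  utils::write.table(summary(categories), spath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, spath))
}
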