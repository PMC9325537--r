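# Per-gene fixed-effect models of log2 expression over a common-garden
# gradient. The basic model decomposes each gene's expression variance into
# genotype (G), environment (E), genotype-by-environment (GxE) and batch (B)
# components; nested and architecture variants split the genotype axis into
# upper/lower biological scales or SNP-cluster/structural-variant groupings.
#
# All genes share one model matrix, so fits are computed in a single
# multi-response least-squares pass. Per-term tests are partial F-tests
# (full model vs. the model with that term's columns removed), with
# Benjamini-Hochberg correction across genes within each term.
#
# Parameterization note: coefficients are reported under the model-intercept
# convention (reference genotype at the reference environment, by default the
# minimum observed level). Two main-effect tests, however, are not invariant
# to that parameterization once interactions are in the model, and are
# computed under equivalent reparameterizations of the same fitted model:
# genotype-type main effects with mean-centered environment columns (so the
# test targets mean expression across all environments, which is how
# differential expression is defined), and the environment main effect with
# mean-centered genotype dummies in the interaction block (so the test
# targets the across-genotype average response, not the reference genotype's
# slope). Interaction tests are invariant to both choices.

#' Model specification for per-gene reaction-norm fits
#'
#' @param model Which variance decomposition to fit: `"basic"` (genotype,
#'   environment, interaction, batch), `"nested"` (adds an upper biological
#'   scale: upper group, genotype-within-group, and both interaction tiers) or
#'   `"architecture"` (SNP-cluster and structural-variant groupings with their
#'   environment interactions).
#' @param env_coding `"linear"` (numeric gradient), `"quadratic"` (adds a
#'   curvature term; needs >=3 distinct environment levels) or `"categorical"`.
#' @param reference_genotype Genotype level all comparisons are made against;
#'   default: first level in sort order.
#' @param reference_env Environment value mapped to the model intercept;
#'   default: minimum observed level.
#' @param alpha FDR threshold used downstream for significance flags.
#' @return Object of class `grn_model_spec`.
#' @export
grn_model_spec <- function(model = c("basic", "nested", "architecture"),
                           env_coding = c("linear", "quadratic", "categorical"),
                           reference_genotype = NULL,
                           reference_env = NULL,
                           alpha = 0.05) {
  model <- match.arg(model)
  env_coding <- match.arg(env_coding)
  if (alpha <= 0 || alpha >= 1) grn_stop("alpha must be in (0, 1)")
  structure(
    list(model = model, env_coding = env_coding,
         reference_genotype = reference_genotype,
         reference_env = reference_env, alpha = alpha),
    class = "grn_model_spec"
  )
}

#' Check a sample design against a model specification
#'
#' Returns findings rather than raising: each row is an `"error"` or
#' `"warning"` with the design field concerned. Notably, nonlinear
#' (quadratic) environment coding is rejected with fewer than three distinct
#' environment levels, since linear and nonlinear reaction norms cannot be
#' distinguished with only two treatments.
#'
#' @param design Sample design data frame (see [read_design()]).
#' @param spec A [grn_model_spec()].
#' @return Data frame of class `grn_findings` with columns `level`, `field`,
#'   `message` (zero rows when the design is clean).
#' @examples
#' d <- data.frame(sample_id = paste0("s", 1:8),
#'                 genotype = rep(c("A", "B"), each = 4),
#'                 environment = rep(c(0, 1), 4), batch = "b1")
#' validate_design(d, grn_model_spec(env_coding = "quadratic"))
#' @export
validate_design <- function(design, spec = grn_model_spec()) {
  findings <- data.frame(level = character(), field = character(),
                         message = character(), stringsAsFactors = FALSE)
  add <- function(level, field, message) {
    findings <<- rbind(findings, data.frame(level = level, field = field,
                                            message = message, stringsAsFactors = FALSE))
  }
  design <- validate_design_table(design)
  env_vals <- sort(unique(design$environment))
  if (length(env_vals) < 2L) {
    add("error", "environment", "fewer than 2 distinct environment values")
  }
  if (spec$env_coding == "quadratic" && length(env_vals) < 3L) {
    add("error", "environment",
        paste("nonlinear reaction norm unidentifiable: quadratic environment",
              "coding requires at least 3 distinct environment levels"))
  }
  if (spec$env_coding == "categorical" && length(env_vals) < 2L) {
    add("error", "environment", "categorical environment coding requires >=2 levels")
  }
  genos <- unique(design$genotype)
  if (spec$model %in% c("basic", "nested") && length(genos) < 2L) {
    add("error", "genotype",
        "only one genotype: G and GxE terms are undefined")
  }
  for (g in genos) {
    ne <- length(unique(design$environment[design$genotype == g]))
    if (ne < 2L) add("error", "genotype",
                     sprintf("genotype '%s' observed at fewer than 2 environment values", g))
  }
  if (!is.null(spec$reference_genotype) && !(spec$reference_genotype %in% genos)) {
    add("error", "reference_genotype",
        sprintf("reference genotype '%s' not present in the design", spec$reference_genotype))
  }
  if (!is.null(spec$reference_env) && !(spec$reference_env %in% env_vals) &&
      spec$env_coding == "categorical") {
    add("error", "reference_env", "categorical coding requires reference_env to be an observed level")
  }
  if (spec$model == "nested") {
    if (is.null(design$upper_genotype)) {
      add("error", "upper_genotype", "nested model requires an upper_genotype column")
    } else {
      map <- unique(design[, c("genotype", "upper_genotype")])
      dup <- map$genotype[duplicated(map$genotype)]
      if (length(dup)) {
        add("error", "upper_genotype",
            sprintf("genotype(s) assigned to multiple upper groups: %s",
                    paste(unique(dup), collapse = ", ")))
      }
    }
  }
  if (spec$model == "architecture") {
    for (col in c("snp_group", "sv_group")) {
      if (is.null(design[[col]])) {
        add("error", col, sprintf("architecture model requires a %s column", col))
      }
    }
  }
  # replication per genotype x environment cell
  if (length(genos) >= 1L && length(env_vals) >= 2L) {
    tab <- table(design$genotype, design$environment)
    if (any(tab == 0L)) {
      add("warning", "design",
          sprintf("%d genotype x environment cell(s) have no observations", sum(tab == 0L)))
    } else if (any(tab == 1L)) {
      add("warning", "design",
          sprintf("%d genotype x environment cell(s) have no replication", sum(tab == 1L)))
    }
  }
  # model-matrix rank, only when no structural error blocks construction
  if (!any(findings$level == "error")) {
    bl <- try(build_blocks(design, spec), silent = TRUE)
    if (inherits(bl, "try-error")) {
      add("error", "design", sprintf("cannot build model matrix: %s",
                                     attr(bl, "condition")$message))
    } else {
      X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(design))), bl$blocks))
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        add(if (spec$model == "architecture") "warning" else "error", "design",
            sprintf("model matrix is rank-deficient; aliased column(s): %s",
                    paste(aliased, collapse = ", ")))
      }
      if (nrow(design) <= qrX$rank) {
        add("error", "design",
            sprintf("design too small: %d samples for model rank %d leaves no residual df",
                    nrow(design), qrX$rank))
      }
    }
  }
  class(findings) <- c("grn_findings", "data.frame")
  findings
}

# ---- model-matrix construction ---------------------------------------------

treatment_dummies <- function(x, ref, prefix) {
  f <- factor(x)
  if (!is.null(ref)) f <- stats::relevel(f, ref = as.character(ref))
  lev <- levels(f)
  if (length(lev) < 2L) {
    m <- matrix(numeric(0), nrow = length(x), ncol = 0L)
    attr(m, "levels") <- lev
    return(m)
  }
  m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  colnames(m) <- paste0(prefix, lev[-1L])
  attr(m, "levels") <- lev
  m
}

env_columns <- function(env, coding, ref_env) {
  if (coding == "categorical") {
    m <- treatment_dummies(env, ref_env, "env")
    attr(m, "ref_env") <- ref_env
    return(m)
  }
  ec <- env - ref_env
  m <- if (coding == "quadratic") cbind(env = ec, env2 = ec^2) else cbind(env = ec)
  attr(m, "ref_env") <- ref_env
  m
}

interact <- function(dummies, envmat, sep = ":") {
  if (ncol(dummies) == 0L || ncol(envmat) == 0L) {
    return(matrix(numeric(0), nrow = nrow(dummies), ncol = 0L))
  }
  cols <- list()
  for (i in seq_len(ncol(dummies))) {
    for (j in seq_len(ncol(envmat))) {
      cols[[paste0(colnames(dummies)[i], sep, colnames(envmat)[j])]] <-
        dummies[, i] * envmat[, j]
    }
  }
  do.call(cbind, cols)
}

# Builds the named column blocks of the model matrix, in canonical order,
# plus the mean-centered environment variants used by genotype-type tests.
build_blocks <- function(design, spec) {
  ref_geno <- spec$reference_genotype %||% sort(unique(design$genotype))[1L]
  ref_env <- spec$reference_env %||% min(design$environment)
  Ec <- env_columns(design$environment, spec$env_coding, ref_env)
  Em <- sweep(Ec, 2L, colMeans(Ec))          # mean-centered environment columns
  Bb <- treatment_dummies(design$batch, NULL, "batch")

  ctr <- function(m) if (ncol(m)) sweep(m, 2L, colMeans(m)) else m

  if (spec$model == "basic") {
    Gd <- treatment_dummies(design$genotype, ref_geno, "genotype")
    blocks <- list(G = Gd, E = Ec, GxE = interact(Gd, Ec), B = Bb)
    blocks_c <- list(G = Gd, E = Em, GxE = interact(Gd, Em), B = Bb)
    blocks_e <- list(G = Gd, E = Ec, GxE = interact(ctr(Gd), Ec), B = Bb)
    geno_terms <- c("G")
  } else if (spec$model == "nested") {
    if (is.null(design$upper_genotype)) grn_stop("nested model requires upper_genotype")
    map <- unique(design[, c("genotype", "upper_genotype")])
    if (anyDuplicated(map$genotype)) {
      grn_stop("genotype(s) assigned to multiple upper groups", class = "grn_design_error")
    }
    ref_upper <- map$upper_genotype[map$genotype == ref_geno][1L]
    Gj <- treatment_dummies(design$upper_genotype, ref_upper, "upper")
    # within-group columns: indicator of every genotype that is not its
    # group's reference genotype; spans genotype jointly with the Gj block
    first_of_group <- tapply(map$genotype, map$upper_genotype, function(g) {
      if (ref_geno %in% g) ref_geno else sort(g)[1L]
    })
    within <- setdiff(map$genotype, unlist(first_of_group))
    Gi <- if (length(within)) {
      sapply(sort(within), function(g) as.numeric(design$genotype == g))
    } else matrix(numeric(0), nrow(design), 0L)
    if (length(within)) colnames(Gi) <- paste0("genotype", sort(within))
    blocks <- list(Gj = Gj, GiGj = Gi, E = Ec,
                   GjxE = interact(Gj, Ec), GiGjxE = interact(Gi, Ec), B = Bb)
    blocks_c <- list(Gj = Gj, GiGj = Gi, E = Em,
                     GjxE = interact(Gj, Em), GiGjxE = interact(Gi, Em), B = Bb)
    blocks_e <- list(Gj = Gj, GiGj = Gi, E = Ec,
                     GjxE = interact(ctr(Gj), Ec), GiGjxE = interact(ctr(Gi), Ec), B = Bb)
    geno_terms <- c("Gj", "GiGj")
  } else { # architecture
    for (col in c("snp_group", "sv_group")) {
      if (is.null(design[[col]])) grn_stop(sprintf("architecture model requires %s", col))
    }
    Gs <- treatment_dummies(design$snp_group, NULL, "snp")
    Gv <- treatment_dummies(design$sv_group, NULL, "sv")
    blocks <- list(Gsnp = Gs, Gsv = Gv, E = Ec,
                   GsnpxE = interact(Gs, Ec), GsvxE = interact(Gv, Ec), B = Bb)
    blocks_c <- list(Gsnp = Gs, Gsv = Gv, E = Em,
                     GsnpxE = interact(Gs, Em), GsvxE = interact(Gv, Em), B = Bb)
    blocks_e <- list(Gsnp = Gs, Gsv = Gv, E = Ec,
                     GsnpxE = interact(ctr(Gs), Ec), GsvxE = interact(ctr(Gv), Ec), B = Bb)
    geno_terms <- c("Gsnp", "Gsv")
  }
  list(blocks = blocks, blocks_centered = blocks_c, blocks_envtest = blocks_e,
       reference_genotype = ref_geno, reference_env = ref_env,
       env_col_means = colMeans(Ec), geno_terms = geno_terms,
       genotype_levels = if (spec$model == "basic") attr(treatment_dummies(design$genotype, ref_geno, "genotype"), "levels") else sort(unique(design$genotype)))
}

bind_X <- function(blocks, n) {
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, n)), blocks))
  idx <- list()
  pos <- 1L
  for (nm in names(blocks)) {
    k <- ncol(blocks[[nm]])
    idx[[nm]] <- if (k > 0L) (pos + 1L):(pos + k) else integer(0)
    pos <- pos + k
  }
  list(X = X, term_cols = idx)
}

rss_of <- function(X, Y) {
  if (ncol(X) == 0L) {
    return(list(rss = colSums(Y^2), rank = 0L))
  }
  f <- stats::lm.fit(X, Y)
  list(rss = colSums(as.matrix(f$residuals)^2), rank = f$rank, fit = f)
}

# ---- main fitting function --------------------------------------------------

#' Fit per-gene reaction-norm models
#'
#' For every gene independently, fits ordinary least squares on log2
#' normalized expression with fixed effects determined by the model
#' specification (basic: genotype + environment + genotype:environment +
#' batch). Each variance component is tested with a partial F-test, and
#' p-values are converted to q-values by Benjamini-Hochberg across genes
#' within each term.
#'
#' Genes with (numerically) constant expression are flagged and their tests
#' reported as `NA` rather than dropped. In the architecture model, perfectly
#' confounded groupings are detected; an aliased term's test is reported as
#' undefined.
#'
#' @param object A `grn_norm` object from [normalize_counts()], or a numeric
#'   matrix of log2 expression (genes x samples).
#' @param design Sample design data frame; aligned to the expression columns
#'   by `sample_id`.
#' @param spec A [grn_model_spec()].
#' @return Object of class `grn_fit` with per-gene `coefficients` and `se`
#'   matrices, residual variance `sigma2`, per-term `tests` (F, p, q), the
#'   fitted-value matrix, term/column bookkeeping and the inputs needed by
#'   [build_reaction_norms()], [variance_partition()] and [grn_classify()].
#' @examples
#' sim <- simulate_grn(grn_sim_config(n_genes = 40, seed = 2))
#' fit <- grn_fit(normalize_counts(sim$counts), sim$design)
#' head(coef(fit))
#' summary(fit)
#' @export
grn_fit <- function(object, design, spec = grn_model_spec()) {
  Y <- as_norm_values(object)      # genes x samples
  design <- validate_design_table(design)
  if (!is.null(colnames(Y))) design <- align_design(Y, design)
  if (nrow(design) != ncol(Y)) {
    grn_stop("design rows must correspond 1:1 to expression columns")
  }
  findings <- validate_design(design, spec)
  errs <- findings$message[findings$level == "error"]
  if (length(errs)) {
    grn_stop(paste0("invalid design for model fit:\n  - ",
                    paste(errs, collapse = "\n  - ")), class = "grn_design_error")
  }

  n <- nrow(design)
  bl <- build_blocks(design, spec)
  ref <- bind_X(bl$blocks, n)
  cen <- bind_X(bl$blocks_centered, n)
  etest <- bind_X(bl$blocks_envtest, n)
  Yt <- t(Y)                        # samples x genes

  full <- rss_of(ref$X, Yt)
  p <- ncol(ref$X)
  rank_full <- full$rank
  df2 <- n - rank_full
  if (df2 <= 0L) grn_stop("no residual degrees of freedom", class = "grn_design_error")

  aliased_cols <- character(0)
  if (rank_full < p) {
    aliased_cols <- colnames(ref$X)[full$fit$qr$pivot[(rank_full + 1L):p]]
  }
  aliased_terms <- names(ref$term_cols)[vapply(names(ref$term_cols), function(tm) {
    any(colnames(ref$X)[ref$term_cols[[tm]]] %in% aliased_cols)
  }, logical(1))]

  coefs <- t(as.matrix(full$fit$coefficients))      # genes x p (NA for aliased)
  colnames(coefs) <- colnames(ref$X)
  rownames(coefs) <- rownames(Y)
  sigma2 <- full$rss / df2

  # standard errors from the non-aliased columns
  keep <- setdiff(colnames(ref$X), aliased_cols)
  XtXinv <- chol2inv(chol(crossprod(ref$X[, keep, drop = FALSE])))
  se <- matrix(NA_real_, nrow(coefs), ncol(coefs), dimnames = dimnames(coefs))
  se[, keep] <- sqrt(outer(sigma2, diag(XtXinv)))

  # degenerate (constant-expression) genes: tests undefined
  tss <- colSums(sweep(Yt, 2L, colMeans(Yt))^2)
  flagged <- tss < 1e-10

  terms_to_test <- setdiff(names(ref$term_cols), "B")
  tests <- list()
  for (tm in terms_to_test) {
    par <- if (tm %in% bl$geno_terms) cen else if (tm == "E") etest else ref
    drop_cols <- par$term_cols[[tm]]
    Xred <- if (length(drop_cols)) par$X[, -drop_cols, drop = FALSE] else par$X
    red <- rss_of(Xred, Yt)
    df1 <- rank_full - red$rank
    if (df1 <= 0L || tm %in% aliased_terms) {
      tests[[tm]] <- data.frame(F = NA_real_, df1 = NA_integer_, df2 = df2,
                                p = NA_real_, q = NA_real_)[rep(1L, nrow(Y)), ]
      rownames(tests[[tm]]) <- rownames(Y)
      next
    }
    Fstat <- pmax(red$rss - full$rss, 0) / df1 / (full$rss / df2)
    pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    Fstat[flagged] <- NA_real_
    pval[flagged] <- NA_real_
    qval <- stats::p.adjust(pval, method = "BH")
    tests[[tm]] <- data.frame(F = Fstat, df1 = df1, df2 = df2, p = pval, q = qval,
                              row.names = rownames(Y))
  }

  fitted <- t(as.matrix(full$fit$fitted.values))
  dimnames(fitted) <- dimnames(Y)

  structure(
    list(
      coefficients = coefs, se = se, sigma2 = sigma2, df_residual = df2,
      tests = tests, term_cols = ref$term_cols, aliased = aliased_cols,
      aliased_terms = aliased_terms, flagged = flagged,
      fitted = fitted, values = Y, design = design, spec = spec,
      blocks = bl$blocks, X = ref$X, Xc = cen$X, term_cols_centered = cen$term_cols,
      reference_genotype = bl$reference_genotype, reference_env = bl$reference_env,
      env_col_means = bl$env_col_means,
      genotype_levels = bl$genotype_levels,
      env_range = range(design$environment),
      findings = findings
    ),
    class = "grn_fit"
  )
}

#' Partition each gene's variance across model terms
#'
#' Sequential (type-I) sums of squares in the fixed canonical order of the
#' fitted model (basic: G, E, GxE, B), expressed as fractions of the total
#' sum of squares around the gene's mean; the remainder is the residual
#' fraction. Fractions sum to 1 by construction. Genes with zero total
#' variance get `NA` fractions.
#'
#' @param fit A [grn_fit()] object.
#' @return Data frame of class `grn_varpart`: one row per gene, one column per
#'   model term plus `residual`.
#' @examples
#' sim <- simulate_grn(grn_sim_config(n_genes = 20, seed = 3))
#' vp <- variance_partition(grn_fit(normalize_counts(sim$counts), sim$design))
#' stopifnot(all(abs(rowSums(vp) - 1) < 1e-9, na.rm = TRUE))
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "grn_fit"))
  Yt <- t(fit$values)
  n <- nrow(Yt)
  tss <- colSums(sweep(Yt, 2L, colMeans(Yt))^2)
  order_terms <- names(fit$term_cols)
  out <- matrix(NA_real_, ncol(Yt), length(order_terms) + 1L,
                dimnames = list(colnames(Yt), c(order_terms, "residual")))
  prev_rss <- tss
  cols <- 1L # intercept
  for (tm in order_terms) {
    cols <- c(cols, fit$term_cols[[tm]])
    r <- rss_of(fit$X[, cols, drop = FALSE], Yt)
    out[, tm] <- prev_rss - r$rss
    prev_rss <- r$rss
  }
  out[, "residual"] <- prev_rss
  frac <- out / tss
  frac[tss < 1e-10, ] <- NA_real_
  out <- as.data.frame(frac)
  class(out) <- c("grn_varpart", "data.frame")
  out
}
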