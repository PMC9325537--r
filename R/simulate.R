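# Synthetic common-garden-gradient experiments with known per-gene
# reaction-norm structure. Every downstream stage of the package is testable
# against the truth tables produced here.

#' Default mixture over the twelve expression-pattern categories
#'
#' A third of genes are null; the remaining mass is spread evenly over the
#' eleven non-null categories so that every pattern is represented.
#' @return Named numeric vector summing to 1.
#' @export
default_category_proportions <- function() {
  labs <- grn_categories()
  p <- stats::setNames(rep(0.06, length(labs)), labs)
  p["null"] <- 1 - sum(p) + p["null"]
  p
}

#' Configuration for a simulated common-garden-gradient experiment
#'
#' Defines a factorial design (genotype units x environment levels x replicates
#' x batches) and the generative model for counts: for gene g in sample s,
#' counts are negative binomial with
#' `log2(mean) = intercept_g(genotype) + slope_g(genotype) * env + batch offset
#' + log2(library factor)`, gene-wise dispersions log-normal, library-size
#' factors log-normal, and batch offsets gene-shared Gaussian shifts on the
#' log2 scale.
#'
#' Per-gene effects are assigned category-first: each gene draws one of the
#' twelve categories (see [grn_categories()]), then intercept and slope
#' deviations realizing that pattern. An affected genotype's slope deviates by
#' `effect_size_dp` from the across-genotype mean slope (so the opposite-slope
#' pattern has slopes +/- `effect_size_dp`), and its environment-averaged mean
#' expression deviates by `effect_size_de` from the across-genotype mean.
#' Deviations are centered across genotypes and their assignment to genotypes
#' is randomized per gene, so mean-direction labels are preserved.
#'
#' @param n_genes Number of genes (positive integer).
#' @param genotypes Character vector of >=2 genotype-unit labels.
#' @param upper_groups Optional named character vector mapping each genotype to
#'   an upper-scale group label (for nested designs).
#' @param env_levels Strictly increasing numeric environment values (>=2).
#' @param n_replicates Replicates per genotype x environment cell.
#' @param n_batches Number of batches; replicates within each cell are spread
#'   over batches in rotation so batch stays balanced.
#' @param category_proportions Named probabilities over the twelve categories.
#' @param effect_size_de Per-genotype deviation of environment-averaged mean
#'   expression, log2 units (default 1.0).
#' @param effect_size_slope Across-genotype mean slope for plastic genes, log2
#'   per environment unit (default 0.5).
#' @param effect_size_dp Per-genotype slope deviation for differentially
#'   plastic genes, log2 per environment unit (default 0.5).
#' @param baseline_log2_range Range of baseline log2 mean expression.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   gene-wise NB dispersion (defaults log(0.1) and 0.5).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size factors.
#' @param batch_effect_sd SD of gene-shared log2 batch offsets (default 0.2);
#'   the first batch is the reference with offset 0.
#' @param seed Integer seed governing all randomness of the simulation.
#' @return Validated object of class `grn_sim_config`.
#' @seealso [simulate_grn()]
#' @export
grn_sim_config <- function(n_genes = 1000L,
                           genotypes = c("G1", "G2", "G3"),
                           upper_groups = NULL,
                           env_levels = c(0, 1, 2),
                           n_replicates = 4L,
                           n_batches = 2L,
                           category_proportions = default_category_proportions(),
                           effect_size_de = 1.0,
                           effect_size_slope = 0.5,
                           effect_size_dp = 0.5,
                           baseline_log2_range = c(2, 12),
                           dispersion_meanlog = log(0.1),
                           dispersion_sdlog = 0.5,
                           libsize_meanlog = 0,
                           libsize_sdlog = 0.2,
                           batch_effect_sd = 0.2,
                           seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), genotypes = as.character(genotypes),
    upper_groups = upper_groups, env_levels = as.numeric(env_levels),
    n_replicates = as.integer(n_replicates), n_batches = as.integer(n_batches),
    category_proportions = unlist(category_proportions),
    effect_size_de = effect_size_de, effect_size_slope = effect_size_slope,
    effect_size_dp = effect_size_dp,
    baseline_log2_range = as.numeric(baseline_log2_range),
    dispersion_meanlog = dispersion_meanlog, dispersion_sdlog = dispersion_sdlog,
    libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
    batch_effect_sd = batch_effect_sd, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "grn_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) grn_stop("n_genes must be >= 1")
  if (length(cfg$genotypes) < 2L || anyDuplicated(cfg$genotypes)) {
    grn_stop("genotypes must be >=2 unique labels")
  }
  e <- cfg$env_levels
  if (length(e) < 2L || any(diff(e) <= 0)) {
    grn_stop("env_levels must be >=2 strictly increasing values with no duplicates")
  }
  if (cfg$n_replicates < 1L) grn_stop("design too small: n_replicates must be >= 1 (replicates)")
  if (cfg$n_batches < 1L) grn_stop("n_batches must be >= 1")
  for (f in c("effect_size_de", "effect_size_slope", "effect_size_dp",
              "dispersion_sdlog", "libsize_sdlog", "batch_effect_sd")) {
    if (cfg[[f]] < 0) grn_stop(sprintf("%s must be >= 0", f))
  }
  p <- unlist(cfg$category_proportions)
  if (is.null(names(p)) || !setequal(names(p), grn_categories())) {
    grn_stop("category_proportions must be named by the 12 canonical categories")
  }
  if (any(p < 0)) grn_stop("category_proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) grn_stop("category_proportions must sum to 1 (within 1e-9)")
  info <- grn_category_info()
  if (cfg$effect_size_de <= 0 && sum(p[info$category[info$de]]) > 0) {
    grn_stop("effect_size_de must be > 0 when DE categories have positive mass")
  }
  if (cfg$effect_size_dp <= 0 && sum(p[info$category[info$dp]]) > 0) {
    grn_stop("effect_size_dp must be > 0 when DP categories have positive mass")
  }
  if (cfg$effect_size_slope <= 0 && sum(p[info$category[info$direction != "none"]]) > 0) {
    grn_stop("effect_size_slope must be > 0 when directional categories have positive mass")
  }
  if (!is.null(cfg$upper_groups)) {
    if (is.null(names(cfg$upper_groups)) ||
        !all(cfg$genotypes %in% names(cfg$upper_groups))) {
      grn_stop("upper_groups must be a named vector covering every genotype")
    }
  }
  # identifiability: samples must exceed the basic-model parameter count
  G <- length(cfg$genotypes); E <- length(e)
  n <- G * E * cfg$n_replicates
  p_model <- 2L * G + max(cfg$n_batches - 1L, 0L) # intercepts+slopes+batch offsets
  if (n < p_model + 1L) {
    grn_stop(sprintf(paste0(
      "design too small for model rank: %d samples but %d parameters; ",
      "increase replicates (deficient factor: replicates)"), n, p_model),
      class = "grn_design_error")
  }
  invisible(cfg)
}

# Zero-mean +/-1 assignment pattern over G genotypes (one 0 when G is odd),
# randomly permuted. Realizes "each affected genotype deviates by the effect
# size" while keeping the across-genotype mean untouched.
centered_pattern <- function(G) {
  half <- G %/% 2L
  v <- c(rep(-1, half), rep(1, half), if (G %% 2L == 1L) 0)
  sample(v)
}

#' Simulate a common-garden-gradient expression experiment
#'
#' Draws per-gene categories, realizes matching reaction-norm coefficients,
#' and generates negative-binomial counts over the factorial design described
#' by the configuration. Identical configurations (including seed) give
#' bit-identical output.
#'
#' @param config A [grn_sim_config()] object.
#' @return Object of class `grn_sim`: list with `counts` (integer matrix),
#'   `design` (data frame, one row per sample), `truth` (data frame, one row
#'   per gene: category, flags, per-genotype true intercepts/slopes on the
#'   log2 scale, dispersion), `batch_offsets`, `lib_factors` and `config`.
#' @examples
#' sim <- simulate_grn(grn_sim_config(n_genes = 50, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$category)
#' @export
simulate_grn <- function(config) {
  if (!inherits(config, "grn_sim_config")) config <- do.call(grn_sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, simulate_grn_impl(config))
}

simulate_grn_impl <- function(cfg) {
  G <- length(cfg$genotypes); E <- length(cfg$env_levels)
  R <- cfg$n_replicates; B <- cfg$n_batches
  n_genes <- cfg$n_genes

  design <- expand.grid(
    replicate = seq_len(R), environment = cfg$env_levels,
    genotype = cfg$genotypes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("genotype", "environment", "replicate")]
  n_samp <- nrow(design)
  design$batch <- paste0("B", ((design$replicate - 1L) %% B) + 1L)
  design$replicate_unit <- paste0(design$genotype, "_E", design$environment,
                                  "_R", design$replicate)
  design$sample_id <- sprintf("S%03d", seq_len(n_samp))
  design$replicate <- NULL
  design <- design[, c("sample_id", "genotype", "environment", "batch", "replicate_unit")]
  if (!is.null(cfg$upper_groups)) {
    design$upper_genotype <- unname(cfg$upper_groups[design$genotype])
  }

  info <- grn_category_info()
  category <- sample(info$category, n_genes, replace = TRUE,
                     prob = cfg$category_proportions[info$category])
  idx <- match(category, info$category)
  de <- info$de[idx]; dp <- info$dp[idx]; dir <- info$direction[idx]

  baseline <- stats::runif(n_genes, cfg$baseline_log2_range[1L], cfg$baseline_log2_range[2L])
  dirsign <- c(none = 0, up = 1, down = -1)[dir]
  sbar <- cfg$effect_size_slope * dirsign

  m_dev <- matrix(0, n_genes, G)      # mean-expression deviations per genotype
  d_dev <- matrix(0, n_genes, G)      # slope deviations per genotype
  for (i in seq_len(n_genes)) {
    if (de[i]) m_dev[i, ] <- cfg$effect_size_de * centered_pattern(G)
    if (dp[i]) d_dev[i, ] <- cfg$effect_size_dp * centered_pattern(G)
  }

  # Environment is referenced at its minimum; mean expression is taken across
  # the observed environment levels, so intercepts are back-computed to give
  # each genotype its target environment-averaged mean.
  ec <- cfg$env_levels - min(cfg$env_levels)
  mbar <- mean(ec)
  slopes <- sweep(d_dev, 1L, sbar, "+")
  intercepts <- baseline + m_dev - d_dev * mbar

  dispersion <- stats::rlnorm(n_genes, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  batch_offsets <- stats::setNames(
    c(0, stats::rnorm(B - 1L, 0, cfg$batch_effect_sd)), paste0("B", seq_len(B)))
  lib_factors <- stats::setNames(
    stats::rlnorm(n_samp, cfg$libsize_meanlog, cfg$libsize_sdlog), design$sample_id)

  gidx <- match(design$genotype, cfg$genotypes)
  ec_s <- design$environment - min(cfg$env_levels)
  log2mu <- intercepts[, gidx, drop = FALSE] +
    slopes[, gidx, drop = FALSE] * rep(ec_s, each = n_genes)
  log2mu <- sweep(log2mu, 2L, batch_offsets[design$batch] + log2(lib_factors), "+")
  mu <- 2^log2mu

  size <- 1 / pmax(dispersion, 1e-12)
  counts <- matrix(
    stats::rnbinom(n_genes * n_samp, mu = as.vector(mu), size = rep(size, times = n_samp)),
    nrow = n_genes, ncol = n_samp
  )
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  dimnames(counts) <- list(gene_ids, design$sample_id)
  storage.mode(counts) <- "integer"

  colnames(intercepts) <- colnames(slopes) <- cfg$genotypes
  truth <- data.frame(
    gene_id = gene_ids, category = category,
    de_flag = de, plastic_flag = dir != "none", dp_flag = dp,
    mean_env_direction = dir,
    baseline_log2 = baseline, dispersion = dispersion,
    stringsAsFactors = FALSE
  )
  truth <- cbind(truth,
                 stats::setNames(as.data.frame(intercepts), paste0("intercept_", cfg$genotypes)),
                 stats::setNames(as.data.frame(slopes), paste0("slope_", cfg$genotypes)))

  # internal consistency: the noise-free classification rule must reproduce
  # every assigned label
  round_trip <- truth_to_category(intercepts, slopes, cfg$env_levels)
  stopifnot(identical(round_trip, category))

  structure(
    list(counts = counts, design = design, truth = truth,
         batch_offsets = batch_offsets, lib_factors = lib_factors, config = cfg),
    class = "grn_sim"
  )
}

#' Category implied by noise-free reaction-norm coefficients
#'
#' Applies the classifier's rule directly to true coefficients: a gene is DE
#' when genotypes differ in environment-averaged mean expression, DP when at
#' least two genotype slopes differ, and its mean direction is the sign of the
#' across-genotype mean slope — all judged against a numeric tolerance rather
#' than a significance test.
#'
#' @param intercepts Matrix (genes x genotypes) of log2 intercepts at the
#'   reference (minimum) environment; a single gene may pass a vector.
#' @param slopes Matching matrix/vector of log2-per-environment-unit slopes.
#' @param env_levels Observed environment values.
#' @param tol Numeric tolerance for calling an effect nonzero.
#' @return Character vector of category labels, one per gene.
#' @examples
#' truth_to_category(c(5, 5), c(0.5, -0.5), 0:2) # opposite slopes, equal means
#' @export
truth_to_category <- function(intercepts, slopes, env_levels, tol = 1e-8) {
  if (is.null(dim(intercepts))) intercepts <- matrix(intercepts, nrow = 1L)
  if (is.null(dim(slopes))) slopes <- matrix(slopes, nrow = 1L)
  stopifnot(identical(dim(intercepts), dim(slopes)))
  ec <- env_levels - min(env_levels)
  means <- intercepts + slopes * mean(ec)
  de <- apply(means, 1L, function(x) diff(range(x))) > tol
  dp <- apply(slopes, 1L, function(x) diff(range(x))) > tol
  ms <- rowMeans(slopes)
  dir <- ifelse(abs(ms) <= tol, "none", ifelse(ms > 0, "up", "down"))
  category_label(de, dp, dir)
}

#' @export
print.grn_sim <- function(x, ...) {
  cat(sprintf("Simulated common-garden experiment: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("%d genotypes x %d environments x %d replicates, %d batch(es); seed %d\n",
              length(x$config$genotypes), length(x$config$env_levels),
              x$config$n_replicates, x$config$n_batches, x$config$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Write a simulated experiment as tab-separated tables
#' @param sim A `grn_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(sim$counts, paths[["counts"]])
  write_design(sim$design, paths[["design"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
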