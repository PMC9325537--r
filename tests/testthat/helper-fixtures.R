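# Programmatic fixtures shared across test files.

# Balanced factorial design: genotypes x environment levels x replicates.
toy_design <- function(genotypes = c("blue", "red"), env = c(0, 1, 2),
                       reps = 2, batches = 1) {
  d <- expand.grid(rep = seq_len(reps), environment = env, genotype = genotypes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample_id <- sprintf("s%02d", seq_len(nrow(d)))
  d$batch <- paste0("b", ((seq_len(nrow(d)) - 1L) %% batches) + 1L)
  d$rep <- NULL
  d[, c("sample_id", "genotype", "environment", "batch")]
}

# Noise-free expression rows built from per-genotype intercepts and slopes.
norm_free_matrix <- function(design, intercepts, slopes, gene_ids = NULL) {
  stopifnot(identical(names(intercepts), names(slopes)))
  Y <- do.call(rbind, lapply(seq_along(intercepts[[1]]), function(i) {
    a <- vapply(intercepts, `[`, numeric(1), i)
    s <- vapply(slopes, `[`, numeric(1), i)
    unname(a[design$genotype] + s[design$genotype] * design$environment)
  }))
  rownames(Y) <- gene_ids %||% paste0("g", seq_len(nrow(Y)))
  colnames(Y) <- design$sample_id
  Y
}

# One-gene noise-free matrix from scalar per-genotype coefficients.
one_gene_matrix <- function(design, intercepts, slopes, gene_id = "g1") {
  y <- intercepts[design$genotype] + slopes[design$genotype] * design$environment
  m <- matrix(unname(y), nrow = 1, dimnames = list(gene_id, design$sample_id))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force OLS oracle via the normal equations.
normal_eq_coef <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Tiny count matrix with dimnames for IO tests.
tiny_counts <- function(n_genes = 5, n_samples = 4, lambda = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(paste0("gene", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

null_proportions <- function() {
  p <- default_category_proportions()
  p[] <- 0
  p["null"] <- 1
  p
}
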