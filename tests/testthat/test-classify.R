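make_rns <- function(intercepts, slopes, env = c(0, 1, 2), ref = "blue") {
  d <- toy_design(genotypes = names(intercepts), env = env, reps = 2)
  Y <- one_gene_matrix(d, intercepts, slopes)
  fit <- grn_fit(Y, d, grn_model_spec(reference_genotype = ref))
  build_reaction_norms(fit)
}

test_that("reaction norms are plain coefficient arithmetic", {
  rns <- make_rns(c(blue = 5, red = 6), c(blue = 1, red = -1))
  expect_equal(unname(rns$intercept["g1", ]), c(5, 6), tolerance = 1e-9)
  expect_equal(unname(rns$slope["g1", ]), c(1, -1), tolerance = 1e-9)
  expect_identical(colnames(rns$slope), c("blue", "red"))
})

test_that("norms evaluated at design points reproduce fitted cell means", {
  sim <- simulate_grn(grn_sim_config(n_genes = 25, n_batches = 1, seed = 14))
  fit <- grn_fit(normalize_counts(sim$counts), sim$design)
  rns <- build_reaction_norms(fit)
  env <- sort(unique(sim$design$environment))
  for (g in rownames(rns$slope)[1:5]) {
    vals <- grnorm:::eval_norms(rns, g, env)
    for (geno in colnames(vals)) {
      sel <- sim$design$genotype == geno
      cellmeans <- tapply(fitted(fit)[g, sel], sim$design$environment[sel], mean)
      expect_equal(unname(vals[, geno]), as.numeric(cellmeans), tolerance = 1e-9)
    }
  }
})

test_that("opposite equal slopes double the DP magnitude; same-sign slopes subtract", {
  s <- 0.75
  rns <- make_rns(c(blue = 5, red = 5 + 2 * s), c(blue = s, red = -s))
  dd <- compute_de_dp(rns, "g1")
  expect_equal(dd$dp_magnitude, 2 * s, tolerance = 1e-9)
  expect_identical(dd$dp_direction, "-")

  rns2 <- make_rns(c(blue = 5, red = 5), c(blue = 1, red = 3))
  dd2 <- compute_de_dp(rns2, "g1")
  expect_equal(dd2$dp_magnitude, 3 - 1, tolerance = 1e-9)
  expect_identical(dd2$dp_direction, "+")

  rns3 <- make_rns(c(blue = 5, red = 5), c(blue = 1, red = 1))
  dd3 <- compute_de_dp(rns3, "g1")
  expect_equal(dd3$de_magnitude, 0, tolerance = 1e-9)
  expect_equal(dd3$dp_magnitude, 0, tolerance = 1e-9)
  expect_identical(dd3$de_direction, "none")
  expect_identical(dd3$dp_direction, "none")
})

test_that("DE sign follows the model-intercept convention", {
  # red has lower mean expression than the blue reference: DE negative;
  # red has the more positive slope: DP positive
  rns <- make_rns(c(blue = 6, red = 3), c(blue = -0.5, red = 0.5))
  dd <- compute_de_dp(rns, "g1", reference = "blue", comparison = "red")
  expect_identical(dd$de_direction, "-")
  expect_identical(dd$dp_direction, "+")
})

test_that("swapping reference and comparison negates directions, keeps magnitudes", {
  set.seed(7)
  for (i in 1:10) {
    ints <- c(blue = runif(1, 2, 8), red = runif(1, 2, 8))
    sls <- c(blue = runif(1, -1, 1), red = runif(1, -1, 1))
    rns <- make_rns(ints, sls)
    ab <- compute_de_dp(rns, "g1", reference = "blue", comparison = "red")
    ba <- compute_de_dp(rns, "g1", reference = "red", comparison = "blue")
    expect_equal(ab$de_magnitude, ba$de_magnitude, tolerance = 1e-9)
    expect_equal(ab$dp_magnitude, ba$dp_magnitude, tolerance = 1e-9)
    flip <- c("+" = "-", "-" = "+", none = "none")
    expect_identical(ba$de_direction, unname(flip[ab$de_direction]))
    expect_identical(ba$dp_direction, unname(flip[ab$dp_direction]))
  }
})

test_that("a missing reference genotype is an error", {
  rns <- make_rns(c(blue = 5, red = 6), c(blue = 1, red = -1))
  expect_error(compute_de_dp(rns, "g1", reference = "green"),
               class = "grn_validation_error")
})

test_that("the classifier grid yields exactly twelve distinct categories", {
  grid <- expand.grid(de = c(FALSE, TRUE), dp = c(FALSE, TRUE),
                      ms = c(0, 0.5, -0.5))
  labels <- classify_gene(grid$de, grid$dp, e_flag = grid$ms != 0,
                          mean_slope = grid$ms)
  expect_identical(length(unique(labels)), 12L)
  expect_setequal(unique(labels), grn_categories())
})

test_that("named classifier cells match their intended patterns", {
  expect_identical(classify_gene(FALSE, FALSE, TRUE, 0.5), "plastic_up")
  expect_identical(classify_gene(FALSE, FALSE, FALSE, 0), "null")
  expect_identical(classify_gene(TRUE, FALSE, FALSE, 0), "de")
  expect_identical(classify_gene(TRUE, TRUE, TRUE, -0.3), "de_dp_mean_down")
  # cancelling slopes with DP but no overall environmental response
  expect_identical(classify_gene(FALSE, TRUE, FALSE, 0), "dp_mean_none")
})

test_that("direction under noise requires the mean slope to clear its error bar", {
  # dp gene with tiny mean slope relative to its SE: no direction
  expect_identical(classify_gene(FALSE, TRUE, FALSE, 0.05, mean_slope_se = 0.1),
                   "dp_mean_none")
  expect_identical(classify_gene(FALSE, TRUE, FALSE, 0.5, mean_slope_se = 0.1),
                   "dp_mean_up")
})

test_that("evolutionary patterns follow the ancestral-proxy geometry", {
  # ancestral slope +1 over [0,1]; derived flat at the high-environment level
  expect_identical(classify_evo_pattern(c(5, 1), c(6, 0), c(0, 1)), "assimilation")
  # derived flat at the ancestral (low-environment) level
  expect_identical(classify_evo_pattern(c(5, 1), c(5, 0), c(0, 1)), "compensation")
  # strictly opposite slopes
  expect_identical(classify_evo_pattern(c(5, 1), c(6, -1), c(0, 1)), "reversal")
  # derived flat but far from both ends
  expect_identical(classify_evo_pattern(c(5, 1), c(8, 0), c(0, 1)), "none")
  # both plastic in the same direction: none
  expect_identical(classify_evo_pattern(c(5, 1), c(5, 0.9), c(0, 1)), "none")
  # a non-plastic ancestor defines no pattern
  expect_identical(classify_evo_pattern(c(5, 0), c(6, 1), c(0, 1)), "none")
  # tau controls the match tolerance
  expect_identical(classify_evo_pattern(c(5, 1), c(6.2, 0), c(0, 1), tau = 0.1), "none")
  expect_identical(classify_evo_pattern(c(5, 1), c(6.2, 0), c(0, 1), tau = 0.3),
                   "assimilation")
})

test_that("every classified gene gets exactly one category and counts add up", {
  sim <- simulate_grn(grn_sim_config(n_genes = 120, seed = 19))
  fit <- grn_fit(normalize_counts(sim$counts), sim$design)
  cats <- grn_classify(fit)
  expect_identical(nrow(cats), 120L)
  expect_true(all(cats$category %in% grn_categories()))
  s <- summary(cats)
  expect_identical(sum(s$n_genes), nrow(cats))
  expect_identical(nrow(s), 12L)
})

test_that("evolutionary labels appear only for DP genes with a designated ancestor", {
  sim <- simulate_grn(grn_sim_config(n_genes = 150, genotypes = c("north", "south"),
                                     seed = 29))
  fit <- grn_fit(normalize_counts(sim$counts), sim$design,
                 grn_model_spec(reference_genotype = "south"))
  cats <- grn_classify(fit, ancestral = "south")
  expect_true("evo_pattern" %in% names(cats))
  expect_true(all(cats$evo_pattern[!cats$dp_flag] == "none"))

  expect_warning(cats2 <- grn_classify(fit, tau = 0.2), class = "grn_no_ancestral")
  expect_false("evo_pattern" %in% names(cats2))
})

test_that("category tables export with a per-category summary companion", {
  sim <- simulate_grn(grn_sim_config(n_genes = 40, seed = 3))
  fit <- grn_fit(normalize_counts(sim$counts), sim$design)
  cats <- grn_classify(fit)
  path <- file.path(withr::local_tempdir(), "categories.tsv")
  paths <- write_categories(cats, path)
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(path)
  expect_identical(nrow(back), nrow(cats))
  smry <- utils::read.delim(sub("\\.tsv$", "_summary.tsv", path))
  expect_identical(sum(smry$n_genes), nrow(cats))
})
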