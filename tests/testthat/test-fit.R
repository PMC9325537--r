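test_that("design validation enforces the three-environment rule for curvature", {
  d2 <- toy_design(env = c(0, 1))
  f <- validate_design(d2, grn_model_spec(env_coding = "quadratic"))
  expect_true(any(f$level == "error" &
                    grepl("nonlinear reaction norm unidentifiable", f$message)))

  d3 <- toy_design(env = c(0, 1, 2))
  f3 <- validate_design(d3, grn_model_spec(env_coding = "quadratic"))
  expect_false(any(grepl("unidentifiable", f3$message)))
  expect_false(any(f3$level == "error"))
})

test_that("a single-genotype design is rejected for the basic model", {
  d <- toy_design(genotypes = "only")
  f <- validate_design(d, grn_model_spec())
  expect_true(any(f$level == "error" & grepl("G and GxE", f$message)))
})

test_that("empty genotype-by-environment cells raise a warning finding", {
  d <- toy_design(reps = 1)
  d <- d[!(d$genotype == "red" & d$environment == 2), ]
  d <- rbind(d, d[1, ])  # keep enough samples for the rank check
  d$sample_id <- paste0("s", seq_len(nrow(d)))
  f <- validate_design(d, grn_model_spec())
  expect_true(any(f$level == "warning" & grepl("no observations", f$message)))
})

test_that("noise-free coefficients are recovered exactly under the intercept convention", {
  d <- toy_design(genotypes = c("blue", "red"), env = c(0, 1, 2), reps = 2)
  Y <- one_gene_matrix(d, c(blue = 5, red = 6), c(blue = 1, red = -1))
  fit <- grn_fit(Y, d, grn_model_spec(reference_genotype = "blue"))
  co <- coef(fit)["g1", ]
  expect_equal(unname(co[["(Intercept)"]]), 5, tolerance = 1e-10)
  expect_equal(unname(co[["genotypered"]]), 1, tolerance = 1e-10)
  expect_equal(unname(co[["env"]]), 1, tolerance = 1e-10)
  expect_equal(unname(co[["genotypered:env"]]), -2, tolerance = 1e-10)
  expect_equal(fitted(fit), Y, tolerance = 1e-10)
  expect_equal(unname(residuals(fit)), matrix(0, 1, 12), tolerance = 1e-10)
})

test_that("a balanced batch offset is absorbed without disturbing the biology", {
  d <- toy_design(genotypes = c("blue", "red"), env = c(0, 1, 2), reps = 2,
                  batches = 2)
  Y <- one_gene_matrix(d, c(blue = 5, red = 6), c(blue = 1, red = -1))
  Y <- Y + 0.3 * (d$batch == "b2")[col(Y)]
  fit <- grn_fit(Y, d, grn_model_spec(reference_genotype = "blue"))
  co <- coef(fit)["g1", ]
  expect_equal(unname(co[["(Intercept)"]]), 5, tolerance = 1e-10)
  expect_equal(unname(co[["genotypered"]]), 1, tolerance = 1e-10)
  expect_equal(unname(co[["env"]]), 1, tolerance = 1e-10)
  expect_equal(unname(co[["genotypered:env"]]), -2, tolerance = 1e-10)
  expect_equal(unname(co[["batchb2"]]), 0.3, tolerance = 1e-10)
})

test_that("coefficients match the normal-equations oracle on random small designs", {
  set.seed(202)
  for (i in 1:20) {
    G <- sample(2:3, 1)
    reps <- sample(1:2, 1)
    d <- toy_design(genotypes = paste0("g", seq_len(G)), env = c(0, 1, 2),
                    reps = reps, batches = sample(1:2, 1))
    expect_lte(nrow(d), 20)
    Y <- matrix(rnorm(3 * nrow(d)), 3,
                dimnames = list(paste0("gene", 1:3), d$sample_id))
    fit <- grn_fit(Y, d, grn_model_spec())
    X <- fit$X
    for (g in 1:3) {
      expect_equal(unname(coef(fit)[g, ]), unname(normal_eq_coef(X, Y[g, ])),
                   tolerance = 1e-8)
    }
  }
})

test_that("changing the reference genotype changes coefficients but not the fit", {
  sim <- simulate_grn(grn_sim_config(n_genes = 60, seed = 13))
  nm <- normalize_counts(sim$counts)
  f1 <- grn_fit(nm, sim$design, grn_model_spec(reference_genotype = "G1"))
  f2 <- grn_fit(nm, sim$design, grn_model_spec(reference_genotype = "G3"))
  expect_false(isTRUE(all.equal(coef(f1), coef(f2), check.attributes = FALSE)))
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-9)
  for (tm in c("G", "E", "GxE")) {
    expect_equal(f1$tests[[tm]]$F, f2$tests[[tm]]$F, tolerance = 1e-9)
    expect_equal(f1$tests[[tm]]$p, f2$tests[[tm]]$p, tolerance = 1e-9)
  }
})

test_that("per-term q-values are monotone in p-values within a term", {
  sim <- simulate_grn(grn_sim_config(n_genes = 120, seed = 23))
  fit <- grn_fit(normalize_counts(sim$counts), sim$design)
  for (tm in names(fit$tests)) {
    tt <- fit$tests[[tm]]
    ord <- order(tt$p)
    expect_true(all(diff(tt$q[ord]) >= -1e-12))
  }
})

test_that("a constant gene is flagged and its tests are undefined, not dropped", {
  d <- toy_design(reps = 2)
  Y <- rbind(
    flat = rep(3, nrow(d)),
    ok = rnorm(nrow(d))
  )
  colnames(Y) <- d$sample_id
  fit <- grn_fit(Y, d, grn_model_spec())
  expect_true(fit$flagged[["flat"]])
  expect_false(fit$flagged[["ok"]])
  expect_true(all(is.na(fit$tests$G["flat", c("F", "p", "q")])))
  expect_false(anyNA(fit$tests$G["ok", c("F", "p")]))
  expect_identical(nrow(coef(fit)), 2L)
})

# ---- nested model -----------------------------------------------------------

test_that("collapsing upper groups to one level reproduces the basic fit", {
  d <- toy_design(genotypes = c("f1", "f2", "f3"), reps = 2)
  d$upper_genotype <- "pop1"
  Y <- matrix(rnorm(4 * nrow(d)), 4,
              dimnames = list(paste0("g", 1:4), d$sample_id))
  basic <- grn_fit(Y, d, grn_model_spec("basic"))
  nested <- grn_fit(Y, d, grn_model_spec("nested"))
  expect_equal(fitted(nested), fitted(basic), tolerance = 1e-9)
  # within-group term carries the genotype structure; upper terms are empty
  expect_equal(nested$tests$GiGj$F, basic$tests$G$F, tolerance = 1e-9)
  expect_equal(nested$tests$GiGjxE$F, basic$tests$GxE$F, tolerance = 1e-9)
  expect_equal(nested$tests$E$F, basic$tests$E$F, tolerance = 1e-9)
  expect_true(all(is.na(nested$tests$Gj$F)))
})

test_that("nested noise-free construction recovers upper-group slope differences", {
  genos <- c("a1", "a2", "b1", "b2")
  d <- toy_design(genotypes = genos, env = c(0, 1, 2), reps = 2)
  d$upper_genotype <- ifelse(d$genotype %in% c("a1", "a2"), "A", "B")
  # upper groups differ only in slope (delta = 1.5); no within-group variation
  slope <- ifelse(d$upper_genotype == "A", 0.5, 2.0)
  y <- 4 + slope * d$environment
  Y <- matrix(y, 1, dimnames = list("g1", d$sample_id))
  fit <- grn_fit(Y, d, grn_model_spec("nested", reference_genotype = "a1"))
  co <- coef(fit)["g1", ]
  expect_equal(unname(co[["upperB:env"]]), 1.5, tolerance = 1e-9)
  expect_equal(unname(co[["env"]]), 0.5, tolerance = 1e-9)
  within_cols <- grep("^genotype", names(co), value = TRUE)
  expect_equal(unname(co[within_cols]), rep(0, length(within_cols)),
               tolerance = 1e-9)
})

test_that("upper-group intercept differences land on the upper term only", {
  genos <- c("a1", "a2", "b1", "b2")
  d <- toy_design(genotypes = genos, env = c(0, 1, 2), reps = 2)
  d$upper_genotype <- ifelse(d$genotype %in% c("a1", "a2"), "A", "B")
  y <- 4 + 0.8 * (d$upper_genotype == "B")
  Y <- matrix(y, 1, dimnames = list("g1", d$sample_id))
  fit <- grn_fit(Y, d, grn_model_spec("nested", reference_genotype = "a1"))
  co <- coef(fit)["g1", ]
  expect_equal(unname(co[["upperB"]]), 0.8, tolerance = 1e-9)
  within_cols <- setdiff(grep("^genotype", names(co), value = TRUE),
                         grep(":", names(co), value = TRUE))
  expect_equal(unname(co[within_cols]), rep(0, length(within_cols)),
               tolerance = 1e-9)
})

test_that("a genotype in two upper groups is a design error", {
  d <- toy_design(genotypes = c("f1", "f2"), reps = 2)
  d$upper_genotype <- ifelse(seq_len(nrow(d)) %% 2 == 0, "A", "B")
  f <- validate_design(d, grn_model_spec("nested"))
  expect_true(any(f$level == "error" & grepl("multiple upper groups", f$message)))
})

# ---- architecture model -----------------------------------------------------

arch_design <- function() {
  d <- toy_design(genotypes = c("p1", "p2", "p3", "p4"), env = c(0, 1, 2), reps = 2)
  d$snp_group <- ifelse(d$genotype %in% c("p1", "p2"), "snpA", "snpB")
  d$sv_group <- ifelse(d$genotype %in% c("p1", "p3"), "svA", "svB")
  d
}

test_that("a constant SV grouping reduces the architecture model to the SNP terms", {
  d <- arch_design()
  d$sv_group <- "sv0"
  y <- 3 + 1.2 * (d$snp_group == "snpB") + 0.4 * d$environment
  Y <- matrix(y, 1, dimnames = list("g1", d$sample_id))
  fit <- grn_fit(Y, d, grn_model_spec("architecture"))
  co <- coef(fit)["g1", ]
  expect_equal(unname(co[["snpsnpB"]]), 1.2, tolerance = 1e-9)
  expect_equal(unname(co[["env"]]), 0.4, tolerance = 1e-9)
  expect_true(all(is.na(fit$tests$Gsv$F)))
  expect_true(all(is.na(fit$tests$GsvxE$F)))
})

test_that("orthogonal SNP/SV groupings recover additive effects exactly", {
  d <- arch_design()  # snp and sv groupings are crossed (orthogonal)
  y <- 3 + 1.0 * (d$snp_group == "snpB") + 0.5 * (d$sv_group == "svB") +
    0.4 * d$environment + 0.2 * d$environment * (d$sv_group == "svB")
  Y <- matrix(y, 1, dimnames = list("g1", d$sample_id))
  fit <- grn_fit(Y, d, grn_model_spec("architecture"))
  co <- coef(fit)["g1", ]
  expect_equal(unname(co[["snpsnpB"]]), 1.0, tolerance = 1e-9)
  expect_equal(unname(co[["svsvB"]]), 0.5, tolerance = 1e-9)
  expect_equal(unname(co[["svsvB:env"]]), 0.2, tolerance = 1e-9)
  expect_equal(unname(co[["snpsnpB:env"]]), 0, tolerance = 1e-9)
})

test_that("perfectly confounded groupings are reported aliased, not crashed", {
  d <- arch_design()
  d$sv_group <- d$snp_group
  Y <- matrix(rnorm(nrow(d)), 1, dimnames = list("g1", d$sample_id))
  expect_warning(
    fit <- grn_fit(Y, d, grn_model_spec("architecture")),
    NA
  )
  expect_true(any(grepl("^Gsv", fit$aliased_terms)))
  expect_true(all(is.na(fit$tests$Gsv$F)))
  # the SV coefficient columns are the ones dropped; SNP effects stay estimable
  expect_true(all(is.na(coef(fit)[, grep("^sv", colnames(coef(fit)))])))
  expect_false(anyNA(coef(fit)[, grep("^snp", colnames(coef(fit)))]))
  # the confounded genotype axis leaves neither grouping separately testable,
  # but the environment term is untouched
  expect_false(anyNA(fit$tests$E$F))
})

test_that("predict reproduces fitted values and extends to new design points", {
  d <- toy_design(reps = 2)
  Y <- one_gene_matrix(d, c(blue = 5, red = 6), c(blue = 1, red = -1))
  fit <- grn_fit(Y, d, grn_model_spec(reference_genotype = "blue"))
  expect_equal(predict(fit), fitted(fit))
  nd <- toy_design(reps = 1)
  nd$environment <- nd$environment + 0.5
  pr <- predict(fit, nd)
  manual <- 5 + 1 * nd$environment
  manual[nd$genotype == "red"] <- 6 - nd$environment[nd$genotype == "red"]
  expect_equal(unname(pr["g1", ]), unname(manual), tolerance = 1e-9)
})
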