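---
title: "Genomic reaction norms: models, classification and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic reaction norms: models, classification and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnorm)
```

## The problem

A genomic reaction norm treats each gene's expression level as a phenotype
measured along an environmental gradient: for every genotype unit (a strain,
family, population or species reared in a common garden), the gene has an
intercept and a slope on the log2 expression scale. Comparing these norms
across genotypes separates three biologically distinct signals:

* **differential expression (DE)** — genotypes differ in mean expression
  across environments (a genotype main effect, `V_G`);
* **plasticity** — expression changes along the gradient (an environment
  effect, `V_E`; a nonzero slope);
* **differential plasticity (DP)** — genotypes respond to the environment
  differently (a genotype-by-environment interaction, `V_G×E`; a slope
  difference).

`grnorm` fits this decomposition gene by gene, reports each term's test,
builds the per-genotype reaction norms, and classifies every gene into one of
twelve canonical expression patterns plus, optionally, an evolutionary
sub-pattern (genetic compensation, genetic assimilation, reversal).

## The per-gene model

For gene $g$ with normalized log2 expression $y$, the basic model is ordinary
least squares with fixed effects

$$ y = \mu + G + E + G{\times}E + B + \varepsilon, $$

where $G$ is the genotype unit, $E$ the (numeric) environment, $G\times E$
their interaction and $B$ the batch. Two extensions re-partition the genotype
axis: a *nested* model (upper-scale group, genotype within group, and both
interaction tiers) for designs spanning multiple levels of biological
organization, and an *architecture* model (SNP-cluster and structural-variant
groupings with their environment interactions) for designs where population
structure has been characterized from the sequence data itself.

Each term is tested with a partial F-test (full model versus the model with
that term's columns removed), and p-values are converted to q-values by
Benjamini–Hochberg across genes *within each term* — gene lists are obtained
per model term, not pooled across terms.

### The intercept convention and test parameterizations

Coefficients are reported under an explicit model-intercept convention: the
reference genotype at the reference environment (by default the minimum
observed level), so every sign reads as "relative to the reference genotype
at the low end of the gradient". Two tests, however, are not invariant to
that parameterization once interactions are present, and are deliberately
computed under equivalent reparameterizations of the same fitted model:

* the genotype-type main-effect tests use mean-centered environment columns,
  because DE is defined with respect to *mean expression across all
  environments* — under the reference parameterization the test would instead
  compare genotypes at the low-environment end only;
* the environment main-effect test uses mean-centered genotype dummies in the
  interaction block, so that it targets the *across-genotype average*
  response. Under treatment coding it would test the reference genotype's
  slope, and a gene whose genotypes respond in exactly opposite directions
  would be called "plastic" even though the average response is flat.

Both reparameterizations leave fitted values, residuals and the interaction
tests identical; only the meaning of the tested main effect changes. This is
why the package's DE/plasticity flags agree with the noise-free
classification rule used by the simulator.

### Why batch is a fixed effect

Batch is conceptually a random nuisance (sequencing run, tank, block), but
these designs typically have two to four batches; per-gene REML estimates of
a variance component from so few levels are unstable, so `grnorm` fits batch
as a fixed effect. The trade-off: one degree of freedom per extra batch
level, in exchange for exact per-term F-tests. Similarly, expression is
modelled by OLS on log2 normalized values rather than a count GLM — the
limma-style workflow — which keeps the per-term partial F-tests exact;
precision weighting and empirical-Bayes variance moderation are deliberately
out of scope.

## Normalization

Size factors are median-of-ratios: each sample's factor is the median, over
zero-free reference genes, of its count divided by the gene's geometric mean
across samples; factors are rescaled to geometric mean 1, and expression is
log2 counts-per-million after size-factor correction with a pseudocount of
0.5 on the count scale. If no gene is zero-free the package falls back to
total-count factors with a warning. Users with their own normalization can
pass a log2 matrix directly to `grn_fit()`.

## The twelve categories

Published pattern taxonomies present twelve panels of reaction-norm shapes
but do not state the grid axes; the only 2×2×3 factorization consistent with
the DE/plastic/DP vocabulary is

$$\{\text{DE no/yes}\} \times \{\text{DP no/yes}\} \times
  \{\text{mean direction up/down/none}\},$$

which `grnorm` adopts as its canonical grid (`grn_category_info()`); it makes
no claim of letter-for-letter correspondence with any published panel
lettering. The mean environmental direction is the sign of the
across-genotype mean slope when the environment term is significant; for a
differentially plastic gene whose environment term is not significant, the
direction is assigned only when the mean slope exceeds twice its standard
error (and a numeric floor of 1e-8). A fixed numeric tolerance would mislabel
essentially every opposite-slope gene under noise, while the 2-SE rule is
exact at zero noise and calibrated (~5% error) under noise.

DE magnitudes use environment-averaged mean expression rather than the
intercept, so they are invariant to the reference-environment choice; DP
magnitudes are slope differences. With slopes $+s$ and $-s$ the DP magnitude
is $2s$; with same-sign slopes it is the difference of the slope magnitudes.
With more than two genotypes the category table reports the average of the
pairwise comparisons against the reference genotype; `compute_de_dp()` gives
any single pair.

## Evolutionary sub-patterns

For differentially plastic genes with a user-designated ancestral-proxy
genotype, the package distinguishes:

* **reversal** — strictly opposite-sign slopes;
* **genetic assimilation** — the derived genotype has lost the plastic
  response and constitutively expresses the level the ancestral norm reaches
  at the *derived*-environment end of the gradient;
* **genetic compensation** — the derived genotype has lost the response but
  holds the ancestral level at the *ancestral*-environment end (its intercept
  offset opposes the plastic direction).

The source concepts are qualitative; the quantitative rules here are this
package's operationalization and are controlled by a tolerance `tau`
(log2 units), defaulting to 25% of the ancestral plastic change over the
observed range. Slopes are compared against `tau / range` so that the two
thresholds describe the same expression-scale quantity. When a near-flat
derived norm matches both ends within `tau`, the closer end wins; an exact
tie is left unlabelled. An ancestor with no plastic response defines no
pattern. These labels are heuristics for hypothesis generation, not tests.

## The simulator

`simulate_grn()` emulates a factorial common-garden-gradient experiment —
genotype units × environment levels × replicates × batches, by default a
3 × 3 design with 4 replicates and 2 balanced batches — with counts drawn
from a negative binomial whose log2 mean is
`intercept(genotype) + slope(genotype)·env + batch offset + log2(library factor)`.
Gene-wise dispersions are log-normal (median 0.1), library-size factors
log-normal, and batch offsets gene-shared Gaussian shifts — the de facto
standard generative model for bulk RNA-seq.

Effects are assigned category-first: each gene draws one of the twelve
categories (by default a third of genes are null and the rest spread evenly),
then coefficients realizing that pattern. Effect-size conventions:

* `effect_size_slope` (0.5 log2/env unit) is the across-genotype mean slope
  of directional genes;
* `effect_size_dp` (0.5) is each affected genotype's slope *deviation* from
  the mean slope, assigned as a centered ±1 pattern over genotypes — so the
  opposite-slope pattern is slopes $\pm s$ with $s$ = `effect_size_dp`,
  matching how the DP-magnitude-equals-$2s$ arithmetic is usually presented;
* `effect_size_de` (1.0) is likewise each affected genotype's deviation in
  environment-averaged mean expression. Intercepts are back-computed from the
  target means, so DP-only genes have genuinely equal genotype means (their
  norms cross mid-gradient) and DE flags stay orthogonal to DP flags.

Baseline log2 means are uniform on [2, 12]. No published effect-size
distribution exists for these defaults; they are documented placeholders
representing a well-powered bulk experiment, not empirical claims. The
simulator guarantees that applying the classifier's noise-free rule to the
true coefficients reproduces every assigned label (it is checked at
generation time), which is what makes end-to-end recovery measurable.

What the simulator does *not* emulate: read-level artifacts, UMI/single-cell
zero inflation, correlated genes (each gene is independent), environment-
dependent dispersion, and unbalanced designs. Passing recovery tests on this
generator therefore demonstrates the correctness and calibration of the
pipeline's statistics, not robustness to every pathology of real data.

## Numerical choices and degenerate inputs

* All genes share one model matrix; fits are one multi-response QR
  least-squares pass, and partial F-tests reuse the full-model residual sum
  of squares. On any small instance the coefficients agree with a
  normal-equations solve to well below 1e-8.
* Constant (zero-variance) genes are flagged and their tests reported as
  `NA`; they are never silently dropped. Variance fractions for such genes
  are `NA`.
* Aliased columns (e.g. a structural-variant grouping perfectly confounded
  with the SNP grouping) are detected by QR pivoting; the aliased term's
  coefficients and test are reported as undefined while the rest of the model
  remains usable.
* Variance partitioning uses sequential (type-I) sums of squares in the fixed
  order genotype terms, environment, interaction terms, batch; the telescoping
  identity makes fractions sum to 1 exactly (machine precision).
* Quadratic environment coding requires at least three distinct environment
  levels — with two, linear and curved norms are indistinguishable — and
  `validate_design()` reports this as an identifiability error before any
  fitting happens.
* The size-factor estimator is defined only up to a global rescaling; the
  geometric-mean-1 convention pins it down. Consequently, multiplying one
  sample's counts by a constant scales its size factor *relative to the other
  samples* by exactly that constant, while all normalized values are
  unchanged up to the (vanishing at high counts) pseudocount effect.

## Problem sizes used in the tests

The bundled checks run the full pipeline on simulated experiments of 1,500 to
2,000 genes under the default 3 × 3 × 4 design (36 samples): null-calibration
checks use 2,000 genes over three seeds, recovery checks 1,500 genes, the
variance-decomposition identity 400 genes, and permutation calibration 500
replicate feature/fitness draws at 199 permutations each. These sizes give
Monte-Carlo error comfortably below the tolerances being asserted while
keeping a complete run in the tens of seconds on a single core.

## Known limitations

* Random-effect/REML batch handling, dispersion shrinkage and spline-shaped
  norms are out of scope by design.
* Reaction norms (and hence classification) require a numeric environment
  coding; categorical environments can be fitted and tested but not reduced
  to slopes, and a design with a single genotype cannot be fitted at all
  (the genotype and interaction terms would be undefined).
* The co-expression module summaries are correlation-distance hierarchical
  clusters with eigengene scores — a deliberately minimal stand-in for full
  weighted network analysis, sufficient for refitting module summaries as
  reaction norms but silent on network topology.
* Statistical power at the default effect sizes is limited for
  genotype-by-environment effects in weakly expressed genes (baseline log2
  mean below ~4); with 4 replicates per cell, DP detection at q < 0.05
  reaches ~85% for well-expressed genes but drops steeply with expression,
  so overall category recovery on simulated data plateaus around 80%.
  Deeper replication (or variance moderation, deliberately not implemented)
  is required to push per-category recovery higher.

## A worked example

```{r example, eval = FALSE}
library(grnorm)

sim <- simulate_grn(grn_sim_config(n_genes = 500, seed = 7))
norm <- normalize_counts(sim$counts)
fit <- grn_fit(norm, sim$design)
summary(fit)

cats <- grn_classify(fit)
summary(cats)

vp <- variance_partition(fit)
colMeans(vp, na.rm = TRUE)

plot(fit, gene = which.max(cats$dp_magnitude))
```

The same pipeline runs from the shell via the bundled driver:

```sh
Rscript inst/exec/grn run-all --out results_dir --seed 7
```
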