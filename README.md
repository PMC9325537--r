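# grnorm — genomic reaction norms from common-garden gene expression

`grnorm` is an R toolkit for analysing gene expression measured across
genotype units (strains, families, populations, species) reared along a
controlled environmental gradient — the common-garden-gradient design. It
treats every gene's expression as a phenotype with its own reaction norm (an
intercept and slope of log2 expression over the environment, per genotype)
and decomposes expression variance gene by gene as

```
V_Px = V_G + V_E + V_G×E + B + ε
```

where `V_G` is genotype (differential expression, DE), `V_E` environment
(plasticity), `V_G×E` their interaction (differential plasticity, DP), and
`B` batch. Nested (`V_Gi(Gj)`) and genomic-architecture (`V_Gsnp` / `V_Gsv`)
variants re-partition the genotype axis. On top of the per-gene fits the
package:

* builds per-genotype reaction norms and DE/DP directions and magnitudes
  under an explicit model-intercept convention (reference genotype at the
  low-environment end);
* classifies every gene into one of **twelve canonical expression patterns**
  ({DE no/yes} × {DP no/yes} × {mean response up/down/none});
* labels differentially plastic genes with evolutionary sub-patterns —
  genetic compensation, genetic assimilation, reversal — relative to a
  designated ancestral-proxy genotype;
* partitions each gene's variance across model terms, summarizes
  co-expression modules as eigengenes refittable as module-level reaction
  norms, and correlates reaction-norm features with fitness phenotypes by
  permutation;
* ships a negative-binomial simulator of the whole design with known
  per-gene truth, so every stage is testable without external data.

Who it is for: eco-evolutionary and molecular ecologists running (or
planning) common-garden RNA-seq experiments who want per-gene G / E / G×E
inference and pattern classification rather than pairwise contrasts.

## Worked example

```r
library(grnorm)

sim  <- simulate_grn(grn_sim_config(n_genes = 500, seed = 7))  # 3x3x4 design
norm <- normalize_counts(sim$counts)          # median-of-ratios log2 CPM
fit  <- grn_fit(norm, sim$design)             # per-gene OLS + partial F-tests
summary(fit)
#> Reaction-norm fit (basic model): 500 genes, 36 samples
#> genes with term q < 0.05:
#>   G   E GxE
#> 195 247 148
```

195 genes are differentially expressed (genotype term), 247 plastic
(environment term) and 148 differentially plastic (interaction term) at
FDR 0.05. Classification turns the flags into pattern categories:

```r
cats <- grn_classify(fit)
summary(cats)
#>           category n_genes
#> 1             null     162
#> 2       plastic_up      27
#> 3     plastic_down      47
#> 4     dp_mean_none      19
#> 5       dp_mean_up      33
#> 6     dp_mean_down      17
#> 7               de      43
#> 8    de_plastic_up      38
#> 9  de_plastic_down      35
#> 10 de_dp_mean_none      26
#> 11   de_dp_mean_up      27
#> 12 de_dp_mean_down      26
```

Per-gene rows carry the flags, directions and log2-scale magnitudes, e.g.

```r
as.data.frame(cats)[cats$gene_id == "gene00012", ]
#>    gene_id de_flag plastic_flag dp_flag de_direction de_magnitude
#>  gene00012   FALSE        FALSE   FALSE            -        0.247
#>  mean_env_direction dp_direction dp_magnitude category
#>                none            +       0.0323     null
```

and the average variance decomposition across genes:

```r
round(colMeans(variance_partition(fit), na.rm = TRUE), 3)
#>        G        E      GxE        B residual
#>    0.259    0.137    0.095    0.016    0.493
```

`plot(fit, gene = "gene00012")` draws the gene's data and fitted norms, one
colour per genotype. With an ancestral proxy,
`grn_classify(fit, ancestral = "G1")` adds the
compensation/assimilation/reversal column. The same pipeline runs from the
shell:

```sh
Rscript inst/exec/grn run-all --out results_dir --seed 7
```

writing counts, design, normalized values, gene fits, variance fractions,
category tables and a machine-readable `manifest.json`.

See `vignettes/genomic-reaction-norms.Rmd` for the model, the intercept
convention, classification rules, simulator conventions and limitations.

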