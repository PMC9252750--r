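# pcga — phenotype-cell-gene association analysis

Most GWAS hits for complex traits fall in non-coding DNA, which leaves two
questions open: *which genes* do the associated variants act through, and
*in which tissues or cell types* does that regulation matter? `pcga`
answers both jointly from nothing more than GWAS summary statistics
(chromosome, position, P-value per variant), a reference genotype panel for
linkage disequilibrium (LD), and reference expression panels of tissues and
cell types. It is aimed at statistical geneticists and functional-genomics
analysts who want a scriptable, fully offline implementation of the
DESE strategy (driver-tissue estimation by selective expression) with a
hierarchical tissue → cell-type stage.

## The method in brief

**Gene-based association (ECS).** Each variant P-value is converted to a
1-df chi-square statistic `q_i`, and a gene's evidence is the sum
`S = Σ q_i` over its variants. Under the null, using
`cov(q_i, q_j) ≈ 2 r_ij²` for LD correlation `r_ij` estimated from the
reference panel, `S` has mean `μ = m` and variance `σ² = 2 Σ_ij r_ij²`.
Referring `S/a` to a chi-square with `d = 2μ²/σ²` degrees of freedom,
`a = σ²/(2μ)`, removes redundant (LD-duplicated) associations: a gene made
of `m` perfect copies of one variant scores exactly like the single
variant.

**Selective expression (REZ).** For each panel column *t*, the gene-wise
response `log2(CPM_t + 1)` is regressed on the leave-one-out median across
all other columns with a Huber robust fit; the standardized residual
`z[g, t]` (MAD scale) measures how selectively gene *g* is expressed in
column *t*.

**Driver estimation (DESE).** Associated genes (FDR < 0.05, with a floor of
the 10 smallest P-values) are tested for *greater* selective expression in
every column by a one-sided Wilcoxon rank-sum test; the candidate genes
are then re-tested conditionally, discounting each variant's chi-square by
`(1 − max r²)` against the variants of the retained genes, ordered by
selective expression in the top-ranked column. Enrichment ranking and
conditional re-testing alternate until the associated set is stable.

**Hierarchy.** Stage 1 ranks bulk tissues; the organs of the significant
tissues (FDR < 0.05) then restrict the cell-type panel for stage 2, or the
user names the organs directly.

The package also builds the reference panels themselves (CPM + TMM +
tissue averaging for bulk counts; UMI/cluster filtering, top-10%
pseudobulk aggregation and homolog mapping for single-cell counts),
computes landscape statistics (hypergeometric category enrichment, Jaccard
phenotype similarity), and ships a seed-deterministic synthetic-data
generator so the whole pipeline runs and is tested without any download.

## Worked example

Simulate the standard study condition — one driver tissue whose 25 causal
genes carry both GWAS signal and selective expression — and recover it:

```r
library(pcga)
cfg <- simulation_config(seed = 42, n_tissues = 12, n_genes = 400,
                         n_causal = 25, n_samples = 300)
geno  <- simulate_genotypes(cfg)
truth <- simulate_expression(cfg)
ct    <- simulate_celltype_expression(cfg, truth)
gwas  <- simulate_gwas(cfg, geno, truth$causal_genes)
res <- hierarchical_estimate(gwas, geno$panel, geno$genes,
                             truth$panel, ct$panel)

truth$driver
#> [1] "tissue_08"
head(res$tissue_run$tissue_table, 3)
#>      column statistic       pvalue          fdr   bonferroni rank
#> 1 tissue_08      9843 2.304484e-16 2.765381e-15 2.765381e-15    1
#> 2 tissue_12      5749 1.737600e-01 8.444378e-01 1.000000e+00    2
#> 3 tissue_03      5671 2.111094e-01 8.444378e-01 1.000000e+00    3
res$organs
#> [1] "organ_08"
head(res$celltype_run$tissue_table, 3)
#>         column statistic       pvalue          fdr   bonferroni rank
#> 1 organ_08_ct1      9924 7.074308e-17 2.122292e-16 2.122292e-16    1
#> 2 organ_08_ct2      2570 9.999982e-01 1.000000e+00 1.000000e+00    2
#> 3 organ_08_ct3      1627 1.000000e+00 1.000000e+00 1.000000e+00    3
```

The planted driver tissue is ranked first with Wilcoxon enrichment
P = 2.3 × 10⁻¹⁶, its organ alone is carried into stage 2, and the driver
cell type within that organ is ranked first. The gene table prioritizes
the susceptibility genes with their LD-corrected and conditional P-values:

```r
head(res$celltype_run$gene_table[, c("symbol", "n_variants", "pvalue",
                                     "conditional_pvalue", "fdr")], 5)
#>     symbol n_variants       pvalue conditional_pvalue          fdr
#> 1 gene0397          5 1.931356e-32       1.931356e-32 7.725423e-30
#> 2 gene0026          5 5.294993e-32       5.294993e-32 1.058999e-29
#> 3 gene0348          5 1.399538e-30       1.399538e-30 1.866050e-28
#> 4 gene0195          5 4.391868e-30       4.391868e-30 4.391868e-28
#> 5 gene0054          5 1.644391e-29       1.644391e-29 1.315512e-27
sum(res$celltype_run$gene_table$fdr < 0.05)
#> [1] 26
```

26 genes pass FDR < 0.05; all 25 planted causal genes are among them.

The same pipeline is available from the shell via the bundled script
(`system.file("cli", "pcga.R", package = "pcga")`), with subcommands
`simulate`, `build-panel`, `rez`, `gene-assoc`, `assoc`, `enrich` and
`similarity`; outputs are plain TSV/JSON and byte-reproducible for a given
seed.

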