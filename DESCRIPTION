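Package: pcga
Title: Phenotype-Cell-Gene Association Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly estimates phenotype-associated tissues, cell types and
    susceptibility genes from genome-wide association study (GWAS) summary
    statistics and reference expression panels. Implements the DESE strategy
    (driver-tissue estimation by selective expression): an effective
    chi-square (ECS) gene-based test with linkage-disequilibrium correction
    from a reference genotype panel, robust-regression Z-score (REZ)
    selective-expression profiles, Wilcoxon rank-sum tissue enrichment, and
    iterative selective-expression-guided conditional gene analysis, plus a
    hierarchical tissue-to-cell-type estimation stage. Includes reference
    expression-panel construction from bulk counts (CPM, trimmed mean of
    M-values, tissue averaging) and single-cell UMI counts (cell and cluster
    filtering, pseudobulk aggregation, homolog mapping), landscape statistics
    (hypergeometric category enrichment, Jaccard phenotype similarity), and a
    seed-deterministic synthetic-data generator for LD-structured genotype
    panels, driver-tissue expression panels, single-cell counts and GWAS
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    MASS,
    Matrix,
    edgeR,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
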