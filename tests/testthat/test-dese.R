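test_that("exact rank-sum enumeration handles extreme and tied labelings", {
  # 3 associated genes holding the 3 largest scores among 6: 1 / C(6,3)
  res <- wilcox_rank_p(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res$pvalue, 1 / choose(6, 3))
  # complete ties: no evidence of enrichment
  expect_equal(wilcox_rank_p(rep(1, 4), rep(1, 5))$pvalue, 1)
  # mid-range labeling agrees with the subset-loop oracle
  x <- c(3, 7, 2); y <- c(5, 1, 4, 6)
  expect_equal(wilcox_rank_p(x, y)$pvalue, oracle_wilcox_greater(x, y))
  # ties, exact branch, against the same oracle
  x2 <- c(2, 2, 5); y2 <- c(1, 2, 3, 5)
  expect_equal(wilcox_rank_p(x2, y2)$pvalue, oracle_wilcox_greater(x2, y2))
})

test_that("the normal-approximation branch matches wilcox.test", {
  set.seed(71)
  x <- rnorm(12, 0.5)
  y <- rnorm(30)
  got <- wilcox_rank_p(x, y)
  ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(got$pvalue, ref$p.value, tolerance = 1e-12)
  # all tied in the large-sample branch
  expect_equal(wilcox_rank_p(rep(2, 20), rep(2, 20))$pvalue, 1)
})

test_that("enrichment rejects degenerate associated sets", {
  z <- make_cpm(n_genes = 20, n_cols = 3)
  expect_error(wilcoxon_enrichment(character(), z, 1),
               class = "pcga_error_degenerate_groups")
  expect_error(wilcoxon_enrichment(rownames(z), z, 1),
               class = "pcga_error_degenerate_groups")
})

test_that("column ranking orders by P-value with adjusted columns", {
  spiked <- sprintf("g%03d", 1:6)
  z <- rez_scores(make_cpm(n_genes = 80, n_cols = 6, seed = 8,
                           spike = list(genes = spiked, col = "col03",
                                        factor = 20)))
  tab <- tissue_enrichment(spiked, z)
  expect_identical(tab$column[1], "col03")
  expect_identical(tab$rank, seq_len(ncol(z)))
  expect_true(all(tab$fdr >= tab$pvalue))
  expect_true(all(tab$bonferroni >= tab$fdr - 1e-15))
  expect_true(!is.unsorted(tab$pvalue))
})

small_run <- function(seed = 81, boost = 2, max_iter = 10) {
  cfg <- simulation_config(seed = seed, n_tissues = 8, n_genes = 120,
                           n_causal = 12, n_samples = 150, boost = boost)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_expression(cfg)
  gwas <- simulate_gwas(cfg, geno, truth$causal_genes)
  ga <- gene_assoc_scan(gwas, geno$panel, geno$genes)
  run <- dese_iterate(ga, rez_scores(truth$panel), geno$panel,
                      dese_config(max_iter = max_iter))
  list(cfg = cfg, truth = truth, run = run, ga = ga, geno = geno)
}

test_that("a stable associated set converges in two iterations", {
  fx <- small_run()
  expect_true(fx$run$converged)
  expect_gte(fx$run$n_iterations, 2)
  last <- fx$run$iterations[[fx$run$n_iterations]]$assoc_genes
  prev <- fx$run$iterations[[fx$run$n_iterations - 1]]$assoc_genes
  expect_setequal(last, prev)
  expect_identical(fx$run$tissue_table$column[1], fx$truth$driver)
})

test_that("a single iteration cannot be declared converged", {
  fx <- small_run(max_iter = 1)
  expect_false(fx$run$converged)
  expect_equal(fx$run$n_iterations, 1)
})

test_that("rerunning DESE on identical inputs reproduces identical results", {
  a <- small_run(seed = 82)
  b <- small_run(seed = 82)
  expect_identical(a$run, b$run)
})

test_that("the gene table carries FDR-adjusted conditional P-values", {
  fx <- small_run()
  gt <- fx$run$gene_table
  expect_true(all(gt$conditional_pvalue >= gt$pvalue - 1e-12))
  expect_true(all(gt$fdr >= gt$conditional_pvalue - 1e-15))
  sig <- gt$symbol[gt$fdr < 0.05]
  expect_gt(mean(fx$truth$causal_genes %in% sig), 0.8)
})

hier_fixture <- function(seed = 91, boost = 2) {
  cfg <- simulation_config(seed = seed, n_tissues = 8, n_genes = 120,
                           n_causal = 12, n_samples = 150, boost = boost)
  geno <- simulate_genotypes(cfg)
  truth <- simulate_expression(cfg)
  ct <- simulate_celltype_expression(cfg, truth)
  gwas <- simulate_gwas(cfg, geno, truth$causal_genes)
  list(cfg = cfg, geno = geno, truth = truth, ct = ct, gwas = gwas)
}

test_that("the hierarchy restricts stage 2 to organs of significant tissues", {
  fx <- hier_fixture()
  res <- hierarchical_estimate(fx$gwas, fx$geno$panel, fx$geno$genes,
                               fx$truth$panel, fx$ct$panel)
  expect_true(fx$truth$driver_organ %in% res$organs)
  used <- res$celltype_run$tissue_table$column
  organ_of <- fx$ct$panel$organ[match(used, colnames(fx$ct$panel$values))]
  expect_true(all(organ_of %in% res$organs))
  expect_identical(res$celltype_run$tissue_table$column[1],
                   fx$ct$driver_celltype)
})

test_that("a manual organ list overrides the automatic selection", {
  fx <- hier_fixture()
  res <- hierarchical_estimate(fx$gwas, fx$geno$panel, fx$geno$genes,
                               fx$truth$panel, fx$ct$panel,
                               organs = c("organ_01", "organ_02", "organ_03"))
  expect_identical(res$organs, c("organ_01", "organ_02", "organ_03"))
  used <- res$celltype_run$tissue_table$column
  expect_true(all(grepl("^organ_0[123]_", used)))
  expect_error(
    hierarchical_estimate(fx$gwas, fx$geno$panel, fx$geno$genes,
                          fx$truth$panel, fx$ct$panel,
                          organs = "no_such_organ"),
    class = "pcga_error_empty_subset")
})

test_that("without a significant tissue, stage 2 falls back to all cell types", {
  fx <- hier_fixture(seed = 92, boost = 0)
  expect_warning(
    res <- hierarchical_estimate(fx$gwas, fx$geno$panel, fx$geno$genes,
                                 fx$truth$panel, fx$ct$panel),
    class = "pcga_warning_fallback")
  expect_setequal(res$celltype_run$tissue_table$column,
                  colnames(fx$ct$panel$values))
})
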