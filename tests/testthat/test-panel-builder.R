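test_that("CPM normalization preserves proportions and rejects empty libraries", {
  m <- cbind(s1 = c(1, 3), s2 = c(5, 5))
  rownames(m) <- c("g1", "g2")
  out <- cpm_normalize(m)
  expect_equal(out[, "s1"], c(g1 = 250000, g2 = 750000))
  expect_equal(unname(out[, "s2"]), c(500000, 500000))

  u <- cbind(s1 = c(5, 5, 5, 5))
  expect_equal(unname(cpm_normalize(u)[, 1]), rep(250000, 4))

  bad <- cbind(ok = c(1, 1), empty = c(0, 0))
  err <- expect_error(cpm_normalize(bad), class = "pcga_error_zero_library_size")
  expect_match(conditionMessage(err), "empty")
})

test_that("CPM normalization is idempotent", {
  set.seed(11)
  m <- matrix(rpois(300, 50) + 1, 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  once <- cpm_normalize(m)
  twice <- cpm_normalize(once)
  expect_lt(max(abs(twice - once) / once), 1e-9)
  expect_equal(unname(colSums(once)), rep(1e6, 6), tolerance = 1e-9)
})

test_that("TMM factors are 1 for composition-free columns and need >= 2 columns", {
  a <- rpois(100, 60) + 1
  same <- cbind(A = a, B = a)
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  depth <- cbind(A = a, B = 2L * a)
  expect_equal(unname(tmm_factors(depth)), c(1, 1))
  expect_error(tmm_factors(cbind(A = a)),
               class = "pcga_error_not_enough_samples")
})

test_that("TMM on a spiked fixture matches the direct trimmed-mean formula", {
  counts <- make_spiked_counts()
  got <- tmm_factors(counts)
  expect_equal(unname(got), unname(oracle_tmm_factors(counts)),
               tolerance = 1e-10)
  # the spiked column must be down-weighted relative to its library size
  expect_lt(got[["B"]], 1)
})

test_that("TMM factors are invariant to uniform depth scaling of a column", {
  counts <- make_spiked_counts()
  scaled <- counts
  scaled[, "C"] <- scaled[, "C"] * 5L
  # the precision-weighting of the trimmed mean depends weakly on absolute
  # depth, so invariance is approximate at realistic depths
  expect_equal(unname(tmm_factors(counts)), unname(tmm_factors(scaled)),
               tolerance = 1e-3)
})

test_that("bulk aggregation averages samples within tissues and re-normalizes", {
  cpm <- cbind(s1 = c(100, 0), s2 = c(0, 100), s3 = c(30, 70), s4 = c(30, 70))
  cpm <- cpm_normalize(`rownames<-`(cpm, c("g1", "g2")) * 1)
  map <- c(s1 = "liver", s2 = "liver", s3 = "lung", s4 = "lung")
  panel <- aggregate_bulk(cpm, map)
  expect_s3_class(panel, "expression_panel")
  # equal-weight mean of the two orthogonal liver samples
  expect_equal(unname(panel$values[, "liver"]), c(5e5, 5e5))
  # duplicated samples leave the profile unchanged
  expect_equal(panel$values[, "lung"], cpm[, "s3"])
  expect_error(aggregate_bulk(cpm, map[-1]),
               class = "pcga_error_missing_tissue_label")
})

test_that("cell filtering uses a strict < threshold on total UMIs", {
  m <- cbind(c1 = c(299, 0), c2 = c(150, 150), c3 = c(400, 100))
  rownames(m) <- c("g1", "g2")
  kept <- filter_cells(m, min_umi = 300)
  expect_identical(colnames(kept), c("c2", "c3"))
  expect_identical(rownames(kept), rownames(m))
  expect_identical(filter_cells(m, min_umi = 100), m)
  expect_warning(empty <- filter_cells(m, min_umi = 1000),
                 class = "pcga_warning_empty")
  expect_equal(ncol(empty), 0)
})

make_sc_fixture <- function() {
  # cluster A: 20 cells; the two highest-total cells carry 4 and 6 counts of
  # gene g1, so the top-10% (= 2 cells) average is 5 pre-CPM.
  set.seed(5)
  n_genes <- 3
  counts <- matrix(0, n_genes, 0,
                   dimnames = list(c("g1", "g2", "g3"), character()))
  add <- function(counts, id, g1, g2, g3) {
    v <- matrix(c(g1, g2, g3), ncol = 1, dimnames = list(rownames(counts), id))
    cbind(counts, v)
  }
  for (i in 1:18) counts <- add(counts, sprintf("A%02d", i), 1, 10, 10)
  counts <- add(counts, "A19", 4, 500, 500)
  counts <- add(counts, "A20", 6, 400, 600)
  for (i in 1:14) counts <- add(counts, sprintf("B%02d", i), 5, 20, 20)
  ann <- data.frame(
    cell_id = colnames(counts),
    cluster_id = rep(c("cA", "cB"), c(20, 14)),
    cell_type_label = rep(c("alpha", "beta"), c(20, 14)),
    sample_condition = "normal",
    dataset_id = "ds1", stringsAsFactors = FALSE)
  list(counts = counts, ann = ann)
}

test_that("pseudobulk averages the top 10% highest-total cells per cluster", {
  fx <- make_sc_fixture()
  panel <- pseudobulk_clusters(fx$counts, fx$ann, min_cells = 15,
                               top_fraction = 0.10)
  # the 14-cell beta cluster is dropped
  expect_identical(colnames(panel$values), "alpha")
  # ceil(0.10 * 20) = 2 cells (A19, A20): pre-CPM g1 profile = mean(4, 6) = 5
  pre <- c(g1 = 5, g2 = mean(c(500, 400)), g3 = mean(c(500, 600)))
  expect_equal(panel$values[, "alpha"], pre / sum(pre) * 1e6)
  expect_equal(sum(panel$values[, "alpha"]), 1e6)
})

test_that("same-labeled clusters merge before top-fraction selection", {
  fx <- make_sc_fixture()
  ann <- fx$ann
  ann$cell_type_label <- "alpha"            # both clusters share one label
  panel <- pseudobulk_clusters(fx$counts, ann, min_cells = 15,
                               top_fraction = 0.10)
  expect_identical(colnames(panel$values), "alpha")
  # pooled 34 cells -> ceil(3.4) = 4 top cells: A19, A20 and two B cells
  totals <- colSums(fx$counts)
  top4 <- names(sort(totals, decreasing = TRUE))[1:4]
  pre <- rowMeans(fx$counts[, top4])
  expect_equal(panel$values[, "alpha"], pre / sum(pre) * 1e6)
})

test_that("pseudobulk drops UNKNOWN and abnormal clusters and needs annotations", {
  fx <- make_sc_fixture()
  ann <- fx$ann
  ann$cell_type_label[ann$cluster_id == "cA"] <- "UNKNOWN"
  expect_error(pseudobulk_clusters(fx$counts, ann), class = "pcga_error_empty")
  ann2 <- fx$ann
  ann2$sample_condition[ann2$cluster_id == "cA"] <- "abnormal"
  expect_error(pseudobulk_clusters(fx$counts, ann2), class = "pcga_error_empty")
  expect_error(pseudobulk_clusters(fx$counts, fx$ann[-1, ]),
               class = "pcga_error_missing_annotation")
})

test_that("pseudobulk of identical cells equals any single cell's CPM profile", {
  counts <- matrix(rep(c(2, 3, 5), 20), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"),
                                   sprintf("c%02d", 1:20)))
  ann <- data.frame(cell_id = colnames(counts), cluster_id = "c",
                    cell_type_label = "gamma", sample_condition = "normal",
                    dataset_id = "d", stringsAsFactors = FALSE)
  panel <- pseudobulk_clusters(counts, ann)
  expect_equal(panel$values[, "gamma"], cpm_normalize(counts)[, 1])
})

test_that("homolog mapping keeps strictly one-to-one pairs", {
  vals <- matrix(1:12, 4, 3,
                 dimnames = list(c("Ma", "Mb", "Mc", "Md"),
                                 c("t1", "t2", "t3")))
  panel <- expression_panel(cpm_normalize(vals), kind = "tissue")
  mapping <- data.frame(src = c("Ma", "Mb", "Mc", "Mc2"),
                        dst = c("HA", "HX", "HX", "HC"))
  # Md has no row; Mb and Mc collide on HX -> only Ma survives
  out <- map_homologs(panel, mapping)
  expect_identical(rownames(out$values), "HA")
  expect_equal(unname(out$values["HA", ]), unname(panel$values["Ma", ]))

  ident <- data.frame(src = rownames(vals), dst = rownames(vals))
  out2 <- map_homologs(panel, ident)
  expect_equal(out2$values, panel$values)
})

test_that("the full bulk pipeline produces CPM tissue columns", {
  counts <- make_spiked_counts()
  map <- c(A = "liver", B = "liver", C = "lung")
  panel <- build_bulk_panel(counts, map, organ = c(liver = "liver", lung = "lung"))
  expect_identical(colnames(panel$values), c("liver", "lung"))
  expect_equal(unname(colSums(panel$values)), c(1e6, 1e6), tolerance = 1e-9)
  expect_identical(panel$organ, c("liver", "lung"))
})

test_that("panels round-trip through the TSV format", {
  sim <- simulate_expression(simulation_config(seed = 2, n_tissues = 4,
                                               n_genes = 20, n_causal = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(sim$panel, path)
  back <- read_panel(path)
  expect_equal(back$values, sim$panel$values, tolerance = 1e-12)
  expect_identical(back$kind, "tissue")
  expect_identical(back$organ, sim$panel$organ)
})
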