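# Seed-deterministic synthetic fixtures: LD-structured genotype panels,
# driver-tissue expression panels, single-cell counts and GWAS summary
# statistics with planted causal genes. These emulate the study conditions
# the pipeline is designed for (selective expression of phenotype-associated
# genes in a driver tissue; LD-redundant GWAS signal) so every stage can be
# exercised without downloads.

#' Default single-cell cluster design
#'
#' A cluster layout that exercises every panel-construction rule: two
#' same-labeled clusters that must merge, an under-sized cluster, an
#' UNKNOWN-labeled cluster, an abnormal-sample cluster, a cluster with a
#' low-depth subset (cells removed by the UMI filter but the cluster
#' survives), a cluster whose cells are all below the UMI threshold, and a
#' cluster pushed under the size threshold by the UMI filter. With the
#' default thresholds (300 UMIs, 15 cells) the surviving cell-type columns
#' are `Monocyte` and `T cell`.
#'
#' @return data frame with columns `dataset`, `cluster`, `label`,
#'   `condition`, `n_cells`, `depth` (expected UMIs per cell; several rows
#'   may describe one cluster with different depths).
#' @export
default_sc_cluster_spec <- function() {
  data.frame(
    dataset = "d1",
    cluster = c("c1", "c2", "c3", "c4", "c5", "c6", "c6", "c7", "c8", "c8"),
    label = c("T cell", "T cell", "B cell", "UNKNOWN", "NK cell",
              "Monocyte", "Monocyte", "Dendritic cell",
              "Macrophage", "Macrophage"),
    condition = c("normal", "normal", "normal", "normal", "abnormal",
                  "normal", "normal", "normal", "normal", "normal"),
    n_cells = c(20L, 18L, 14L, 30L, 25L, 22L, 8L, 20L, 10L, 10L),
    depth = c(2000, 2000, 2000, 2000, 2000, 2000, 50, 50, 2000, 50),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults define the
#' standard driver-tissue study condition: 20 tissues, 1,000 genes of which
#' 40 are causal and selectively over-expressed (+2 on the log2 scale) in
#' one driver tissue, 5-variant LD blocks with AR(1) latent correlation
#' 0.5, 500 reference individuals, and per-causal-variant chi-square
#' noncentrality 30.
#'
#' @param seed integer seed; every generator derives its random stream from
#'   it, so identical configurations reproduce identical data.
#' @param n_tissues,n_genes,n_causal panel and signal dimensions.
#' @param driver driver tissue index (1-based); `NULL` (default) draws it
#'   from the seed.
#' @param block_size variants per gene/LD block.
#' @param rho AR(1) latent correlation within a block, in \[0, 1).
#' @param n_samples reference-panel individuals.
#' @param maf allele frequency used to threshold the latent Gaussian.
#' @param noncentrality 1-df chi-square noncentrality per causal variant.
#' @param boost additive log2 expression boost of causal genes in the
#'   driver column.
#' @param n_chrom chromosomes the genes are laid out on.
#' @param gene_spacing,variant_spacing bp between gene starts on a
#'   chromosome and between variants within a block.
#' @param baseline_mean,baseline_sd,tissue_sd log2 expression model: gene
#'   baselines are N(`baseline_mean`, `baseline_sd`), tissue deviations
#'   N(0, `tissue_sd`).
#' @param celltypes_per_organ cell types per organ in the cell-type panel.
#' @param sc_cluster_spec single-cell design, see
#'   [default_sc_cluster_spec()].
#' @param sc_n_genes genes in the single-cell counts matrix.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_tissues = 20, n_genes = 1000,
                              n_causal = 40, driver = NULL, block_size = 5,
                              rho = 0.5, n_samples = 500, maf = 0.3,
                              noncentrality = 30, boost = 2, n_chrom = 22,
                              gene_spacing = 2e6, variant_spacing = 1000,
                              baseline_mean = 4, baseline_sd = 1,
                              tissue_sd = 0.5, celltypes_per_organ = 3,
                              sc_cluster_spec = default_sc_cluster_spec(),
                              sc_n_genes = 300) {
  stopifnot(n_tissues >= 3, n_genes >= 10, n_causal >= 1,
            n_causal <= n_genes, block_size >= 1, rho >= 0, rho < 1,
            n_samples >= 2, maf > 0, maf < 1, noncentrality >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# Deterministic gene layout: round-robin across chromosomes, evenly spaced
# slots, one LD block of equally spaced variants per gene.
gene_layout <- function(config) {
  i <- seq_len(config$n_genes)
  chrom <- as.character((i - 1) %% config$n_chrom + 1)
  slot <- (i - 1) %/% config$n_chrom
  start <- 1e6 + slot * config$gene_spacing
  end <- start + (config$block_size - 1) * config$variant_spacing
  genes <- data.frame(symbol = sprintf("gene%04d", i), chrom = chrom,
                      start = as.integer(start), end = as.integer(end),
                      stringsAsFactors = FALSE)
  vpos <- lapply(i, function(g)
    as.integer(start[g] + (seq_len(config$block_size) - 1) *
                 config$variant_spacing))
  list(genes = genes, variant_pos = vpos)
}

#' Simulate an LD-structured reference genotype panel
#'
#' Draws, per gene, one LD block of biallelic dosages: two latent AR(1)
#' Gaussian haplotypes per individual are thresholded at the allele
#' frequency, and the dosage is their sum. Blocks are independent of each
#' other.
#'
#' @param config a [simulation_config()].
#' @return list with `panel` (a [reference_panel]), `genes` (gene regions)
#'   and `variant_gene` (gene symbol per panel row).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed + 11L)
  lay <- gene_layout(config)
  L <- config$block_size
  nb <- config$n_genes
  nh <- 2L * config$n_samples
  z <- matrix(0, L, nb * nh)
  z[1, ] <- stats::rnorm(nb * nh)
  if (L > 1) {
    s <- sqrt(1 - config$rho^2)
    for (t in 2:L)
      z[t, ] <- config$rho * z[t - 1, ] + s * stats::rnorm(nb * nh)
  }
  allele <- (z < stats::qnorm(config$maf)) * 1
  a3 <- array(allele, dim = c(L, nh, nb))
  dos3 <- a3[, seq(1, nh, 2), , drop = FALSE] +
    a3[, seq(2, nh, 2), , drop = FALSE]
  dos <- matrix(aperm(dos3, c(1, 3, 2)), nrow = L * nb)
  colnames(dos) <- sprintf("S%04d", seq_len(config$n_samples))
  chrom <- rep(lay$genes$chrom, each = L)
  pos <- unlist(lay$variant_pos, use.names = FALSE)
  list(panel = reference_panel(dos, chrom, pos),
       genes = lay$genes,
       variant_gene = rep(lay$genes$symbol, each = L))
}

# Dosage -> minimal VCF 4.2 with GT fields (0/0, 0/1, 1/1).
write_vcf <- function(panel, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[round(panel$dosages) + 1],
               nrow = nrow(panel$dosages))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(panel$dosages)),
                     collapse = "\t")), con)
  body <- paste(panel$chrom, panel$pos, panel$id, "A", "G", ".", ".", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Simulate a reference panel and write it as VCF
#'
#' @param config a [simulation_config()].
#' @param path output VCF path.
#' @return the [simulate_genotypes()] result, with `path` added.
#' @export
simulate_panel_vcf <- function(config, path) {
  g <- simulate_genotypes(config)
  write_vcf(g$panel, path)
  g$path <- path
  g
}

#' Simulate a driver-tissue expression panel
#'
#' Log-normal baseline expression across tissues; the causal genes receive
#' an additive log2-scale boost only in the driver column, emulating
#' selective expression of phenotype-associated genes in the driver tissue.
#' Each tissue is assigned its own organ label (`organ_<i>`), shared with
#' the cell-type panel from [simulate_celltype_expression()].
#'
#' @param config a [simulation_config()].
#' @return list with `panel` (tissue [expression_panel]), `causal_genes`,
#'   `driver` (tissue column id), `driver_organ`.
#' @export
simulate_expression <- function(config) {
  set.seed(config$seed + 22L)
  nt <- config$n_tissues; ng <- config$n_genes
  driver <- if (is.null(config$driver))
    sample.int(nt, 1) else as.integer(config$driver)
  causal <- sort(sample.int(ng, config$n_causal))
  mu <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  lv <- matrix(stats::rnorm(ng * nt, 0, config$tissue_sd), ng, nt) + mu
  lv[causal, driver] <- lv[causal, driver] + config$boost
  symbols <- sprintf("gene%04d", seq_len(ng))
  tissues <- sprintf("tissue_%02d", seq_len(nt))
  dimnames(lv) <- list(symbols, tissues)
  organ <- stats::setNames(sprintf("organ_%02d", seq_len(nt)), tissues)
  panel <- expression_panel(cpm_normalize(2^lv), kind = "tissue",
                            organ = organ, dataset = "sim_bulk",
                            species = "human")
  list(panel = panel, causal_genes = symbols[causal],
       driver = tissues[driver], driver_organ = unname(organ[driver]))
}

#' Simulate a cell-type expression panel matching the tissue panel
#'
#' Generates `celltypes_per_organ` cell types for every organ of the tissue
#' panel; the causal genes are boosted in one driver cell type, which
#' belongs to the driver organ.
#'
#' @param config a [simulation_config()].
#' @param truth the [simulate_expression()] result (fixes the causal genes
#'   and the driver organ); regenerated from `config` when `NULL`.
#' @return list with `panel` (cell-type [expression_panel]),
#'   `driver_celltype`.
#' @export
simulate_celltype_expression <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- simulate_expression(config)
  set.seed(config$seed + 33L)
  nt <- config$n_tissues; ng <- config$n_genes
  k <- config$celltypes_per_organ
  organs <- sprintf("organ_%02d", seq_len(nt))
  cts <- as.vector(t(outer(organs, seq_len(k),
                           function(o, j) sprintf("%s_ct%d", o, j))))
  ct_organ <- rep(organs, each = k)
  causal <- match(truth$causal_genes, sprintf("gene%04d", seq_len(ng)))
  mu <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  lv <- matrix(stats::rnorm(ng * length(cts), 0, config$tissue_sd),
               ng, length(cts)) + mu
  driver_ct <- which(ct_organ == truth$driver_organ)[1]
  lv[causal, driver_ct] <- lv[causal, driver_ct] + config$boost
  dimnames(lv) <- list(sprintf("gene%04d", seq_len(ng)), cts)
  panel <- expression_panel(cpm_normalize(2^lv), kind = "cell_type",
                            organ = stats::setNames(ct_organ, cts),
                            dataset = "sim_sc", species = "human")
  list(panel = panel, driver_celltype = cts[driver_ct])
}

#' Simulate GWAS summary statistics with planted causal genes
#'
#' Null variants receive P-values uniform on (0, 1); every variant of a
#' causal gene receives the upper-tail P-value of a draw from the
#' noncentral 1-df chi-square with the configured noncentrality.
#'
#' @param config a [simulation_config()].
#' @param genotypes result of [simulate_genotypes()] (provides variant
#'   positions and the variant-to-gene map).
#' @param causal_genes character vector of causal gene symbols.
#' @return data frame `chrom`, `pos`, `p` (one row per panel variant).
#' @export
simulate_gwas <- function(config, genotypes, causal_genes) {
  set.seed(config$seed + 44L)
  panel <- genotypes$panel
  nv <- nrow(panel$dosages)
  p <- stats::runif(nv)
  is_causal <- genotypes$variant_gene %in% causal_genes
  missing <- setdiff(causal_genes, genotypes$variant_gene)
  if (length(missing))
    pcga_warn(paste("causal gene(s) without variants skipped:",
                    paste(missing, collapse = ", ")), "pcga_warning_skip")
  nc <- sum(is_causal)
  if (nc) {
    stat <- stats::rchisq(nc, df = 1, ncp = config$noncentrality)
    p[is_causal] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  p[p == 0] <- 1e-300
  data.frame(chrom = panel$chrom, pos = panel$pos, p = p,
             stringsAsFactors = FALSE)
}

#' Simulate a single-cell UMI counts matrix and its annotation
#'
#' Poisson counts at the designed per-cell depths, with gene relative
#' abundances drawn once from a gamma distribution. The returned
#' `expected_columns` element lists the cell-type columns that the
#' panel-construction rules should retain under the design (UMI filter at
#' `min_umi`, pooled-cluster size filter at `min_cells`, UNKNOWN and
#' abnormal exclusion, same-label merging).
#'
#' @param config a [simulation_config()]; the design is
#'   `config$sc_cluster_spec`.
#' @param min_umi,min_cells thresholds used to derive the expected column
#'   set (defaults 300 and 15, matching [filter_cells()] and
#'   [pseudobulk_clusters()]).
#' @return list with `counts` (genes x cells), `annotation` (one row per
#'   cell), `expected_columns`, `config`.
#' @export
simulate_sc_counts <- function(config, min_umi = 300, min_cells = 15) {
  set.seed(config$seed + 55L)
  design <- config$sc_cluster_spec
  ng <- config$sc_n_genes
  wt <- stats::rgamma(ng, shape = 0.8)
  wt <- wt / sum(wt)
  n_total <- sum(design$n_cells)
  counts <- matrix(0L, ng, n_total,
                   dimnames = list(sprintf("scgene%03d", seq_len(ng)),
                                   rep("", n_total)))
  ann <- vector("list", nrow(design))
  col0 <- 0L
  cell_counter <- stats::setNames(integer(0), character(0))
  for (i in seq_len(nrow(design))) {
    nc <- design$n_cells[i]
    key <- paste(design$dataset[i], design$cluster[i], sep = "_")
    offset <- if (key %in% names(cell_counter)) cell_counter[[key]] else 0L
    cell_counter[[key]] <- offset + nc
    ids <- sprintf("%s_%03d", key, offset + seq_len(nc))
    lam <- outer(wt, rep(design$depth[i], nc))
    counts[, col0 + seq_len(nc)] <- stats::rpois(ng * nc, lam)
    colnames(counts)[col0 + seq_len(nc)] <- ids
    ann[[i]] <- data.frame(cell_id = ids, cluster_id = design$cluster[i],
                           cell_type_label = design$label[i],
                           sample_condition = design$condition[i],
                           dataset_id = design$dataset[i],
                           stringsAsFactors = FALSE)
    col0 <- col0 + nc
  }
  annotation <- do.call(rbind, ann)
  # expected survivors from the design (depths are far from the UMI
  # threshold, so realized totals match the design with probability ~ 1)
  ok <- design$condition == "normal" & toupper(design$label) != "UNKNOWN"
  surv <- design$n_cells * (design$depth >= min_umi) * ok
  multi <- length(unique(design$dataset)) > 1
  pool <- if (multi) paste(design$dataset, design$label, sep = ":") else design$label
  pooled <- tapply(surv, pool, sum)
  expected <- sort(names(pooled)[pooled >= min_cells &
                                   tapply(ok, pool, any)])
  list(counts = counts, annotation = annotation,
       expected_columns = expected, config = config)
}

#' Write the complete synthetic fixture set
#'
#' Generates every input the pipeline consumes -- reference VCF, gene
#' regions, GWAS summary statistics, tissue and cell-type expression
#' panels, organ map, single-cell counts and annotations -- plus a
#' `manifest.json` recording the configuration and the ground truth
#' (driver tissue/cell type, causal genes, expected surviving single-cell
#' columns).
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
simulate_fixtures <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  geno <- simulate_panel_vcf(config, fp("ref.vcf"))
  truth <- simulate_expression(config)
  ct <- simulate_celltype_expression(config, truth)
  gwas <- simulate_gwas(config, geno, truth$causal_genes)
  sc <- simulate_sc_counts(config)
  write_summary(gwas, fp("gwas.tsv"))
  utils::write.table(geno$genes, fp("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_panel(truth$panel, fp("tissue_panel.tsv"))
  write_panel(ct$panel, fp("celltype_panel.tsv"))
  organ_map <- rbind(
    data.frame(column = colnames(truth$panel$values),
               organ = truth$panel$organ, stringsAsFactors = FALSE),
    data.frame(column = colnames(ct$panel$values),
               organ = ct$panel$organ, stringsAsFactors = FALSE))
  utils::write.table(organ_map, fp("organ_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sc$counts, fp("sc_counts.tsv"))
  utils::write.table(sc$annotation, fp("cell_annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = unclass(config)[setdiff(names(config), "sc_cluster_spec")],
    driver_tissue = truth$driver,
    driver_organ = truth$driver_organ,
    driver_celltype = ct$driver_celltype,
    causal_genes = truth$causal_genes,
    expected_sc_columns = sc$expected_columns)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
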