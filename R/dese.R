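# The DESE loop: Wilcoxon selective-expression enrichment per tissue or
# cell type, conditional gene re-testing guided by the top-ranked column,
# iterated to convergence; plus the hierarchical tissue -> cell-type stage.

#' One-sided Wilcoxon rank-sum P-value (greater)
#'
#' Tests whether `x_assoc` values tend to be greater than `x_other`.
#' When both groups have at most `exact_max` elements the P-value is
#' computed by exact enumeration over all group labelings of the (mid)ranks,
#' which is valid under ties; otherwise the normal approximation with tie
#' correction and continuity correction is used. If every observation is
#' tied the P-value is 1.
#'
#' @param x_assoc,x_other numeric vectors.
#' @param exact_max exact-enumeration group-size limit (default 8).
#' @return list with `statistic` (rank sum of the first group) and `pvalue`.
#' @export
wilcox_rank_p <- function(x_assoc, x_other, exact_max = 8) {
  nx <- length(x_assoc); ny <- length(x_other)
  stopifnot(nx > 0, ny > 0)
  n <- nx + ny
  r <- rank(c(x_assoc, x_other))
  w <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    combs <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(sums >= w - 1e-9)
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zst <- (w - mu - 0.5) / sqrt(sigma2)   # continuity correction
      p <- stats::pnorm(zst, lower.tail = FALSE)
    }
  }
  list(statistic = w, pvalue = min(max(p, .Machine$double.xmin), 1))
}

#' Selective-expression enrichment of associated genes in one column
#'
#' One-sided Wilcoxon rank-sum test that the phenotype-associated genes
#' have greater selective-expression scores in the given column than the
#' non-associated genes.
#'
#' @param assoc_genes character vector of associated gene symbols; must be
#'   a nonempty proper subset of `rownames(rez)`.
#' @param rez selective-expression matrix from [rez_scores()].
#' @param column column name or index.
#' @return list `column`, `statistic`, `pvalue`.
#' @export
wilcoxon_enrichment <- function(assoc_genes, rez, column) {
  genes <- rownames(rez)
  is_assoc <- genes %in% assoc_genes
  if (!any(is_assoc) || all(is_assoc))
    pcga_stop("associated genes must be a nonempty proper subset of the panel genes",
              "pcga_error_degenerate_groups")
  zc <- rez[, column]
  res <- wilcox_rank_p(zc[is_assoc], zc[!is_assoc])
  list(column = if (is.character(column)) column else colnames(rez)[column],
       statistic = res$statistic, pvalue = res$pvalue)
}

#' Rank all panel columns by enrichment of associated genes
#'
#' @inheritParams wilcoxon_enrichment
#' @return data frame `column`, `statistic`, `pvalue`, `fdr` (Benjamini-
#'   Hochberg), `bonferroni`, `rank`, ordered by increasing P-value (ties
#'   broken by column name).
#' @export
tissue_enrichment <- function(assoc_genes, rez) {
  cols <- colnames(rez)
  res <- lapply(cols, function(cc) wilcoxon_enrichment(assoc_genes, rez, cc))
  tab <- data.frame(column = cols,
                    statistic = vapply(res, `[[`, numeric(1), "statistic"),
                    pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
                    stringsAsFactors = FALSE)
  tab$fdr <- adjust_pvalues(tab$pvalue, "bh")
  tab$bonferroni <- adjust_pvalues(tab$pvalue, "bonferroni")
  tab <- tab[order(tab$pvalue, tab$column, method = "radix"), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' DESE configuration
#'
#' @param fdr significance level for FDR-adjusted P-values, both for the
#'   associated-gene rule and for tissue significance in the hierarchy
#'   (default 0.05).
#' @param min_assoc floor on the associated-gene set: if fewer than this
#'   many genes pass the FDR rule, the `min_assoc` smallest-P genes are
#'   used so the enrichment test stays defined (default 10).
#' @param max_iter maximum DESE iterations (default 10).
#' @param r2_cap,window conditioning parameters, see [condition_genes()].
#' @return list of class `dese_config`.
#' @export
dese_config <- function(fdr = 0.05, min_assoc = 10, max_iter = 10,
                        r2_cap = 0.95, window = 1e7) {
  stopifnot(fdr > 0, fdr < 1, min_assoc >= 1, max_iter >= 1)
  structure(list(fdr = fdr, min_assoc = min_assoc, max_iter = max_iter,
                 r2_cap = r2_cap, window = window), class = "dese_config")
}

# Associated-gene rule: BH-adjusted working P < fdr; fall back to the
# min_assoc smallest; always a proper subset of `symbols`.
assoc_rule <- function(p, symbols, fdr, min_assoc) {
  adj <- adjust_pvalues(p, "bh")
  sel <- which(adj < fdr)
  floor_n <- min(min_assoc, length(symbols) - 1)
  if (length(sel) < floor_n)
    sel <- order(p, symbols, method = "radix")[seq_len(floor_n)]
  if (length(sel) >= length(symbols))
    sel <- order(p, symbols, method = "radix")[seq_len(length(symbols) - 1)]
  sort(symbols[sel])
}

#' Iterative driver-tissue estimation (DESE)
#'
#' Alternates (1) defining the associated gene set from the current
#' (conditional) gene P-values, (2) ranking every panel column by
#' [tissue_enrichment()], and (3) re-running the conditional gene-based
#' analysis with the retained genes ordered by selective expression in the
#' top-ranked column (ties broken by smaller P-value, then symbol), until
#' the associated gene set is unchanged between consecutive iterations or
#' `max_iter` is reached.
#'
#' @param ga a `gene_assoc` object from [gene_assoc_scan()].
#' @param rez selective-expression matrix from [rez_scores()].
#' @param panel the [reference_panel] (LD provider for conditioning).
#' @param config a [dese_config()].
#' @return object of class `dese_run`: list with `iterations` (each holding
#'   the associated gene set and the column ranking), `converged`,
#'   `n_iterations`, `tissue_table` (final ranking), `gene_table` (final
#'   gene results, ordered by conditional P-value).
#' @export
dese_iterate <- function(ga, rez, panel, config = dese_config()) {
  stopifnot(inherits(ga, "gene_assoc"))
  shared <- intersect(ga$table$symbol, rownames(rez))
  if (length(shared) < 2)
    pcga_stop("fewer than two genes shared between GWAS results and the expression panel",
              "pcga_error_empty_analysis")
  zs <- rez[shared, , drop = FALSE]
  iterations <- list()
  prev <- NULL
  converged <- FALSE
  ranking <- NULL
  for (it in seq_len(config$max_iter)) {
    ti <- match(shared, ga$table$symbol)
    p_work <- ifelse(is.na(ga$table$conditional_pvalue[ti]),
                     ga$table$pvalue[ti], ga$table$conditional_pvalue[ti])
    assoc <- assoc_rule(p_work, shared, config$fdr, config$min_assoc)
    ranking <- tissue_enrichment(assoc, zs)
    iterations[[it]] <- list(assoc_genes = assoc, ranking = ranking)
    if (!is.null(prev) && setequal(assoc, prev)) {
      converged <- TRUE
      break
    }
    prev <- assoc
    top <- ranking$column[1]
    pa <- p_work[match(assoc, shared)]
    retained <- assoc[order(-zs[assoc, top], pa, assoc, method = "radix")]
    ga <- condition_genes(ga, panel, retained, r2_cap = config$r2_cap,
                          window = config$window)
  }
  gt <- ga$table
  gt$conditional_pvalue <- ifelse(is.na(gt$conditional_pvalue), gt$pvalue,
                                  gt$conditional_pvalue)
  gt$fdr <- adjust_pvalues(gt$conditional_pvalue, "bh")
  gt <- gt[order(gt$conditional_pvalue, gt$symbol, method = "radix"), ,
           drop = FALSE]
  rownames(gt) <- NULL
  structure(list(iterations = iterations, converged = converged,
                 n_iterations = length(iterations),
                 tissue_table = ranking, gene_table = gt,
                 config = config),
            class = "dese_run")
}

#' @export
print.dese_run <- function(x, ...) {
  cat(sprintf("<dese_run> %d iteration(s), converged: %s\n",
              x$n_iterations, x$converged))
  cat("top columns:\n")
  print(utils::head(x$tissue_table, 5))
  invisible(x)
}

# Subset an expression panel to a set of columns.
panel_subset <- function(panel, cols) {
  idx <- match(cols, colnames(panel$values))
  expression_panel(panel$values[, idx, drop = FALSE], kind = panel$kind,
                   organ = panel$organ[idx],
                   dataset = panel$provenance$dataset[idx],
                   species = panel$provenance$species[idx],
                   note = panel$note)
}

#' Hierarchical tissue and cell-type estimation
#'
#' Stage 1 runs DESE on the bulk tissue panel. The organs of the
#' significant tissues (FDR-adjusted P < `config$fdr`) then restrict the
#' cell-type panel for stage 2, which runs DESE again on the cell types
#' belonging to those organs. If no tissue is significant, all cell types
#' are used with a warning. A user-supplied `organs` vector bypasses the
#' automatic organ selection (manual selection by prior knowledge).
#'
#' @param variants GWAS summary data frame from [read_summary()].
#' @param ref_panel a [reference_panel] for LD.
#' @param genes gene regions from [read_gene_regions()].
#' @param tissue_panel,celltype_panel [expression_panel] objects sharing an
#'   organ vocabulary.
#' @param organs optional character vector of organ labels overriding the
#'   automatic selection.
#' @param config a [dese_config()].
#' @param flank gene window flank in bp.
#' @return list with `tissue_run`, `celltype_run` (both [dese_iterate()]
#'   results), and `organs` (the organ set used for stage 2).
#' @export
hierarchical_estimate <- function(variants, ref_panel, genes, tissue_panel,
                                  celltype_panel, organs = NULL,
                                  config = dese_config(), flank = 5000) {
  ga <- gene_assoc_scan(variants, ref_panel, genes, flank = flank)
  run_t <- dese_iterate(ga, rez_scores(tissue_panel), ref_panel, config)
  all_ct <- colnames(celltype_panel$values)
  if (is.null(organs)) {
    sig <- run_t$tissue_table$column[run_t$tissue_table$fdr < config$fdr]
    organs <- unique(tissue_panel$organ[match(sig,
                                              colnames(tissue_panel$values))])
    organs <- organs[!is.na(organs)]
    if (!length(organs)) {
      pcga_warn("no significant tissue; using all cell types for stage 2",
                "pcga_warning_fallback")
      organs <- unique(celltype_panel$organ)
    }
  }
  cols <- all_ct[celltype_panel$organ %in% organs]
  if (!length(cols))
    pcga_stop("no cell type belongs to the selected organs",
              "pcga_error_empty_subset")
  sub <- panel_subset(celltype_panel, cols)
  ga2 <- ga
  ga2$table$conditional_pvalue <- NA_real_
  ga2$table$conditioned_on <- ""
  run_c <- dese_iterate(ga2, rez_scores(sub), ref_panel, config)
  list(tissue_run = run_t, celltype_run = run_c, organs = organs)
}
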