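# Effective chi-square (ECS) gene-based association and conditional
# re-testing. ECS aggregates the per-variant 1-df chi-squares of a gene and
# corrects the null distribution for linkage disequilibrium among the
# variants, so that duplicated (fully correlated) association signals do
# not inflate the gene-level evidence.

#' Effective chi-square (ECS) test for one gene
#'
#' Converts each variant P-value to its 1-df chi-square quantile
#' `q_i = Qchisq(1 - p_i)` and sums them, `S = sum(q_i)`. Under the null the
#' statistic has mean `mu = m` and, using `cov(q_i, q_j) ~ 2 r_ij^2`,
#' variance `sigma^2 = 2 * sum_ij r_ij^2`. `S` is referred to the
#' moment-matched scaled chi-square with scale `a = sigma^2 / (2 mu)` and
#' degrees of freedom `d = 2 mu^2 / sigma^2`: the gene P-value is the upper
#' tail of `chisq_d` at `S / a`. With a single variant (or identity LD) this
#' reduces exactly to the ordinary chi-square test; with `m` fully
#' correlated copies of one variant it reduces to the single-copy test, so
#' redundant associations are removed.
#'
#' @param pvalues per-variant P-values in (0, 1].
#' @param ld square LD (Pearson r) matrix matching `pvalues`, or `NULL` for
#'   a single variant.
#' @param q optional precomputed per-variant chi-square statistics; when
#'   supplied they override `pvalues` (used by conditional re-testing).
#' @return list with `stat` (S), `scale_a`, `df_d`, `pvalue`, `q` and
#'   `n_variants`.
#' @export
ecs_test <- function(pvalues, ld = NULL, q = NULL) {
  if (is.null(q)) {
    if (!length(pvalues))
      pcga_stop("gene has no variants", "pcga_error_empty_gene")
    if (any(pvalues <= 0 | pvalues > 1))
      pcga_stop("variant P-values must be in (0, 1]", "pcga_error_format")
    q <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  }
  m <- length(q)
  if (!m) pcga_stop("gene has no variants", "pcga_error_empty_gene")
  if (is.null(ld)) ld <- diag(1, m)
  ld <- as.matrix(ld)
  stopifnot(nrow(ld) == m, ncol(ld) == m)
  S <- sum(q)
  mu <- m
  sigma2 <- 2 * sum(ld^2)
  a <- sigma2 / (2 * mu)
  d <- 2 * mu^2 / sigma2
  p <- stats::pchisq(S / a, df = d, lower.tail = FALSE)
  list(stat = S, scale_a = a, df_d = d,
       pvalue = max(p, .Machine$double.xmin), q = q, n_variants = m)
}

#' Gene-based association scan
#'
#' Runs [ecs_test()] for every gene: variants are assigned to gene windows,
#' matched by chromosome and position to the reference panel, and the
#' within-gene LD matrix is computed from panel dosages. Variants absent
#' from the panel are dropped (no LD is available for them); genes with no
#' usable variant are skipped.
#'
#' @param variants GWAS summary data frame from [read_summary()].
#' @param panel a [reference_panel] for LD.
#' @param genes gene regions from [read_gene_regions()].
#' @param flank gene window flank in bp (default 5000).
#' @return object of class `gene_assoc`: list with
#'   * `table`: data frame `symbol`, `chrom`, `n_variants`, `stat`,
#'     `scale_a`, `df_d`, `pvalue`, `conditional_pvalue` (NA until
#'     [condition_genes()] runs), `conditioned_on`;
#'   * `q`: per-gene list of variant chi-squares;
#'   * `variant_rows`: per-gene list of panel row indices (for LD lookups).
#' @export
gene_assoc_scan <- function(variants, panel, genes, flank = 5000) {
  stopifnot(inherits(panel, "reference_panel"))
  sets <- map_variants_to_genes(variants, genes, flank = flank)
  key_panel <- paste(panel$chrom, panel$pos, sep = ":")
  key_var <- paste(norm_chrom(variants$chrom), variants$pos, sep = ":")
  rows <- list(); qs <- list(); recs <- list()
  for (i in seq_along(sets)) {
    vi <- sets[[i]]
    if (!length(vi)) next
    pi_rows <- match(key_var[vi], key_panel)
    ok <- !is.na(pi_rows)
    if (!any(ok)) next
    vi <- vi[ok]; pi_rows <- pi_rows[ok]
    sym <- names(sets)[i]
    ld <- ld_matrix(panel, pi_rows)
    fit <- ecs_test(variants$p[vi], ld)
    rows[[sym]] <- pi_rows
    qs[[sym]] <- fit$q
    recs[[sym]] <- data.frame(symbol = sym, chrom = genes$chrom[i],
                              n_variants = fit$n_variants, stat = fit$stat,
                              scale_a = fit$scale_a, df_d = fit$df_d,
                              pvalue = fit$pvalue,
                              conditional_pvalue = NA_real_,
                              conditioned_on = "",
                              stringsAsFactors = FALSE)
  }
  if (!length(recs))
    pcga_stop("no gene has usable variants", "pcga_error_empty")
  tab <- do.call(rbind, recs)
  rownames(tab) <- NULL
  structure(list(table = tab, q = qs, variant_rows = rows),
            class = "gene_assoc")
}

#' @export
print.gene_assoc <- function(x, ...) {
  cat(sprintf("<gene_assoc> %d genes tested\n", nrow(x$table)))
  print(utils::head(x$table[order(x$table$pvalue), ], 5))
  invisible(x)
}

#' Selective-expression-guided conditional gene-based analysis
#'
#' Re-tests every gene not in `retained` after discounting variant signal
#' shared, through LD, with the retained genes. For each candidate variant
#' *j* the residual chi-square is
#' `q_j' = q_j * (1 - min(r2_cap, max r^2))`, where the maximum runs over
#' all variants of all retained genes on the same chromosome within
#' `window` bp (cross-chromosome and out-of-window pairs contribute 0), and
#' [ecs_test()] is recomputed on the residual statistics. Retained genes
#' keep their unconditional P-value as the conditional one.
#'
#' @param ga a `gene_assoc` object from [gene_assoc_scan()].
#' @param panel the [reference_panel] used for the scan.
#' @param retained ordered character vector of retained gene symbols
#'   (typically ordered by selective expression in the current top tissue).
#' @param r2_cap ceiling on the subtracted r-squared (default 0.95), so a
#'   near-duplicate neighbour cannot erase a candidate entirely; set to 1
#'   for full conditioning.
#' @param window same-chromosome distance in bp within which cross-gene LD
#'   is computed (default 1e7).
#' @return the `gene_assoc` object with `conditional_pvalue` and
#'   `conditioned_on` filled in.
#' @export
condition_genes <- function(ga, panel, retained, r2_cap = 0.95,
                            window = 1e7) {
  stopifnot(inherits(ga, "gene_assoc"), inherits(panel, "reference_panel"))
  retained <- intersect(retained, ga$table$symbol)
  tab <- ga$table
  tab$conditional_pvalue <- tab$pvalue
  tab$conditioned_on <- ""
  if (!length(retained)) { ga$table <- tab; return(ga) }
  ret_rows <- unlist(ga$variant_rows[retained], use.names = FALSE)
  ret_chrom <- panel$chrom[ret_rows]
  ret_pos <- panel$pos[ret_rows]
  # standardized dosages for fast correlation via crossprod
  dos <- panel$dosages
  ns <- ncol(dos)
  candidates <- setdiff(tab$symbol, retained)
  cond_label <- paste(retained, collapse = ",")
  for (sym in candidates) {
    rows_g <- ga$variant_rows[[sym]]
    chrom_g <- panel$chrom[rows_g[1]]
    sel <- which(ret_chrom == chrom_g)
    shrink <- numeric(length(rows_g))
    if (length(sel)) {
      in_win <- outer(panel$pos[rows_g], ret_pos[sel],
                      function(a, b) abs(a - b) <= window)
      if (any(in_win)) {
        r <- suppressWarnings(stats::cor(t(dos[rows_g, , drop = FALSE]),
                                         t(dos[ret_rows[sel], , drop = FALSE])))
        r[is.na(r)] <- 0
        r2 <- r^2
        r2[!in_win] <- 0
        shrink <- pmin(r2_cap, apply(r2, 1, max))
      }
    }
    q_res <- ga$q[[sym]] * (1 - shrink)
    ld <- ld_matrix(panel, rows_g)
    fit <- ecs_test(NULL, ld, q = q_res)
    i <- match(sym, tab$symbol)
    tab$conditional_pvalue[i] <- fit$pvalue
    tab$conditioned_on[i] <- cond_label
  }
  ga$table <- tab
  ga
}
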