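# Landscape statistics: hypergeometric category enrichment, Jaccard
# phenotype similarity, multiple-testing adjustment.

#' Hypergeometric category enrichment P-value
#'
#' Given `N` association P-values of which `M` are significant, and `n`
#' P-values between a phenotype category and a tissue/cell-type category of
#' which `k` are significant, the enrichment P-value is
#' `P = 1 - sum_{x=0}^{k-1} C(M, x) C(N - M, n - x) / C(N, n)`,
#' i.e. the upper tail `P(X >= k)` of the hypergeometric distribution,
#' evaluated in log space (via [stats::phyper()]) so large `N` do not
#' overflow the binomial coefficients.
#'
#' @param N total number of association P-values.
#' @param M number of significant P-values (e.g. FDR-adjusted P < 0.05).
#' @param n number of P-values between the category pair.
#' @param k number of significant P-values among those `n`.
#' @return the enrichment P-value in (0, 1]. Vectorized over all arguments.
#' @export
hypergeom_enrichment <- function(N, M, n, k) {
  bad <- M > N | n > N | k > pmin(M, n) | N < 0 | M < 0 | n < 0 | k < 0
  if (any(bad))
    pcga_stop("invalid counts: need 0 <= k <= min(M, n), M <= N, n <= N",
              "pcga_error_invalid_counts")
  p <- exp(stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE,
                         log.p = TRUE))
  pmax(p, .Machine$double.xmin)   # a valid query always has positive mass
}

#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 0 with a warning.
#'
#' @param genes_a,genes_b character vectors (treated as sets).
#' @return similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(genes_a, genes_b) {
  a <- unique(genes_a); b <- unique(genes_b)
  u <- length(union(a, b))
  if (u == 0) {
    pcga_warn("both gene sets empty; Jaccard similarity defined as 0",
              "pcga_warning_empty")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (`"bh"`) or Bonferroni (`"bonferroni"`)
#' adjustment via [stats::p.adjust()].
#'
#' @param pvalues raw P-values in (0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @return adjusted P-values in the input order.
#' @export
adjust_pvalues <- function(pvalues, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(pvalues, method = if (method == "bh") "BH" else "bonferroni")
}

#' Category-level enrichment across an association table
#'
#' Applies [hypergeom_enrichment()] to every phenotype-category x
#' tissue-category pair of an association table. Significance of the
#' individual associations is defined by FDR-adjusted P < `alpha` computed
#' over the whole table, which also fixes `N` (all rows) and `M` (all
#' significant rows).
#'
#' @param assoc data frame with columns `phenotype`, `column` (tissue or
#'   cell type) and `pvalue`, one row per association test.
#' @param phen_category named character vector: phenotype -> category.
#' @param tissue_category named character vector: column -> category.
#' @param alpha FDR significance level (default 0.05).
#' @return data frame with one row per category pair: `phen_category`,
#'   `tissue_category`, `N`, `M`, `n`, `k`, `pvalue`, `bonferroni`.
#' @export
category_enrichment <- function(assoc, phen_category, tissue_category,
                                alpha = 0.05) {
  need <- c("phenotype", "column", "pvalue")
  if (!all(need %in% names(assoc)))
    pcga_stop("association table needs columns phenotype, column, pvalue",
              "pcga_error_format")
  ph <- unname(phen_category[as.character(assoc$phenotype)])
  tc <- unname(tissue_category[as.character(assoc$column)])
  keep <- !is.na(ph) & !is.na(tc)
  assoc <- assoc[keep, , drop = FALSE]
  ph <- ph[keep]; tc <- tc[keep]
  N <- nrow(assoc)
  if (!N) pcga_stop("no association maps to both category tables",
                    "pcga_error_empty")
  sig <- adjust_pvalues(assoc$pvalue, "bh") < alpha
  M <- sum(sig)
  pairs <- unique(data.frame(H = ph, T = tc, stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$H, pairs$T, method = "radix"), , drop = FALSE]
  n <- k <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    in_pair <- ph == pairs$H[i] & tc == pairs$T[i]
    n[i] <- sum(in_pair)
    k[i] <- sum(in_pair & sig)
  }
  p <- hypergeom_enrichment(N, M, n, k)
  data.frame(phen_category = pairs$H, tissue_category = pairs$T,
             N = N, M = M, n = n, k = k, pvalue = p,
             bonferroni = adjust_pvalues(p, "bonferroni"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank catalog phenotypes by genetic similarity to a target
#'
#' Computes the Jaccard similarity between the target's significantly
#' associated gene set and each catalog phenotype's set, and returns the
#' `top_k` most similar, ties broken lexicographically by phenotype id.
#'
#' @param target character vector: the target phenotype's gene set.
#' @param catalog named list of character vectors, one per catalog
#'   phenotype.
#' @param top_k number of phenotypes returned (default all).
#' @return data frame `phenotype`, `jaccard`, ordered by descending
#'   similarity.
#' @export
similarity_ranking <- function(target, catalog, top_k = length(catalog)) {
  if (!length(catalog))
    pcga_stop("catalog is empty", "pcga_error_empty")
  ids <- names(catalog)
  if (is.null(ids)) ids <- sprintf("phenotype_%03d", seq_along(catalog))
  j <- vapply(catalog, function(g) jaccard_similarity(target, g), numeric(1))
  ord <- order(-j, ids, method = "radix")
  out <- data.frame(phenotype = ids[ord], jaccard = unname(j[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}
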