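# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (direct formula evaluation, brute-force
# enumeration) rather than calling the package's own code paths.

# Trimmed mean of M-values, evaluated directly from the published formula:
# pairwise weighted trimmed mean of log ratios against a reference column
# (upper quartile closest to the mean upper quartile), trimming 30% of
# M-values and 5% of A-values, factors scaled to unit geometric mean.
oracle_tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  pair <- function(obs, ref) {
    n_obs <- sum(obs); n_ref <- sum(ref)
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    M <- log2((obs / n_obs) / (ref / n_ref))
    A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
    w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }
  uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75) / sum(x))
  ref_col <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)),
              function(i) pair(counts[, i], counts[, ref_col]), numeric(1))
  f / exp(mean(log(f)))
}

# Hypergeometric upper tail 1 - sum_{x=0}^{k-1} C(M,x) C(N-M,n-x) / C(N,n),
# by direct enumeration of the mass function with choose().
oracle_hyper_tail <- function(N, M, n, k) {
  if (k == 0) return(1)
  x <- 0:(k - 1)
  1 - sum(choose(M, x) * choose(N - M, n - x) / choose(N, n))
}

# One-sided (greater) rank-sum P-value by looping over every subset of the
# pooled observations that could be the "associated" group.
oracle_wilcox_greater <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  hits <- 0
  for (j in seq_len(ncol(combs)))
    if (sum(r[combs[, j]]) >= w_obs - 1e-9) hits <- hits + 1
  hits / ncol(combs)
}

# Small deterministic bulk counts fixture with a composition-biased column:
# column B is a pure depth shift of A except for one strongly spiked gene.
make_spiked_counts <- function(n_genes = 200, spike_factor = 10, seed = 7) {
  set.seed(seed)
  base <- rpois(n_genes, 100) + 1
  b <- base
  b[1] <- b[1] * spike_factor
  counts <- cbind(A = base, B = b * 2L, C = base + rpois(n_genes, 5))
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  counts
}

# Reference panel built directly from a dosage matrix (variants x samples).
make_panel <- function(dosages, chrom = NULL, pos = NULL) {
  nv <- nrow(dosages)
  if (is.null(chrom)) chrom <- rep("1", nv)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = nv)
  reference_panel(dosages, chrom, pos)
}

# Three-gene-set conditioning fixture: gene "dup"'s variants are exact
# dosage copies of gene "src"'s (r2 = 1 pairs on the same chromosome);
# gene "far" sits on another chromosome, so its conditioning shrinkage is
# exactly zero.
make_cond_fixture <- function(seed = 61) {
  set.seed(seed)
  src <- matrix(rbinom(3 * 400, 2, 0.3), 3, 400)
  far <- matrix(rbinom(3 * 400, 2, 0.3), 3, 400)
  dos <- rbind(src, src, far)
  panel <- reference_panel(dos, rep(c("1", "2"), c(6, 3)),
                           c(1000L, 2000L, 3000L,
                             101000L, 102000L, 103000L,
                             501000L, 502000L, 503000L))
  genes <- data.frame(symbol = c("src", "dup", "far"),
                      chrom = c("1", "1", "2"),
                      start = c(1000L, 101000L, 501000L),
                      end = c(3000L, 103000L, 503000L),
                      stringsAsFactors = FALSE)
  variants <- data.frame(chrom = c(rep("1", 6), rep("2", 3)),
                         pos = panel$pos,
                         p = c(1e-6, 1e-5, 1e-4, 1e-6, 1e-5, 1e-4,
                               0.01, 0.2, 0.5),
                         stringsAsFactors = FALSE)
  ga <- gene_assoc_scan(variants, panel, genes, flank = 100)
  list(ga = ga, panel = panel)
}

# Tiny CPM expression matrix with named genes/columns.
make_cpm <- function(n_genes = 50, n_cols = 6, seed = 1, spike = NULL) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_cols, 6, 1), n_genes, n_cols,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("col%02d", seq_len(n_cols))))
  if (!is.null(spike)) m[spike$genes, spike$col] <- m[spike$genes, spike$col] * spike$factor
  cpm_normalize(m)
}
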