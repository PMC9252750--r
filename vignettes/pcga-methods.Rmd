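---
title: "Methods: driver-tissue and susceptibility-gene estimation in pcga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: driver-tissue and susceptibility-gene estimation in pcga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`pcga` estimates, from GWAS summary statistics alone, the tissues and cell
types in which a phenotype's genetic signal plausibly acts, and the genes
carrying that signal. The working assumption of the DESE strategy is that
phenotype-associated genes — regardless of effect direction — tend to be
*selectively* expressed in the phenotype's driver tissues and cell types in
normal samples. Everything else follows from making the two halves of that
statement testable and letting them inform each other:

1. a gene-based association test that aggregates per-variant P-values
   while correcting for linkage disequilibrium (LD), and
2. a per-column selective-expression score against which the associated
   gene set is tested for enrichment.

The loop between them (conditional re-testing guided by the current top
tissue, then re-ranking tissues with the conditioned gene P-values) is
what distinguishes the approach from one-shot enrichment methods: genes
whose signal is an LD shadow of a retained gene are discounted, which
sharpens both the gene list and the tissue ranking.

## Gene-based test: effective chi-square (ECS)

For gene *g* with variants `i = 1..m`, each variant P-value becomes the
1-df chi-square quantile `q_i`, and the gene statistic is `S = Σ q_i`.
Under the global null the `q_i` are 1-df chi-squares correlated through
LD; we use the approximation `cov(q_i, q_j) ≈ 2 r_ij²` (exact for jointly
normal variant Z-scores), giving moments `μ = m`,
`σ² = 2 Σ_ij r_ij²`. `S` is then referred to a moment-matched scaled
chi-square: scale `a = σ²/(2μ)`, degrees of freedom `d = 2μ²/σ²`. This
construction is a *declared reconstruction*: the published ECS software is
described elsewhere and only named by the framework we re-implement, so we
chose the deterministic closed form that satisfies the method's stated
purpose of removing redundant associations. Its contracts are enforced by
tests: a single variant reduces to the variant test; `m` fully correlated
copies reduce to one copy; identity LD reduces to `χ²_m`; null gene
P-values are uniform.

LD comes from Pearson correlation of reference-panel dosages (biallelic
SNVs only; missing genotypes imputed to the site mean; monomorphic sites
excluded). Variants belong to a gene if they fall within its annotated
span ± a flank (default 5 kb, configurable — the convention for gene-based
tests; no flank value is canonical, so it is a parameter rather than a
constant).

## Conditional gene-based analysis

Given an ordered set of retained genes, each candidate variant *j* is
shrunk by the strongest LD it shares with any retained variant on the same
chromosome within a 10 Mb window: `q_j' = q_j (1 − min(c, max r²))`, and
the ECS test is recomputed on the residual statistics. Cross-chromosome
pairs contribute exactly zero. The cap `c` defaults to 0.95 so that a
near-duplicate neighbour cannot erase a candidate entirely; with `c = 1` a
fully overlapping candidate's conditional P-value is exactly 1, which is
the behaviour the conditioning contract (and its test) pins down.
Conditioning can only remove evidence: conditional P ≥ unconditional P,
always.

Whether conditioning should act at the variant level or on gene-level
statistics was an open design choice; variant-level was chosen because it
composes with arbitrary gene windows (shared variants and LD shadows are
handled identically) and keeps the re-test a pure function of per-variant
statistics.

## Selective expression: robust regression Z-score (REZ)

For column *t*, the response `x = log2(CPM_t + 1)` is regressed on the
baseline `m = median of log2(CPM + 1) over all other columns`, with a
Huber IRLS fit (tuning constant 1.345, ≤ 50 iterations, MAD scale — the
deterministic standard). The score is the standardized residual
`z = (x − fit(m)) / (1.4826 · MAD)`. Three choices deserve note:

* **Leave-one-out baseline.** Including the focal column in its own
  baseline would let a strongly selective column drag the reference level
  toward itself; "selective" means relative to *other* tissues.
* **log2(CPM + 1).** Variance stabilization; raw CPM residuals would be
  dominated by the most expressed genes.
* **Degenerate columns.** If the residual MAD is zero (e.g. all columns
  identical) the column's scores are defined as 0 with a warning, since no
  gene is selectively expressed relative to an exactly-shared profile.
  A consequence worth knowing: in an exactly noise-free panel where a
  single gene is raised in one column, every other residual is identically
  zero, the MAD collapses, and the degenerate rule (z = 0) wins. Any
  realistic amount of biological noise restores the intended behaviour —
  the raised gene attains the column's maximum score — and the test suite
  exercises exactly that.

The exact regression design of the published REZ score is not restated in
the framework we re-implement; the above is this package's declared
reconstruction and is validated against an OLS oracle on clean Gaussian
panels (robust and ordinary fits coincide within 0.05 RMS).

## Tissue/cell-type enrichment and the DESE loop

Associated genes are tested for *greater* `z` in a column by a one-sided
Wilcoxon rank-sum test: exact enumeration over labelings when both groups
have ≤ 8 members (valid under ties), otherwise the normal approximation
with tie and continuity corrections. The one-sided direction is the
hypothesis itself — enrichment of *high* selective expression.

The working associated set is "FDR-adjusted (Benjamini–Hochberg)
conditional P < 0.05, with a floor of the 10 smallest-P genes". The
published framework reports significance at FDR < 0.05 but never states
the iteration's working rule; the floor keeps the rank-sum test defined
when few genes are significant. Convergence is exact set equality of the
associated genes between consecutive iterations (at most 10 — in
practice the loop converges in 2–3). Retained-gene order during
conditioning is descending `z` in the current top-ranked column, ties
broken by smaller P then symbol, which is how "guided by selective
expression" is made concrete. The iteration re-ranks columns against the
single best column's ordering (not a pool of top tissues); this is
configurable in principle but single-best is the default because it makes
the retained order unambiguous.

The hierarchical stage runs DESE on the bulk tissue panel first; organs of
the FDR-significant tissues select the cell-type columns for a second DESE
pass. A user-supplied organ list overrides the automatic selection; if no
tissue is significant, all cell types are used with a warning rather than
silently returning nothing.

# Reference-panel construction

Bulk counts are CPM-normalized within samples, corrected across samples by
the trimmed mean of M-values (TMM; 30% M-trim, 5% A-trim, upper-quartile
reference — the canonical published defaults, delegated to edgeR and
cross-checked in the tests against a direct evaluation of the formula),
then averaged within tissues and re-normalized. Because the weighted
trimmed mean uses precision weights that depend on absolute counts, TMM
factors are invariant to uniform depth rescaling only up to ~1e-3 at
realistic depths; the tests assert that tolerance deliberately.

Single-cell UMI counts go through: cell filter (total UMIs < 300 removed;
a cell at exactly 300 is kept), exclusion of clusters with unknown labels
or from abnormal samples, merging of same-labeled clusters within a
dataset (cell pools are united *before* any selection), removal of pooled
clusters with < 15 cells, and pseudobulk aggregation. "Top 10% highly
expressed cells" is interpreted as cells ranked by total UMI within the
pool, taking `ceiling(0.10 · n)` cells and averaging their raw UMI
vectors; total UMI is the only cluster-level expression summary available
before aggregation, and rounding up guarantees at least one cell. The
rule order (exclude → merge → size-filter → select) is this package's
resolution of an ambiguity: merging precedes selection by construction,
and the size filter applies to the merged pool, so two 14-cell clusters
with one label survive jointly while an unmergeable 14-cell cluster does
not.

Homolog mapping (for mouse panels) keeps strictly one-to-one pairs:
many-to-one and one-to-many mappings are dropped with a logged count to
avoid double-counting expression; expression values are *not*
re-normalized afterwards (column totals may fall below 1e6, recorded in
the panel's provenance note) so that mapped values remain comparable
across columns.

# Landscape statistics

Category enrichment uses the hypergeometric upper tail
`P = 1 − Σ_{x<k} C(M,x) C(N−M,n−x) / C(N,n)`, evaluated in log space so
that landscape-scale `N` neither overflows the binomial coefficients nor
underflows the tail to zero (the result is floored at the smallest
positive double, preserving `P ∈ (0, 1]`). The implementation is verified
against brute-force enumeration for every valid `(N ≤ 30, M, n, k)` with
maximum absolute error below 1e-12. Phenotype similarity is the Jaccard
coefficient of significantly associated gene sets (FDR < 0.05 on
conditional gene P-values, matching the association convention); two
empty sets are defined to have similarity 0 with a warning.

# The synthetic generator: what it emulates, what it does not

The generator produces the study conditions the pipeline is designed for,
with every stage's ground truth recorded in a manifest:

* **Genotypes.** One LD block per gene: two latent AR(1) Gaussian
  haplotypes per individual (correlation `rho`, default 0.5), thresholded
  at allele frequency 0.3, summed to dosages. Blocks are independent, so
  cross-gene LD is near zero by construction.
* **Expression.** Gene baselines `N(4, 1)` on the log2 scale with
  `N(0, 0.5)` tissue deviations; causal genes gain +2 log2 units in the
  driver column only. The defaults — 20 tissues, 1,000 genes, 40 causal
  genes, 500 reference individuals — are the standard fixture used
  throughout the tests and the acceptance script; they are desk-scale
  stand-ins for (not samples of) tissue-atlas panels.
* **GWAS.** Effect injection happens at the P-value level: causal-gene
  variants draw from a noncentral 1-df chi-square (noncentrality 30,
  giving median causal-variant P below 1e-4, i.e. clearly genome-wide
  relevant but not degenerate); null variants are Uniform(0, 1). This
  isolates exactly the contract DESE consumes — P-values — without
  simulating phenotypes.
* **Single cells.** Poisson counts at designed per-cell depths, with a
  cluster layout that exercises every filtering rule and whose surviving
  column set is derivable from the design.

What the generator does **not** emulate: realistic human LD maps and
population structure, expression correlation between tissues of the same
organ system, count overdispersion beyond Poisson, batch effects, doublets
or ambient RNA. Passing tests therefore demonstrate that the algorithms
honor their statistical contracts under controlled conditions — not that
real-data panels are free of the curation issues those phenomena cause.

# Numerical choices and degenerate inputs

* P-values of exactly 0 in summary files are clamped to 1e-300 with a
  warning (genome-wide files routinely underflow); other P outside (0, 1]
  are row errors.
* Gene-level and enrichment P-values are floored at the smallest positive
  double, never 0.
* Wilcoxon with all observations tied returns P = 1 (the tie-corrected
  variance is 0; there is no evidence of enrichment).
* Ties in every ordering (retained genes, column ranking, similarity
  ranking) are broken deterministically (P-value, then lexicographic), so
  identical inputs give byte-identical outputs — a property the test
  suite asserts across all CLI subcommands.
* Chromosome labels are normalized by stripping a leading `chr`; BED
  input is converted from 0-based half-open to 1-based inclusive on read.

# Problem sizes used by the tests

The suite and acceptance script use the default fixture (20 tissues,
1,000 genes, 40 causal, 500 individuals) for 50-replicate driver recovery
and 1,000-column null calibration, 2,000 simulated genes for ECS null
uniformity, 1,000 label permutations for rank-sum calibration, and the
complete `(N ≤ 30)` grid (87,295 cases) for the hypergeometric check —
sizes at which the Monte-Carlo tolerances quoted in the tests are
comfortably binomially stable.

# Known limitations

* ECS and REZ are reconstructions of published methods from their stated
  purpose and interface, not ports; numerical agreement with the original
  software is not claimed.
* The multivariate-normal tail of the gene statistic is moment-matched,
  not computed exactly; extremely asymmetric LD structures are
  approximated.
* Conditioning is greedy in the retained order and bounded by a 10 Mb
  window; signal shared at longer range (e.g. through structural variation)
  is not discounted.
* Liftover between genome builds, allele-frequency matching of the
  reference panel, and clustering of single cells are out of scope: the
  package consumes coordinates, panels and cluster labels as given.
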