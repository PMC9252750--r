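#' Reference expression panel
#'
#' Container for a genes-by-columns expression matrix in counts-per-million
#' (CPM), where columns are tissues (bulk) or cell types (single-cell
#' pseudobulk). Each column carries an organ label drawn from a unified
#' organ/tissue vocabulary and provenance (dataset, species).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   tissues or cell types in columns (colnames required). Values are CPM.
#' @param kind `"tissue"` or `"cell_type"`.
#' @param organ character vector of organ labels, one per column (recycled
#'   `NA` if omitted). Names are matched to `colnames(values)` when present.
#' @param dataset,species per-column provenance; scalars are recycled.
#' @param note free-text provenance note (e.g. records of dropped genes).
#'
#' @return An object of class `expression_panel`: a list with elements
#'   `values`, `kind`, `organ`, `provenance` (data frame with one row per
#'   column) and `note`.
#' @export
expression_panel <- function(values, kind = c("tissue", "cell_type"),
                             organ = NULL, dataset = NA_character_,
                             species = NA_character_, note = character()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    pcga_stop("expression panel columns must be named", "pcga_error_format")
  if (is.null(rownames(values)))
    pcga_stop("expression panel genes must be named", "pcga_error_format")
  if (anyDuplicated(colnames(values)))
    pcga_stop("duplicate column identifiers in expression panel",
              "pcga_error_format")
  if (any(values < 0))
    pcga_stop("negative expression values", "pcga_error_format")
  nc <- ncol(values)
  if (is.null(organ)) organ <- rep(NA_character_, nc)
  if (!is.null(names(organ))) organ <- unname(organ[colnames(values)])
  organ <- rep_len(as.character(organ), nc)
  prov <- data.frame(column = colnames(values),
                     organ = organ,
                     dataset = rep_len(as.character(dataset), nc),
                     species = rep_len(as.character(species), nc),
                     stringsAsFactors = FALSE)
  structure(list(values = values, kind = kind, organ = organ,
                 provenance = prov, note = note),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d genes x %d %s columns\n",
              nrow(x$values), ncol(x$values),
              sub("_", " ", x$kind)))
  shown <- utils::head(colnames(x$values), 6)
  cat("  columns:", paste(shown, collapse = ", "),
      if (ncol(x$values) > 6) "..." else "", "\n")
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Counts-per-million normalization
#'
#' Scales every column of a counts matrix so that it sums to one million,
#' preserving within-column proportions.
#'
#' @param counts non-negative numeric matrix, genes in rows, samples or
#'   cells in columns.
#' @param lib_size optional vector of effective library sizes (defaults to
#'   column sums); used to fold TMM scale factors into the normalization.
#' @return matrix of the same shape with each column summing to 1e6.
#' @seealso [tmm_factors()]
#' @export
cpm_normalize <- function(counts, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0))
    pcga_stop("counts must be non-negative", "pcga_error_format")
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    pcga_stop(sprintf("zero library size in column(s): %s",
                      paste(bad, collapse = ", ")),
              "pcga_error_zero_library_size")
  }
  if (is.null(lib_size)) lib_size <- totals
  sweep(counts, 2, lib_size / 1e6, "/")
}

#' Trimmed-mean-of-M-values (TMM) scale factors
#'
#' Computes per-column normalization factors correcting for RNA composition
#' differences between samples, via [edgeR::calcNormFactors()] with the
#' canonical TMM settings (trim 30% of M-values and 5% of A-values;
#' reference column = upper quartile closest to the mean upper quartile).
#' Effective library size for CPM is `colSums(counts) * factors`.
#'
#' @param counts non-negative counts matrix with at least two columns.
#' @param reference_column column name or index to use as the TMM reference,
#'   or `"auto"` (default) for the upper-quartile rule.
#' @return numeric vector of positive scale factors, one per column,
#'   normalized to unit geometric mean.
#' @export
tmm_factors <- function(counts, reference_column = "auto") {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    pcga_stop("TMM requires at least two columns", "pcga_error_not_enough_samples")
  if (any(colSums(counts) <= 0))
    pcga_stop("TMM requires positive column totals",
              "pcga_error_zero_library_size")
  ref <- NULL
  if (!identical(reference_column, "auto")) {
    ref <- if (is.character(reference_column))
      match(reference_column, colnames(counts)) else as.integer(reference_column)
    if (is.na(ref) || ref < 1 || ref > ncol(counts))
      pcga_stop("unknown reference column", "pcga_error_format")
  }
  f <- if (is.null(ref))
    edgeR::calcNormFactors(counts, method = "TMM")
  else
    edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Average CPM columns within tissues
#'
#' Collapses a sample-level CPM matrix to one column per tissue by
#' arithmetic mean of the samples mapped to that tissue, then re-normalizes
#' each tissue column to CPM.
#'
#' @param cpm CPM matrix, genes x samples.
#' @param sample_to_tissue named character vector (names = sample ids,
#'   values = tissue labels) or a two-column data frame `(sample, tissue)`.
#' @param organ optional named character vector mapping tissue label to
#'   organ label, passed through to the returned panel.
#' @return an [expression_panel] with `kind = "tissue"`, columns ordered by
#'   tissue label.
#' @export
aggregate_bulk <- function(cpm, sample_to_tissue, organ = NULL) {
  cpm <- as.matrix(cpm)
  map <- sample_to_tissue
  if (is.data.frame(map)) map <- stats::setNames(as.character(map[[2]]),
                                                 as.character(map[[1]]))
  samples <- colnames(cpm)
  missing <- setdiff(samples, names(map))
  if (length(missing))
    pcga_stop(sprintf("no tissue label for sample(s): %s",
                      paste(missing, collapse = ", ")),
              "pcga_error_missing_tissue_label")
  tissue <- map[samples]
  tissues <- sort(unique(tissue))
  agg <- vapply(tissues, function(tt)
    rowMeans(cpm[, tissue == tt, drop = FALSE]), numeric(nrow(cpm)))
  agg <- matrix(agg, nrow = nrow(cpm),
                dimnames = list(rownames(cpm), tissues))
  expression_panel(cpm_normalize(agg), kind = "tissue", organ = organ)
}

#' Build a tissue expression panel from bulk counts
#'
#' Full bulk pipeline: CPM normalization within samples, TMM correction
#' across all samples, then tissue averaging.
#'
#' @inheritParams aggregate_bulk
#' @param counts raw counts matrix, genes x samples.
#' @return an [expression_panel] of tissue columns.
#' @export
build_bulk_panel <- function(counts, sample_to_tissue, organ = NULL) {
  counts <- as.matrix(counts)
  f <- if (ncol(counts) >= 2) tmm_factors(counts) else
    stats::setNames(1, colnames(counts))
  cpm <- cpm_normalize(counts, lib_size = colSums(counts) * f)
  aggregate_bulk(cpm, sample_to_tissue, organ = organ)
}

#' Filter low-depth cells
#'
#' Removes cells whose total UMI count is below `min_umi` (strictly; a cell
#' at exactly the threshold is kept). The gene set is unchanged.
#'
#' @param counts UMI counts matrix, genes x cells.
#' @param min_umi minimum total UMI count per retained cell (default 300).
#' @return the counts matrix restricted to retained cells; a warning is
#'   emitted if no cell survives.
#' @export
filter_cells <- function(counts, min_umi = 300) {
  counts <- as.matrix(counts)
  keep <- colSums(counts) >= min_umi
  if (!any(keep))
    pcga_warn(sprintf("all %d cells below %d UMIs; empty matrix returned",
                      ncol(counts), min_umi), "pcga_warning_empty")
  counts[, keep, drop = FALSE]
}

#' Pseudobulk cell-type profiles from clustered single cells
#'
#' Aggregates a UMI counts matrix into one CPM profile per cell type.
#' Clusters from abnormal samples or with unknown labels are dropped;
#' clusters sharing a cell-type label within a dataset are merged (their
#' cell pools are united before any selection); merged pools with fewer
#' than `min_cells` cells are dropped; within each surviving pool the cells
#' are ranked by total UMI count and the top `ceiling(top_fraction * n)`
#' cells are averaged (mean raw UMI per gene), then CPM-normalized.
#'
#' @param counts UMI counts matrix, genes x cells (apply [filter_cells()]
#'   first).
#' @param annotation data frame with columns `cell_id`, `cluster_id`,
#'   `cell_type_label` (`"UNKNOWN"` marks unlabeled clusters),
#'   `sample_condition` (`"normal"` or `"abnormal"`) and `dataset_id`.
#' @param min_cells minimum pooled cluster size (default 15).
#' @param top_fraction fraction of highest-total cells averaged per pool
#'   (default 0.10).
#' @param organ optional named character vector, cell-type column -> organ.
#' @return an [expression_panel] with `kind = "cell_type"`. Column names are
#'   the cell-type labels, prefixed `dataset:` when the annotation spans
#'   more than one dataset.
#' @export
pseudobulk_clusters <- function(counts, annotation, min_cells = 15,
                                top_fraction = 0.10, organ = NULL) {
  counts <- as.matrix(counts)
  cells <- colnames(counts)
  idx <- match(cells, annotation$cell_id)
  if (anyNA(idx))
    pcga_stop(sprintf("no annotation for cell(s): %s",
                      paste(utils::head(cells[is.na(idx)], 5), collapse = ", ")),
              "pcga_error_missing_annotation")
  ann <- annotation[idx, , drop = FALSE]
  ok <- ann$sample_condition == "normal" &
    !is.na(ann$cell_type_label) &
    toupper(ann$cell_type_label) != "UNKNOWN"
  counts <- counts[, ok, drop = FALSE]
  ann <- ann[ok, , drop = FALSE]
  multi <- length(unique(annotation$dataset_id)) > 1
  pool <- if (multi)
    paste(ann$dataset_id, ann$cell_type_label, sep = ":")
  else as.character(ann$cell_type_label)
  keep_pools <- names(which(table(pool) >= min_cells))
  if (!length(keep_pools))
    pcga_stop("no cell cluster survives filtering", "pcga_error_empty")
  keep_pools <- sort(keep_pools)
  totals <- colSums(counts)
  prof <- vapply(keep_pools, function(pp) {
    in_pool <- which(pool == pp)
    n_top <- ceiling(top_fraction * length(in_pool))
    # stable order: by descending total, ties broken by cell id
    ord <- in_pool[order(-totals[in_pool], colnames(counts)[in_pool])]
    rowMeans(counts[, ord[seq_len(n_top)], drop = FALSE])
  }, numeric(nrow(counts)))
  prof <- matrix(prof, nrow = nrow(counts),
                 dimnames = list(rownames(counts), keep_pools))
  ds <- vapply(keep_pools, function(pp)
    as.character(ann$dataset_id[match(pp, pool)]), character(1))
  expression_panel(cpm_normalize(prof), kind = "cell_type", organ = organ,
                   dataset = ds)
}

#' Map panel genes to human HGNC symbols
#'
#' Renames genes using a species-gene-to-HGNC-symbol mapping table, keeping
#' only strictly one-to-one pairs: genes without a mapping row, source genes
#' sharing a target symbol and target symbols claimed by several source
#' genes are all dropped (counts recorded in the panel note). Expression
#' values are kept as-is; column totals may therefore fall below 1e6, which
#' is recorded in the provenance note rather than re-normalized away.
#'
#' @param panel an [expression_panel].
#' @param mapping two-column data frame: source gene id, human HGNC symbol.
#' @return the panel with mapped, renamed genes.
#' @export
map_homologs <- function(panel, mapping) {
  stopifnot(inherits(panel, "expression_panel"))
  src <- as.character(mapping[[1]])
  dst <- as.character(mapping[[2]])
  keep <- !(src %in% src[duplicated(src)]) & !(dst %in% dst[duplicated(dst)])
  map <- stats::setNames(dst[keep], src[keep])
  genes <- rownames(panel$values)
  hit <- genes %in% names(map)
  n_dropped <- sum(!hit)
  vals <- panel$values[hit, , drop = FALSE]
  rownames(vals) <- unname(map[genes[hit]])
  expression_panel(vals, kind = panel$kind, organ = panel$organ,
                   dataset = panel$provenance$dataset,
                   species = panel$provenance$species,
                   note = c(panel$note,
                            sprintf("homolog mapping: %d of %d genes retained (one-to-one); column totals not re-normalized",
                                    sum(hit), length(genes))))
}
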