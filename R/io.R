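# File-format helpers. All formats are plain text: dense TSV matrices
# (first column = gene symbol, header row), MatrixMarket triplets with
# sidecar gene/barcode files, and headered TSV tables.

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a counts or expression matrix
#'
#' Reads either a dense TSV (header row; first column gene symbols) or a
#' MatrixMarket `.mtx` triplet with sidecar files `<stem>.genes.txt` and
#' `<stem>.barcodes.txt` (one identifier per line).
#'
#' @param path path to `.tsv`(`.gz`) or `.mtx` file.
#' @return a base dense matrix, genes x columns.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".genes.txt"))
    colnames(m) <- readLines(paste0(stem, ".barcodes.txt"))
    return(m)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as dense TSV
#'
#' @param m matrix with row and column names.
#' @param path output path; `.gz` suffix enables gzip compression.
#' @param id_col header label for the gene-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write an expression panel
#'
#' Serializes an [expression_panel] as a TSV matrix preceded by `#`-prefixed
#' metadata lines (`#kind=` plus one `#column` line per column holding the
#' organ label and provenance).
#'
#' @param panel an [expression_panel].
#' @param path output path (`.gz` allowed).
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "expression_panel"))
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("#kind=%s", panel$kind), con)
  pv <- panel$provenance
  writeLines(sprintf("#column\t%s\t%s\t%s\t%s", pv$column,
                     ifelse(is.na(pv$organ), ".", pv$organ),
                     ifelse(is.na(pv$dataset), ".", pv$dataset),
                     ifelse(is.na(pv$species), ".", pv$species)), con)
  m <- panel$values
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read an expression panel written by [write_panel()]
#'
#' @param path panel TSV path.
#' @return an [expression_panel].
#' @export
read_panel <- function(path) {
  con <- open_maybe_gz(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kind <- sub("^#kind=", "", meta[startsWith(meta, "#kind=")][1])
  colmeta <- meta[startsWith(meta, "#column\t")]
  organ <- dataset <- species <- NULL
  if (length(colmeta)) {
    parts <- do.call(rbind, strsplit(colmeta, "\t", fixed = TRUE))
    dot_na <- function(x) ifelse(x == ".", NA_character_, x)
    organ <- stats::setNames(dot_na(parts[, 3]), parts[, 2])
    dataset <- dot_na(parts[, 4])
    species <- dot_na(parts[, 5])
  }
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  expression_panel(m, kind = if (is.na(kind)) "tissue" else kind,
                   organ = organ,
                   dataset = if (is.null(dataset)) NA_character_ else dataset,
                   species = if (is.null(species)) NA_character_ else species)
}

#' Read a cell annotation table
#'
#' Headered TSV with columns `cell_id`, `cluster_id`, `cell_type_label`,
#' `sample_condition`, `dataset_id`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_cell_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cluster_id", "cell_type_label", "sample_condition",
            "dataset_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pcga_stop(paste("annotation file missing column(s):",
                    paste(miss, collapse = ", ")), "pcga_error_format")
  df
}

#' Read a two-column mapping table (headered TSV)
#'
#' Used for the organ map (column id -> organ) and the homolog map
#' (species gene -> HGNC symbol).
#'
#' @param path TSV path.
#' @param named if `TRUE` return a named character vector, else the data
#'   frame.
#' @export
read_mapping <- function(path, named = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    pcga_stop("mapping file needs two columns", "pcga_error_format")
  if (named) stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  else df
}
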