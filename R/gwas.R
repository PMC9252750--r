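# GWAS summary-statistics ingestion, reference genotype panels and LD.

norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

#' Read GWAS summary statistics
#'
#' Parses a tab- or comma-delimited text file (delimiter auto-detected from
#' the header line) with at least chromosome, base-pair position and
#' P-value columns. The full variant set is retained: gene-based testing
#' needs all variants, not just the significant ones, so no P-value
#' filtering is applied. Chromosome labels are normalized by stripping a
#' leading `chr`. P-values of exactly zero (numerical underflow in the
#' source study) are clamped to 1e-300 with a warning; other P-values
#' outside (0, 1] and non-numeric positions are row errors.
#'
#' @param path summary-statistics file.
#' @param column_map named character vector giving the header names of the
#'   required columns; defaults to `c(chrom = "CHR", pos = "BP", p = "P")`.
#' @return data frame with columns `chrom`, `pos`, `p`.
#' @export
read_summary <- function(path, column_map = c(chrom = "CHR", pos = "BP", p = "P")) {
  if (!file.exists(path))
    pcga_stop(paste("file not found:", path), "pcga_error_format")
  header <- readLines(path, n = 1)
  if (!length(header) || !nzchar(header))
    pcga_stop("empty summary file (header line is required)",
              "pcga_error_format")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- column_map[c("chrom", "pos", "p")]
  miss <- setdiff(need, names(df))
  if (length(miss))
    pcga_stop(paste("summary file missing required column(s):",
                    paste(miss, collapse = ", ")), "pcga_error_format")
  pos <- suppressWarnings(as.numeric(df[[need[["pos"]]]]))
  p <- suppressWarnings(as.numeric(df[[need[["p"]]]]))
  bad_pos <- which(is.na(pos) | pos <= 0 | pos != floor(pos))
  if (length(bad_pos))
    pcga_stop(sprintf("invalid position at data line %d", bad_pos[1] + 1),
              "pcga_error_row")
  n_zero <- sum(!is.na(p) & p == 0)
  if (n_zero) {
    pcga_warn(sprintf("%d P-value(s) of 0 clamped to 1e-300", n_zero),
              "pcga_warning_clamp")
    p[p == 0] <- 1e-300
  }
  bad_p <- which(is.na(p) | p <= 0 | p > 1)
  if (length(bad_p))
    pcga_stop(sprintf("invalid P-value at data line %d", bad_p[1] + 1),
              "pcga_error_row")
  data.frame(chrom = norm_chrom(df[[need[["chrom"]]]]),
             pos = as.integer(pos), p = p, stringsAsFactors = FALSE)
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary()]: tab-delimited with header `CHR BP P`.
#'
#' @param variants data frame with `chrom`, `pos`, `p`.
#' @param path output path.
#' @export
write_summary <- function(variants, path) {
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  writeLines("CHR\tBP\tP", con)
  writeLines(paste(variants$chrom, variants$pos,
                   format(variants$p, trim = TRUE, digits = 15),
                   sep = "\t"), con)
  invisible(path)
}

#' Reference genotype panel
#'
#' Holds allele dosages (0/1/2) for LD computation: one row per biallelic
#' variant, one column per individual.
#'
#' @param dosages numeric matrix, variants x samples.
#' @param chrom,pos per-variant chromosome label and 1-based position.
#' @param id optional variant identifiers (default `chrom:pos`).
#' @return object of class `reference_panel`.
#' @export
reference_panel <- function(dosages, chrom, pos, id = NULL) {
  dosages <- as.matrix(dosages)
  chrom <- norm_chrom(chrom)
  pos <- as.integer(pos)
  stopifnot(length(chrom) == nrow(dosages), length(pos) == nrow(dosages))
  if (is.null(id)) id <- paste(chrom, pos, sep = ":")
  rownames(dosages) <- id
  structure(list(dosages = dosages, chrom = chrom, pos = pos, id = id),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d variants x %d samples (%d chromosome(s))\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom))))
  invisible(x)
}

#' Load a reference genotype panel from VCF
#'
#' Reads GT fields from a (optionally bgzipped) VCF and converts them to
#' allele dosages. Only biallelic single-nucleotide variants are used
#' (multi-allelic sites and indels are skipped with a count); missing
#' genotypes are imputed to the per-site mean dosage; monomorphic sites are
#' excluded with a warning since their LD is undefined.
#'
#' @param vcf_path path to the VCF.
#' @param region optional `list(chrom =, start =, end =)` restricting the
#'   loaded variants.
#' @return a [reference_panel].
#' @export
load_panel <- function(vcf_path, region = NULL) {
  v <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                error = function(e)
                  pcga_stop(paste("cannot read VCF:", conditionMessage(e)),
                            "pcga_error_format"))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- norm_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt)
  n_skip <- sum(!snv)
  if (n_skip)
    pcga_warn(sprintf("%d non-biallelic-SNV site(s) skipped", n_skip),
              "pcga_warning_skip")
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[snv, , drop = FALSE]
  chrom <- chrom[snv]; pos <- pos[snv]
  if (!is.null(region)) {
    keep <- chrom == norm_chrom(region$chrom) &
      pos >= region$start & pos <= region$end
    gt <- gt[keep, , drop = FALSE]; chrom <- chrom[keep]; pos <- pos[keep]
  }
  # "0/0", "0|1", ... -> count of alternate alleles; "./." -> NA
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  # impute missing to site mean
  if (anyNA(dos)) {
    mu <- rowMeans(dos, na.rm = TRUE)
    ii <- which(is.na(dos), arr.ind = TRUE)
    dos[ii] <- mu[ii[, 1]]
  }
  poly <- apply(dos, 1, stats::sd) > 0
  if (any(!poly))
    pcga_warn(sprintf("%d monomorphic site(s) excluded", sum(!poly)),
              "pcga_warning_skip")
  reference_panel(dos[poly, , drop = FALSE], chrom[poly], pos[poly])
}

#' Read gene regions
#'
#' Accepts BED (0-based half-open; no header; symbol in column 4) or a
#' headered TSV with columns `symbol`, `chrom`, `start`, `end` (1-based
#' inclusive). BED coordinates are converted to 1-based inclusive on read.
#'
#' @param path annotation file; `.bed` extension selects BED parsing.
#' @return data frame `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_regions <- function(path) {
  if (grepl("\\.bed$", path)) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    out <- data.frame(symbol = as.character(df[[4]]),
                      chrom = norm_chrom(df[[1]]),
                      start = as.integer(df[[2]]) + 1L,
                      end = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("symbol", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      pcga_stop("gene table needs columns symbol, chrom, start, end",
                "pcga_error_format")
    out <- data.frame(symbol = as.character(df$symbol),
                      chrom = norm_chrom(df$chrom),
                      start = as.integer(df$start),
                      end = as.integer(df$end), stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end))
    pcga_stop("gene region with start > end", "pcga_error_format")
  out
}

#' Assign variants to gene windows
#'
#' A variant belongs to gene *g* iff
#' `start - flank <= position <= end + flank` (inclusive on both sides);
#' variants inside several overlapping windows are assigned to every one of
#' them.
#'
#' @param variants data frame with `chrom`, `pos`.
#' @param genes data frame from [read_gene_regions()].
#' @param flank symmetric window extension in bp (default 5000).
#' @return named list (one element per gene symbol) of integer row indices
#'   into `variants`; attribute `n_unassigned` counts variants in no window.
#' @export
map_variants_to_genes <- function(variants, genes, flank = 5000) {
  stopifnot(flank >= 0)
  vc <- norm_chrom(variants$chrom)
  assigned <- logical(nrow(variants))
  sets <- vector("list", nrow(genes))
  names(sets) <- genes$symbol
  for (i in seq_len(nrow(genes))) {
    hit <- which(vc == genes$chrom[i] &
                   variants$pos >= genes$start[i] - flank &
                   variants$pos <= genes$end[i] + flank)
    sets[[i]] <- hit
    assigned[hit] <- TRUE
  }
  attr(sets, "n_unassigned") <- sum(!assigned)
  sets
}

#' Pairwise LD matrix
#'
#' Pearson correlation of dosage vectors for the requested variants.
#'
#' @param panel a [reference_panel].
#' @param variant_ids variant identifiers or integer row indices.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(panel, variant_ids) {
  stopifnot(inherits(panel, "reference_panel"))
  idx <- if (is.numeric(variant_ids)) as.integer(variant_ids)
  else match(variant_ids, panel$id)
  if (anyNA(idx) || any(idx < 1 | idx > nrow(panel$dosages)))
    pcga_stop("requested variant absent from the reference panel",
              "pcga_error_missing_variant")
  x <- t(panel$dosages[idx, , drop = FALSE])
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(panel$id[idx], panel$id[idx])
  r
}
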