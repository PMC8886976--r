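# Readers for the annotation tracks consumed by the TAD environment builder.
# All are thin fread wrappers around plain-text BED / BED-like TSV formats;
# coordinates are 0-based half-open throughout.

#' @noRd
read_bedlike <- function(path, col_names, header = FALSE, what = basename(path)) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  x <- data.table::fread(path, header = header, sep = "\t")
  if (ncol(x) < length(col_names)) {
    stop(sprintf("%s: expected >= %d columns (%s)", what, length(col_names),
                 paste(col_names, collapse = ", ")))
  }
  x <- x[, seq_along(col_names), with = FALSE]
  data.table::setnames(x, col_names)
  x[, chrom := as.character(chrom)]
  validate_intervals(x, what)
  x
}

#' Read TAD boundaries (BED + stability score)
#'
#' BED file whose 4th column is the cross-tissue boundary stability score.
#'
#' @param path BED file.
#' @return data.table with chrom, start, end, stability.
#' @export
read_tad_boundaries <- function(path) {
  read_bedlike(path, c("chrom", "start", "end", "stability"))
}

#' Read TAD regions (plain BED)
#'
#' @param path BED file of TAD intervals.
#' @return data.table with chrom, start, end.
#' @export
read_tads <- function(path) {
  read_bedlike(path, c("chrom", "start", "end"))
}

#' Read a gene annotation table
#'
#' Tab-separated with header: chrom, start, end, gene_id, p_hi, loeuf,
#' hi_log_odds, ddg2p (0/1). Missing scores are encoded as NA.
#'
#' @param path gene TSV.
#' @return data.table of gene records.
#' @export
read_genes <- function(path) {
  x <- read_bedlike(path, c("chrom", "start", "end", "gene_id", "p_hi",
                            "loeuf", "hi_log_odds", "ddg2p"), header = TRUE)
  x[, gene_id := as.character(gene_id)]
  x[, ddg2p := as.logical(ddg2p)]
  if (any(!is.na(x$p_hi) & (x$p_hi < 0 | x$p_hi > 1))) stop("p_hi must be in [0, 1]")
  if (any(!is.na(x$loeuf) & x$loeuf < 0)) stop("loeuf must be non-negative")
  x
}

#' Read exon intervals
#'
#' BED-like TSV with columns chrom, start, end, gene_id (no header).
#'
#' @param path exon file.
#' @return data.table with chrom, start, end, gene_id.
#' @export
read_exons <- function(path) {
  x <- read_bedlike(path, c("chrom", "start", "end", "gene_id"))
  x[, gene_id := as.character(gene_id)]
  x
}

#' Read enhancers (BED with optional conservation score column)
#'
#' @param path BED file; 4th column, when present, is the aggregated per-base
#'   conservation score (mean PhastCons-like).
#' @return data.table with chrom, start, end, conservation (NA when absent).
#' @export
read_enhancers <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(x) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path))
  nm <- c("chrom", "start", "end", "conservation")
  x <- x[, seq_len(min(ncol(x), 4L)), with = FALSE]
  data.table::setnames(x, nm[seq_len(ncol(x))])
  if (!"conservation" %in% names(x)) x[, conservation := NA_real_]
  x[, chrom := as.character(chrom)]
  x[, conservation := suppressWarnings(as.numeric(conservation))]
  validate_intervals(x, basename(path))
  x
}

#' Read CTCF peaks (BED / narrowPeak; extra columns ignored)
#'
#' @param path BED or narrowPeak file.
#' @return data.table with chrom, start, end.
#' @export
read_ctcf <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(x) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path))
  x <- x[, 1:3, with = FALSE]
  data.table::setnames(x, c("chrom", "start", "end"))
  x[, chrom := as.character(chrom)]
  validate_intervals(x, basename(path))
  x
}

#' Read promoter-capture Hi-C promoter--other interactions
#'
#' Tab-separated with header: chrom, start, end (the interacting "other end"
#' fragment), gene_id (the promoter's gene) and neg_log10_p (interaction
#' significance as -log10 p-value).
#'
#' @param path pcHi-C pair table.
#' @return data.table of interactions.
#' @export
read_pchic <- function(path) {
  x <- read_bedlike(path, c("chrom", "start", "end", "gene_id", "neg_log10_p"),
                    header = TRUE)
  x[, gene_id := as.character(gene_id)]
  if (any(x$neg_log10_p < 0)) stop("neg_log10_p must be >= 0")
  x
}

#' Read a bedGraph-style run-length score track
#'
#' Columns chrom, start, end, value (no header); used for per-base
#' conservation runs and windowed GC content.
#'
#' @param path bedGraph file.
#' @return data.table with chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  read_bedlike(path, c("chrom", "start", "end", "value"))
}

#' Read a chromosome sizes table (chrom, size; no header)
#'
#' @param path two-column TSV.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(x) < 2L) stop(sprintf("%s: expected chrom and size columns", path))
  stats::setNames(as.numeric(x[[2L]]), as.character(x[[1L]]))
}
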