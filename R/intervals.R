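# Interval arithmetic on 0-based, half-open [start, end) coordinates (BED
# convention). All tabular containers are data.frames/data.tables with at
# least chrom/start/end columns; GenomicRanges is used where overlap joins
# are cleaner, with the +1 shift applied at the boundary.

#' Validate a table of genomic intervals
#'
#' Checks the `chrom`, `start`, `end` columns and the half-open coordinate
#' invariants (`start >= 0`, `end > start`).
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly, as a `data.table`.
#' @export
validate_intervals <- function(x, what = "intervals") {
  x <- data.table::as.data.table(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0L) {
    if (any(is.na(x$start)) || any(is.na(x$end))) {
      stop(sprintf("%s: NA coordinates", what))
    }
    if (any(x$start < 0)) stop(sprintf("%s: negative start", what))
    if (any(x$end <= x$start)) {
      bad <- which(x$end <= x$start)[1L]
      stop(sprintf("%s: empty or inverted interval at row %d (start=%s end=%s)",
                   what, bad, x$start[bad], x$end[bad]))
    }
  }
  invisible(x)
}

#' Reciprocal overlap of two genomic intervals
#'
#' The reciprocal overlap of intervals `a` and `b` is
#' `min(ov / len(a), ov / len(b))` where `ov` is the length of their
#' intersection. It is symmetric, lies in `[0, 1]`, equals 1 iff the two
#' intervals are identical, and is 0 for intervals on different chromosomes.
#' A reciprocal overlap of at least 0.9 is the conventional "same variant"
#' criterion for CNV call deduplication.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end`; rows are
#'   paired (recycled if one side has a single row).
#' @return numeric vector of overlap fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  a <- validate_intervals(a, "a"); b <- validate_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n)]
  if (nrow(b) == 1L) b <- b[rep(1L, n)]
  if (nrow(a) != nrow(b)) stop("a and b must have the same number of rows (or one row)")
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  pmin(ov / (a$end - a$start), ov / (b$end - b$start))
}

#' Extend intervals symmetrically, clipped to chromosome bounds
#'
#' Grows each interval by `pad_bp` on both sides and clips the result to
#' `[0, chromosome length]`. Used e.g. to extend telomeric regions by 5 Mbp
#' before enrichment testing.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param pad_bp non-negative padding in bp added to each side.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), or a
#'   data.frame with columns `chrom` and `size`.
#' @return data.table with the padded, clipped coordinates.
#' @export
extend_intervals <- function(intervals, pad_bp, chrom_sizes) {
  stopifnot(pad_bp >= 0)
  x <- data.table::copy(validate_intervals(intervals, "intervals"))
  sizes <- as_chrom_sizes(chrom_sizes)
  unknown <- setdiff(unique(x$chrom), names(sizes))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  x[, start := pmax(0, start - pad_bp)]
  x[, end := pmin(sizes[chrom], end + pad_bp)]
  x[]
}

#' @noRd
as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stats::setNames(as.numeric(chrom_sizes$size), chrom_sizes$chrom)
  } else {
    if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
    chrom_sizes
  }
}

#' Merge overlapping or book-ended intervals
#'
#' Returns the disjoint union of the input intervals per chromosome
#' (book-ended intervals such as `[0,5)` and `[5,10)` are merged).
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return data.table of disjoint intervals sorted by (chrom, start).
#' @export
merge_intervals <- function(intervals) {
  x <- validate_intervals(intervals, "intervals")
  if (nrow(x) == 0L) return(data.table::data.table(chrom = character(), start = numeric(), end = numeric()))
  x <- x[order(chrom, start, end), .(chrom, start = as.numeric(start), end = as.numeric(end))]
  # a new run starts where start exceeds the running max end of previous rows
  x[, grp := cumsum(start > data.table::shift(cummax(end), fill = -Inf)), by = chrom]
  out <- x[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  out[order(chrom, start)]
}

# ---- global (genome-linearised) coordinates -------------------------------
# Chromosomes are laid end to end with a 1 bp guard gap so that no interval
# on one chromosome can appear to touch an interval on the next. Global
# coordinates are doubles to avoid 32-bit overflow on concatenated genomes.

#' @noRd
genome_offsets <- function(chrom_sizes) {
  sizes <- as_chrom_sizes(chrom_sizes)
  offs <- cumsum(c(0, as.numeric(sizes[-length(sizes)]) + 1))
  stats::setNames(offs, names(sizes))
}

#' @noRd
to_global <- function(x, offsets) {
  unknown <- setdiff(unique(x$chrom), names(offsets))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  off <- offsets[x$chrom]
  list(start = as.numeric(x$start) + off, end = as.numeric(x$end) + off)
}

# Query intervals [qs, qe) against a reference set of *disjoint* intervals
# sorted by start (same global coordinate system). Returns TRUE for queries
# intersecting at least one reference interval by >= 1 bp.
#' @noRd
overlaps_any <- function(qs, qe, rs, re) {
  nq <- length(qs); nr <- length(rs)
  if (nr == 0L || nq == 0L) return(logical(nq))
  idx <- findInterval(qs, rs)
  hit_left <- idx >= 1L & re[pmax(idx, 1L)] > qs
  hit_right <- idx < nr & rs[pmin(idx + 1L, nr)] < qe
  hit_left | hit_right
}

# Gap in bp between paired intervals (0 when they intersect or touch).
#' @noRd
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

#' @noRd
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
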