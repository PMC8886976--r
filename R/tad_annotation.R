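# TAD environments: annotation tracks sorted into the TAD they fall in.
# A TAD environment is the set of genes, enhancers and CTCF sites whose
# intervals intersect the TAD region, plus the two flanking boundaries.
# Elements straddling a TAD border are attached to every TAD they intersect.

#' Derive TAD regions from boundary intervals
#'
#' TAD environments are the inter-boundary intervals: on each chromosome the
#' regions between consecutive boundary intervals, plus the terminal regions
#' up to the chromosome ends.
#'
#' @param boundaries data.table with chrom, start, end (and optionally
#'   stability).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return data.table of TAD regions (chrom, start, end).
#' @export
tads_from_boundaries <- function(boundaries, chrom_sizes) {
  b <- validate_intervals(boundaries, "boundaries")
  sizes <- as_chrom_sizes(chrom_sizes)
  out <- lapply(names(sizes), function(ch) {
    bb <- b[chrom == ch][order(start)]
    cuts_start <- c(0, bb$end)
    cuts_end <- c(bb$start, sizes[[ch]])
    data.table::data.table(chrom = ch, start = cuts_start, end = cuts_end)
  })
  out <- data.table::rbindlist(out)
  out[end > start]
}

#' Build annotated TAD environments
#'
#' Sorts each annotation track into the TAD regions it intersects. Every
#' element is attached to every TAD region it intersects by at least 1 bp;
#' each TAD additionally records its two flanking boundaries (the boundary
#' intervals closest to its start and end coordinates).
#'
#' @param tads data.table of TAD regions (chrom, start, end); must be
#'   non-overlapping within a chromosome.
#' @param boundaries data.table with chrom, start, end, stability.
#' @param genes gene table (see [read_genes()]); may have zero rows.
#' @param enhancers enhancer table (see [read_enhancers()]).
#' @param ctcf CTCF peak table.
#' @return an object of class `tad_environments`.
#' @export
build_environments <- function(tads, boundaries, genes, enhancers, ctcf) {
  tads <- data.table::copy(validate_intervals(tads, "tads"))
  boundaries <- data.table::copy(validate_intervals(boundaries, "boundaries"))
  if (!"stability" %in% names(boundaries)) boundaries[, stability := NA_real_]
  genes <- data.table::as.data.table(genes)
  enhancers <- data.table::as.data.table(enhancers)
  ctcf <- data.table::as.data.table(ctcf)

  tads <- tads[order(chrom, start)]
  # consecutive sorted TADs must not overlap within a chromosome
  bad <- tads[, any(start < data.table::shift(end, fill = -Inf)), by = chrom]
  if (any(bad$V1)) stop("TAD regions overlap within a chromosome")
  tads[, tad_id := sprintf("tad_%s_%d", chrom, seq_len(.N)), by = chrom]

  tad_gr <- as_granges(tads)
  incidence <- function(track) {
    if (nrow(track) == 0L) {
      return(data.table::data.table(tad_id = character(), element_idx = integer()))
    }
    hits <- GenomicRanges::findOverlaps(tad_gr, as_granges(track))
    data.table::data.table(
      tad_id = tads$tad_id[S4Vectors::queryHits(hits)],
      element_idx = S4Vectors::subjectHits(hits)
    )
  }

  # flanking boundaries: per TAD edge, the boundary minimising the gap to it
  flank <- function(edge_pos, ch) {
    vapply(seq_along(edge_pos), function(i) {
      cand <- which(boundaries$chrom == ch[i])
      if (length(cand) == 0L) return(NA_integer_)
      gap <- interval_gap(boundaries$start[cand], boundaries$end[cand],
                          edge_pos[i], edge_pos[i] + 1)
      cand[which.min(gap)]
    }, integer(1))
  }
  tads[, left_boundary := flank(pmax(start - 1, 0), chrom)]
  tads[, right_boundary := flank(end, chrom)]

  structure(list(
    tads = tads,
    boundaries = boundaries,
    genes = genes,
    enhancers = enhancers,
    ctcf = ctcf,
    incidence = list(genes = incidence(genes),
                     enhancers = incidence(enhancers),
                     ctcf = incidence(ctcf))
  ), class = "tad_environments")
}

#' @export
print.tad_environments <- function(x, ...) {
  cat(sprintf("tad_environments: %d TADs, %d genes, %d enhancers, %d CTCF sites, %d boundaries\n",
              nrow(x$tads), nrow(x$genes), nrow(x$enhancers), nrow(x$ctcf),
              nrow(x$boundaries)))
  invisible(x)
}

#' Elements attached to one TAD environment
#'
#' @param envs a `tad_environments` object.
#' @param tad one `tad_id` from `envs$tads`.
#' @return list with `region`, `genes`, `enhancers`, `ctcf`, `boundaries`
#'   (the two flanking boundary records).
#' @export
tad_elements <- function(envs, tad) {
  stopifnot(inherits(envs, "tad_environments"))
  row <- envs$tads[tad_id == tad]
  if (nrow(row) == 0L) stop(sprintf("unknown tad_id: %s", tad))
  pick <- function(track, inc) track[inc[tad_id == tad]$element_idx]
  bidx <- stats::na.omit(c(row$left_boundary, row$right_boundary))
  list(
    region = row[, .(chrom, start, end)],
    genes = pick(envs$genes, envs$incidence$genes),
    enhancers = pick(envs$enhancers, envs$incidence$enhancers),
    ctcf = pick(envs$ctcf, envs$incidence$ctcf),
    boundaries = envs$boundaries[unique(bidx)]
  )
}

#' Mean of a per-base score track over an interval
#'
#' Arithmetic mean of base-wise scores (supplied as run-length bedGraph
#' rows) over the bases of `interval` that carry a score; `NA` when no base
#' is scored.
#'
#' @param interval single-row data.frame with chrom, start, end.
#' @param basewise_scores data.table with chrom, start, end, value.
#' @return mean score, or `NA_real_`.
#' @export
aggregate_conservation <- function(interval, basewise_scores) {
  iv <- validate_intervals(interval, "interval")
  stopifnot(nrow(iv) == 1L)
  tr <- data.table::as.data.table(basewise_scores)
  tr <- tr[chrom == iv$chrom]
  if (nrow(tr) == 0L) return(NA_real_)
  ov <- pmax(0, pmin(tr$end, iv$end) - pmax(tr$start, iv$start))
  covered <- sum(ov)
  if (covered == 0) return(NA_real_)
  sum(ov * tr$value) / covered
}

#' Empirical percentile threshold over a background score distribution
#'
#' Linear-interpolation empirical percentile of `scores`; elements strictly
#' above the 75th / 90th percentile threshold are called "conserved" /
#' "highly conserved" respectively.
#'
#' @param scores numeric background distribution (e.g. aggregated
#'   conservation over all enhancers); NAs dropped.
#' @param q percentile in (0, 100).
#' @return the threshold value.
#' @export
conservation_percentile_threshold <- function(scores, q) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("scores must be non-empty")
  stopifnot(q > 0, q < 100)
  unname(stats::quantile(scores, probs = q / 100, type = 7))
}

#' Stratify genes by haploinsufficiency and loss-of-function constraint
#'
#' HI genes have `p_hi > p_hi_high`; HS (haplosufficient) genes have
#' `p_hi < p_hi_low` (strict inequalities; a gene at exactly 0.9 belongs to
#' neither stratum). Under the default `"standard"` LOEUF semantics, low
#' LOEUF marks intolerance: pLoF-intolerant genes have `loeuf < loeuf_low`
#' and pLoF-tolerant genes `loeuf > loeuf_high`. `loeuf_semantics =
#' "inverted"` swaps the two LOEUF strata for compatibility with sources
#' using the opposite convention. Genes with a missing score belong to no
#' stratum on that axis.
#'
#' @param genes gene table.
#' @param p_hi_high,p_hi_low,loeuf_low,loeuf_high stratum thresholds.
#' @param loeuf_semantics `"standard"` (low LOEUF = intolerant) or
#'   `"inverted"`.
#' @return the gene table with logical columns `hi`, `hs`, `plof_intolerant`,
#'   `plof_tolerant` appended.
#' @export
stratify_genes <- function(genes, p_hi_high = 0.9, p_hi_low = 0.1,
                           loeuf_low = 0.1, loeuf_high = 0.9,
                           loeuf_semantics = c("standard", "inverted")) {
  loeuf_semantics <- match.arg(loeuf_semantics)
  stopifnot(p_hi_high > 0, p_hi_high < 1, p_hi_low > 0, p_hi_low < 1)
  x <- data.table::copy(data.table::as.data.table(genes))
  x[, hi := !is.na(p_hi) & p_hi > p_hi_high]
  x[, hs := !is.na(p_hi) & p_hi < p_hi_low]
  intol <- !is.na(x$loeuf) & x$loeuf < loeuf_low
  tol <- !is.na(x$loeuf) & x$loeuf > loeuf_high
  if (loeuf_semantics == "standard") {
    x[, `:=`(plof_intolerant = intol, plof_tolerant = tol)]
  } else {
    x[, `:=`(plof_intolerant = tol, plof_tolerant = intol)]
  }
  x[]
}

#' Classify TADs by regulatory importance
#'
#' Assigns each TAD environment exactly one class --
#' `no_annotation`, `coding_only`, `regulatory_only` or
#' `coding_and_regulatory` -- according to the presence of gene and enhancer
#' annotation, plus two flags: whether the TAD contains at least one
#' pLoF-intolerant gene and whether it contains at least one highly
#' conserved enhancer (aggregated conservation strictly above the
#' `conservation_q` percentile of the background over all enhancers).
#'
#' @param envs a `tad_environments` object.
#' @param loeuf_low LOEUF cutoff below which a gene counts as
#'   pLoF-intolerant.
#' @param conservation_q background percentile (default 90) defining highly
#'   conserved enhancers.
#' @return data.table with tad_id, regulatory_class,
#'   has_plof_intolerant_gene, has_highly_conserved_enhancer.
#' @export
stratify_tads <- function(envs, loeuf_low = 0.1, conservation_q = 90) {
  stopifnot(inherits(envs, "tad_environments"))
  gene_inc <- envs$incidence$genes
  enh_inc <- envs$incidence$enhancers
  cons <- envs$enhancers$conservation
  thr <- if (any(!is.na(cons))) conservation_percentile_threshold(cons, conservation_q) else Inf
  intol_idx <- which(!is.na(envs$genes$loeuf) & envs$genes$loeuf < loeuf_low)
  hc_idx <- which(!is.na(cons) & cons > thr)
  out <- data.table::data.table(tad_id = envs$tads$tad_id)
  out[, has_gene := tad_id %in% gene_inc$tad_id]
  out[, has_enh := tad_id %in% enh_inc$tad_id]
  out[, has_plof_intolerant_gene :=
        tad_id %in% gene_inc[element_idx %in% intol_idx]$tad_id]
  out[, has_highly_conserved_enhancer :=
        tad_id %in% enh_inc[element_idx %in% hc_idx]$tad_id]
  out[, regulatory_class := data.table::fcase(
    has_gene & has_enh, "coding_and_regulatory",
    has_gene & !has_enh, "coding_only",
    !has_gene & has_enh, "regulatory_only",
    default = "no_annotation"
  )]
  out[, c("has_gene", "has_enh") := NULL]
  out[]
}
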