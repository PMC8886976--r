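# Isochore-constrained bootstrap enrichment tests. Query segments (merged
# CNVs) are repeatedly re-placed uniformly at random inside isochores of the
# same GC class as their original location, lengths preserved; the observed
# per-annotation overlap statistic is compared to the sampled distribution,
# yielding an empirical p-value, a log2 fold change and BH q-values.

#' Build isochores from a windowed GC track
#'
#' GC fractions are binned into `n_gc_classes` equal-width classes on
#' `[0, 1]`; contiguous same-class windows (book-ended, same chromosome)
#' merge into one isochore. The windows must tile the workspace: every
#' window must fall inside a workspace interval.
#'
#' @param workspace data.frame of assayable regions (chrom, start, end).
#' @param gc_track data.frame with chrom, start, end, value (GC fraction per
#'   window, in `[0, 1]`).
#' @param n_gc_classes number of equal-width GC classes (default 4).
#' @return data.table with chrom, start, end, gc_class; isochores tile the
#'   union of the windows without overlap.
#' @export
build_isochores <- function(workspace, gc_track, n_gc_classes = 4) {
  ws <- merge_intervals(validate_intervals(workspace, "workspace"))
  gc <- data.table::as.data.table(validate_intervals(gc_track, "gc_track"))
  if (!"value" %in% names(gc)) stop("gc_track needs a value column")
  if (any(gc$value < 0 | gc$value > 1)) stop("GC fractions must be in [0, 1]")
  stopifnot(n_gc_classes >= 1)
  # every window must lie inside some workspace interval
  sizes <- ws[, .(size = max(end)), by = chrom]
  offs <- genome_offsets(sizes)
  wsg <- to_global(ws, offs)
  inside <- logical(nrow(gc))
  known <- gc$chrom %in% names(offs)
  if (any(known)) {
    gcg <- to_global(gc[known], offs)
    idx <- findInterval(gcg$start, wsg$start)
    inside[known] <- idx >= 1L & gcg$end <= wsg$end[pmax(idx, 1L)]
  }
  if (!all(inside)) {
    stop(sprintf("%d GC window(s) outside the workspace", sum(!inside)))
  }
  gc <- gc[order(chrom, start)]
  gc[, gc_class := pmin(floor(value * n_gc_classes) + 1L, n_gc_classes)]
  # run-length merge of book-ended same-class windows
  gc[, grp := cumsum(gc_class != data.table::shift(gc_class, fill = -1L) |
                       start != data.table::shift(end, fill = -1)), by = chrom]
  out <- gc[, .(start = min(start), end = max(end), gc_class = gc_class[1L]),
            by = .(chrom, grp)]
  out[, grp := NULL]
  out[order(chrom, start)]
}

# Precomputed placement machinery shared by all bootstrap draws: for each
# (merged) query segment, the candidate isochores of its own GC class large
# enough to contain it, with placement weight (len - seg_len + 1), laid out
# as one flat cumulative-weight vector so a whole draw is vectorised.
#' @noRd
segment_sampler <- function(segments, isochores) {
  seg <- merge_intervals(segments)
  iso <- data.table::as.data.table(isochores)
  stopifnot(all(c("chrom", "start", "end", "gc_class") %in% names(iso)))
  iso <- iso[order(chrom, start)]
  sizes <- iso[, .(size = max(end)), by = chrom]
  offs <- genome_offsets(sizes)
  isog <- to_global(iso, offs)
  iso_len <- iso$end - iso$start

  segg <- to_global(seg, offs)
  seg_len <- seg$end - seg$start
  mid <- (segg$start + segg$end) / 2
  # original isochore = the one containing the segment midpoint
  oi <- findInterval(mid, isog$start)
  if (any(oi < 1L | mid >= isog$end[pmax(oi, 1L)])) {
    stop("every segment must lie inside the isochore workspace")
  }
  orig_class <- iso$gc_class[oi]

  n_fallback <- 0L
  flat_iso <- integer(0); flat_seg <- integer(0); flat_w <- numeric(0)
  for (i in seq_along(seg_len)) {
    cand <- which(iso$gc_class == orig_class[i] & iso_len >= seg_len[i])
    if (length(cand) == 0L) {
      cand <- which(iso_len >= seg_len[i])
      n_fallback <- n_fallback + 1L
    }
    if (length(cand) == 0L) {
      stop(sprintf("segment of length %d exceeds every workspace interval", seg_len[i]))
    }
    flat_iso <- c(flat_iso, cand)
    flat_seg <- c(flat_seg, rep(i, length(cand)))
    flat_w <- c(flat_w, iso_len[cand] - seg_len[i] + 1)
  }
  if (n_fallback > 0L) {
    warning(sprintf("%d segment(s) larger than every same-class isochore; placed anywhere in the workspace", n_fallback))
  }
  cum <- cumsum(flat_w)
  left_edge <- c(0, cum[-length(cum)])
  seg_first <- match(seq_along(seg_len), flat_seg)
  seg_base <- left_edge[seg_first]
  seg_total <- vapply(seq_along(seg_len), function(i) sum(flat_w[flat_seg == i]),
                      numeric(1))
  list(
    segments = seg, seg_len = seg_len, offsets = offs,
    iso = iso, iso_gstart = isog$start,
    flat_iso = flat_iso, left_edge = left_edge,
    seg_base = seg_base, seg_total = seg_total
  )
}

# One bootstrap draw in global coordinates (start vector; end = start + len).
#' @noRd
sampler_draw <- function(sp) {
  v <- sp$seg_base + stats::runif(length(sp$seg_len)) * sp$seg_total
  j <- findInterval(v, sp$left_edge)
  off <- floor(v - sp$left_edge[j])
  start <- sp$iso_gstart[sp$flat_iso[j]] + off
  list(start = start, end = start + sp$seg_len, iso_idx = sp$flat_iso[j], local_off = off)
}

#' Randomise segments within their GC-class isochores
#'
#' Each merged query segment is placed uniformly at random inside an
#' isochore of the same GC class as its original location (the isochore
#' containing its midpoint), preserving its length; placements are
#' independent. A segment larger than every same-class isochore falls back
#' to a uniform placement anywhere in the workspace, with a warning.
#'
#' @param segments data.frame of query intervals (merged before placement).
#' @param isochores data.table from [build_isochores()].
#' @param seed integer seed.
#' @return data.table with chrom, start, end (one randomised placement per
#'   merged input segment; the multiset of lengths is conserved).
#' @export
sample_segments <- function(segments, isochores, seed = 1L) {
  sp <- segment_sampler(segments, isochores)
  d <- with_seed(seed, sampler_draw(sp))
  data.table::data.table(
    chrom = sp$iso$chrom[d$iso_idx],
    start = sp$iso$start[d$iso_idx] + d$local_off,
    end = sp$iso$start[d$iso_idx] + d$local_off + sp$seg_len
  )
}

#' Number of query segments overlapping an annotation
#'
#' Counts query segments intersecting the annotation by at least 1 bp; each
#' segment is counted at most once however many annotation intervals it
#' touches (GAT's segment-overlap counter).
#'
#' @param segments data.frame of query intervals.
#' @param annotation data.frame of annotation intervals.
#' @return integer count.
#' @export
segment_overlap_count <- function(segments, annotation) {
  seg <- validate_intervals(segments, "segments")
  if (nrow(seg) == 0L) return(0L)
  anno <- merge_intervals(validate_intervals(annotation, "annotation"))
  if (nrow(anno) == 0L) return(0L)
  chroms <- sort(unique(c(seg$chrom, anno$chrom)))
  sizes <- stats::setNames(rep(0, length(chroms)), chroms)
  for (d in list(seg, anno)) {
    mx <- tapply(d$end, d$chrom, max)
    sizes[names(mx)] <- pmax(sizes[names(mx)], mx)
  }
  offs <- genome_offsets(sizes)
  sg <- to_global(seg, offs)
  ag <- to_global(anno, offs)
  ord <- order(ag$start)
  sum(overlaps_any(sg$start, sg$end, ag$start[ord], ag$end[ord]))
}

#' Isochore-constrained bootstrap enrichment test
#'
#' Merges the query segments, counts the observed segment-overlap statistic
#' against each annotation, and compares it to the statistic over
#' `n_samples` randomised placements drawn by [sample_segments()] (one shared
#' set of draws for all annotations). The empirical p-value uses the
#' add-one pseudocount `(k + 1) / (n + 1)`; enrichment and depletion are
#' tested one-sided and the smaller p is reported with its direction.
#' `log2_fc = log2(observed / expected)`; an observed overlap with zero
#' expectation is reported as `Inf` with the `fc_defined` flag unset.
#' q-values are Benjamini--Hochberg across the supplied annotations.
#'
#' @param segments query CNV intervals (merged in a preprocessing step).
#' @param annotations one data.frame, or a named list of data.frames.
#' @param isochores data.table from [build_isochores()].
#' @param n_samples number of bootstrap samples (default 10000).
#' @param seed integer seed.
#' @return data.table with columns annotation, observed, expected, log2_fc,
#'   p_value, p_enriched, p_depleted, q_value, direction, fc_defined,
#'   n_samples. The reported `p_value` is the smaller one-sided p; because it
#'   is not doubled, it is a directional summary whose null distribution is
#'   conservative in the small-p tail but bounded near 0.5 from above -- use
#'   the one-sided columns for calibration checks.
#' @export
enrichment_test <- function(segments, annotations, isochores,
                            n_samples = 10000, seed = 1L) {
  stopifnot(n_samples >= 1)
  if (is.data.frame(annotations)) annotations <- list(annotation = annotations)
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("annotations must be named")
  }
  sp <- segment_sampler(segments, isochores)
  segg <- to_global(sp$segments, sp$offsets)

  # annotations in the sampler's global coordinate system, merged and sorted
  anno_g <- lapply(annotations, function(a) {
    a <- merge_intervals(validate_intervals(a, "annotation"))
    a <- a[chrom %in% names(sp$offsets)]
    g <- to_global(a, sp$offsets)
    ord <- order(g$start)
    list(start = g$start[ord], end = g$end[ord])
  })

  observed <- vapply(anno_g, function(a) {
    sum(overlaps_any(segg$start, segg$end, a$start, a$end))
  }, numeric(1))

  sampled <- matrix(0, nrow = n_samples, ncol = length(anno_g))
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      d <- sampler_draw(sp)
      for (k in seq_along(anno_g)) {
        sampled[s, k] <- sum(overlaps_any(d$start, d$end,
                                          anno_g[[k]]$start, anno_g[[k]]$end))
      }
    }
  })

  expected <- colMeans(sampled)
  p_enr <- (colSums(sampled >= rep(observed, each = n_samples)) + 1) / (n_samples + 1)
  p_dep <- (colSums(sampled <= rep(observed, each = n_samples)) + 1) / (n_samples + 1)
  p <- pmin(p_enr, p_dep)
  direction <- ifelse(p_enr <= p_dep, "enriched", "depleted")
  fc_defined <- expected > 0 & observed > 0
  log2_fc <- ifelse(observed > 0 & expected > 0, log2(observed / expected),
                    ifelse(observed > 0, Inf, ifelse(expected > 0, -Inf, 0)))
  out <- data.table::data.table(
    annotation = names(anno_g),
    observed = observed,
    expected = expected,
    log2_fc = log2_fc,
    p_value = p,
    p_enriched = p_enr,
    p_depleted = p_dep,
    q_value = correct_pvalues(p),
    direction = direction,
    fc_defined = fc_defined,
    n_samples = as.integer(n_samples)
  )
  out
}

#' Benjamini--Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p_values empirical p-values, all in (0, 1].
#' @return q-values in the input order.
#' @export
correct_pvalues <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / seq(m, 1) * p_values[o]))[ro]
  q
}

#' Compare per-annotation fold changes between two enrichment results
#'
#' @param result_a,result_b data.tables from [enrichment_test()] over the
#'   same annotation names (a mismatch is an error listing the difference).
#' @param q_threshold joint significance threshold (default 0.01).
#' @return data.table with annotation, log2_fc_a, log2_fc_b, fc_difference
#'   and both_significant (both q-values at or below the threshold).
#' @export
compare_fold_changes <- function(result_a, result_b, q_threshold = 0.01) {
  a <- data.table::as.data.table(result_a)
  b <- data.table::as.data.table(result_b)
  sym <- c(setdiff(a$annotation, b$annotation), setdiff(b$annotation, a$annotation))
  if (length(sym) > 0L) {
    stop(sprintf("annotation sets differ: %s", paste(sym, collapse = ", ")))
  }
  m <- merge(a, b, by = "annotation", suffixes = c("_a", "_b"))
  data.table::data.table(
    annotation = m$annotation,
    log2_fc_a = m$log2_fc_a,
    log2_fc_b = m$log2_fc_b,
    fc_difference = m$log2_fc_a - m$log2_fc_b,
    both_significant = m$q_value_a <= q_threshold & m$q_value_b <= q_threshold
  )
}
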