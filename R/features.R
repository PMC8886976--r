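# Per-CNV functional feature vectors, restricted to the TAD environment(s)
# the CNV intersects. The default registry holds the 12 text-documented
# features: four distances (gene, DDG2P gene, enhancer, CTCF), the boundary
# distance, constraint scores of the closest gene (LOEUF, p(HI), HI log
# odds), conservation of the closest enhancer, stability of the closest
# boundary, the pcHi-C regulatory-overlap score and the exon-overlap count.
# User-defined BED tracks each add one distance feature.

#' Default feature names
#'
#' @return character vector of the 12 default feature column names.
#' @export
default_feature_names <- function() {
  c("dist_gene", "dist_ddg2p_gene", "dist_enhancer", "dist_ctcf",
    "dist_boundary", "loeuf_closest_gene", "p_hi_closest_gene",
    "hi_log_odds_closest_gene", "enh_conservation_closest",
    "boundary_stability_closest", "pchic_score", "exon_overlap")
}

#' Distance from a CNV to the closest of a set of elements
#'
#' 0 when any element intersects the CNV, otherwise the minimum end-to-end
#' gap in bp; `NA` when the element list is empty. Elements are expected to
#' be drawn from the TAD environment(s) the CNV intersects.
#'
#' @param cnv single-row data.frame with chrom, start, end.
#' @param elements data.frame of candidate intervals (same chromosome space).
#' @return non-negative distance in bp, or `NA_real_`.
#' @export
distance_to_closest <- function(cnv, elements) {
  ce <- closest_element(cnv, elements)
  ce$distance
}

#' Closest element and its distance
#'
#' Returns the element achieving the minimum distance to the CNV; ties are
#' broken by smaller element start, then by row order.
#'
#' @inheritParams distance_to_closest
#' @return list with `index` (row in `elements`, `NA` if empty) and
#'   `distance`.
#' @export
closest_element <- function(cnv, elements) {
  cnv <- validate_intervals(cnv, "cnv")
  stopifnot(nrow(cnv) == 1L)
  el <- data.table::as.data.table(elements)
  el <- el[el$chrom == cnv$chrom]
  if (nrow(el) == 0L) return(list(index = NA_integer_, distance = NA_real_))
  d <- interval_gap(cnv$start, cnv$end, el$start, el$end)
  ord <- order(d, el$start)
  list(index = ord[1L], distance = d[ord[1L]], element = el[ord[1L]])
}

#' pcHi-C regulatory-overlap score of a CNV
#'
#' For each gene `g` with promoter--other interactions in the CNV's
#' environment, the per-gene score is the number of `g`'s interacting
#' fragments overlapped by the CNV (each fragment contributing 1 or 0)
#' divided by `g`'s LOEUF value. The feature aggregates per-gene scores with
#' `max` (default) or `sum`; 0 when no fragment is overlapped. Genes with a
#' missing or zero LOEUF are skipped with a warning.
#'
#' @param cnv single-row data.frame with chrom, start, end.
#' @param interactions pcHi-C table (chrom, start, end, gene_id,
#'   neg_log10_p), already restricted to significant interactions and to
#'   genes in the CNV's environment.
#' @param gene_loeuf named numeric vector mapping gene_id to LOEUF.
#' @param aggregate `"max"` or `"sum"`.
#' @return non-negative score.
#' @export
pchic_score <- function(cnv, interactions, gene_loeuf,
                        aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  cnv <- validate_intervals(cnv, "cnv")
  stopifnot(nrow(cnv) == 1L)
  x <- data.table::as.data.table(interactions)
  if (nrow(x) == 0L) return(0)
  ov <- x$chrom == cnv$chrom &
    pmin(x$end, cnv$end) > pmax(x$start, cnv$start)
  counts <- tapply(ov, x$gene_id, sum)
  lo <- gene_loeuf[names(counts)]
  bad <- is.na(lo) | lo == 0
  if (any(bad & counts > 0)) {
    warning(sprintf("skipped %d gene(s) with missing or zero LOEUF in pcHi-C scoring",
                    sum(bad & counts > 0)))
  }
  s <- as.numeric(counts[!bad]) / as.numeric(lo[!bad])
  if (length(s) == 0L) return(0)
  if (aggregate == "max") max(s, 0) else sum(s)
}

#' Number of distinct exons overlapped by a CNV
#'
#' @param cnv single-row data.frame with chrom, start, end.
#' @param exons exon table (chrom, start, end, ...), restricted to genes in
#'   the CNV's environment.
#' @param mode `"count"` (distinct exon intervals intersected by >= 1 bp,
#'   the default) or `"bp"` (total overlapped exonic bp after merging exons).
#' @return non-negative count (or bp).
#' @export
exon_overlap <- function(cnv, exons, mode = c("count", "bp")) {
  mode <- match.arg(mode)
  cnv <- validate_intervals(cnv, "cnv")
  stopifnot(nrow(cnv) == 1L)
  x <- data.table::as.data.table(exons)
  if (nrow(x) == 0L) return(0)
  x <- x[x$chrom == cnv$chrom]
  if (nrow(x) == 0L) return(0)
  if (mode == "count") {
    sum(pmin(x$end, cnv$end) > pmax(x$start, cnv$start))
  } else {
    m <- merge_intervals(x)
    sum(pmax(0, pmin(m$end, cnv$end) - pmax(m$start, cnv$start)))
  }
}

#' Annotate CNVs with TAD-environment features
#'
#' Computes one feature vector per CNV intersecting at least one TAD
#' environment. Candidate elements for a CNV spanning several TADs are the
#' union over all intersected environments; flanking boundaries of those
#' TADs are the boundary candidates. CNVs intersecting no TAD region are
#' routed to the `unscored` side table and receive no features.
#'
#' @param cnvs CNV table.
#' @param envs a `tad_environments` object (see [build_environments()]).
#' @param exons optional exon table with gene_id (enables `exon_overlap`).
#' @param pchic optional pcHi-C interaction table (enables `pchic_score`).
#' @param extra_tracks optional named list of BED-like data.frames; each adds
#'   a `dist_<name>` feature (distance to the closest element of that track
#'   within the TAD environment).
#' @param features character vector of feature names to compute (defaults to
#'   the full registry plus one distance per extra track). Unknown names are
#'   an error listing the available features.
#' @param pchic_min_neg_log10_p significance filter on interactions
#'   (default 3, i.e. p <= 1e-3).
#' @param pchic_aggregate `"max"` or `"sum"` across per-gene pcHi-C scores.
#' @param exon_mode `"count"` or `"bp"` for the exon-overlap feature.
#' @return list with `features` (data.table: id, svtype, label, then one
#'   column per feature, rows in input order of scored CNVs) and `unscored`
#'   (CNV rows outside every TAD region).
#' @export
annotate_cnvs <- function(cnvs, envs, exons = NULL, pchic = NULL,
                          extra_tracks = list(),
                          features = NULL,
                          pchic_min_neg_log10_p = 3,
                          pchic_aggregate = c("max", "sum"),
                          exon_mode = c("count", "bp")) {
  stopifnot(inherits(envs, "tad_environments"))
  pchic_aggregate <- match.arg(pchic_aggregate)
  exon_mode <- match.arg(exon_mode)
  x <- as_cnv_table(cnvs)
  extra_names <- if (length(extra_tracks) > 0L) paste0("dist_", names(extra_tracks)) else character(0)
  available <- c(default_feature_names(), extra_names)
  if (is.null(features)) features <- available
  unknown <- setdiff(features, available)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown feature(s): %s\navailable: %s",
                 paste(unknown, collapse = ", "), paste(available, collapse = ", ")))
  }

  tads <- envs$tads
  # CNV -> TAD incidence
  if (nrow(x) == 0L) {
    return(list(features = data.table::data.table(), unscored = x))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(tads))
  cnv_tad <- data.table::data.table(
    cnv_idx = S4Vectors::queryHits(hits),
    tad_id = tads$tad_id[S4Vectors::subjectHits(hits)]
  )
  scored_idx <- sort(unique(cnv_tad$cnv_idx))
  unscored <- x[setdiff(seq_len(nrow(x)), scored_idx)]
  if (length(scored_idx) == 0L) {
    return(list(features = data.table::data.table(), unscored = unscored))
  }

  # candidate elements per CNV: union over all intersected environments
  pairs <- function(inc) unique(merge(cnv_tad, inc, by = "tad_id",
                                      allow.cartesian = TRUE)[, .(cnv_idx, element_idx)])
  gene_pairs <- pairs(envs$incidence$genes)
  enh_pairs <- pairs(envs$incidence$enhancers)
  ctcf_pairs <- pairs(envs$incidence$ctcf)
  bmap <- data.table::data.table(
    tad_id = rep(tads$tad_id, 2L),
    element_idx = c(tads$left_boundary, tads$right_boundary)
  )[!is.na(element_idx)]
  bnd_pairs <- pairs(unique(bmap))

  min_dist <- function(p, track) {
    if (nrow(p) == 0L) {
      return(data.table::data.table(cnv_idx = integer(), dist = numeric(),
                                    element_idx = integer()))
    }
    d <- interval_gap(x$start[p$cnv_idx], x$end[p$cnv_idx],
                      track$start[p$element_idx], track$end[p$element_idx])
    p2 <- data.table::data.table(cnv_idx = p$cnv_idx, element_idx = p$element_idx,
                                 dist = d, estart = track$start[p$element_idx])
    p2 <- p2[order(cnv_idx, dist, estart, element_idx)]
    p2[!duplicated(cnv_idx), .(cnv_idx, dist, element_idx)]
  }

  g_min <- min_dist(gene_pairs, envs$genes)
  ddg2p_pairs <- gene_pairs[envs$genes$ddg2p[element_idx] %in% TRUE]
  d_min <- min_dist(ddg2p_pairs, envs$genes)
  e_min <- min_dist(enh_pairs, envs$enhancers)
  c_min <- min_dist(ctcf_pairs, envs$ctcf)
  b_min <- min_dist(bnd_pairs, envs$boundaries)

  out <- data.table::data.table(cnv_idx = scored_idx)
  put <- function(out, m, dist_col, score_col = NULL, score_vals = NULL) {
    mm <- m[match(out$cnv_idx, m$cnv_idx)]
    if (!is.null(dist_col)) out[, (dist_col) := mm$dist]
    if (!is.null(score_col)) out[, (score_col) := score_vals[mm$element_idx]]
    out
  }
  out <- put(out, g_min, "dist_gene")
  out <- put(out, d_min, "dist_ddg2p_gene")
  out <- put(out, e_min, "dist_enhancer", "enh_conservation_closest",
             envs$enhancers$conservation)
  out <- put(out, c_min, "dist_ctcf")
  out <- put(out, b_min, "dist_boundary", "boundary_stability_closest",
             envs$boundaries$stability)
  out <- put(out, g_min, NULL, "loeuf_closest_gene", envs$genes$loeuf)
  out <- put(out, g_min, NULL, "p_hi_closest_gene", envs$genes$p_hi)
  out <- put(out, g_min, NULL, "hi_log_odds_closest_gene", envs$genes$hi_log_odds)

  # exon overlap: exons of genes present in the CNV's environment(s)
  exon_counts <- rep(0, length(scored_idx))
  if (!is.null(exons) && nrow(exons) > 0L && nrow(gene_pairs) > 0L) {
    ex <- data.table::as.data.table(exons)
    env_genes <- data.table::data.table(
      cnv_idx = gene_pairs$cnv_idx,
      gene_id = envs$genes$gene_id[gene_pairs$element_idx]
    )
    exj <- merge(env_genes, ex, by = "gene_id", allow.cartesian = TRUE)
    if (nrow(exj) > 0L) {
      if (exon_mode == "count") {
        exj[, ov := pmin(end, x$end[cnv_idx]) > pmax(start, x$start[cnv_idx]) &
              chrom == x$chrom[cnv_idx]]
        cnt <- exj[ov == TRUE, .N, by = cnv_idx]
      } else {
        exj[, ovbp := pmax(0, pmin(end, x$end[cnv_idx]) - pmax(start, x$start[cnv_idx])) *
              (chrom == x$chrom[cnv_idx])]
        cnt <- exj[, .(N = sum(ovbp)), by = cnv_idx]
      }
      exon_counts[match(cnt$cnv_idx, scored_idx)] <- cnt$N
    }
  }
  out[, exon_overlap := exon_counts]

  # pcHi-C score: significant interactions of environment genes
  pc_scores <- rep(0, length(scored_idx))
  if (!is.null(pchic) && nrow(pchic) > 0L && nrow(gene_pairs) > 0L) {
    pc <- data.table::as.data.table(pchic)[neg_log10_p >= pchic_min_neg_log10_p]
    gene_loeuf <- stats::setNames(envs$genes$loeuf, envs$genes$gene_id)
    env_genes <- data.table::data.table(
      cnv_idx = gene_pairs$cnv_idx,
      gene_id = envs$genes$gene_id[gene_pairs$element_idx]
    )
    pcj <- merge(env_genes, pc, by = "gene_id", allow.cartesian = TRUE)
    if (nrow(pcj) > 0L) {
      pcj[, ov := as.integer(pmin(end, x$end[cnv_idx]) > pmax(start, x$start[cnv_idx]) &
                               chrom == x$chrom[cnv_idx])]
      per_gene <- pcj[, .(n_ov = sum(ov)), by = .(cnv_idx, gene_id)]
      per_gene[, lo := gene_loeuf[gene_id]]
      skipped <- per_gene[(is.na(lo) | lo == 0) & n_ov > 0]
      if (nrow(skipped) > 0L) {
        warning(sprintf("pcHi-C: skipped %d gene/CNV score(s) with missing or zero LOEUF",
                        nrow(skipped)))
      }
      per_gene <- per_gene[!is.na(lo) & lo > 0]
      if (nrow(per_gene) > 0L) {
        agg <- if (pchic_aggregate == "max") {
          per_gene[, .(s = max(n_ov / lo)), by = cnv_idx]
        } else {
          per_gene[, .(s = sum(n_ov / lo)), by = cnv_idx]
        }
        pc_scores[match(agg$cnv_idx, scored_idx)] <- pmax(agg$s, 0)
      }
    }
  }
  out[, pchic_score := pc_scores]

  # user-defined distance tracks, sorted into the same TAD environments
  for (nm in names(extra_tracks)) {
    tr <- validate_intervals(extra_tracks[[nm]], nm)
    if (nrow(tr) == 0L) {
      out[, (paste0("dist_", nm)) := NA_real_]
      next
    }
    th <- GenomicRanges::findOverlaps(as_granges(tads), as_granges(tr))
    inc <- data.table::data.table(tad_id = tads$tad_id[S4Vectors::queryHits(th)],
                                  element_idx = S4Vectors::subjectHits(th))
    m <- min_dist(pairs(inc), tr)
    out <- put(out, m, paste0("dist_", nm))
  }

  meta <- x[scored_idx, .(id, chrom, start, end, svtype, label)]
  res <- cbind(meta, out[, setdiff(names(out), "cnv_idx"), with = FALSE])
  keep_cols <- c("id", "chrom", "start", "end", "svtype", "label", features)
  res <- res[, intersect(keep_cols, names(res)), with = FALSE]
  list(features = res, unscored = unscored)
}

#' Coding-penalty transform of a feature table
#'
#' Rows whose CNV does not directly affect a coding region (no exon overlap)
#' have their gene-constraint features replaced by fixed values of least
#' regulatory importance: `p_hi_closest_gene = 0`,
#' `hi_log_odds_closest_gene = -10`, `loeuf_closest_gene = 2`. Coding rows
#' are unchanged; the transform is idempotent.
#'
#' @param features feature table from [annotate_cnvs()].
#' @param coding_overlap optional logical vector aligned with rows; defaults
#'   to `exon_overlap > 0`.
#' @return transformed copy of the feature table.
#' @export
coding_penalty_transform <- function(features, coding_overlap = NULL) {
  x <- data.table::copy(data.table::as.data.table(features))
  if (is.null(coding_overlap)) {
    if (!"exon_overlap" %in% names(x)) {
      stop("coding_overlap not supplied and no exon_overlap column present")
    }
    coding_overlap <- !is.na(x$exon_overlap) & x$exon_overlap > 0
  }
  if (length(coding_overlap) != nrow(x)) {
    stop("coding_overlap must align with feature rows")
  }
  nc <- which(!coding_overlap)
  if ("p_hi_closest_gene" %in% names(x)) x[nc, p_hi_closest_gene := 0]
  if ("hi_log_odds_closest_gene" %in% names(x)) x[nc, hi_log_odds_closest_gene := -10]
  if ("loeuf_closest_gene" %in% names(x)) x[nc, loeuf_closest_gene := 2]
  x[]
}
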