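# Reading, validating, filtering, deduplicating and size-matching CNV call
# sets. CNV tables carry: chrom, start, end (0-based half-open), svtype
# (DEL/DUP), label (pathogenic/nonpathogenic/unknown), af (allele frequency,
# NA allowed), source_tag (provenance) and id.

CNV_COLUMNS <- c("chrom", "start", "end", "svtype", "label", "af", "source_tag", "id")

#' Run code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package operations do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' @noRd
as_cnv_table <- function(x) {
  x <- data.table::as.data.table(x)
  if (!"label" %in% names(x)) x[, label := "unknown"]
  if (!"af" %in% names(x)) x[, af := NA_real_]
  if (!"source_tag" %in% names(x)) x[, source_tag := NA_character_]
  if (!"id" %in% names(x)) {
    x[, id := sprintf("%s:%s-%s_%s_%d", chrom, start, end, svtype, seq_len(.N))]
  }
  validate_intervals(x, "CNVs")
  bad_type <- !x$svtype %in% c("DEL", "DUP")
  if (any(bad_type)) stop("svtype must be DEL or DUP")
  if (any(!is.na(x$af) & (x$af < 0 | x$af > 1))) stop("af must be in [0, 1] or NA")
  x[, CNV_COLUMNS, with = FALSE]
}

#' Read a CNV call set from BED or VCF
#'
#' BED input is tab-separated with columns chrom, start, end and optionally
#' svtype (DEL/DUP), label, allele frequency and source tag; coordinates are
#' 0-based half-open and used as-is. VCF input must carry `SVTYPE` and `END`
#' INFO fields; 1-based inclusive VCF coordinates are converted to the
#' internal half-open 0-based convention (`POS=1001, END=2000` becomes
#' `[1000, 2000)`). Records with an SVTYPE other than DEL/DUP are skipped
#' with a single summary warning.
#'
#' @param path input file.
#' @param format `"BED"` or `"VCF"`; guessed from the file extension when
#'   omitted.
#' @param source_tag provenance tag stored with every record (defaults to the
#'   file name).
#' @return data.table of CNVs (possibly with zero rows).
#' @export
read_cnvs <- function(path, format = c("auto", "BED", "VCF"), source_tag = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "VCF" else "BED"
  }
  if (is.null(source_tag)) source_tag <- basename(path)
  if (format == "BED") read_cnvs_bed(path, source_tag) else read_cnvs_vcf(path, source_tag)
}

#' @noRd
read_cnvs_bed <- function(path, src) {
  empty <- data.table::data.table(
    chrom = character(), start = numeric(), end = numeric(),
    svtype = character(), label = character(), af = numeric(),
    source_tag = character(), id = character()
  )
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  x <- tryCatch(
    data.table::fread(text = lines, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop(sprintf("%s: parse error: %s", path, conditionMessage(e)))
  )
  if (ncol(x) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path))
  cols <- c("chrom", "start", "end", "svtype", "label", "af", "source_col", "id")
  data.table::setnames(x, cols[seq_len(min(ncol(x), 8L))])
  x[, chrom := as.character(chrom)]
  for (cc in c("start", "end")) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    if (any(is.na(v))) {
      stop(sprintf("%s: malformed %s at line %d", path, cc, which(is.na(v))[1L]))
    }
    data.table::set(x, j = cc, value = v)
  }
  bad <- which(x$end <= x$start | x$start < 0)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid interval at line %d", path, bad[1L]))
  }
  if (!"svtype" %in% names(x)) x[, svtype := "DEL"]
  keep <- x$svtype %in% c("DEL", "DUP")
  if (any(!keep)) {
    warning(sprintf("%s: skipped %d record(s) with unsupported SVTYPE", path, sum(!keep)))
    x <- x[keep]
  }
  if (nrow(x) == 0L) return(empty)
  if ("af" %in% names(x)) x[, af := suppressWarnings(as.numeric(af))]
  if ("source_col" %in% names(x)) {
    x[, source_tag := as.character(source_col)]
  } else {
    x[, source_tag := src]
  }
  as_cnv_table(x)
}

#' @noRd
read_cnvs_vcf <- function(path, src) {
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (!all(c("SVTYPE", "END") %in% names(info))) {
    stop(sprintf("%s: VCF records must carry SVTYPE and END INFO fields", path))
  }
  svtype <- as.character(info$SVTYPE)
  keep <- svtype %in% c("DEL", "DUP")
  if (any(!keep)) {
    warning(sprintf("%s: skipped %d record(s) with unsupported SVTYPE", path, sum(!keep)))
  }
  if (!any(keep)) {
    return(as_cnv_table(data.table::data.table(
      chrom = character(), start = numeric(), end = numeric(), svtype = character()
    )))
  }
  af <- rep(NA_real_, length(svtype))
  if ("AF" %in% names(info)) {
    af_raw <- info$AF
    af <- vapply(seq_along(af_raw), function(i) {
      v <- unlist(af_raw[i])
      if (length(v) == 0L) NA_real_ else as.numeric(v[1L])
    }, numeric(1))
  }
  ids <- names(rr)
  if (is.null(ids)) ids <- sprintf("sv%d", seq_along(rr))
  x <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = as.numeric(GenomicRanges::start(rr)) - 1, # 1-based -> 0-based
    end = as.numeric(unlist(info$END)),
    svtype = svtype, af = af, id = ids, source_tag = src
  )[keep]
  as_cnv_table(x)
}

#' Filter a CNV set by size, chromosome, label and allele frequency
#'
#' Mirrors the standard pathogenic-call curation: keep variants strictly
#' larger than `min_size_bp` (a 50 bp CNV is removed at the default
#' threshold), restrict to autosomes, and optionally restrict labels and cap
#' the allele frequency. Filtering is total and idempotent.
#'
#' @param cnvs CNV table.
#' @param min_size_bp retain only `end - start > min_size_bp` (strict).
#' @param autosomes_only drop chromosomes other than (chr)1..22.
#' @param allowed_labels optional character vector of labels to keep.
#' @param af_max optional allele-frequency cap; records with `NA` af always
#'   pass.
#' @param af_mode `"strict"` keeps `af < af_max`, `"inclusive"` keeps
#'   `af <= af_max`.
#' @return filtered CNV data.table.
#' @export
filter_cnvs <- function(cnvs, min_size_bp = 50, autosomes_only = TRUE,
                        allowed_labels = NULL, af_max = NULL,
                        af_mode = c("strict", "inclusive")) {
  af_mode <- match.arg(af_mode)
  x <- as_cnv_table(cnvs)
  keep <- (x$end - x$start) > min_size_bp
  if (autosomes_only) {
    keep <- keep & grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", x$chrom)
  }
  if (!is.null(allowed_labels)) keep <- keep & x$label %in% allowed_labels
  if (!is.null(af_max)) {
    pass <- if (af_mode == "strict") x$af < af_max else x$af <= af_max
    keep <- keep & (is.na(x$af) | pass)
  }
  x[keep]
}

#' Cluster overlapping CNVs and keep one representative per cluster
#'
#' CNVs of the same type on the same chromosome connected by a reciprocal
#' overlap of at least `threshold` (single-linkage transitive closure) form a
#' cluster; one representative is retained per cluster. Under the
#' `"smallest"` rule the shortest variant wins (ties broken lexicographically
#' by chrom, start, end, id); under `"source_priority"` the variant whose
#' `source_tag` appears earliest in `priority` wins (sources missing from the
#' list sort last, with a warning; remaining ties fall back to the smallest
#' rule).
#'
#' @param cnvs CNV table.
#' @param threshold reciprocal-overlap threshold in (0, 1]; default 0.9.
#' @param tie_rule `"smallest"` or `"source_priority"`.
#' @param priority ordered character vector of source tags (highest first);
#'   required for `"source_priority"`.
#' @return deduplicated CNV data.table (a subset of the input rows).
#' @export
cluster_and_deduplicate <- function(cnvs, threshold = 0.9,
                                    tie_rule = c("smallest", "source_priority"),
                                    priority = NULL) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(threshold > 0, threshold <= 1)
  x <- as_cnv_table(cnvs)
  if (nrow(x) <= 1L) return(x)
  if (tie_rule == "source_priority" && is.null(priority)) {
    stop("source_priority requires a priority vector")
  }
  gr <- as_granges(x)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  same_type <- x$svtype[qi] == x$svtype[si]
  qi <- qi[same_type]; si <- si[same_type]
  if (length(qi) > 0L) {
    ro <- reciprocal_overlap(x[qi], x[si])
    pass <- ro >= threshold
    qi <- qi[pass]; si <- si[pass]
  }
  # union-find over qualifying pairs (single-linkage closure)
  parent <- seq_len(nrow(x))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(qi)) {
    a <- find(qi[k]); b <- find(si[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nrow(x)), find, integer(1))
  x[, `:=`(.cluster = root, .len = end - start)]
  if (tie_rule == "source_priority") {
    rank_map <- stats::setNames(seq_along(priority), priority)
    prio <- rank_map[x$source_tag]
    if (any(is.na(prio) & x$.cluster %in% x$.cluster[duplicated(x$.cluster)])) {
      warning("some clustered CNVs have a source_tag absent from the priority list")
    }
    prio[is.na(prio)] <- length(priority) + 1L
    x[, .prio := prio]
  } else {
    x[, .prio := 1L]
  }
  ord <- order(x$.cluster, x$.prio, x$.len, x$chrom, x$start, x$end, x$id)
  x <- x[ord]
  out <- x[!duplicated(x$.cluster)]
  out[, c(".cluster", ".len", ".prio") := NULL]
  out[order(chrom, start, end)]
}

#' Equal-probability size bins from an empirical CDF
#'
#' Computes `n_bins` equal-probability bins from the empirical distribution
#' of `sizes`: edges are the linear-interpolation quantiles at `k / n_bins`,
#' `k = 0..n_bins`, with duplicate edges collapsed. Every input size falls in
#' exactly one bin (terminal bins are closed).
#'
#' @param sizes numeric vector of variant lengths in bp.
#' @param n_bins number of bins (default 60).
#' @return an object of class `size_binning` with elements `edges` and
#'   `n_bins`.
#' @export
ecdf_size_bins <- function(sizes, n_bins = 60) {
  if (length(sizes) == 0L) stop("sizes must be non-empty")
  if (n_bins < 1) stop("n_bins must be >= 1")
  edges <- unname(stats::quantile(sizes, probs = seq(0, 1, length.out = n_bins + 1),
                                  type = 7, names = FALSE))
  edges <- unique(edges)
  structure(list(edges = edges, n_bins = max(1L, length(edges) - 1L)),
            class = "size_binning")
}

#' Assign sizes to ECDF bins
#'
#' @param binning a `size_binning` object.
#' @param sizes numeric vector; values outside the edge range are clamped
#'   into the terminal bins.
#' @return integer bin index per size, in `1..binning$n_bins`.
#' @export
assign_size_bins <- function(binning, sizes) {
  stopifnot(inherits(binning, "size_binning"))
  if (length(binning$edges) == 1L) return(rep(1L, length(sizes)))
  findInterval(sizes, binning$edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Size-match pathogenic and non-pathogenic CNV sets
#'
#' Bins the non-pathogenic sizes into `n_bins` equal-probability ECDF bins
#' and, within each bin, retains `min(n_pathogenic, n_nonpathogenic)` variants
#' from each class, sampled without replacement. The two returned sets are
#' balanced per bin and overall; results are reproducible under `seed`.
#'
#' @param pathogenic,nonpathogenic CNV tables.
#' @param n_bins number of ECDF bins (default 60).
#' @param seed integer seed.
#' @return list with elements `pathogenic`, `nonpathogenic` (matched subsets)
#'   and `binning`.
#' @export
size_match <- function(pathogenic, nonpathogenic, n_bins = 60, seed = 1L) {
  p <- as_cnv_table(pathogenic); n <- as_cnv_table(nonpathogenic)
  if (nrow(p) == 0L || nrow(n) == 0L) stop("both CNV sets must be non-empty")
  binning <- ecdf_size_bins(n$end - n$start, n_bins)
  pb <- assign_size_bins(binning, p$end - p$start)
  nb <- assign_size_bins(binning, n$end - n$start)
  keep_p <- integer(0); keep_n <- integer(0)
  with_seed(seed, {
    for (b in sort(unique(c(pb, nb)))) {
      ip <- which(pb == b); jn <- which(nb == b)
      m <- min(length(ip), length(jn))
      if (m == 0L) next
      keep_p <- c(keep_p, if (length(ip) == m) ip else sample(ip, m))
      keep_n <- c(keep_n, if (length(jn) == m) jn else sample(jn, m))
    }
  })
  list(pathogenic = p[sort(keep_p)], nonpathogenic = n[sort(keep_n)],
       binning = binning)
}
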