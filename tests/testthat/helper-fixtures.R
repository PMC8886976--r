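# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use the dumbest correct algorithm (per-base membership, double loops,
# exhaustive pair counting) so they stay independent of the implementation
# paths they check.

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 1000L, max_len = 120L) {
  tadcnv::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE)
    len <- sample.int(max_len, n, replace = TRUE)
    data.table::data.table(
      chrom = sample(chroms, n, replace = TRUE),
      start = start, end = start + len
    )
  })
}

# per-base membership reciprocal overlap
brute_reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ba <- seq(a$start, a$end - 1)
  bb <- seq(b$start, b$end - 1)
  ov <- length(intersect(ba, bb))
  min(ov / length(ba), ov / length(bb))
}

brute_min_distance <- function(cnv, elements) {
  el <- elements[elements$chrom == cnv$chrom, ]
  if (nrow(el) == 0L) return(NA_real_)
  d <- vapply(seq_len(nrow(el)), function(i) {
    if (el$start[i] < cnv$end && el$end[i] > cnv$start) return(0)
    min(abs(c(el$start[i] - cnv$end, cnv$start - el$end[i])))
  }, numeric(1))
  min(d)
}

# exhaustive concordant-pair AUC with half credit for ties
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

brute_segment_overlap_count <- function(segments, annotation) {
  n <- 0L
  for (i in seq_len(nrow(segments))) {
    hit <- FALSE
    for (j in seq_len(nrow(annotation))) {
      if (segments$chrom[i] == annotation$chrom[j] &&
          segments$start[i] < annotation$end[j] &&
          segments$end[i] > annotation$start[j]) hit <- TRUE
    }
    n <- n + hit
  }
  n
}

# small genome used across module tests (cheap to annotate)
tiny_genome <- function(seed = 7L) {
  tadcnv::generate_genome(tadcnv::toy_genome_config(
    n_chromosomes = 2, chrom_length_bp = 2e6, n_tads = 4,
    genes_per_tad = 2, enhancers_per_tad = 3, ctcf_per_tad = 3,
    seed = seed
  ))
}

tiny_envs <- function(genome = tiny_genome()) {
  tadcnv::build_environments(genome$tads, genome$boundaries, genome$genes,
                             genome$enhancers, genome$ctcf)
}

# feature matrix with one informative feature (signal), one correlated copy
# and noise features; labels planted on the signal
planted_features <- function(n = 300, seed = 1L) {
  tadcnv::with_seed(seed, {
    y <- rep(c("pathogenic", "nonpathogenic"), length.out = n)
    signal <- ifelse(y == "pathogenic", 1, 0) + rnorm(n, 0, 0.4)
    data.table::data.table(
      signal = signal,
      echo = signal + rnorm(n, 0, 0.05),
      noise1 = rnorm(n),
      noise2 = rnorm(n),
      constant = rep(1, n),
      label = y
    )
  })
}
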