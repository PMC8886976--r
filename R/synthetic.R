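# Toy-genome simulator: a stated world with planted, parameterised signal so
# that every other module is testable without downloads. TADs tile each
# chromosome; genes, enhancers and CTCF sites are sorted into them; gene
# constraint scores are drawn from fixed distributions; pathogenic CNVs are
# forced to overlap highly haploinsufficient (p(HI) > 0.9) genes with a
# stated probability while non-pathogenic CNVs tend to avoid them.

#' Toy genome configuration
#'
#' Defaults describe a two-chromosome, 10 Mb/chromosome toy genome with
#' 20 TADs per chromosome (500 kb TADs, 10 kb boundaries), 3 genes, 5
#' enhancers and 5 CTCF sites per TAD -- a scaled-down caricature of the
#' density of the human annotation tracks the pipeline consumes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length (bp).
#' @param n_tads TADs per chromosome.
#' @param genes_per_tad,enhancers_per_tad,ctcf_per_tad element densities.
#' @param boundary_bp TAD boundary width (bp).
#' @param gc_profile `"uniform"` (one GC class) or `"blocky"` (alternating
#'   GC blocks giving multiple isochores per chromosome).
#' @param gc_window_bp GC track window size (bp).
#' @param missing_rate fraction of gene scores set to missing (exercises the
#'   imputer).
#' @param seed integer seed.
#' @return config list of class `toy_genome_config`.
#' @export
toy_genome_config <- function(n_chromosomes = 2, chrom_length_bp = 10e6,
                              n_tads = 20, genes_per_tad = 3,
                              enhancers_per_tad = 5, ctcf_per_tad = 5,
                              boundary_bp = 10e3,
                              gc_profile = c("blocky", "uniform"),
                              gc_window_bp = 100e3,
                              missing_rate = 0.05, seed = 1L) {
  gc_profile <- match.arg(gc_profile)
  stopifnot(n_chromosomes >= 1, chrom_length_bp > 0, n_tads >= 1,
            genes_per_tad >= 0, enhancers_per_tad >= 0, ctcf_per_tad >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "toy_genome_config")
}

#' Generate a toy genome with annotation tracks
#'
#' TADs tile each chromosome with boundary intervals at the internal
#' borders (stability ~ Beta(2, 2)). Gene scores: p(HI) ~ Beta(0.5, 0.5)
#' (about a fifth of genes exceed 0.9), LOEUF ~ Gamma(2, scale 0.4)
#' truncated at 2, HI log odds = logit(p(HI)) + N(0, 0.5) noise (so the two
#' haploinsufficiency scores are strongly correlated, as in real constraint
#' tables), DDG2P flags ~ Bernoulli(0.15). Enhancer conservation ~
#' Beta(2, 5). A random `missing_rate` fraction of each gene score column is
#' set to NA. pcHi-C interactions connect half of the genes to 1--5
#' fragments in their own TAD. Fully reproducible under the config seed.
#'
#' @param config a `toy_genome_config`.
#' @return list of class `toy_genome` with chrom_sizes, tads, boundaries,
#'   genes, exons, enhancers, ctcf, pchic, gc_track.
#' @export
generate_genome <- function(config = toy_genome_config()) {
  stopifnot(inherits(config, "toy_genome_config"))
  L <- config$chrom_length_bp
  tad_w <- L / config$n_tads
  if (config$boundary_bp >= tad_w) stop("boundaries wider than TADs: infeasible packing")
  max_gene_w <- 5e4
  if (config$genes_per_tad > 0 && max_gene_w >= tad_w - config$boundary_bp) {
    stop("TADs too small for the gene width range: infeasible packing")
  }
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sizes <- stats::setNames(rep(L, length(chroms)), chroms)

  with_seed(config$seed, {
    boundaries <- data.table::rbindlist(lapply(chroms, function(ch) {
      centers <- tad_w * seq_len(config$n_tads - 1)
      if (length(centers) == 0L) {
        return(data.table::data.table(chrom = character(), start = numeric(),
                                      end = numeric(), stability = numeric()))
      }
      data.table::data.table(
        chrom = ch,
        start = centers - config$boundary_bp / 2,
        end = centers + config$boundary_bp / 2,
        stability = rbeta(length(centers), 2, 2)
      )
    }))
    tads <- tads_from_boundaries(boundaries, sizes)

    place_in <- function(region_start, region_end, width) {
      # uniform start such that [start, start + width) stays inside the region
      region_start + floor(runif(length(width)) * (region_end - region_start - width + 1))
    }
    per_tad <- function(n_per_tad, wmin, wmax) {
      if (n_per_tad == 0L || nrow(tads) == 0L) {
        return(data.table::data.table(chrom = character(), start = numeric(), end = numeric()))
      }
      idx <- rep(seq_len(nrow(tads)), each = n_per_tad)
      w <- round(exp(runif(length(idx), log(wmin), log(wmax))))
      data.table::data.table(
        chrom = tads$chrom[idx],
        start = place_in(tads$start[idx], tads$end[idx], w),
        w = w
      )[, .(chrom, start, end = start + w)]
    }

    genes <- per_tad(config$genes_per_tad, 5e3, max_gene_w)
    if (nrow(genes) > 0L) {
      genes[, gene_id := sprintf("g%04d", seq_len(.N))]
      genes[, p_hi := rbeta(.N, 0.5, 0.5)]
      genes[, loeuf := pmin(rgamma(.N, shape = 2, scale = 0.4), 2)]
      genes[, hi_log_odds := qlogis(pmin(pmax(p_hi, 1e-4), 1 - 1e-4)) + rnorm(.N, 0, 0.5)]
      genes[, ddg2p := rbinom(.N, 1, 0.15) == 1L]
      for (col in c("p_hi", "loeuf", "hi_log_odds")) {
        nas <- runif(nrow(genes)) < config$missing_rate
        data.table::set(genes, which(nas), col, NA_real_)
      }
    } else {
      genes <- data.table::data.table(chrom = character(), start = numeric(),
                                      end = numeric(), gene_id = character(),
                                      p_hi = numeric(), loeuf = numeric(),
                                      hi_log_odds = numeric(), ddg2p = logical())
    }

    exons <- if (nrow(genes) > 0L) {
      data.table::rbindlist(lapply(seq_len(nrow(genes)), function(i) {
        n_ex <- sample(2:8, 1)
        gw <- genes$end[i] - genes$start[i]
        piece <- gw / (2 * n_ex)
        starts <- genes$start[i] + (2 * seq_len(n_ex) - 2) * piece
        data.table::data.table(
          chrom = genes$chrom[i],
          start = floor(starts),
          end = floor(starts + piece),
          gene_id = genes$gene_id[i]
        )
      }))
    } else {
      data.table::data.table(chrom = character(), start = numeric(),
                             end = numeric(), gene_id = character())
    }

    enhancers <- per_tad(config$enhancers_per_tad, 200, 2000)
    if (nrow(enhancers) > 0L) enhancers[, conservation := rbeta(.N, 2, 5)]
    else enhancers[, conservation := numeric(0)]

    ctcf <- per_tad(config$ctcf_per_tad, 150, 400)

    pchic <- if (nrow(genes) > 0L) {
      tad_gr <- as_granges(tads)
      gi <- GenomicRanges::findOverlaps(
        as_granges(genes[, .(chrom, start, end)]), tad_gr, select = "arbitrary"
      )
      linked <- which(runif(nrow(genes)) < 0.5 & !is.na(gi))
      data.table::rbindlist(lapply(linked, function(i) {
        td <- tads[gi[i]]
        n_frag <- sample(1:5, 1)
        w <- rep(4e3, n_frag)
        data.table::data.table(
          chrom = td$chrom,
          start = place_in(rep(td$start, n_frag), rep(td$end, n_frag), w),
          gene_id = genes$gene_id[i],
          neg_log10_p = runif(n_frag, 0, 10)
        )[, .(chrom, start, end = start + 4e3, gene_id, neg_log10_p)]
      }))
    } else {
      data.table::data.table(chrom = character(), start = numeric(),
                             end = numeric(), gene_id = character(),
                             neg_log10_p = numeric())
    }

    gc_track <- data.table::rbindlist(lapply(chroms, function(ch) {
      starts <- seq(0, L - 1, by = config$gc_window_bp)
      ends <- pmin(starts + config$gc_window_bp, L)
      value <- if (config$gc_profile == "uniform") {
        rep(0.45, length(starts))
      } else {
        # blocks of 10 windows alternating between a low- and a high-GC class
        rep_len(rep(c(0.35, 0.55), each = 10), length(starts))
      }
      data.table::data.table(chrom = ch, start = starts, end = ends, value = value)
    }))

    structure(list(
      chrom_sizes = sizes, tads = tads, boundaries = boundaries,
      genes = genes, exons = exons, enhancers = enhancers, ctcf = ctcf,
      pchic = pchic, gc_track = gc_track, config = config
    ), class = "toy_genome")
  })
}

#' CNV effect model for the simulator
#'
#' Encodes the planted statistical structure the classifier assumes:
#' pathogenic CNVs overlap a highly haploinsufficient gene (p(HI) > 0.9)
#' with probability `p_hit_pathogenic`; otherwise they are placed uniformly
#' while avoiding such genes. Non-pathogenic CNVs hit with probability
#' `p_hit_nonpathogenic`. Setting both probabilities to 0 gives the null
#' world with no class signal. Sizes are log-uniform within each class's
#' range.
#'
#' @param n_pathogenic,n_nonpathogenic class sizes.
#' @param p_hit_pathogenic,p_hit_nonpathogenic forced-hit probabilities in
#'   `[0, 1]`.
#' @param size_range_pathogenic,size_range_nonpathogenic `c(min, max)` bp.
#' @param svtype variant type for the whole set.
#' @param seed integer seed.
#' @return list of class `cnv_effect_model`.
#' @export
cnv_effect_model <- function(n_pathogenic = 1000, n_nonpathogenic = 1000,
                             p_hit_pathogenic = 0.9,
                             p_hit_nonpathogenic = 0.1,
                             size_range_pathogenic = c(5e3, 2e5),
                             size_range_nonpathogenic = c(2e3, 1e5),
                             svtype = "DEL", seed = 1L) {
  stopifnot(p_hit_pathogenic >= 0, p_hit_pathogenic <= 1,
            p_hit_nonpathogenic >= 0, p_hit_nonpathogenic <= 1,
            all(size_range_pathogenic > 0), all(size_range_nonpathogenic > 0))
  structure(as.list(environment()), class = "cnv_effect_model")
}

#' Generate a labeled CNV set with planted signal
#'
#' @param genome a `toy_genome`.
#' @param model a `cnv_effect_model`.
#' @return CNV data.table with ground-truth labels.
#' @export
generate_cnvs <- function(genome, model = cnv_effect_model()) {
  stopifnot(inherits(genome, "toy_genome"), inherits(model, "cnv_effect_model"))
  sizes <- genome$chrom_sizes
  hi_genes <- genome$genes[!is.na(p_hi) & p_hi > 0.9]
  needs_hits <- model$p_hit_pathogenic > 0 || model$p_hit_nonpathogenic > 0
  if (needs_hits && nrow(hi_genes) == 0L) {
    stop("genome has no p(HI) > 0.9 genes to plant hits on")
  }
  chroms <- names(sizes)

  gen_class <- function(n, p_hit, size_range, label) {
    if (n == 0L) return(NULL)
    w <- round(exp(runif(n, log(size_range[1]), log(size_range[2]))))
    w <- pmin(w, min(sizes) - 1)
    hit <- runif(n) < p_hit
    chrom <- character(n); start <- numeric(n)
    for (i in seq_len(n)) {
      if (hit[i]) {
        g <- hi_genes[sample.int(nrow(hi_genes), 1L)]
        lo <- max(0, g$start - w[i] + 1)
        hi_pos <- min(sizes[[g$chrom]] - w[i], g$end - 1)
        chrom[i] <- g$chrom
        start[i] <- lo + floor(runif(1) * (hi_pos - lo + 1))
      } else {
        for (try in seq_len(100L)) {
          ch <- sample(chroms, 1L, prob = sizes / sum(sizes))
          st <- floor(runif(1) * (sizes[[ch]] - w[i]))
          clash <- nrow(hi_genes) > 0L &&
            any(hi_genes$chrom == ch & hi_genes$start < st + w[i] &
                  hi_genes$end > st)
          if (!clash) break
        }
        chrom[i] <- ch; start[i] <- st
      }
    }
    data.table::data.table(
      chrom = chrom, start = start, end = start + w,
      svtype = model$svtype, label = label, af = NA_real_,
      source_tag = "synthetic",
      id = sprintf("%s_%s_%d", label, model$svtype, seq_len(n))
    )
  }

  with_seed(model$seed, {
    out <- data.table::rbindlist(list(
      gen_class(model$n_pathogenic, model$p_hit_pathogenic,
                model$size_range_pathogenic, "pathogenic"),
      gen_class(model$n_nonpathogenic, model$p_hit_nonpathogenic,
                model$size_range_nonpathogenic, "nonpathogenic")
    ))
    as_cnv_table(out)
  })
}

#' Write a toy genome to the standard plain-text files
#'
#' Emits exactly the formats the package readers consume: TAD boundaries as
#' BED + stability, genes and pcHi-C as headered TSV, exons/enhancers/CTCF as
#' BED, GC as bedGraph, chromosome sizes as a two-column table.
#'
#' @param genome a `toy_genome`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_genome_files <- function(genome, dir) {
  stopifnot(inherits(genome, "toy_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite0 <- function(x, file, header) {
    data.table::fwrite(x, file, sep = "\t", col.names = header)
    file
  }
  paths <- c(
    boundaries = fwrite0(genome$boundaries[, .(chrom, start, end, stability)],
                         file.path(dir, "tad_boundaries.bed"), FALSE),
    tads = fwrite0(genome$tads[, .(chrom, start, end)],
                   file.path(dir, "tads.bed"), FALSE),
    genes = fwrite0(genome$genes[, .(chrom, start, end, gene_id, p_hi, loeuf,
                                     hi_log_odds, ddg2p = as.integer(ddg2p))],
                    file.path(dir, "genes.tsv"), TRUE),
    exons = fwrite0(genome$exons[, .(chrom, start, end, gene_id)],
                    file.path(dir, "exons.bed"), FALSE),
    enhancers = fwrite0(genome$enhancers[, .(chrom, start, end, conservation)],
                        file.path(dir, "enhancers.bed"), FALSE),
    ctcf = fwrite0(genome$ctcf[, .(chrom, start, end)],
                   file.path(dir, "ctcf.bed"), FALSE),
    pchic = fwrite0(genome$pchic[, .(chrom, start, end, gene_id, neg_log10_p)],
                    file.path(dir, "pchic.tsv"), TRUE),
    gc = fwrite0(genome$gc_track[, .(chrom, start, end, value)],
                 file.path(dir, "gc.bedgraph"), FALSE),
    chrom_sizes = fwrite0(data.table::data.table(chrom = names(genome$chrom_sizes),
                                                 size = genome$chrom_sizes),
                          file.path(dir, "chrom.sizes"), FALSE)
  )
  invisible(paths)
}
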