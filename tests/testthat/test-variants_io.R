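# CNV reading, filtering, reciprocal-overlap deduplication and size matching.

write_bed <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_cnvs parses BED with direct field mapping", {
  f <- write_bed(c("chr1\t1000\t2000\tDEL",
                   "chr2\t500\t800\tDUP\tpathogenic\t0.05\tsrcA"))
  x <- read_cnvs(f)
  expect_equal(nrow(x), 2L)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(1000, 500))
  expect_equal(x$end, c(2000, 800))
  expect_equal(x$svtype, c("DEL", "DUP"))
  expect_equal(x$label[2], "pathogenic")
  expect_equal(x$af[2], 0.05)
  expect_equal(x$source_tag[2], "srcA")
})

test_that("read_cnvs handles empty files, bad svtypes and malformed lines", {
  expect_equal(nrow(read_cnvs(write_bed(character(0)))), 0L)
  f <- write_bed(c("chr1\t0\t100\tDEL", "chr1\t50\t90\tINV"))
  expect_warning(x <- read_cnvs(f), "unsupported SVTYPE")
  expect_equal(nrow(x), 1L)
  expect_error(read_cnvs(write_bed("chr1\tabc\t100\tDEL")), "line 1")
  expect_error(read_cnvs(write_bed("chr1\t200\t100\tDEL")), "line 1")
  expect_error(read_cnvs("/nonexistent/file.bed"), "no such file")
})

test_that("read_cnvs converts VCF 1-based coordinates to half-open 0-based", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="AF">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1001\tsv1\tN\t<DEL>\t.\t.\tSVTYPE=DEL;END=2000;AF=0.25",
    "chr1\t5001\tsv2\tN\t<INS>\t.\t.\tSVTYPE=INS;END=5200"
  ), f)
  expect_warning(x <- read_cnvs(f), "unsupported SVTYPE")
  expect_equal(nrow(x), 1L)
  expect_equal(x$start, 1000)  # POS 1001 -> 0-based 1000
  expect_equal(x$end, 2000)
  expect_equal(x$af, 0.25)
  expect_equal(x$id, "sv1")
})

test_that("filter_cnvs applies the strict >50 bp rule, autosomes and AF modes", {
  cnvs <- data.table::data.table(
    chrom = c("chr1", "chrX", "chr2", "chr2"),
    start = c(0, 0, 0, 0),
    end = c(50, 200, 200, 300),
    svtype = "DEL",
    label = c("pathogenic", "pathogenic", "unknown", "benign"),
    af = c(NA, NA, 0.1, 0.05),
    source_tag = "t", id = c("a", "b", "c", "d")
  )
  out <- filter_cnvs(cnvs, min_size_bp = 50)
  expect_false("a" %in% out$id)  # length exactly 50 is removed
  expect_false("b" %in% out$id)  # chrX removed
  expect_setequal(out$id, c("c", "d"))

  keep <- filter_cnvs(cnvs, allowed_labels = c("pathogenic", "unknown"))
  expect_false("d" %in% keep$id)

  strict <- filter_cnvs(cnvs, af_max = 0.1)
  expect_false("c" %in% strict$id)  # af == 0.1 fails the strict boundary
  incl <- filter_cnvs(cnvs, af_max = 0.1, af_mode = "inclusive")
  expect_true("c" %in% incl$id)

  # idempotence and identity case
  expect_identical(filter_cnvs(out), out)
  all_pass <- data.table::copy(cnvs)[, `:=`(chrom = "chr1", end = 1000)]
  expect_equal(nrow(filter_cnvs(all_pass)), nrow(all_pass))
})

test_that("reciprocal_overlap matches hand examples and the per-base oracle", {
  iv <- function(s, e, ch = "chr1") data.table::data.table(chrom = ch, start = s, end = e)
  expect_equal(reciprocal_overlap(iv(100, 200), iv(100, 200)), 1)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(200, 300)), 0)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(50, 150)), 0.5)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(0, 100, "chr2")), 0)

  x <- random_intervals(60, seed = 42)
  for (i in seq_len(30)) {
    a <- x[i]; b <- x[i + 30]
    ro <- reciprocal_overlap(a, b)
    expect_equal(ro, brute_reciprocal_overlap(a, b))
    expect_equal(ro, reciprocal_overlap(b, a))  # symmetry
    expect_gte(ro, 0); expect_lte(ro, 1)
    if (ro == 1) expect_true(a$start == b$start && a$end == b$end && a$chrom == b$chrom)
  }
})

test_that("cluster_and_deduplicate keeps the smallest variant per cluster", {
  cnvs <- data.table::data.table(
    chrom = "chr1", start = c(0, 0, 5000), end = c(1000, 990, 6000),
    svtype = "DEL", label = "unknown", af = NA_real_, source_tag = "s",
    id = c("A", "B", "C")
  )
  out <- cluster_and_deduplicate(cnvs, threshold = 0.9)
  expect_setequal(out$id, c("B", "C"))  # B is smaller; C is disjoint

  # smallest-rule postcondition: no surviving pair above the threshold
  x <- random_intervals(80, seed = 11, chroms = "chr1", max_pos = 400, max_len = 80)
  x[, `:=`(svtype = "DEL", label = "unknown", af = NA_real_, source_tag = "s",
           id = sprintf("v%d", .I))]
  dd <- cluster_and_deduplicate(x, threshold = 0.9)
  expect_true(all(dd$id %in% x$id))  # output subset of input
  if (nrow(dd) > 1L) {
    for (i in seq_len(nrow(dd) - 1L)) {
      for (j in seq(i + 1L, nrow(dd))) {
        expect_lt(reciprocal_overlap(dd[i], dd[j]), 0.9)
      }
    }
  }
})

test_that("source-priority dedup follows the configured provenance order", {
  priority <- c("audano2019", "gnomad_sv", "dgv", "ukbiobank")
  cnvs <- data.table::data.table(
    chrom = "chr1", start = c(0, 2), end = c(1000, 1002),
    svtype = "DEL", label = "unknown", af = NA_real_,
    source_tag = c("dgv", "audano2019"), id = c("dgv-call", "audano-call")
  )
  out <- cluster_and_deduplicate(cnvs, threshold = 0.9,
                                 tie_rule = "source_priority", priority = priority)
  expect_equal(out$id, "audano-call")

  unknown_src <- data.table::copy(cnvs)[2, source_tag := "mystery"]
  expect_warning(
    out2 <- cluster_and_deduplicate(unknown_src, threshold = 0.9,
                                    tie_rule = "source_priority", priority = priority),
    "absent from the priority list"
  )
  expect_equal(out2$id, "dgv-call")  # known source wins over unknown
})

test_that("ecdf_size_bins builds equal-probability bins", {
  b <- ecdf_size_bins(1:120, n_bins = 60)
  bins <- assign_size_bins(b, 1:120)
  expect_equal(as.vector(table(bins)), rep(2L, 60))  # each bin holds exactly 2 values

  expect_equal(ecdf_size_bins(rep(7, 10))$n_bins, 1L)  # degenerate distribution
  b1 <- ecdf_size_bins(c(3, 9, 27), n_bins = 1)
  expect_equal(b1$edges, c(3, 27))
  expect_error(ecdf_size_bins(1:10, n_bins = 0), "n_bins")
  expect_error(ecdf_size_bins(numeric(0)), "non-empty")
  # every size falls in exactly one bin
  s <- c(1, 60, 120)
  expect_true(all(assign_size_bins(b, s) %in% 1:60))
})

test_that("size_match balances classes per bin without replacement", {
  mk <- function(sizes, label) data.table::data.table(
    chrom = "chr1", start = 0, end = sizes, svtype = "DEL", label = label,
    af = NA_real_, source_tag = "s", id = sprintf("%s%d", label, seq_along(sizes))
  )
  # symmetric input: both fully retained
  p <- mk(c(100, 200, 300, 400), "pathogenic")
  n <- mk(c(100, 200, 300, 400), "nonpathogenic")
  sm <- size_match(p, n, n_bins = 2, seed = 1)
  expect_equal(nrow(sm$pathogenic), 4L)
  expect_equal(nrow(sm$nonpathogenic), 4L)

  # one bin with 5 pathogenic vs 2 nonpathogenic -> 2 of each retained
  p2 <- mk(rep(100, 5), "pathogenic")
  n2 <- mk(rep(100, 2), "nonpathogenic")
  sm2 <- size_match(p2, n2, n_bins = 60, seed = 1)
  expect_equal(nrow(sm2$pathogenic), 2L)
  expect_equal(nrow(sm2$nonpathogenic), 2L)

  # adversarial: disjoint size ranges still give balanced output without
  # repetition, reproducibly
  p3 <- mk(round(exp(seq(log(5e4), log(5e5), length.out = 80))), "pathogenic")
  n3 <- mk(round(exp(seq(log(100), log(8e4), length.out = 120))), "nonpathogenic")
  a <- size_match(p3, n3, seed = 9)
  b <- size_match(p3, n3, seed = 9)
  expect_identical(a, b)  # determinism
  expect_equal(nrow(a$pathogenic), nrow(a$nonpathogenic))  # balance
  expect_false(any(duplicated(a$pathogenic$id)))
  expect_false(any(duplicated(a$nonpathogenic$id)))
  expect_true(all(a$pathogenic$id %in% p3$id))
  expect_true(all(a$nonpathogenic$id %in% n3$id))
})
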