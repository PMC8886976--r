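# Isochores, constrained segment randomisation and the bootstrap test.

simple_workspace <- function(L = 1e6, chroms = "chr1") {
  data.table::data.table(chrom = chroms, start = 0, end = L)
}

test_that("build_isochores merges same-class runs", {
  ws <- simple_workspace(3000)
  # GC values (0.3, 0.31, 0.6) with 2 classes -> a 2-window and a 1-window isochore
  gc <- data.table::data.table(chrom = "chr1", start = c(0, 1000, 2000),
                               end = c(1000, 2000, 3000), value = c(0.3, 0.31, 0.6))
  iso <- build_isochores(ws, gc, n_gc_classes = 2)
  expect_equal(nrow(iso), 2L)
  expect_equal(iso$end - iso$start, c(2000, 1000))
  expect_equal(iso$gc_class, c(1L, 2L))

  # uniform GC -> one isochore per chromosome
  ws2 <- data.table::data.table(chrom = c("chr1", "chr2"), start = 0, end = 2000)
  gc2 <- data.table::data.table(chrom = rep(c("chr1", "chr2"), each = 2),
                                start = rep(c(0, 1000), 2), end = rep(c(1000, 2000), 2),
                                value = 0.45)
  expect_equal(nrow(build_isochores(ws2, gc2, 4)), 2L)

  # alternating classes -> one isochore per window
  gc3 <- data.table::data.table(chrom = "chr1", start = c(0, 1000, 2000),
                                end = c(1000, 2000, 3000), value = c(0.2, 0.8, 0.2))
  expect_equal(nrow(build_isochores(ws, gc3, 2)), 3L)

  # window outside the workspace is an error
  gc_bad <- data.table::data.table(chrom = "chr1", start = 2500, end = 3500, value = 0.5)
  expect_error(build_isochores(ws, gc_bad, 2), "outside")
  expect_error(build_isochores(ws, data.table::copy(gc)[1, value := 1.5], 2), "GC")
})

test_that("sample_segments preserves lengths and GC-class conditioning", {
  ws <- simple_workspace(1e6)
  gc <- data.table::data.table(chrom = "chr1",
                               start = seq(0, 9e5, by = 1e5),
                               end = seq(1e5, 1e6, by = 1e5),
                               value = rep(c(0.3, 0.7), 5))
  iso <- build_isochores(ws, gc, n_gc_classes = 2)
  segs <- data.table::data.table(chrom = "chr1",
                                 start = c(10000, 150000, 430000),
                                 end = c(12000, 155000, 431000))
  out <- sample_segments(segs, iso, seed = 4)
  expect_equal(sort(out$end - out$start), sort(segs$end - segs$start))
  # class conditioning: each placement stays in an isochore of its own class
  orig_class <- iso$gc_class[findInterval((segs$start + segs$end) / 2, iso$start)]
  for (r in 1:20) {
    o <- sample_segments(segs, iso, seed = 100 + r)
    placed_class <- iso$gc_class[findInterval(o$start, iso$start)]
    expect_equal(placed_class, orig_class)
    # placement lies wholly inside one isochore
    k <- findInterval(o$start, iso$start)
    expect_true(all(o$end <= iso$end[k]))
  }

  # forced placement: an isochore exactly the segment's length
  iso1 <- data.table::data.table(chrom = "chr1", start = 0, end = 500, gc_class = 1L)
  seg1 <- data.table::data.table(chrom = "chr1", start = 0, end = 500)
  for (r in 1:5) {
    expect_equal(sample_segments(seg1, iso1, seed = r),
                 data.table::data.table(chrom = "chr1", start = 0, end = 500))
  }
})

test_that("sampled start positions are uniform on a uniform-GC chromosome", {
  L <- 1e5; l <- 1000
  iso <- data.table::data.table(chrom = "chr1", start = 0, end = L, gc_class = 1L)
  seg <- data.table::data.table(chrom = "chr1", start = 0, end = l)
  starts <- vapply(1:2000, function(r) sample_segments(seg, iso, seed = r)$start,
                   numeric(1))
  expect_gte(min(starts), 0)
  expect_lte(max(starts), L - l)
  cs <- suppressWarnings(chisq.test(table(cut(starts, seq(0, L - l, length.out = 11)))))
  expect_gt(cs$p.value, 0.001)
})

test_that("segment_overlap_count matches the brute-force counter", {
  anno <- data.table::data.table(chrom = "chr1", start = c(100, 300), end = c(200, 400))
  segs <- data.table::data.table(chrom = c("chr1", "chr1", "chr2"),
                                 start = c(150, 500, 150), end = c(160, 600, 160))
  expect_equal(segment_overlap_count(segs, anno), 1L)
  expect_equal(segment_overlap_count(segs, anno[0]), 0L)
  # a segment spanning two annotation intervals counts once
  span <- data.table::data.table(chrom = "chr1", start = 50, end = 450)
  expect_equal(segment_overlap_count(span, anno), 1L)

  for (i in 1:30) {
    s <- random_intervals(15, seed = 300 + i)
    a <- random_intervals(10, seed = 600 + i)
    expect_equal(segment_overlap_count(s, a), brute_segment_overlap_count(s, a))
  }
})

test_that("enrichment_test saturates on a full-workspace annotation", {
  ws <- simple_workspace(1e6)
  gc <- data.table::data.table(chrom = "chr1", start = 0, end = 1e6, value = 0.45)
  iso <- build_isochores(ws, gc, 2)
  segs <- data.table::data.table(chrom = "chr1", start = c(1e3, 5e5), end = c(2e3, 5.1e5))
  res <- enrichment_test(segs, list(everything = ws), iso, n_samples = 50, seed = 1)
  expect_equal(res$observed, 2)
  expect_equal(res$expected, 2)
  expect_equal(res$log2_fc, 0)
  expect_equal(res$p_value, 1)
  # p-values never fall below the pseudocount floor
  expect_gte(res$p_value, 1 / 51)
  # log2 fold-change arithmetic: observed 8, expected 4 -> 1
  expect_equal(log2(8 / 4), 1)
})

test_that("planted enrichment is detected on a toy genome", {
  g <- generate_genome(toy_genome_config(seed = 31))
  ws <- data.table::data.table(chrom = names(g$chrom_sizes), start = 0,
                               end = g$chrom_sizes)
  iso <- build_isochores(ws, g$gc_track, n_gc_classes = 4)
  cnvs <- generate_cnvs(g, cnv_effect_model(n_pathogenic = 100, n_nonpathogenic = 0,
                                            p_hit_pathogenic = 1, seed = 32))
  hi <- g$genes[!is.na(p_hi) & p_hi > 0.9, .(chrom, start, end)]
  res <- enrichment_test(cnvs[, .(chrom, start, end)], list(hi_genes = hi), iso,
                         n_samples = 999, seed = 33)
  expect_gt(res$log2_fc, 0)
  expect_lte(res$q_value, 0.01)
  expect_equal(res$direction, "enriched")
})

test_that("correct_pvalues implements BH step-up", {
  expect_equal(correct_pvalues(0.037), 0.037)  # single p
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(correct_pvalues(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.005, 0.04, 0.9, 0.011)
  expect_equal(correct_pvalues(p), p.adjust(p, method = "BH"))
  expect_error(correct_pvalues(c(0.5, 0)), "0, 1")
  expect_error(correct_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("compare_fold_changes diffs log2 FCs with joint significance", {
  mk <- function(fc, q) data.table::data.table(
    annotation = c("a", "b"), observed = 1, expected = 1,
    log2_fc = fc, p_value = q, q_value = q, direction = "enriched",
    fc_defined = TRUE, n_samples = 100L
  )
  r1 <- mk(c(0.5, 1), c(0.005, 0.005))
  expect_equal(compare_fold_changes(r1, r1)$fc_difference, c(0, 0))
  r2 <- mk(c(-0.3, 0.2), c(0.005, 0.5))
  cmp <- compare_fold_changes(r1, r2)
  expect_equal(cmp[annotation == "a"]$fc_difference, 0.8)
  expect_true(cmp[annotation == "a"]$both_significant)
  expect_false(cmp[annotation == "b"]$both_significant)  # one side fails q <= 0.01
  r3 <- mk(c(0, 0), c(0.5, 0.5))[annotation == "a"]
  expect_error(compare_fold_changes(r1, r3), "b")
})
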