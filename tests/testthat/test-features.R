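# Per-CNV feature computation in the TAD environment.

test_that("distance_to_closest and closest_element follow the gap/tie rules", {
  cnv <- data.table::data.table(chrom = "chr1", start = 1000, end = 2000)
  els <- data.table::data.table(chrom = "chr1", start = c(2500, 100), end = c(3000, 200))
  expect_equal(distance_to_closest(cnv, els), 500)
  overl <- data.table::data.table(chrom = "chr1", start = 1500, end = 1600)
  expect_equal(distance_to_closest(cnv, overl), 0)
  expect_true(is.na(distance_to_closest(cnv, els[0])))

  # two equidistant elements: smaller start wins
  tie <- data.table::data.table(chrom = "chr1", start = c(2100, 800), end = c(2200, 900))
  ce <- closest_element(cnv, tie)
  expect_equal(ce$element$start, 800)
  # an overlapping element beats any nonzero gap
  mix <- rbind(tie, overl)
  expect_equal(closest_element(cnv, mix)$element$start, 1500)
})

test_that("pchic_score divides fragment overlap counts by LOEUF and aggregates", {
  cnv <- data.table::data.table(chrom = "chr1", start = 1000, end = 5000)
  frags <- data.table::data.table(
    chrom = "chr1",
    start = c(1100, 4000, 9000, 2000, 20000),
    end = c(1200, 4100, 9100, 2100, 20100),
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    neg_log10_p = 5
  )
  loeuf <- c(gA = 0.5, gB = 2)
  # gA: 2 of 3 fragments overlapped, loeuf 0.5 -> 4; gB: 1/2 = 0.5
  expect_equal(pchic_score(cnv, frags, loeuf), 4)
  expect_equal(pchic_score(cnv, frags, loeuf, aggregate = "sum"), 4.5)
  none <- data.table::data.table(chrom = "chr1", start = 9e6, end = 9e6 + 10,
                                 gene_id = "gA", neg_log10_p = 5)
  expect_equal(pchic_score(cnv, none, loeuf), 0)
  expect_warning(s <- pchic_score(cnv, frags, c(gA = 0, gB = 2)), "LOEUF")
  expect_equal(s, 0.5)  # gA skipped, gB remains
})

test_that("pchic_score is monotone as the CNV grows", {
  frags <- tiny_genome()$pchic
  gl <- setNames(tiny_genome()$genes$loeuf, tiny_genome()$genes$gene_id)
  gl[is.na(gl)] <- 0.5
  prev <- -Inf
  for (w in c(1e3, 1e4, 1e5, 1e6)) {
    cnv <- data.table::data.table(chrom = "chr1", start = 5e5, end = 5e5 + w)
    s <- suppressWarnings(pchic_score(cnv, frags, gl))
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("exon_overlap counts distinct intersected exons", {
  exons <- data.table::data.table(
    chrom = "chr1", start = c(100, 300, 500), end = c(200, 400, 600),
    gene_id = "g"
  )
  span <- data.table::data.table(chrom = "chr1", start = 50, end = 650)
  expect_equal(exon_overlap(span, exons), 3)
  intron <- data.table::data.table(chrom = "chr1", start = 210, end = 290)
  expect_equal(exon_overlap(intron, exons), 0)
  expect_equal(exon_overlap(span, exons[0]), 0)  # intergenic / no exons
  expect_equal(exon_overlap(span, exons, mode = "bp"), 300)
})

test_that("annotate_cnvs routes CNVs, computes features and is deterministic", {
  g <- tiny_genome()
  envs <- tiny_envs(g)
  cnvs <- generate_cnvs(g, cnv_effect_model(n_pathogenic = 30, n_nonpathogenic = 30,
                                            size_range_pathogenic = c(2e3, 5e4),
                                            size_range_nonpathogenic = c(2e3, 5e4),
                                            seed = 5))
  ann <- annotate_cnvs(cnvs, envs, exons = g$exons, pchic = g$pchic)
  expect_equal(nrow(ann$features) + nrow(ann$unscored), nrow(cnvs))
  expect_true(all(default_feature_names() %in% names(ann$features)))
  # row order matches input order of scored CNVs
  expect_equal(ann$features$id, cnvs$id[cnvs$id %in% ann$features$id])

  # determinism and permutation equivariance
  ann2 <- annotate_cnvs(cnvs, envs, exons = g$exons, pchic = g$pchic)
  expect_identical(ann$features, ann2$features)
  perm <- with_seed(3, sample(nrow(cnvs)))
  ann3 <- annotate_cnvs(cnvs[perm], envs, exons = g$exons, pchic = g$pchic)
  a <- ann$features[order(id)]
  b <- ann3$features[order(id)]
  expect_equal(a, b)

  # annotation-track order invariance
  envs4 <- build_environments(g$tads, g$boundaries,
                              g$genes[with_seed(4, sample(nrow(g$genes)))],
                              g$enhancers[with_seed(4, sample(nrow(g$enhancers)))],
                              g$ctcf)
  ann4 <- annotate_cnvs(cnvs, envs4, exons = g$exons, pchic = g$pchic)
  expect_equal(ann$features, ann4$features)

  # unknown feature names are an error listing the registry
  expect_error(annotate_cnvs(cnvs, envs, features = "dist_nonsense"),
               "available")
})

test_that("distance features match the brute-force all-pairs minimum", {
  g <- tiny_genome()
  envs <- tiny_envs(g)
  cnvs <- generate_cnvs(g, cnv_effect_model(n_pathogenic = 20, n_nonpathogenic = 20,
                                            seed = 6))
  ann <- annotate_cnvs(cnvs, envs)
  feats <- ann$features
  tad_gr <- envs$tads
  for (i in seq_len(nrow(feats))) {
    cnv <- feats[i, .(chrom, start, end)]
    # environment = union of elements in all intersected TADs
    tids <- tad_gr[chrom == cnv$chrom & start < cnv$end & end > cnv$start]$tad_id
    gene_idx <- unique(envs$incidence$genes[tad_id %in% tids]$element_idx)
    expected <- brute_min_distance(cnv, g$genes[gene_idx])
    expect_equal(feats$dist_gene[i], expected)
    enh_idx <- unique(envs$incidence$enhancers[tad_id %in% tids]$element_idx)
    expect_equal(feats$dist_enhancer[i], brute_min_distance(cnv, g$enhancers[enh_idx]))
  }
})

test_that("CNVs outside every TAD are unscored; empty TADs give vacuous rows", {
  tads <- data.table::data.table(chrom = "chr1", start = c(0, 5000), end = c(1000, 6000))
  bnd <- data.table::data.table(chrom = "chr1", start = 4990, end = 5010, stability = 0.4)
  genes <- data.table::data.table(chrom = "chr1", start = 100, end = 200,
                                  gene_id = "g1", p_hi = 0.5, loeuf = 0.3,
                                  hi_log_odds = 1, ddg2p = FALSE)
  enh <- data.table::data.table(chrom = character(), start = numeric(),
                                end = numeric(), conservation = numeric())
  ctcf <- enh[, .(chrom, start, end)]
  envs <- build_environments(tads, bnd, genes, enh, ctcf)
  cnvs <- data.table::data.table(
    chrom = "chr1", start = c(100, 2000, 5100), end = c(300, 2100, 5200),
    svtype = "DEL", label = "unknown", af = NA_real_, source_tag = "s",
    id = c("in_gene_tad", "between_tads", "in_empty_tad")
  )
  ann <- annotate_cnvs(cnvs, envs)
  expect_equal(ann$unscored$id, "between_tads")
  empty_row <- ann$features[id == "in_empty_tad"]
  expect_true(is.na(empty_row$dist_gene))
  expect_true(is.na(empty_row$dist_enhancer))
  expect_equal(empty_row$pchic_score, 0)
  expect_equal(empty_row$exon_overlap, 0)
  expect_equal(ann$features[id == "in_gene_tad"]$dist_gene, 0)
})

test_that("user-defined BED tracks add TAD-restricted distance features", {
  g <- tiny_genome()
  envs <- tiny_envs(g)
  track <- data.table::data.table(chrom = "chr1", start = c(1e5, 9e5), end = c(1e5 + 100, 9e5 + 100))
  cnv <- data.table::data.table(chrom = "chr1", start = 1.2e5, end = 1.3e5,
                                svtype = "DEL", label = "unknown", af = NA_real_,
                                source_tag = "s", id = "q")
  ann <- annotate_cnvs(cnv, envs, extra_tracks = list(hars = track))
  expect_true("dist_hars" %in% names(ann$features))
  expect_equal(ann$features$dist_hars, 1.2e5 - (1e5 + 100))
})

test_that("coding_penalty_transform substitutes the fixed triple and is idempotent", {
  x <- data.table::data.table(
    p_hi_closest_gene = c(0.95, 0.4),
    hi_log_odds_closest_gene = c(3.2, 1.0),
    loeuf_closest_gene = c(0.12, 0.5),
    exon_overlap = c(0, 2)
  )
  t1 <- coding_penalty_transform(x)
  expect_equal(unlist(t1[1, 1:3]), c(p_hi_closest_gene = 0,
                                     hi_log_odds_closest_gene = -10,
                                     loeuf_closest_gene = 2))
  expect_equal(t1[2], x[2])  # coding row unchanged
  expect_identical(coding_penalty_transform(t1), t1)  # idempotent
  all_coding <- data.table::copy(x)[, exon_overlap := 5]
  expect_identical(coding_penalty_transform(all_coding), all_coding)
  expect_error(coding_penalty_transform(x, coding_overlap = TRUE), "align")
})
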