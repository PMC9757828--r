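test_that("structural-RNA hits filter at the bitscore threshold inclusively", {
  hits <- data.frame(
    qseqid = c("L1", "L2", "L3", "L3"),
    sseqid = c("RF00026|U6", "RF00001|5S_rRNA", "RF00005|tRNA", "RF00026|U6"),
    pident = 95, length = 80, mismatch = 1, gapopen = 0, qstart = 1, qend = 80,
    sstart = 1, send = 80, evalue = 1e-10,
    bitscore = c(50.0, 49.9, 60, 80), stringsAsFactors = FALSE)
  out <- classify_rfam(hits)
  expect_setequal(out$locus_id, c("L1", "L3"))       # 49.9 dropped, 50.0 kept
  expect_equal(out$merged_category[out$locus_id == "L1"], "snRNA")
  # best hit per locus retained
  expect_equal(out$family_name[out$locus_id == "L3"], "U6")
  expect_equal(out$bitscore[out$locus_id == "L3"], 80)
  # unmapped family falls back with a warning
  h2 <- hits[1, ]; h2$sseqid <- "RFX|mystery_fam"
  expect_warning(out2 <- classify_rfam(h2), "unmapped")
  expect_equal(out2$merged_category, "other_structural")
})

test_that("BLAST tabular files round-trip through the reader", {
  hits <- data.frame(
    qseqid = "L1", sseqid = "RF00026|U6", pident = 97.5, length = 100,
    mismatch = 2, gapopen = 0, qstart = 1, qend = 100, sstart = 5, send = 104,
    evalue = 1e-30, bitscore = 180.4, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_hits(hits, f)
  back <- read_blast_hits(f)
  expect_equal(back, hits)
})

test_that("closest feature: distance, zero-overlap and the TE tie rule", {
  genes <- feature_row("chr1", 1151, 2000, "gene", "g1")
  tes <- empty_feature_table()
  locus <- test_locus(start = 1001, end = 1100)
  cf <- closest_feature(locus, genes, tes)
  expect_equal(cf$distance, 50L)
  expect_equal(cf$feature_type, "gene")
  # overlap on both: the TE is reported
  tes2 <- feature_row("chr1", 1050, 1200, "TE", "te1")
  genes2 <- rbind(genes, feature_row("chr1", 1000, 1250, "gene", "g2"))
  cf2 <- closest_feature(locus, genes2, tes2)
  expect_equal(cf2$feature_type, "TE")
  expect_equal(cf2$distance, 0L)
  # touching intervals count as distance zero
  cf3 <- closest_feature(test_locus(start = 1001, end = 1150), genes, tes)
  expect_equal(cf3$distance, 0L)
  # no features at all
  cf4 <- closest_feature(locus, empty_feature_table(), empty_feature_table())
  expect_true(is.na(cf4$distance))
})

test_that("context classes follow the adjacency and fraction rules", {
  te <- feature_row("chr1", 5000, 5400, "TE", "te1")
  gene <- rbind(
    feature_row("chr1", 1000, 3000, "gene", "g1"),
    feature_row("chr1", 1000, 1400, "exon", "g1.e1", "g1"),
    feature_row("chr1", 2600, 3000, "exon", "g1.e2", "g1"),
    feature_row("chr1", 1100, 1400, "CDS", "g1.c1", "g1"),
    feature_row("chr1", 2600, 2900, "CDS", "g1.c2", "g1"))
  ctx <- function(start, end)
    classify_context(test_locus(start = start, end = end), gene, te)$context
  expect_equal(ctx(1350, 1449), "PCG_CDS")      # 51% CDS overlap
  expect_equal(ctx(1390, 1489), "PCG_intron")   # 11% exon/CDS: falls through
  expect_equal(ctx(1500, 1599), "PCG_intron")   # wholly inside the intron
  expect_equal(ctx(3050, 3149), "near_PCG")     # 49 nt from the gene
  expect_equal(ctx(3200, 3299), "intergenic")   # 199 nt away
  expect_equal(ctx(5100, 5199), "TE")
  expect_equal(ctx(5450, 5549), "near_TE")      # 49 nt from the TE
})

test_that("the fifteen-percent rule is strict", {
  gene <- rbind(
    feature_row("chr1", 1000, 3000, "gene", "g1"),
    feature_row("chr1", 1000, 1400, "exon", "g1.e1", "g1"),
    feature_row("chr1", 1000, 1400, "CDS", "g1.c1", "g1"))
  te <- empty_feature_table()
  # 100-nt hairpin with 16 nt of CDS overlap: >15% qualifies
  c16 <- classify_context(test_locus(start = 1385, end = 1484), gene, te)
  expect_equal(c16$context, "PCG_CDS")
  expect_equal(c16$cds_fraction, 0.16)
  # exactly 15 nt: not CDS (strict >) nor UTR; the locus lies inside the
  # gene span so it falls through to the intron call
  c15 <- classify_context(test_locus(start = 1386, end = 1485), gene, te)
  expect_equal(c15$cds_fraction, 0.15)
  expect_equal(c15$context, "PCG_intron")
})

test_that("a hairpin overlapping two genes uses the larger overlap", {
  gene <- rbind(
    feature_row("chr1", 900, 1030, "gene", "gA"),
    feature_row("chr1", 900, 1030, "exon", "gA.e", "gA"),
    feature_row("chr1", 900, 1030, "CDS", "gA.c", "gA"),
    feature_row("chr1", 1040, 2000, "gene", "gB"),
    feature_row("chr1", 1040, 2000, "exon", "gB.e", "gB"))
  cc <- classify_context(test_locus(start = 1001, end = 1100),
                         gene, empty_feature_table())
  # 30 nt in gA vs 61 nt in gB; gB is exonic but non-coding -> UTR
  expect_equal(cc$context, "PCG_UTR")
})

test_that("a gene without exon children is treated as single-exon", {
  gene <- feature_row("chr1", 1000, 2000, "gene", "g1")
  expect_warning(
    cc <- classify_context(test_locus(start = 1200, end = 1299), gene,
                           empty_feature_table()),
    "no exon children")
  expect_equal(cc$context, "PCG_UTR")
})

test_that("removing TE features never changes a gene-derived classification", {
  set_fixture_seed(501)
  gene <- rbind(
    feature_row("chr1", 1000, 3000, "gene", "g1"),
    feature_row("chr1", 1000, 1500, "exon", "g1.e1", "g1"),
    feature_row("chr1", 1000, 1500, "CDS", "g1.c1", "g1"))
  far_te <- feature_row("chr1", 9000, 9400, "TE", "te1")
  for (i in 1:50) {
    st <- sample(500:3500, 1)
    locus <- test_locus(start = st, end = st + 99)
    with_te <- classify_context(locus, gene, far_te)$context
    without <- classify_context(locus, gene, empty_feature_table())$context
    if (!with_te %in% c("TE", "near_TE"))
      expect_equal(without, with_te)
  }
})

test_that("intergenic calls require no Rfam hit, intergenic context, not failed", {
  expect_true(call_intergenic(FALSE, "intergenic", "confirmed"))
  expect_true(call_intergenic(FALSE, "intergenic", "no_libraries"))
  expect_false(call_intergenic(TRUE, "intergenic", "confirmed"))
  expect_false(call_intergenic(FALSE, "near_TE", "confirmed"))
  expect_false(call_intergenic(FALSE, "intergenic", "failed"))
})

test_that("gene model GFF3 and TE BED readers produce feature tables", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
    "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\texon\t1000\t1200\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\tsrc\tCDS\t1050\t1200\t.\t+\t0\tID=c1;Parent=m1"), gff)
  fx <- read_features_gff3(gff)
  expect_setequal(fx$type, c("gene", "exon", "CDS"))
  # exon/CDS parentage resolved through the mRNA to the gene
  expect_equal(fx$parent_id[fx$type == "exon"], "g1")
  expect_equal(fx$parent_id[fx$type == "CDS"], "g1")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tte1\t0\t+", bed)
  te <- read_te_features(bed)
  expect_equal(te$start, 1000L)  # BED is 0-based half-open
  expect_equal(te$end, 2000L)
  expect_equal(te$type, "TE")
})
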