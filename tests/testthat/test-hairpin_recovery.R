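test_that("a uniquely planted mature yields exactly one locality", {
  set_fixture_seed(201)
  hp <- make_perfect_hairpin(21)
  g <- make_genome_with_hairpin(hp$hairpin, at = 801, total = 3000)
  loc <- find_localities(hp$mature, g, seed = 1)
  # the perfect stem also carries the mature's reverse complement on the
  # star arm, so both orientations of the same planted site are reported
  expect_true(nrow(loc) >= 1)
  expect_true(all(loc$anchor_start >= 801 - nchar(hp$hairpin) &
                    loc$anchor_end <= 800 + 2 * nchar(hp$hairpin)))
})

test_that("multiple planted copies give one locality each, seed-stable", {
  set_fixture_seed(202)
  m <- rand_seq(22)
  g <- genome_assembly(c(chr1 = paste0(rand_seq(500), m, rand_seq(900), m,
                                       rand_seq(900), m, rand_seq(500))),
                       species_tag = "Tessp")
  # brute-force substring scan oracle
  expected <- gregexpr(m, as.character(g$sequences[["chr1"]]), fixed = TRUE)[[1]]
  loc <- find_localities(m, g, seed = 5)
  expect_equal(nrow(loc), 3)
  expect_setequal(loc$anchor_start, as.integer(expected))
  expect_identical(find_localities(m, g, seed = 5), loc)
  expect_error(find_localities("ACGT", g), "shorter")
})

test_that("dual matures must co-occur within the joint window", {
  set_fixture_seed(203)
  m1 <- rand_seq(21); m2 <- rand_seq(21)
  near <- paste0(rand_seq(300), m1, rand_seq(40), m2, rand_seq(300))
  far <- paste0(rand_seq(300), m1, rand_seq(2000), m2, rand_seq(300))
  g_near <- genome_assembly(c(chr1 = near), species_tag = "Tessp")
  g_far <- genome_assembly(c(chr1 = far), species_tag = "Tessp")
  expect_equal(nrow(find_localities(c(m1, m2), g_near, seed = 1)), 1)
  expect_equal(nrow(find_localities(c(m1, m2), g_far, seed = 1)), 0)
})

test_that("candidate enumeration spaces window starts over the admissible range", {
  set_fixture_seed(204)
  g <- genome_assembly(c(chr1 = rand_seq(3000)), species_tag = "Tessp")
  locality <- list(chrom = "chr1", anchor_start = 1501, anchor_end = 1521,
                   strand = "+")
  cand <- enumerate_candidates(locality, g,
                               substr(as.character(g$sequences[[1]]), 1501, 1521))
  expect_equal(nrow(cand), 30)
  # every window contains the mature anchor
  expect_true(all(cand$start <= 1501 & cand$end >= 1521))
  s150 <- cand$start[cand$size_class == 150]
  expect_equal(s150, unique(round(seq(1521 - 150 + 1, 1501, length.out = 10))))
  expect_true(all(cand$end - cand$start + 1 == cand$size_class))
})

test_that("windows clip at contig ends and deduplicate", {
  set_fixture_seed(205)
  g <- genome_assembly(c(chr1 = rand_seq(400)), species_tag = "Tessp")
  locality <- list(chrom = "chr1", anchor_start = 11, anchor_end = 31, strand = "+")
  cand <- enumerate_candidates(locality, g,
                               substr(as.character(g$sequences[[1]]), 11, 31))
  expect_lte(nrow(cand), 30)
  expect_true(all(cand$start >= 1 & cand$end <= 400))
})

test_that("selection picks the modal duplex, smallest window, leftmost", {
  dup <- function(start, size, key, valid = TRUE)
    data.frame(chrom = "chr1", start = start, end = start + size - 1,
               strand = "+", size_class = size, seq = "N", structure = ".",
               valid = valid, duplex_key = key, stringsAsFactors = FALSE)
  cand <- rbind(dup(100, 300, "D1"), dup(120, 150, "D1"), dup(90, 150, "D1"),
                dup(100, 600, "D2"), dup(50, 150, "D3", valid = FALSE))
  cand$duplex <- replicate(nrow(cand), NULL, simplify = FALSE)
  pick <- select_hairpin(cand)
  expect_equal(pick$duplex_key, "D1")
  expect_equal(pick$size_class, 150)
  expect_equal(pick$start, 90)   # leftmost among equal-size carriers
  # tie between two duplexes: smaller window wins
  tie <- rbind(dup(100, 300, "A"), dup(400, 150, "B"))
  tie$duplex <- replicate(nrow(tie), NULL, simplify = FALSE)
  expect_equal(select_hairpin(tie)$duplex_key, "B")
  none <- dup(100, 150, NA_character_, valid = FALSE)
  none$duplex <- list(NULL)
  expect_null(select_hairpin(none))
})

test_that("recovery finds a planted hairpin from the mature alone", {
  set_fixture_seed(207)
  hp <- make_perfect_hairpin(24, loop = "GTTAAC")
  g <- make_genome_with_hairpin(hp$hairpin, at = 1201, total = 4000)
  locus <- list(locus_id = "L1", chrom = NA_character_, start = NA_integer_,
                end = NA_integer_, strand = ".", hairpin = NA_character_,
                mature1 = hp$mature, mature2 = NA_character_)
  out <- recover_locus(locus, g, seed = 3)
  expect_equal(out$status, "recovered")
  w <- out$window
  expect_true(w$start <= 1200 + nchar(hp$hairpin) && w$end >= 1201)
  expect_true(w$valid)
  expect_true(grepl(hp$mature, w$seq, fixed = TRUE))
})

test_that("an absent mature is unrecoverable", {
  set_fixture_seed(208)
  g <- genome_assembly(c(chr1 = rand_seq(2000)), species_tag = "Tessp")
  locus <- list(locus_id = "L1", chrom = NA_character_, start = NA_integer_,
                end = NA_integer_, strand = ".", hairpin = NA_character_,
                mature1 = "GACTAGCTAGGCTAGCTAACG", mature2 = NA_character_)
  out <- recover_locus(locus, g, seed = 3)
  expect_equal(out$status, "unrecoverable")
  expect_equal(out$n_localities, 0L)
})

test_that("recovery is reproducible for a fixed seed", {
  cfg <- scenario_config(seed = 31, n_hairpins = 4, genome_length = 25000,
                         n_decoys = 0, n_subject_genomes = 0, read_depth = 10)
  sc <- generate_scenario(cfg)
  r1 <- evaluate_recovery(sc$loci, sc$genome, seed = 7)
  r2 <- evaluate_recovery(sc$loci, sc$genome, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$n_total, 4L)
})

test_that("empty input reports metrics as not applicable", {
  g <- genome_assembly(c(chr1 = "ACGTACGTACGT"), species_tag = "Tessp")
  out <- evaluate_recovery(data.frame(), g)
  expect_true(is.na(out$locality_precision))
  expect_true(is.na(out$duplex_precision))
  expect_equal(out$n_total, 0L)
})
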