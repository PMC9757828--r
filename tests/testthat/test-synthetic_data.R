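test_that("the same seed reproduces a scenario bit-for-bit", {
  cfg <- scenario_config(seed = 7, n_hairpins = 5, genome_length = 25000,
                         n_decoys = 1, n_subject_genomes = 2,
                         subject_genome_length = 12000, read_depth = 50)
  sc1 <- generate_scenario(cfg)
  sc2 <- generate_scenario(cfg)
  expect_identical(as.character(sc1$genome$sequences), as.character(sc2$genome$sequences))
  expect_identical(sc1$loci, sc2$loci)
  expect_identical(sc1$pcg_features, sc2$pcg_features)
  r1 <- simulate_reads(sc1); r2 <- simulate_reads(sc2)
  expect_identical(r1[[1]]$reads, r2[[1]]$reads)
  h1 <- generate_hit_tables(sc1); h2 <- generate_hit_tables(sc2)
  expect_identical(h1, h2)
  # different seed, different world
  sc3 <- generate_scenario(scenario_config(seed = 8, n_hairpins = 5,
                                           genome_length = 25000, n_decoys = 1,
                                           n_subject_genomes = 2,
                                           subject_genome_length = 12000,
                                           read_depth = 50))
  expect_false(identical(sc1$loci$hairpin, sc3$loci$hairpin))
})

test_that("planted hairpins sit in the genome and validate by construction", {
  cfg <- scenario_config(seed = 21, n_hairpins = 8, genome_length = 40000,
                         n_decoys = 0, n_subject_genomes = 0, read_depth = 10)
  sc <- generate_scenario(cfg)
  expect_true(all(sc$loci$hairpin_valid_planted))
  for (i in seq_len(nrow(sc$loci))) {
    l <- sc$loci[i, ]
    expect_true(hairpin_matches_genome(l, sc$genome))
    expect_true(grepl(l$mature1, l$hairpin, fixed = TRUE))
  }
  # matures are unique in the genome on the planted strand
  for (i in seq_len(nrow(sc$loci))) {
    loc <- find_localities(sc$loci$mature1[i], sc$genome, seed = 1)
    expect_equal(nrow(loc), 1L)
  }
})

test_that("planted context classes are realized by the generated annotation", {
  ctxs <- c("intergenic", "near_PCG", "PCG_intron", "PCG_UTR", "PCG_CDS",
            "TE", "near_TE")
  cfg <- scenario_config(seed = 33, n_hairpins = 7, genome_length = 40000,
                         planted_contexts = ctxs, n_decoys = 0,
                         n_subject_genomes = 0, read_depth = 10)
  sc <- generate_scenario(cfg)
  for (i in seq_len(nrow(sc$loci))) {
    cc <- classify_context(sc$loci[i, ], sc$pcg_features, sc$te_features)
    expect_equal(cc$context, sc$loci$context_planted[i],
                 label = sprintf("locus %d (%s)", i, sc$loci$context_planted[i]))
  }
})

test_that("degenerate read models hit their limits exactly", {
  cfg <- scenario_config(seed = 41, n_hairpins = 3, genome_length = 20000,
                         n_decoys = 0, n_subject_genomes = 0,
                         read_depth = 200, n_libraries = 1,
                         dicing_precision = 1, strandedness = 1,
                         background_fraction = 0)
  sc <- generate_scenario(cfg)
  lib <- simulate_reads(sc)[[1]]
  trimmed <- trim_reads(lib$reads, cfg$adapter)
  expect_equal(length(trimmed), length(lib$reads))
  al <- align_reads(trimmed, sc$genome, seed = 1)
  for (i in seq_len(nrow(sc$loci))) {
    p <- profile_locus(al, sc$loci[i, ])
    expect_equal(dicing_specificity(p), 1)
    expect_equal(p$strandedness, 1)
    expect_equal(sum(p$seq_counts), 200L)
  }
})

test_that("simulated truth matches read classes and strands", {
  cfg <- scenario_config(seed = 43, n_hairpins = 2, genome_length = 20000,
                         n_decoys = 0, n_subject_genomes = 0,
                         read_depth = 500, n_libraries = 2)
  sc <- generate_scenario(cfg)
  libs <- simulate_reads(sc)
  expect_length(libs, 2)
  truth <- libs[[1]]$truth
  expect_equal(nrow(truth), length(libs[[1]]$reads))
  expect_setequal(unique(truth$class), c("mature", "jittered", "background"))
  # raw reads all carry the adapter (insert <= 28 nt, read length 50)
  expect_true(all(grepl(substr(cfg$adapter, 1, 8),
                        libs[[1]]$reads[truth$class != "background"],
                        fixed = TRUE)))
  # mature-class sense reads are exactly the planted mature
  m1 <- truth$locus_id == sc$loci$locus_id[1] & truth$class == "mature" & truth$sense
  ins <- trim_reads(libs[[1]]$reads[m1], cfg$adapter)
  expect_true(all(ins == sc$loci$mature1[1]))
})

test_that("decoy loci receive retained structural-RNA hits, others do not", {
  cfg <- scenario_config(seed = 51, n_hairpins = 6, genome_length = 35000,
                         n_decoys = 2, n_subject_genomes = 0, read_depth = 10)
  sc <- generate_scenario(cfg)
  hits <- generate_hit_tables(sc)
  rf <- classify_rfam(hits$rfam_hits)
  decoys <- sc$loci$locus_id[sc$loci$is_decoy]
  expect_setequal(rf$locus_id, decoys)
  expect_true(all(rf$bitscore >= 50))
})

test_that("infeasible configurations are rejected with an explanation", {
  cfg <- scenario_config(seed = 1, n_hairpins = 50, genome_length = 10000,
                         read_depth = 10)
  expect_error(generate_scenario(cfg), "infeasible")
})

test_that("scenarios write to standard formats and read back", {
  cfg <- scenario_config(seed = 61, n_hairpins = 3, genome_length = 20000,
                         n_decoys = 1, n_subject_genomes = 1,
                         subject_genome_length = 10000, read_depth = 20)
  sc <- generate_scenario(cfg)
  libs <- simulate_reads(sc)
  hits <- generate_hit_tables(sc)
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir, libraries = libs, hit_tables = hits)
  g <- read_genome_fasta(paths$genome)
  expect_identical(as.character(g$sequences[["chr1"]]),
                   as.character(sc$genome$sequences[["chr1"]]))
  loci <- read_locus_table(paths$loci)
  expect_equal(loci$locus_id, sc$loci$locus_id)
  expect_equal(loci$hairpin, sc$loci$hairpin)
  fx <- read_features_gff3(paths$genes)
  expect_true(all(c("gene", "exon", "CDS") %in% fx$type))
  te <- read_te_features(paths$tes)
  expect_equal(sort(te$start), sort(sc$te_features$start))
  reads <- read_fastq(paths$lib1)
  expect_identical(unname(reads), unname(libs[[1]]$reads))
  hh <- read_tblout(paths$homologs)
  expect_equal(nrow(hh), nrow(hits$homolog_hits))
})
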