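# Fixtures built in code: hairpins with known structure and small worlds.

set_fixture_seed <- function(seed) {
  # tests that draw random fixtures pin their own RNG state
  set.seed(seed)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Perfect stem-loop: arm + loop + exact reverse complement of the arm.
make_perfect_hairpin <- function(arm_len = 21, loop = "TTAA", arm = NULL) {
  if (is.null(arm)) arm <- rand_seq(arm_len)
  list(hairpin = paste0(arm, loop, rc(arm)), mature = arm,
       arm_len = nchar(arm), loop_len = nchar(loop))
}

# Hairpin with k non-pairing bases inserted symmetrically in each arm, and
# the matching hand-built dot-bracket (A-helix, bulges, B-helix, loop).
make_bulged_hairpin <- function(a_len = 10, k = 3, b_len = 8, loop_len = 4) {
  a <- rand_seq(a_len); b <- rand_seq(b_len)
  x <- paste(rep("A", k), collapse = "")   # bulge bases, chosen non-pairing
  y <- paste(rep("C", k), collapse = "")
  hairpin <- paste0(a, x, b, paste(rep("T", loop_len), collapse = ""),
                    rc(b), y, rc(a))
  db <- paste0(strrep("(", a_len), strrep(".", k), strrep("(", b_len),
               strrep(".", loop_len), strrep(")", b_len), strrep(".", k),
               strrep(")", a_len))
  list(hairpin = hairpin, structure = db, mature = paste0(a, x, b))
}

# Two side-by-side stem-loops; a mature spanning the junction has its
# duplex split across both helices (a branched "duplex region").
make_branched_hairpin <- function() {
  a <- rand_seq(6); b <- rand_seq(4)
  hairpin <- paste0(a, "TTTT", rc(a), b, "TTTT", rc(b))
  db <- paste0(strrep("(", 6), "....", strrep(")", 6),
               strrep("(", 4), "....", strrep(")", 4))
  list(hairpin = hairpin, structure = db,
       mature = paste0(substr(rc(a), 1, 6), b))
}

# Genome with one planted hairpin (plus strand) at a known offset.
make_genome_with_hairpin <- function(hairpin, at = 501, total = 2000,
                                     species_tag = "Tessp") {
  left <- rand_seq(at - 1)
  right <- rand_seq(total - (at - 1) - nchar(hairpin))
  milrcurate::genome_assembly(
    c(chr1 = paste0(left, hairpin, right)),
    assembly_id = "testasm", species_tag = species_tag)
}

empty_feature_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), type = character(), feature_id = character(),
             parent_id = character(), stringsAsFactors = FALSE)
}

feature_row <- function(chrom, start, end, type, id, parent = NA_character_) {
  data.frame(chrom = chrom, start = start, end = end, strand = "+",
             type = type, feature_id = id, parent_id = parent,
             stringsAsFactors = FALSE)
}

# Minimal alignment table for profile tests.
make_alignments <- function(seqs, starts, strands, chrom = "chr1",
                            library_id = "lib1") {
  n <- length(seqs)
  data.frame(read_id = sprintf("r%04d", seq_len(n)), seq = seqs,
             chrom = rep(chrom, n), start = starts,
             end = starts + nchar(seqs) - 1L, strand = strands,
             multimap_count = rep(1L, n), library_id = rep(library_id, n),
             stringsAsFactors = FALSE)
}

test_locus <- function(id = "L1", chrom = "chr1", start = 101, end = 200,
                       strand = "+") {
  list(locus_id = id, chrom = chrom, start = start, end = end, strand = strand)
}
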