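#' Read an nhmmer-style tblout hit table
#'
#' Parses the whitespace-delimited tabular output of nucleotide homology
#' searches (`--tblout`), skipping `#` comment lines. The fields used are
#' target name, query name, alignment coordinates, strand and score; the
#' subject assembly and species are recovered from the target name, which
#' the pipeline writes as `assembly_id|species_tag|chrom`.
#'
#' @param path tblout path.
#' @return `data.frame`: `query_locus_id`, `subject_assembly_id`,
#'   `subject_species_tag`, `subject_chrom`, `ali_from`, `ali_to`,
#'   `strand`, `bitscore`.
#' @export
read_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(query_locus_id = character(), subject_assembly_id = character(),
                      subject_species_tag = character(), subject_chrom = character(),
                      ali_from = integer(), ali_to = integer(), strand = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  f <- strsplit(trimws(lines), "\\s+")
  target <- vapply(f, `[`, "", 1L)
  tparts <- strsplit(target, "|", fixed = TRUE)
  data.frame(
    query_locus_id = vapply(f, `[`, "", 3L),
    subject_assembly_id = vapply(tparts, `[`, "", 1L),
    subject_species_tag = vapply(tparts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    subject_chrom = vapply(tparts, function(p) p[length(p)], ""),
    ali_from = as.integer(vapply(f, `[`, "", 7L)),
    ali_to = as.integer(vapply(f, `[`, "", 8L)),
    strand = vapply(f, `[`, "", 12L),
    bitscore = as.numeric(vapply(f, `[`, "", 14L)),
    stringsAsFactors = FALSE)
}

#' Write homology hits in tblout-compatible layout
#'
#' @param hits `data.frame` in [read_tblout()] shape.
#' @param path Output path.
#' @export
write_tblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# target name        accession  query name           accession  hmmfrom hmm to alifrom  ali to envfrom  env to  sq len strand  E-value  score  bias  description of target",
               "#------------------- ---------- -------------------- ---------- ------- ------- ------- ------- ------- ------- ------- ------ --------- ------ ----- ---------------------"),
             con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    target <- paste(h$subject_assembly_id, h$subject_species_tag, h$subject_chrom, sep = "|")
    writeLines(sprintf("%s - %s - 1 %d %d %d %d %d %d %s %.2g %.1f 0.0 -",
                       target, h$query_locus_id,
                       abs(h$ali_to - h$ali_from) + 1L,
                       h$ali_from, h$ali_to, h$ali_from, h$ali_to,
                       abs(h$ali_to - h$ali_from) + 1L,
                       h$strand, 1e-5, h$bitscore), con)
  }
  invisible(path)
}

#' Filter cross-genome homology hits
#'
#' Drops hits within the query's own species, keeps the single best hit
#' (by bitscore) per query and subject species, and retains hits whose
#' bitscore normalized by query hairpin length exceeds
#' `min_bits_per_nt` (strict `>`); the normalization allows shorter
#' hairpins to be detected alongside long ones. The filter is idempotent.
#'
#' @param hits Hit `data.frame` from [read_tblout()] or
#'   [naive_hairpin_search()].
#' @param query_lengths Named integer vector: hairpin length (nt) per query
#'   locus id. A hit referencing an unknown query is an error.
#' @param query_species Named character vector: species tag per query locus.
#' @param min_bits_per_nt Retention cutoff (default 0.4).
#' @return Filtered hit `data.frame` with an added `bits_per_nt` column.
#' @export
filter_homolog_hits <- function(hits, query_lengths, query_species,
                                min_bits_per_nt = 0.4) {
  if (!nrow(hits)) { hits$bits_per_nt <- numeric(0); return(hits) }
  unknown <- setdiff(hits$query_locus_id, names(query_lengths))
  if (length(unknown))
    stop("hit(s) reference unknown query locus: ", paste(unknown, collapse = ", "))
  hits <- hits[hits$subject_species_tag != query_species[hits$query_locus_id], , drop = FALSE]
  hits <- hits[order(hits$query_locus_id, hits$subject_species_tag, -hits$bitscore), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query_locus_id", "subject_species_tag")]), , drop = FALSE]
  hits$bits_per_nt <- hits$bitscore / as.numeric(query_lengths[hits$query_locus_id])
  hits <- hits[hits$bits_per_nt > min_bits_per_nt, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Summarize conservation evidence per intergenic locus
#'
#' Counts, per query locus, the subject species and subject genomes with a
#' retained homology hit. Only intergenic loci (see [call_intergenic()])
#' are queried, since genic overlap would confound hairpin homology.
#'
#' @param hits Filtered hits from [filter_homolog_hits()].
#' @param intergenic_ids Character vector of locus ids eligible as queries.
#' @param min_genomes Number of subject genomes required for the
#'   top-conservation flag (default 2; the source genome is not counted).
#' @return `data.frame`: `locus_id`, `n_subject_species`,
#'   `n_subject_genomes`, `conserved_multi` (at least one other species),
#'   `conserved_two_plus_genomes`.
#' @export
summarize_conservation <- function(hits, intergenic_ids, min_genomes = 2) {
  hits <- hits[hits$query_locus_id %in% intergenic_ids, , drop = FALSE]
  n_sp <- n_gen <- stats::setNames(integer(length(intergenic_ids)), intergenic_ids)
  if (nrow(hits)) {
    sp <- tapply(hits$subject_species_tag, hits$query_locus_id,
                 function(x) length(unique(x)))
    gn <- tapply(hits$subject_assembly_id, hits$query_locus_id,
                 function(x) length(unique(x)))
    n_sp[names(sp)] <- sp
    n_gen[names(gn)] <- gn
  }
  data.frame(locus_id = intergenic_ids,
             n_subject_species = unname(n_sp),
             n_subject_genomes = unname(n_gen),
             conserved_multi = unname(n_sp >= 1L),
             conserved_two_plus_genomes = unname(n_gen >= min_genomes),
             stringsAsFactors = FALSE)
}

#' Naive ungapped hairpin search against a subject genome
#'
#' A simple built-in homology scanner for offline testing: an ungapped
#' +1/-1 log-odds scan of the query against both subject strands, scaled
#' to a pseudo-bitscore of half the raw score, reporting the top
#' non-overlapping sites in the hit-table shape of [read_tblout()]. An
#' exact copy of an `L`-nt hairpin therefore scores `L/2` bits, i.e. 0.5
#' bits per nt.
#'
#' @param query_seq Hairpin sequence.
#' @param query_locus_id Query locus id carried into the hit table.
#' @param genome Subject [genome_assembly()].
#' @param top_k Sites reported per strand and chromosome (default 3).
#' @param min_bitscore Minimum pseudo-bitscore reported (default 0).
#' @return Hit `data.frame` ([read_tblout()] shape).
#' @export
naive_hairpin_search <- function(query_seq, query_locus_id, genome,
                                 top_k = 3, min_bitscore = 0) {
  query_seq <- as_dna(query_seq)
  rows <- list()
  for (chrom in names(genome$sequences)) {
    subj <- as.character(genome$sequences[[chrom]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query_seq else revcomp(query_seq)
      sc <- .ungapped_scan_cpp(subj, q)
      if (!length(sc)) next
      ord <- order(-sc)
      taken <- integer()
      n <- nchar(q)
      for (s in ord) {
        if (length(taken) >= top_k) break
        if (any(abs(taken - s) < n)) next
        bit <- sc[s] / 2
        if (bit < min_bitscore) break
        a_from <- s; a_to <- s + n - 1L
        if (strand == "-") { tmp <- a_from; a_from <- a_to; a_to <- tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          query_locus_id = query_locus_id,
          subject_assembly_id = genome$assembly_id,
          subject_species_tag = genome$species_tag,
          subject_chrom = chrom, ali_from = a_from, ali_to = a_to,
          strand = strand, bitscore = bit, stringsAsFactors = FALSE)
        taken <- c(taken, s)
      }
    }
  }
  if (!length(rows))
    return(data.frame(query_locus_id = character(), subject_assembly_id = character(),
                      subject_species_tag = character(), subject_chrom = character(),
                      ali_from = integer(), ali_to = integer(), strand = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$bitscore), , drop = FALSE]
}
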