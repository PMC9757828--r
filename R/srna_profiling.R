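#' Read a FASTQ file of small RNA reads
#' @param path FASTQ path.
#' @return Named character vector of read sequences (DNA alphabet).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write small RNA reads to FASTQ
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  if (is.null(names(x))) names(x) <- sprintf("read%06d", seq_along(x))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Trim 3' adapters from small RNA reads
#'
#' Exact-match adapter trimming: the full adapter occurring inside a read is
#' removed together with everything 3' of it; otherwise a read suffix equal
#' to an adapter prefix of at least `min_overlap` nt is removed. Reads are
#' then retained iff their trimmed length is within `[min_len, max_len]`
#' and they contain no `N`. Unlike general-purpose trimmers no mismatches
#' are tolerated; synthetic reads are error-free and pre-trimmed production
#' reads can be supplied directly.
#'
#' @param reads Character vector of reads (or a FASTQ path).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len Retained length bounds (defaults 10 and 50).
#' @param min_overlap Minimum read-suffix/adapter-prefix overlap (default 4).
#' @return Character vector of retained trimmed reads, with a `stats`
#'   attribute: `n_input`, `n_trimmed`, `n_kept`, `n_short`, `n_long`,
#'   `n_with_n`.
#' @export
trim_reads <- function(reads, adapter, min_len = 10, max_len = 50, min_overlap = 4) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  adapter <- as_dna(adapter)
  nm <- names(reads)
  reads0 <- as_dna(reads)
  names(reads0) <- nm
  n_input <- length(reads0)
  trimmed <- reads0
  # full internal adapter occurrence (leftmost)
  pos <- regexpr(adapter, trimmed, fixed = TRUE)
  hit <- pos > 0L
  trimmed[hit] <- substr(trimmed[hit], 1L, pos[hit] - 1L)
  # partial adapter at the read 3' end, longest overlap first
  todo <- !hit
  kmax <- min(nchar(adapter) - 1L,
              if (any(todo)) max(nchar(trimmed[todo])) else 0L)
  for (k in (if (kmax >= min_overlap) seq(kmax, min_overlap) else integer())) {
    if (!any(todo)) break
    idx <- which(todo & nchar(trimmed) >= k)
    if (!length(idx)) next
    suff <- substr(trimmed[idx], nchar(trimmed[idx]) - k + 1L, nchar(trimmed[idx]))
    m <- suff == substr(adapter, 1L, k)
    if (any(m)) {
      sel <- idx[m]
      trimmed[sel] <- substr(trimmed[sel], 1L, nchar(trimmed[sel]) - k)
      todo[sel] <- FALSE
    }
  }
  n_trimmed <- sum(nchar(trimmed) < nchar(reads0))
  len <- nchar(trimmed)
  has_n <- grepl("N", trimmed, fixed = TRUE)
  keep <- len >= min_len & len <= max_len & !has_n
  out <- trimmed[keep]
  attr(out, "stats") <- list(
    n_input = n_input, n_trimmed = n_trimmed, n_kept = sum(keep),
    n_short = sum(len < min_len), n_long = sum(len > max_len),
    n_with_n = sum(has_n & len >= min_len & len <= max_len))
  out
}

# All exact-match sites of each unique sequence on both genome strands,
# as one flat table (uidx = index into useqs). Sequences are grouped by
# width so each group scans the genome once with a preprocessed dictionary
# (Aho-Corasick via Biostrings::PDict).
match_sites <- function(useqs, genome) {
  widths <- nchar(useqs)
  chunks <- list()
  for (w in unique(widths)) {
    idx <- which(widths == w)
    fw <- Biostrings::DNAStringSet(useqs[idx])
    pd_fw <- Biostrings::PDict(fw)
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(fw))
    for (chrom in names(genome$sequences)) {
      subj <- genome$sequences[[chrom]]
      if (length(subj) < w) next
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPDict(if (strand == "+") pd_fw else pd_rc, subj)
        nh <- S4Vectors::elementNROWS(m)
        if (!sum(nh)) next
        r <- unlist(m)
        chunks[[length(chunks) + 1L]] <- data.frame(
          uidx = rep(idx, nh), chrom = chrom,
          start = Biostrings::start(r), end = Biostrings::end(r),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(chunks))
    return(data.frame(uidx = integer(), chrom = character(), start = integer(),
                      end = integer(), strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, chunks)
}

#' Align reads exactly and place multimappers by local unique abundance
#'
#' Reads are matched exactly against both genome strands. Uniquely mapping
#' reads are placed directly; each multimapping read is assigned to the
#' candidate site whose surrounding window contains the most uniquely
#' mapped reads, with remaining ties broken by a seeded random draw. Reads
#' matching nowhere are counted as unplaced.
#'
#' @param reads Character vector of trimmed reads.
#' @param genome A [genome_assembly()].
#' @param window Width in nt of the window centered on a candidate site
#'   used to count local unique reads (default 250).
#' @param seed Seed for tie-breaking.
#' @param library_id Library label attached to the alignments.
#' @return `data.frame` of alignments (`read_id`, `seq`, `chrom`, `start`,
#'   `end`, `strand`, `multimap_count`, `library_id`) with attributes
#'   `n_unplaced` and `library_total_aligned`.
#' @export
align_reads <- function(reads, genome, window = 250, seed = 1, library_id = "lib1") {
  reads <- as_dna(reads)
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    names(reads) <- sprintf("r%07d", seq_along(reads))
  useqs <- unique(reads)
  sites <- match_sites(useqs, genome)
  nsites <- tabulate(sites$uidx, length(useqs))
  read_uidx <- match(reads, useqs)
  ucount <- tabulate(read_uidx, length(useqs))
  # unique-read coverage map for multimapper placement
  single <- sites[nsites[sites$uidx] == 1L, , drop = FALSE]
  uniq_gr <- GenomicRanges::GRanges(single$chrom,
                                    IRanges::IRanges(single$start, single$end))
  uniq_w <- as.numeric(ucount[single$uidx])
  multi_idx <- which(nsites > 1L)
  picked <- with_seed(seed, {
    lapply(multi_idx, function(u) {
      s <- sites[sites$uidx == u, , drop = FALSE]
      centers <- floor((s$start + s$end) / 2)
      win <- GenomicRanges::GRanges(
        s$chrom, IRanges::IRanges(pmax(1L, centers - as.integer(window / 2)),
                                  centers + as.integer(window / 2)))
      score <- rep(0, nrow(s))
      if (length(uniq_gr)) {
        ov <- GenomicRanges::findOverlaps(win, uniq_gr)
        if (length(ov)) {
          agg <- tapply(uniq_w[subjectHits(ov)], queryHits(ov), sum)
          score[as.integer(names(agg))] <- agg
        }
      }
      best <- which(score == max(score))
      pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
      s[pick, , drop = FALSE]
    })
  })
  placed_tab <- rbind(single, if (length(picked)) do.call(rbind, picked))
  if (nrow(placed_tab)) {
    pl <- match(read_uidx, placed_tab$uidx)
    ok <- !is.na(pl)
    tab <- placed_tab[pl[ok], , drop = FALSE]
    out <- data.frame(read_id = names(reads)[ok], seq = unname(reads[ok]),
                      chrom = tab$chrom, start = tab$start, end = tab$end,
                      strand = tab$strand,
                      multimap_count = nsites[tab$uidx],
                      library_id = library_id, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(read_id = character(), seq = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      multimap_count = integer(), library_id = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_unplaced") <- length(reads) - nrow(out)
  attr(out, "library_total_aligned") <- nrow(out)
  out
}

#' Read pre-aligned reads from a SAM file
#'
#' Accepts ungapped primary alignments (CIGAR `<n>M`); other records are
#' skipped and counted. Requires the Rsamtools package.
#'
#' @param path SAM file path.
#' @param library_id Library label.
#' @return Alignment `data.frame` in the shape of [align_reads()], with
#'   attributes `n_skipped` and `library_total_aligned`.
#' @export
read_sam_alignments <- function(path, library_id = "lib1") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM input")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1]]
  mapped <- !is.na(rec$pos)
  ungapped <- mapped & grepl("^[0-9]+M$", rec$cigar)
  keep <- which(ungapped)
  strand <- ifelse(bitwAnd(rec$flag[keep], 16L) > 0L, "-", "+")
  seqs <- as.character(rec$seq[keep])
  # BAM stores reference-strand sequence; report the read as sequenced
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  len <- as.integer(sub("M$", "", rec$cigar[keep]))
  out <- data.frame(read_id = rec$qname[keep], seq = seqs,
                    chrom = as.character(rec$rname[keep]), start = rec$pos[keep],
                    end = rec$pos[keep] + len - 1L, strand = strand,
                    multimap_count = 1L, library_id = library_id,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(mapped & !ungapped)
  attr(out, "library_total_aligned") <- nrow(out)
  out
}

#' Per-library expression profile of a hairpin locus
#'
#' Reads fully contained within the hairpin interval (closed containment,
#' either strand) populate the per-sequence counts; reads overlapping but
#' crossing a boundary are counted as out-of-bounds and excluded. The
#' most-abundant sequence (MAS) is the highest-count in-bounds sequence,
#' with ties broken lexicographically (with a warning). `mas_rpm` uses all
#' genomically aligned reads of the library as the denominator.
#'
#' @param alignments Alignment `data.frame` from [align_reads()] /
#'   [read_sam_alignments()] (one library).
#' @param locus A list/row with `locus_id`, `chrom`, `start`, `end`,
#'   `strand` (the annotated hairpin strand).
#' @param library_total_aligned Genome-wide aligned read count; defaults to
#'   the `library_total_aligned` attribute of `alignments`.
#' @param library_id Library label; defaults from the alignments.
#' @return A list of class `LocusProfile`: `locus_id`, `library_id`,
#'   `seq_counts` (named integer vector), `sense_count`, `antisense_count`,
#'   `strandedness`, `out_of_bounds_count`, `mas_seq`, `mas_count`,
#'   `mas_rpm`, `mas_interval`, `library_total_aligned`.
#' @export
profile_locus <- function(alignments, locus, library_total_aligned = NULL,
                          library_id = NULL) {
  if (is_blank(locus$chrom) || is.na(locus$start) || is.na(locus$end))
    stop("locus must carry a genomic interval to be profiled")
  library_total_aligned <- library_total_aligned %||%
    attr(alignments, "library_total_aligned") %||% nrow(alignments)
  library_id <- library_id %||%
    (if (nrow(alignments)) alignments$library_id[1] else "lib1")
  locus_strand <- if (locus$strand %in% c("+", "-")) locus$strand else "+"
  on_chrom <- alignments$chrom == locus$chrom
  overlaps <- on_chrom & alignments$start <= locus$end & alignments$end >= locus$start
  inside <- overlaps & alignments$start >= locus$start & alignments$end <= locus$end
  oob <- sum(overlaps & !inside)
  inb <- alignments[inside, , drop = FALSE]
  seq_counts <- integer(0)
  sense <- antisense <- 0L
  mas_seq <- NA_character_; mas_count <- 0L; mas_interval <- NULL
  if (nrow(inb)) {
    sense <- sum(inb$strand == locus_strand)
    antisense <- nrow(inb) - sense
    counts <- table(inb$seq)
    seq_counts <- as.integer(counts)
    names(seq_counts) <- names(counts)
    mx <- max(seq_counts)
    top <- sort(names(seq_counts)[seq_counts == mx])
    if (length(top) > 1L)
      warning("MAS tie at ", locus$locus_id, "; choosing lexicographically smallest")
    mas_seq <- top[1]
    mas_count <- mx
    mrow <- inb[inb$seq == mas_seq, , drop = FALSE][1, ]
    mas_interval <- list(chrom = mrow$chrom, start = mrow$start, end = mrow$end,
                         strand = mrow$strand)
  }
  structure(list(
    locus_id = locus$locus_id, library_id = library_id,
    seq_counts = seq_counts, sense_count = sense, antisense_count = antisense,
    strandedness = if (sense + antisense > 0) sense / (sense + antisense) else NA_real_,
    out_of_bounds_count = oob, mas_seq = mas_seq, mas_count = mas_count,
    mas_rpm = if (library_total_aligned > 0) mas_count * 1e6 / library_total_aligned else NA_real_,
    mas_interval = mas_interval,
    library_total_aligned = library_total_aligned), class = "LocusProfile")
}

#' Classify a locus by agreement between reported mature and observed MAS
#'
#' @param profile A [profile_locus()] result.
#' @param reported_mature The published mature sequence.
#' @return One of `"reported_is_mas"` (reported mature is the MAS),
#'   `"other_mas"` (another sequence is the MAS; downstream analyses should
#'   substitute it), `"not_present"` (reported sequence absent from the
#'   locus reads), `"no_reads"` (no aligned reads at all).
#' @export
classify_mas <- function(profile, reported_mature) {
  if (!length(profile$seq_counts)) return("no_reads")
  reported_mature <- as_dna(reported_mature)
  if (identical(profile$mas_seq, reported_mature)) return("reported_is_mas")
  if (reported_mature %in% names(profile$seq_counts)) return("other_mas")
  "not_present"
}

#' The working mature sequence for downstream rules
#'
#' When another sequence is the locus MAS, that sequence replaces the
#' reported mature for duplex and rule evaluation.
#'
#' @inheritParams classify_mas
#' @return A sequence, or `NA` if the locus has no reads.
#' @export
effective_mature <- function(profile, reported_mature) {
  cat_ <- classify_mas(profile, reported_mature)
  switch(cat_,
         reported_is_mas = as_dna(reported_mature),
         other_mas = profile$mas_seq,
         not_present = profile$mas_seq,
         no_reads = NA_character_)
}

rule_row <- function(rule_id, measured, threshold, passed) {
  data.frame(rule_id = rule_id, measured_value = as.numeric(measured),
             threshold = as.numeric(threshold), passed = passed,
             stringsAsFactors = FALSE)
}

#' Apply the three minimal locus-profile rules (fn1-fn3)
#'
#' * `fn1_stranded`: at least `min_strandedness` (default 80%) of in-bounds
#'   reads on the annotated hairpin strand;
#' * `fn2_expression`: MAS abundance of at least `min_rpm` (default 0.5)
#'   reads per million genomically aligned reads;
#' * `fn3_duplex_clean`: the duplex for the observed MAS contains no
#'   secondary structure (re-evaluated for the MAS, which may differ from
#'   the reported mature).
#'
#' Both thresholds are inclusive. With zero in-bounds reads, fn1 and fn2
#' fail with measured value 0.
#'
#' @param profile A [profile_locus()] result.
#' @param hairpin Hairpin sequence of the locus.
#' @param structure Dot-bracket fold of the hairpin (`NULL` to fold with
#'   [fold_fallback()]).
#' @param min_strandedness,min_rpm Rule thresholds.
#' @return `data.frame` of rule outcomes (`rule_id`, `measured_value`,
#'   `threshold`, `passed`).
#' @export
apply_minimal_rules <- function(profile, hairpin, structure = NULL,
                                min_strandedness = 0.8, min_rpm = 0.5) {
  total <- profile$sense_count + profile$antisense_count
  strandedness <- if (total > 0) profile$sense_count / total else 0
  rpm <- if (total > 0) profile$mas_rpm else 0
  fn3_pass <- FALSE; fn3_val <- NA_real_
  if (total > 0 && !is.na(profile$mas_seq)) {
    hairpin <- as_dna(hairpin)
    if (is.null(structure)) structure <- fold_fallback(hairpin)
    pairs <- if (is.character(structure)) parse_dotbracket(structure) else structure
    dup <- tryCatch(locate_duplex(hairpin, pairs, profile$mas_seq),
                    milrcurate_error = function(e) NULL)
    if (!is.null(dup)) {
      fn3_pass <- duplex_span_single_stem(pairs, dup)
      fn3_val <- as.numeric(fn3_pass)
    }
  }
  rbind(
    rule_row("fn1_stranded", strandedness, min_strandedness,
             strandedness >= min_strandedness),
    rule_row("fn2_expression", rpm, min_rpm, rpm >= min_rpm),
    rule_row("fn3_duplex_clean", fn3_val, 1, fn3_pass)
  )
}

#' Read a strict rule-set configuration
#'
#' Rule sets modeled on published miRNA annotation criteria ship with the
#' package (`system.file("rulesets", package = "milrcurate")`): a
#' ShortStack-style set and an Axtell-2018-style plant set. Files are YAML
#' maps of predicate name to threshold; all thresholds are editable.
#'
#' @param path Path to a YAML rule-set file, or the name of a shipped set
#'   (`"shortstack"`, `"axtell2018"`).
#' @return Named list of predicate parameters with a `name` element.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("rulesets", paste0(path, ".yaml"), package = "milrcurate")
    if (nzchar(shipped)) path <- shipped else stop("rule set not found: ", path)
  }
  yaml::read_yaml(path)
}

strict_predicates <- c("duplex_read_precision", "star_expression_required",
                       "max_duplex_mismatches", "max_asymmetric_bulge",
                       "hairpin_length_range", "mas_length_range",
                       "replication_required")

#' Apply a strict (plant-style) annotation rule set
#'
#' Evaluates the configured predicates independently against a locus
#' profile and its folded hairpin. Supported predicates:
#' `duplex_read_precision` (fraction of in-bounds reads whose placement
#' matches the MAS or star arm), `star_expression_required` (star sequence
#' observed at least k times), `max_duplex_mismatches` (unpaired duplex
#' positions), `max_asymmetric_bulge` (longest unpaired run within an arm),
#' `hairpin_length_range` (duplex-to-duplex length), `mas_length_range`.
#' The `replication_required` predicate is enforced at the
#' cross-library stage ([confirm_across_libraries()]).
#'
#' @param profile A [profile_locus()] result.
#' @param hairpin Hairpin sequence.
#' @param structure Dot-bracket fold (`NULL` to fold with [fold_fallback()]).
#' @param ruleset Named list from [read_ruleset()].
#' @return `data.frame` of rule outcomes.
#' @export
apply_strict_rules <- function(profile, hairpin, structure = NULL, ruleset) {
  unknown <- setdiff(setdiff(names(ruleset), "name"), strict_predicates)
  if (length(unknown))
    stop("unknown strict-rule predicate(s): ", paste(unknown, collapse = ", "))
  hairpin <- as_dna(hairpin)
  if (is.null(structure)) structure <- fold_fallback(hairpin)
  pairs <- if (is.character(structure)) parse_dotbracket(structure) else structure
  dup <- if (!is.na(profile$mas_seq))
    tryCatch(locate_duplex(hairpin, pairs, profile$mas_seq),
             milrcurate_error = function(e) NULL) else NULL
  star_seq <- if (!is.null(dup))
    substr(hairpin, dup$star_arm[1], dup$star_arm[2]) else NA_character_
  out <- list()
  total_inb <- sum(profile$seq_counts)
  for (pred in setdiff(names(ruleset), c("name", "replication_required"))) {
    thr <- ruleset[[pred]]
    row <- switch(pred,
      duplex_read_precision = {
        val <- if (total_inb > 0 && !is.null(dup)) {
          star_rc <- revcomp(star_seq)
          hits <- names(profile$seq_counts) %in% c(profile$mas_seq, star_seq, star_rc)
          sum(profile$seq_counts[hits]) / total_inb
        } else 0
        rule_row(pred, val, thr, val >= thr)
      },
      star_expression_required = {
        val <- if (!is.na(star_seq)) {
          star_rc <- revcomp(star_seq)
          sum(profile$seq_counts[names(profile$seq_counts) %in% c(star_seq, star_rc)])
        } else 0
        rule_row(pred, val, thr, val >= thr)
      },
      max_duplex_mismatches = {
        val <- if (!is.null(dup)) dup$unpaired_count else NA_real_
        rule_row(pred, val, thr, !is.na(val) && val <= thr)
      },
      max_asymmetric_bulge = {
        val <- if (!is.null(dup)) max_unpaired_run(pairs, dup) else NA_real_
        rule_row(pred, val, thr, !is.na(val) && val <= thr)
      },
      hairpin_length_range = {
        val <- if (!is.null(dup)) hairpin_length_metric(dup) else NA_real_
        ok <- !is.na(val) && val >= thr[1] && val <= thr[2]
        rule_row(pred, val, thr[2], ok)
      },
      mas_length_range = {
        val <- if (!is.na(profile$mas_seq)) nchar(profile$mas_seq) else NA_real_
        ok <- !is.na(val) && val >= thr[1] && val <= thr[2]
        rule_row(pred, val, thr[2], ok)
      })
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

# Longest run of consecutive duplex positions (within one arm) whose
# partner is not on the opposite arm.
max_unpaired_run <- function(pairs, duplex) {
  run <- function(arm, other) {
    pos <- arm[1]:arm[2]
    ok <- !is.na(pairs[pos]) & pairs[pos] >= other[1] & pairs[pos] <= other[2]
    r <- rle(!ok)
    mx <- r$lengths[r$values]
    if (length(mx)) max(mx) else 0L
  }
  max(run(duplex$mature_arm, duplex$star_arm),
      run(duplex$star_arm, duplex$mature_arm))
}

#' Aggregate per-library rule outcomes into a confirmation status
#'
#' @param outcomes_by_library List (one element per library) of rule-outcome
#'   `data.frame`s as returned by [apply_minimal_rules()].
#' @return A list of class `ConfirmationStatus`: `status`
#'   (`no_libraries` / `failed` / `confirmed` / `confirmed_replicated`),
#'   `n_libraries_passing`, `n_libraries`.
#' @export
confirm_across_libraries <- function(outcomes_by_library) {
  n_lib <- length(outcomes_by_library)
  if (!n_lib)
    return(structure(list(status = "no_libraries", n_libraries_passing = 0L,
                          n_libraries = 0L), class = "ConfirmationStatus"))
  passes <- vapply(outcomes_by_library, function(df) all(df$passed), logical(1))
  n_pass <- sum(passes)
  status <- if (n_pass >= 2L) "confirmed_replicated"
            else if (n_pass == 1L) "confirmed"
            else "failed"
  structure(list(status = status, n_libraries_passing = n_pass,
                 n_libraries = n_lib), class = "ConfirmationStatus")
}

#' Dicing specificity of a locus
#'
#' The ratio of the most-abundant sequence to all reads matching the
#' hairpin strand; a proxy for the precision of precursor processing.
#'
#' @param profile A [profile_locus()] result.
#' @return Fraction in `[0, 1]`, or `NA` if no sense-strand reads.
#' @export
dicing_specificity <- function(profile) {
  if (profile$sense_count == 0) return(NA_real_)
  profile$mas_count / profile$sense_count
}

#' Write per-locus profiles to TSV
#' @param profiles List of [profile_locus()] results.
#' @param path Output TSV path.
#' @export
write_profile_table <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) data.frame(
    locus_id = p$locus_id, library_id = p$library_id,
    mas_seq = p$mas_seq, mas_count = p$mas_count, mas_rpm = p$mas_rpm,
    strandedness = p$strandedness, sense_count = p$sense_count,
    antisense_count = p$antisense_count,
    out_of_bounds = p$out_of_bounds_count,
    library_total_aligned = p$library_total_aligned,
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
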