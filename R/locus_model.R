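#' Construct a genome assembly object
#'
#' A light container for an assembly: a named set of chromosome/scaffold
#' sequences plus the identifiers used throughout the pipeline. The species
#' tag is the five-letter abbreviation convention used for fungal species
#' (e.g. `"Necra"` for *Neurospora crassa*); it is the unit of identity for
#' same-species exclusion in conservation analysis.
#'
#' @param sequences Named character vector or `DNAStringSet` of chromosome
#'   sequences. Normalized to uppercase DNA alphabet (`U` mapped to `T`).
#' @param assembly_id Assembly identifier.
#' @param species_tag Five-letter species abbreviation.
#' @return An object of class `GenomeAssembly`: a list with elements
#'   `assembly_id`, `species_tag` and `sequences` (a `DNAStringSet`).
#' @export
genome_assembly <- function(sequences, assembly_id = "asm", species_tag = "Synsp") {
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || anyNA(names(sequences)))
      stop("sequences must be named")
    nm0 <- names(sequences)
    sequences <- Biostrings::DNAStringSet(as_dna(sequences))
    names(sequences) <- nm0
  }
  nm <- names(sequences)
  if (is.null(nm) || anyDuplicated(nm))
    stop("sequence names must be present and unique")
  if (any(Biostrings::width(sequences) == 0L))
    stop("empty sequence in assembly: ", paste(nm[Biostrings::width(sequences) == 0L], collapse = ", "))
  structure(
    list(assembly_id = assembly_id, species_tag = species_tag, sequences = sequences),
    class = "GenomeAssembly"
  )
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat(sprintf("<GenomeAssembly> %s (%s): %d sequence(s), %s nt total\n",
              x$assembly_id, x$species_tag, length(x$sequences),
              format(sum(Biostrings::width(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' Read a genome FASTA into a GenomeAssembly
#'
#' Sequence names are the first whitespace-delimited token of each header.
#' Case is folded to upper and `U` is mapped to `T` on load.
#'
#' @param path Path to a FASTA file.
#' @inheritParams genome_assembly
#' @return A [genome_assembly()] object.
#' @export
read_genome_fasta <- function(path, assembly_id = basename(path), species_tag = "Synsp") {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm))
    stop("duplicate sequence names in FASTA: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- as_dna(as.character(raw))
  names(seqs) <- nm
  genome_assembly(seqs, assembly_id = assembly_id, species_tag = species_tag)
}

#' Write a GenomeAssembly to FASTA
#' @param genome A [genome_assembly()] object.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}

# Extract the strand-oriented sequence of a genomic window.
genome_subseq <- function(genome, chrom, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(genome$sequences[[chrom]], start = start, end = end))
  if (identical(strand, "-")) revcomp(s) else s
}

chrom_length <- function(genome, chrom) Biostrings::width(genome$sequences[chrom])

locus_table_columns <- c(
  "locus_id", "species", "assembly", "chrom", "start", "end", "strand",
  "hairpin", "mature1", "mature2", "source_pub"
)

#' Read a reported-locus table
#'
#' Reads the TSV-of-record describing reported mi/milRNA loci. Expected
#' columns (header required, blanks allowed): `locus_id`, `species`,
#' `assembly`, `chrom`, `start`, `end`, `strand`, `hairpin`, `mature1`,
#' `mature2`, `source_pub`. File coordinates are 1-based inclusive and are
#' kept 1-based closed internally (the Bioconductor convention).
#'
#' Each row is assigned a `reporting_class` reflecting how completely the
#' locus was reported:
#' * `coordinates` — genomic coordinates present;
#' * `hairpin_only` — a precursor hairpin sequence but no coordinates;
#' * `fail_lacking` — neither; only mature sequence(s) reported. These loci
#'   are candidates for hairpin recovery (see [recover_locus()]).
#'
#' Malformed rows are collected into the `"errors"` attribute rather than
#' aborting the read; a duplicated `locus_id` is fatal.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with one row per well-formed locus row, the columns
#'   above plus `reporting_class`, and attribute `errors` (character vector
#'   of row-level problems).
#' @export
read_locus_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  missing_cols <- setdiff(locus_table_columns, names(df))
  if (length(missing_cols))
    stop("locus table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id in table: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  errors <- character()
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    has_coord <- !is_blank(row$chrom) && !is_blank(row$start) && !is_blank(row$end)
    has_hairpin <- !is_blank(row$hairpin)
    has_mature <- !is_blank(row$mature1) || !is_blank(row$mature2)
    if (!has_coord && !has_hairpin && !has_mature) {
      errors <- c(errors, sprintf("row %d (%s): no interval, hairpin or mature sequence", i, row$locus_id))
      next
    }
    if (has_coord) {
      st <- suppressWarnings(as.integer(row$start)); en <- suppressWarnings(as.integer(row$end))
      if (is.na(st) || is.na(en) || st < 1L || en < st) {
        errors <- c(errors, sprintf("row %d (%s): malformed coordinates", i, row$locus_id))
        next
      }
      if (!is_blank(row$strand) && !row$strand %in% c("+", "-", ".")) {
        errors <- c(errors, sprintf("row %d (%s): bad strand '%s'", i, row$locus_id, row$strand))
        next
      }
    }
    keep[i] <- TRUE
  }
  out <- df[keep, , drop = FALSE]
  out$start <- suppressWarnings(as.integer(out$start))
  out$end <- suppressWarnings(as.integer(out$end))
  for (col in c("hairpin", "mature1", "mature2"))
    out[[col]] <- ifelse(is_blank(out[[col]]), NA_character_, as_dna(out[[col]]))
  out$strand <- ifelse(is_blank(out$strand), ".", out$strand)
  has_coord <- !is.na(out$chrom) & !is.na(out$start) & !is.na(out$end)
  out$reporting_class <- ifelse(has_coord, "coordinates",
                         ifelse(!is.na(out$hairpin), "hairpin_only", "fail_lacking"))
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Write a locus table
#'
#' Inverse of [read_locus_table()]; coordinates are emitted 1-based
#' inclusive and sequence columns in the DNA alphabet.
#'
#' @param loci Locus `data.frame` as returned by [read_locus_table()].
#' @param path Output TSV path.
#' @export
write_locus_table <- function(loci, path) {
  cols <- intersect(c(locus_table_columns, "reporting_class"), names(loci))
  utils::write.table(loci[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Check a reported hairpin against the genome
#'
#' For loci reporting both coordinates and a hairpin sequence, the hairpin
#' must equal the strand-oriented genomic substring.
#'
#' @param locus One row of a locus table (list or single-row data.frame).
#' @param genome A [genome_assembly()].
#' @return Logical; `NA` if the locus lacks coordinates or hairpin.
#' @export
hairpin_matches_genome <- function(locus, genome) {
  if (is_blank(locus$chrom) || is.na(locus$start) || is_blank(locus$hairpin)) return(NA)
  strand <- if (locus$strand %in% c("+", "-")) locus$strand else "+"
  identical(as_dna(locus$hairpin),
            genome_subseq(genome, locus$chrom, locus$start, locus$end, strand))
}

#' Write curated loci as GFF3
#'
#' Emits one `miRNA_primary_transcript` feature per precursor and one child
#' `miRNA` feature per reported mature sequence, with 1-based inclusive
#' coordinates. When evidence columns (`tier`, `confirmation`, `context`)
#' are present on `loci` they are carried as GFF3 attributes. Mature child
#' features are placed at the position of the mature within the hairpin when
#' it can be located, otherwise they span the precursor.
#'
#' @param loci Locus `data.frame`; rows without coordinates are skipped with
#'   a warning.
#' @param path Output GFF3 path.
#' @param source Value for the GFF3 source column.
#' @return Invisibly, the `GRanges` that was written.
#' @export
write_locus_gff3 <- function(loci, path, source = "milrcurate") {
  no_coord <- is.na(loci$start) | is.na(loci$end) | is_blank(loci$chrom)
  if (any(no_coord)) {
    warning(sum(no_coord), " locus/loci without an interval skipped in GFF3 output")
    loci <- loci[!no_coord, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    strand <- if (l$strand %in% c("+", "-")) l$strand else "*"
    meta <- list(ID = l$locus_id, Name = l$locus_id)
    for (extra in c("tier", "confirmation", "context"))
      if (!is.null(l[[extra]]) && !is.na(l[[extra]])) meta[[extra]] <- as.character(l[[extra]])
    rows[[length(rows) + 1L]] <- c(
      list(chrom = l$chrom, start = l$start, end = l$end, strand = strand,
           type = "miRNA_primary_transcript"), meta)
    matures <- c(l$mature1, l$mature2)
    matures <- matures[!is.na(matures)]
    for (k in seq_along(matures)) {
      m <- matures[k]
      mstart <- l$start; mend <- l$end
      if (!is.na(l$hairpin)) {
        hit <- regexpr(m, l$hairpin, fixed = TRUE)
        if (hit > 0) {
          off <- as.integer(hit) - 1L; len <- nchar(m)
          if (strand == "-") {
            mend <- l$end - off; mstart <- mend - len + 1L
          } else {
            mstart <- l$start + off; mend <- mstart + len - 1L
          }
        }
      }
      rows[[length(rows) + 1L]] <- list(
        chrom = l$chrom, start = mstart, end = mend, strand = strand,
        type = "miRNA", ID = sprintf("%s.mature%d", l$locus_id, k),
        Parent = l$locus_id)
    }
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
  } else {
    all_keys <- unique(unlist(lapply(rows, names)))
    tab <- do.call(rbind, lapply(rows, function(r) {
      r <- r[all_keys]; names(r) <- all_keys
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v), stringsAsFactors = FALSE)
    }))
    gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end), strand = tab$strand)
    mcols(gr)$source <- source
    mcols(gr)$type <- tab$type
    for (col in setdiff(all_keys, c("chrom", "start", "end", "strand", "type")))
      mcols(gr)[[col]] <- tab[[col]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(gr)
}

#' Read a locus GFF3 back into interval form
#'
#' Companion reader for [write_locus_gff3()] round trips: returns the
#' precursor features as a `data.frame` of 1-based closed intervals.
#'
#' @param path GFF3 path.
#' @return `data.frame` with `locus_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_locus_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[mcols(gr)$type == "miRNA_primary_transcript"]
  data.frame(
    locus_id = as.character(mcols(gr)$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
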