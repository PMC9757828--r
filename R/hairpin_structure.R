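#' Parse a dot-bracket secondary structure into a pair table
#'
#' @param structure A string over `"()."` with balanced brackets (the
#'   RNAfold output alphabet; pseudoknot brackets are not supported).
#' @return An integer vector of the same length: element `i` is the 1-based
#'   index of the base paired with position `i`, or `NA` if unpaired.
#' @examples
#' parse_dotbracket("((..))")
#' @export
parse_dotbracket <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad))
    stop("illegal character(s) in dot-bracket string: ", paste(bad, collapse = " "))
  pairs <- rep(NA_integer_, length(chars))
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket string: ", length(stack), " unmatched '('")
  pairs
}

#' Serialize a pair table back to dot-bracket
#' @param pairs Integer pair table as returned by [parse_dotbracket()].
#' @return A dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs) {
  out <- rep(".", length(pairs))
  paired <- which(!is.na(pairs))
  out[paired[pairs[paired] > paired]] <- "("
  out[paired[pairs[paired] < paired]] <- ")"
  paste(out, collapse = "")
}

#' Built-in maximum base-pairing fold
#'
#' A deterministic Nussinov-style dynamic program maximizing the number of
#' base pairs (Watson-Crick plus G:U wobble) subject to a minimum
#' hairpin-loop size. It is the built-in fold used when no external
#' thermodynamic fold (e.g. RNAfold dot-bracket output, see
#' [read_dotbracket_file()]) is supplied. Ties are broken by pairing each
#' 3' base with its 5'-most admissible partner, so output is reproducible.
#'
#' @param seq Nucleotide sequence (RNA or DNA alphabet).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3, the steric minimum).
#' @return A dot-bracket string of the same length as `seq`.
#' @examples
#' fold_fallback("GGGAAAACCC")
#' @export
fold_fallback <- function(seq, min_loop = 3) {
  seq <- as_dna(seq)
  if (!nzchar(seq)) stop("empty sequence")
  .nussinov_fold_cpp(seq, as.integer(min_loop))
}

#' Fold a hairpin with RNAfold if available
#'
#' Thin wrapper over the ViennaRNA `RNAfold` executable (`--noPS`, default
#' energy model). Used as the production fold when the binary is on the
#' `PATH`; tests and the synthetic pipeline default to [fold_fallback()].
#'
#' @inheritParams fold_fallback
#' @return A dot-bracket string.
#' @export
fold_rnafold <- function(seq) {
  if (!nzchar(Sys.which("RNAfold"))) stop("RNAfold executable not found on PATH")
  out <- system2("RNAfold", c("--noPS"), input = as_rna(seq), stdout = TRUE)
  db <- strsplit(out[2], " ")[[1]][1]
  if (nchar(db) != nchar(seq)) stop("unexpected RNAfold output")
  db
}

#' Fold a sequence with the configured method
#' @inheritParams fold_fallback
#' @param method `"fallback"` (built-in maximum pairing) or `"rnafold"`.
#' @return Dot-bracket string.
#' @export
fold_hairpin <- function(seq, method = c("fallback", "rnafold"), min_loop = 3) {
  method <- match.arg(method)
  if (method == "rnafold") fold_rnafold(seq) else fold_fallback(seq, min_loop)
}

#' Read an RNAfold-style dot-bracket file
#'
#' Parses records of the form header line (`>name`), sequence line, and
#' structure line (optionally followed by the free energy in parentheses).
#'
#' @param path Path to the dot-bracket file.
#' @return Named list of `list(seq=, structure=)`, one element per record.
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no records in dot-bracket file: ", path)
  out <- list()
  for (s in starts) {
    if (s + 2 > length(lines)) stop("truncated dot-bracket record at line ", s)
    name <- sub("^>\\s*", "", lines[s])
    name <- sub("\\s.*$", "", name)
    db <- sub("\\s+\\([^()]*\\)\\s*$", "", lines[s + 2])
    out[[name]] <- list(seq = as_dna(lines[s + 1]), structure = db)
  }
  out
}

# First occurrence of mature in hairpin (5'-most); warns on multiples.
find_mature_arm <- function(hairpin, mature) {
  hits <- gregexpr(mature, hairpin, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  if (length(hits) > 1L)
    warning("mature sequence occurs ", length(hits),
            " times in hairpin; using the 5'-most occurrence")
  c(start = as.integer(hits[1]), end = as.integer(hits[1]) + nchar(mature) - 1L)
}

#' Locate the mature/star duplex within a folded hairpin
#'
#' The mature arm is the (5'-most) occurrence of the mature sequence in the
#' hairpin; the star arm is derived from the pairing partners of the mature
#' positions, extrapolated to the mature ends and offset by the configured
#' 2-nt overhang convention, then clipped to the hairpin and kept disjoint
#' from the mature arm. Positions within either arm whose partner does not
#' lie in the other arm are counted as unpaired, excluding the two terminal
#' overhang positions of each arm (those are unpaired by convention, not
#' structural defects).
#'
#' @param hairpin Hairpin sequence (RNA or DNA alphabet).
#' @param pairs Pair table from [parse_dotbracket()] for the hairpin fold.
#' @param mature Mature (or star) sequence to anchor the duplex.
#' @param overhang_side `"three_prime"` (standard Dicer duplex geometry,
#'   default) or `"five_prime"`.
#' @param overhang_len Overhang length in nt (default 2).
#' @return A list of class `DuplexRegion`: `mature_arm` and `star_arm`
#'   (1-based closed `c(start, end)` within the hairpin), `overhang_side`,
#'   `overhang_len` and `unpaired_count`.
#' @export
locate_duplex <- function(hairpin, pairs, mature,
                          overhang_side = c("three_prime", "five_prime"),
                          overhang_len = 2) {
  overhang_side <- match.arg(overhang_side)
  hairpin <- as_dna(hairpin); mature <- as_dna(mature)
  n <- nchar(hairpin)
  arm <- find_mature_arm(hairpin, mature)
  if (is.null(arm))
    hp_stop("mature sequence not found in hairpin", "mas_absent")
  m1 <- arm[["start"]]; m2 <- arm[["end"]]
  mpos <- m1:m2
  partners <- pairs[mpos]
  outside <- !is.na(partners) & (partners < m1 | partners > m2)
  if (!any(outside))
    hp_stop("mature arm has no pairing partner outside itself (degenerate duplex)",
            "degenerate_duplex")
  paired_pos <- mpos[outside]
  a <- min(paired_pos); b <- max(paired_pos)
  shift <- if (overhang_side == "three_prime") overhang_len else -overhang_len
  # extrapolate partner positions to the unpaired mature termini, then shift
  star_lo <- pairs[b] - (m2 - b) + shift
  star_hi <- pairs[a] + (a - m1) + shift
  if (star_lo > star_hi) { tmp <- star_lo; star_lo <- star_hi; star_hi <- tmp }
  star_lo <- max(1L, star_lo); star_hi <- min(n, star_hi)
  # keep the arms disjoint
  if (star_lo <= m2 && star_hi >= m1) {
    if (mean(c(star_lo, star_hi)) > mean(c(m1, m2))) star_lo <- max(star_lo, m2 + 1L)
    else star_hi <- min(star_hi, m1 - 1L)
  }
  if (star_lo > star_hi)
    hp_stop("star arm collapsed after clipping (degenerate duplex)", "degenerate_duplex")
  duplex <- structure(
    list(mature_arm = c(m1, m2), star_arm = c(star_lo, star_hi),
         overhang_side = overhang_side, overhang_len = overhang_len),
    class = "DuplexRegion"
  )
  duplex$unpaired_count <- duplex_unpaired_count(pairs, duplex)
  duplex
}

# Positions excluded from the unpaired tally: the overhang_len terminal
# positions of each arm on the overhang side (3' end = high coordinates in
# linear hairpin space for both arms).
overhang_positions <- function(duplex) {
  k <- duplex$overhang_len
  pick <- function(arm) {
    len <- arm[2] - arm[1] + 1L
    kk <- min(k, len)
    if (duplex$overhang_side == "three_prime") seq(arm[2] - kk + 1L, arm[2])
    else seq(arm[1], arm[1] + kk - 1L)
  }
  c(pick(duplex$mature_arm), pick(duplex$star_arm))
}

duplex_unpaired_count <- function(pairs, duplex) {
  mpos <- duplex$mature_arm[1]:duplex$mature_arm[2]
  spos <- duplex$star_arm[1]:duplex$star_arm[2]
  ok_m <- !is.na(pairs[mpos]) & pairs[mpos] >= duplex$star_arm[1] & pairs[mpos] <= duplex$star_arm[2]
  ok_s <- !is.na(pairs[spos]) & pairs[spos] >= duplex$mature_arm[1] & pairs[spos] <= duplex$mature_arm[2]
  unpaired <- c(mpos[!ok_m], spos[!ok_s])
  sum(!unpaired %in% overhang_positions(duplex))
}

# The minimal span covering both duplex arms must fold as one stem-loop:
# every base pair touching the span must belong to a single totally nested
# helix chain (no side-by-side helices / multiloop). Enclosing pairs below
# the duplex (the lower stem of the precursor) are part of that chain and
# are allowed; a second helix branching off inside the span is not.
duplex_span_single_stem <- function(pairs, duplex) {
  lo <- min(duplex$mature_arm[1], duplex$star_arm[1])
  hi <- max(duplex$mature_arm[2], duplex$star_arm[2])
  in_span <- function(x) x >= lo & x <= hi
  idx <- seq_along(pairs)
  opens <- idx[!is.na(pairs) & pairs > idx &
                 (in_span(idx) | in_span(pairs))]
  if (!length(opens)) return(TRUE)
  closes <- pairs[opens]
  # sorted by opening position, closings must strictly decrease for total nesting
  ord <- order(opens)
  all(diff(closes[ord]) < 0)
}

#' Three-criterion hairpin validity test
#'
#' A reported hairpin is valid iff (1) every supplied mature sequence occurs
#' as a substring, (2) the minimal span covering the mature/star duplex
#' folds as a single stem-loop (no base in the span pairs outside it and no
#' multibranch within it), and (3) the duplex contains no more than
#' `max_unpaired` base positions without a partner on the opposite arm.
#'
#' @param hairpin Hairpin sequence.
#' @param structure Dot-bracket structure of the hairpin fold, or `NULL` to
#'   fold with [fold_fallback()].
#' @param mature_seqs Character vector of 1-2 reported mature/star sequences.
#' @param max_unpaired Maximum tolerated unpaired duplex positions
#'   (default 20).
#' @param overhang_side,overhang_len Passed to [locate_duplex()].
#' @return A list of class `ValidityReport`: `valid`, `reasons` (subset of
#'   `mas_absent`, `secondary_stem_in_duplex`, `too_many_unpaired`) and
#'   `unpaired_count` (max over matures; `NA` when no duplex was locatable).
#' @export
validate_hairpin <- function(hairpin, structure = NULL, mature_seqs,
                             max_unpaired = 20,
                             overhang_side = "three_prime", overhang_len = 2) {
  hairpin <- as_dna(hairpin)
  mature_seqs <- as_dna(mature_seqs[!is.na(mature_seqs) & nzchar(mature_seqs)])
  if (!length(mature_seqs)) stop("at least one mature sequence required")
  if (is.null(structure)) structure <- fold_fallback(hairpin)
  pairs <- if (is.character(structure)) parse_dotbracket(structure) else structure
  reasons <- character()
  unpaired <- NA_integer_
  for (m in mature_seqs) {
    dup <- tryCatch(
      locate_duplex(hairpin, pairs, m, overhang_side = overhang_side,
                    overhang_len = overhang_len),
      mas_absent = function(e) "mas_absent",
      degenerate_duplex = function(e) "degenerate"
    )
    if (identical(dup, "mas_absent")) { reasons <- c(reasons, "mas_absent"); next }
    if (identical(dup, "degenerate")) { reasons <- c(reasons, "secondary_stem_in_duplex"); next }
    if (!duplex_span_single_stem(pairs, dup))
      reasons <- c(reasons, "secondary_stem_in_duplex")
    unpaired <- max(unpaired, dup$unpaired_count, na.rm = TRUE)
    if (dup$unpaired_count > max_unpaired)
      reasons <- c(reasons, "too_many_unpaired")
  }
  reasons <- unique(reasons)
  structure(list(valid = length(reasons) == 0L, reasons = reasons,
                 unpaired_count = unpaired),
            class = "ValidityReport")
}

#' Duplex-to-duplex hairpin length
#'
#' The distance from the 5'-most to the 3'-most duplex base, inclusive of
#' the duplex itself — the hairpin-length metric used when comparing
#' precursor sizes across kingdoms.
#'
#' @param duplex A `DuplexRegion` from [locate_duplex()].
#' @return Integer length in nucleotides.
#' @export
hairpin_length_metric <- function(duplex) {
  stopifnot(inherits(duplex, "DuplexRegion"))
  max(duplex$mature_arm[2], duplex$star_arm[2]) -
    min(duplex$mature_arm[1], duplex$star_arm[1]) + 1L
}
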