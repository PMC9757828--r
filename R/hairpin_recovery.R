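#' Find candidate localities for a hairpin from mature sequence evidence
#'
#' Exact-match search of the mature sequence(s) on both genome strands.
#' With two matures (mature + star) only sites where both match within a
#' joint window are retained, since two matures farther apart than the
#' largest candidate hairpin cannot share a precursor. The returned
#' localities are shuffled with the supplied seed (the order in which
#' localities are tested is arbitrary, so it is randomized reproducibly).
#'
#' @param mature_seqs Character vector of 1-2 mature sequences, each at
#'   least `min_mature` nt (shorter queries match spuriously genome-wide).
#' @param genome A [genome_assembly()].
#' @param seed Integer seed controlling locality order (default 9182).
#' @param joint_window Maximum span containing both matures (default 600,
#'   the largest candidate hairpin size).
#' @param min_mature Minimum mature length accepted for genome search.
#' @return `data.frame` with columns `chrom`, `anchor_start`, `anchor_end`
#'   (1-based closed span of the mature evidence), `strand`, `origin`;
#'   zero rows when the locus is unrecoverable.
#' @export
find_localities <- function(mature_seqs, genome, seed = 9182,
                            joint_window = 600, min_mature = 15) {
  mature_seqs <- as_dna(mature_seqs[!is.na(mature_seqs) & nzchar(mature_seqs)])
  if (!length(mature_seqs) || length(mature_seqs) > 2)
    stop("1 or 2 mature sequences required")
  if (any(nchar(mature_seqs) < min_mature))
    stop("mature sequence shorter than ", min_mature, " nt; refusing genome search")
  site_tab <- function(m) {
    out <- list()
    for (chrom in names(genome$sequences)) {
      subj <- genome$sequences[[chrom]]
      for (strand in c("+", "-")) {
        q <- if (strand == "+") m else revcomp(m)
        hits <- Biostrings::matchPattern(q, subj)
        if (length(hits))
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = Biostrings::start(hits),
            end = Biostrings::end(hits), strand = strand,
            stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                        end = integer(), strand = character()))
    do.call(rbind, out)
  }
  s1 <- site_tab(mature_seqs[1])
  if (length(mature_seqs) == 1L) {
    loc <- s1
    origin <- "mature_match"
  } else {
    s2 <- site_tab(mature_seqs[2])
    rows <- list()
    for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
      if (s1$chrom[i] != s2$chrom[j] || s1$strand[i] != s2$strand[j]) next
      lo <- min(s1$start[i], s2$start[j]); hi <- max(s1$end[i], s2$end[j])
      if (hi - lo + 1L <= joint_window)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = s1$chrom[i], start = lo, end = hi, strand = s1$strand[i],
          stringsAsFactors = FALSE)
    }
    loc <- if (length(rows)) unique(do.call(rbind, rows)) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character())
    origin <- "dual_mature_intersection"
  }
  if (!nrow(loc)) {
    return(data.frame(chrom = character(), anchor_start = integer(),
                      anchor_end = integer(), strand = character(),
                      origin = character(), stringsAsFactors = FALSE))
  }
  names(loc)[names(loc) == "start"] <- "anchor_start"
  names(loc)[names(loc) == "end"] <- "anchor_end"
  loc$origin <- origin
  rownames(loc) <- NULL
  ord <- with_seed(seed, sample.int(nrow(loc)))
  loc <- loc[ord, , drop = FALSE]
  rownames(loc) <- NULL
  loc
}

#' Enumerate candidate hairpin windows over a locality
#'
#' For each window size (by default 150, 300 and 600 nt), 10 windows are
#' placed with starts evenly spaced over the admissible range that keeps
#' the anchored mature fully contained; windows are clipped at contig ends
#' and deduplicated. Each window is folded and its duplex located and
#' validated.
#'
#' @param locality One row of [find_localities()] output (or a list with
#'   `chrom`, `anchor_start`, `anchor_end`, `strand`).
#' @param genome A [genome_assembly()].
#' @param mature Mature sequence anchoring the duplex (oriented to the
#'   locality strand).
#' @param sizes Candidate window sizes in nt.
#' @param n_per_size Windows per size class.
#' @param fold_method Passed to [fold_hairpin()].
#' @param folds Optional named list of precomputed dot-bracket structures
#'   keyed by `"chrom:start-end:strand"`; used instead of folding when
#'   present.
#' @return `data.frame` of candidates: window coordinates, `size_class`,
#'   `seq`, `structure`, `valid`, `duplex_key` (mature-arm + star-arm
#'   sequence, `NA` when no duplex), plus a list-column `duplex`.
#' @export
enumerate_candidates <- function(locality, genome, mature,
                                 sizes = c(150L, 300L, 600L), n_per_size = 10L,
                                 fold_method = "fallback", folds = NULL) {
  chrom <- locality$chrom
  clen <- chrom_length(genome, chrom)
  a1 <- locality$anchor_start; a2 <- locality$anchor_end
  strand <- locality$strand %||% "+"
  rows <- list()
  for (L in sizes) {
    lo <- a2 - L + 1L; hi <- a1
    starts <- unique(round(seq(lo, hi, length.out = n_per_size)))
    for (s in starts) {
      st <- max(1L, as.integer(s))
      en <- min(clen, st + L - 1L)
      if (st > a1 || en < a2) { st <- min(st, a1); en <- max(en, a2) }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = st, end = en, strand = strand, size_class = L,
        stringsAsFactors = FALSE)
    }
  }
  cand <- unique(do.call(rbind, rows))
  rownames(cand) <- NULL
  mature <- as_dna(mature)
  seqs <- character(nrow(cand)); dbs <- character(nrow(cand))
  valid <- logical(nrow(cand)); key <- rep(NA_character_, nrow(cand))
  duplexes <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- genome_subseq(genome, chrom, cand$start[i], cand$end[i], strand)
    seqs[i] <- s
    fkey <- sprintf("%s:%d-%d:%s", chrom, cand$start[i], cand$end[i], strand)
    db <- if (!is.null(folds) && !is.null(folds[[fkey]])) folds[[fkey]]
          else fold_hairpin(s, method = fold_method)
    dbs[i] <- db
    pairs <- parse_dotbracket(db)
    rep_i <- validate_hairpin(s, pairs, mature)
    valid[i] <- rep_i$valid
    dup <- tryCatch(locate_duplex(s, pairs, mature), milrcurate_error = function(e) NULL)
    if (!is.null(dup)) {
      duplexes[[i]] <- dup
      key[i] <- paste(
        substr(s, dup$mature_arm[1], dup$mature_arm[2]),
        substr(s, dup$star_arm[1], dup$star_arm[2]), sep = "|")
    }
  }
  cand$seq <- seqs; cand$structure <- dbs; cand$valid <- valid
  cand$duplex_key <- key
  cand$duplex <- duplexes
  cand
}

#' Select the recovered hairpin among candidate windows
#'
#' Among valid candidates the modal duplex sequence (mature arm plus star
#' arm) is identified; of its carriers, the smallest window is returned,
#' breaking remaining ties by leftmost genomic start.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @return A single-row `data.frame` (with `duplex` list-column), or `NULL`
#'   when no candidate is valid.
#' @export
select_hairpin <- function(candidates) {
  ok <- candidates[candidates$valid & !is.na(candidates$duplex_key), , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  tab <- table(ok$duplex_key)
  modal <- names(tab)[tab == max(tab)]
  if (length(modal) > 1L) {
    # tied duplexes: minimal-precursor principle, then leftmost
    best <- lapply(modal, function(k) {
      rows <- ok[ok$duplex_key == k, , drop = FALSE]
      rows[order(rows$size_class, rows$start), , drop = FALSE][1, , drop = FALSE]
    })
    best <- do.call(rbind, best)
    choice <- best[order(best$size_class, best$start), , drop = FALSE][1, , drop = FALSE]
    return(choice)
  }
  rows <- ok[ok$duplex_key == modal, , drop = FALSE]
  rows[order(rows$size_class, rows$start), , drop = FALSE][1, , drop = FALSE]
}

#' Recover a precursor hairpin for an incompletely reported locus
#'
#' Localities are identified from the mature sequence(s) (or taken from
#' reported mature coordinates when present), then tested in seeded-random
#' order; the first locality yielding a valid hairpin wins and all
#' subsequent localities are ignored.
#'
#' @param locus One row of a locus table: uses `mature1`/`mature2`, and
#'   `chrom`/`start`/`end` as a coordinate anchor when present without a
#'   hairpin.
#' @param genome A [genome_assembly()].
#' @inheritParams find_localities
#' @inheritParams enumerate_candidates
#' @return A list: `status` (`"recovered"` or `"unrecoverable"`), `window`
#'   (single-row data.frame or `NULL`), `n_localities`, `locality_rank`
#'   (which locality in test order succeeded).
#' @export
recover_locus <- function(locus, genome, seed = 9182,
                          sizes = c(150L, 300L, 600L), n_per_size = 10L,
                          fold_method = "fallback", folds = NULL) {
  matures <- c(locus$mature1, locus$mature2)
  matures <- as_dna(matures[!is.na(matures) & nzchar(matures)])
  has_coord <- !is_blank(locus$chrom) && !is.na(locus$start) && !is.na(locus$end)
  if (has_coord) {
    loc <- data.frame(chrom = locus$chrom, anchor_start = locus$start,
                      anchor_end = locus$end,
                      strand = if (locus$strand %in% c("+", "-")) locus$strand else "+",
                      origin = "mature_coords", stringsAsFactors = FALSE)
    anchor_seq <- genome_subseq(genome, loc$chrom, loc$anchor_start, loc$anchor_end, loc$strand)
    if (!length(matures)) matures <- anchor_seq
  } else {
    if (!length(matures)) stop("locus has neither coordinates nor mature sequences")
    loc <- find_localities(matures, genome, seed = seed)
  }
  if (!nrow(loc))
    return(list(status = "unrecoverable", window = NULL,
                n_localities = 0L, locality_rank = NA_integer_))
  for (i in seq_len(nrow(loc))) {
    mat_i <- if (loc$origin[i] == "mature_coords") matures[1] else {
      # orient the anchoring mature to the locality strand
      anchor <- genome_subseq(genome, loc$chrom[i], loc$anchor_start[i],
                              loc$anchor_end[i], loc$strand[i])
      hit <- which(vapply(matures, function(m) grepl(m, anchor, fixed = TRUE), logical(1)))
      if (length(hit)) matures[hit[1]] else matures[1]
    }
    cand <- enumerate_candidates(loc[i, ], genome, mat_i, sizes = sizes,
                                 n_per_size = n_per_size,
                                 fold_method = fold_method, folds = folds)
    pick <- select_hairpin(cand)
    if (!is.null(pick))
      return(list(status = "recovered", window = pick,
                  n_localities = nrow(loc), locality_rank = i))
  }
  list(status = "unrecoverable", window = NULL,
       n_localities = nrow(loc), locality_rank = NA_integer_)
}

#' Benchmark hairpin recovery against fully reported loci
#'
#' Runs recovery from mature sequences alone for loci with a known hairpin
#' interval, and scores each result as locality-correct (recovered window
#' overlaps the true hairpin interval) and duplex-correct (recovered duplex
#' sequences equal the duplex located on the true hairpin).
#'
#' @param loci Locus `data.frame` with `chrom`, `start`, `end`, `strand`,
#'   `hairpin` and `mature1` populated.
#' @param genome A [genome_assembly()].
#' @inheritParams recover_locus
#' @return A list with `per_locus` (`data.frame` of outcomes) and the
#'   aggregate `locality_precision`, `locality_sensitivity`,
#'   `duplex_precision`, `duplex_sensitivity` (NA when undefined),
#'   `n_recovered`, `n_total`.
#' @export
evaluate_recovery <- function(loci, genome, seed = 9182, fold_method = "fallback") {
  n <- nrow(loci)
  if (!n) {
    return(list(per_locus = data.frame(), locality_precision = NA_real_,
                locality_sensitivity = NA_real_, duplex_precision = NA_real_,
                duplex_sensitivity = NA_real_, n_recovered = 0L, n_total = 0L))
  }
  res <- data.frame(locus_id = loci$locus_id, recovered = FALSE,
                    locality_correct = FALSE, duplex_correct = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    l <- loci[i, ]
    stripped <- l
    stripped$chrom <- NA_character_; stripped$start <- NA_integer_; stripped$end <- NA_integer_
    stripped$hairpin <- NA_character_
    out <- recover_locus(stripped, genome, seed = seed, fold_method = fold_method)
    if (out$status != "recovered") next
    res$recovered[i] <- TRUE
    w <- out$window
    res$locality_correct[i] <- w$chrom == l$chrom && w$start <= l$end && w$end >= l$start
    true_db <- fold_hairpin(l$hairpin, method = fold_method)
    true_dup <- tryCatch(
      locate_duplex(l$hairpin, parse_dotbracket(true_db), as_dna(l$mature1)),
      milrcurate_error = function(e) NULL)
    if (!is.null(true_dup)) {
      true_key <- paste(
        substr(l$hairpin, true_dup$mature_arm[1], true_dup$mature_arm[2]),
        substr(l$hairpin, true_dup$star_arm[1], true_dup$star_arm[2]), sep = "|")
      res$duplex_correct[i] <- identical(w$duplex_key, true_key)
    }
  }
  n_rec <- sum(res$recovered)
  list(per_locus = res,
       locality_precision = if (n_rec) sum(res$locality_correct) / n_rec else NA_real_,
       locality_sensitivity = sum(res$locality_correct) / n,
       duplex_precision = if (n_rec) sum(res$duplex_correct) / n_rec else NA_real_,
       duplex_sensitivity = sum(res$duplex_correct) / n,
       n_recovered = n_rec, n_total = n)
}
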