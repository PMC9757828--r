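# Independent oracles used to cross-check the package implementation.
# These deliberately use naive loops / O(n^2) enumeration rather than the
# package's vectorized or compiled code paths.

# Maximum base-pairing count by a plain-R dynamic program.
oracle_pair_count <- function(seq, min_loop = 3) {
  b <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  ok <- c("AT", "TA", "GC", "CG", "GT", "TG")
  n <- length(b)
  if (n <= min_loop) return(0L)
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- N[i, j - 1]
      for (k in i:(j - min_loop - 1)) {
        if (!(paste0(b[k], b[j]) %in% ok)) next
        left <- if (k > i) N[i, k - 1] else 0L
        mid <- if (k + 1 <= j - 1) N[k + 1, j - 1] else 0L
        sc <- 1L + left + mid
        if (sc > best) best <- sc
      }
      N[i, j] <- best
    }
  }
  N[1, n]
}

count_pairs_db <- function(db) lengths(regmatches(db, gregexpr("\\(", db)))

# Validity decision by explicit enumeration over the pair table.
oracle_validity <- function(hairpin, db, mature, max_unpaired = 20,
                            overhang = 2) {
  pairs <- milrcurate::parse_dotbracket(db)
  n <- nchar(hairpin)
  reasons <- character()
  hit <- regexpr(mature, hairpin, fixed = TRUE)
  if (hit < 0) return(list(valid = FALSE, reasons = "mas_absent"))
  m1 <- as.integer(hit); m2 <- m1 + nchar(mature) - 1L
  # partners of mature positions outside the mature itself
  outs <- integer()
  for (q in m1:m2) {
    pq <- pairs[q]
    if (!is.na(pq) && (pq < m1 || pq > m2)) outs <- c(outs, q)
  }
  if (!length(outs))
    return(list(valid = FALSE, reasons = "secondary_stem_in_duplex"))
  a <- min(outs); bpos <- max(outs)
  lo_s <- pairs[bpos] - (m2 - bpos) + overhang
  hi_s <- pairs[a] + (a - m1) + overhang
  if (lo_s > hi_s) { t <- lo_s; lo_s <- hi_s; hi_s <- t }
  lo_s <- max(1L, lo_s); hi_s <- min(n, hi_s)
  if (lo_s <= m2 && hi_s >= m1) {
    if ((lo_s + hi_s) / 2 > (m1 + m2) / 2) lo_s <- max(lo_s, m2 + 1L)
    else hi_s <- min(hi_s, m1 - 1L)
  }
  if (lo_s > hi_s)
    return(list(valid = FALSE, reasons = "secondary_stem_in_duplex"))
  # unpaired positions, skipping the conventional 3' overhang of each arm
  skip <- c(max(m1, m2 - overhang + 1L):m2, max(lo_s, hi_s - overhang + 1L):hi_s)
  unpaired <- 0L
  for (q in m1:m2) {
    if (q %in% skip) next
    pq <- pairs[q]
    if (is.na(pq) || pq < lo_s || pq > hi_s) unpaired <- unpaired + 1L
  }
  for (q in lo_s:hi_s) {
    if (q %in% skip) next
    pq <- pairs[q]
    if (is.na(pq) || pq < m1 || pq > m2) unpaired <- unpaired + 1L
  }
  if (unpaired > max_unpaired) reasons <- c(reasons, "too_many_unpaired")
  # single-stem: all pairs touching the span must be pairwise nested
  span_lo <- min(m1, lo_s); span_hi <- max(m2, hi_s)
  plist <- list()
  for (q in seq_len(n)) {
    pq <- pairs[q]
    if (is.na(pq) || pq < q) next
    if ((q >= span_lo && q <= span_hi) || (pq >= span_lo && pq <= span_hi))
      plist[[length(plist) + 1L]] <- c(q, pq)
  }
  branched <- FALSE
  if (length(plist) > 1) {
    for (x in seq_len(length(plist) - 1)) for (y in (x + 1):length(plist)) {
      p1 <- plist[[x]]; p2 <- plist[[y]]
      nested <- (p1[1] < p2[1] && p2[2] < p1[2]) || (p2[1] < p1[1] && p1[2] < p2[2])
      if (!nested) { branched <- TRUE; break }
    }
  }
  if (branched) reasons <- c(reasons, "secondary_stem_in_duplex")
  list(valid = length(reasons) == 0L, reasons = sort(unique(reasons)))
}

# Closest-feature call by a plain all-pairs scan with the TE tie rule.
oracle_closest <- function(locus, genes, tes) {
  dist1 <- function(f) {
    if (f$chrom != locus$chrom) return(NA_integer_)
    if (f$start > locus$end) return(f$start - locus$end - 1L)
    if (f$end < locus$start) return(locus$start - f$end - 1L)
    0L
  }
  best_g <- NULL; best_t <- NULL
  for (i in seq_len(nrow(genes))) {
    d <- dist1(genes[i, ])
    if (!is.na(d) && (is.null(best_g) || d < best_g$distance))
      best_g <- list(feature_id = genes$feature_id[i], feature_type = "gene", distance = d)
  }
  for (i in seq_len(nrow(tes))) {
    d <- dist1(tes[i, ])
    if (!is.na(d) && (is.null(best_t) || d < best_t$distance))
      best_t <- list(feature_id = tes$feature_id[i], feature_type = "TE", distance = d)
  }
  if (is.null(best_g) && is.null(best_t))
    return(list(feature_id = NA_character_, feature_type = NA_character_,
                distance = NA_integer_))
  if (is.null(best_t)) return(best_g)
  if (is.null(best_g)) return(best_t)
  if (best_t$distance <= best_g$distance) best_t else best_g
}
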