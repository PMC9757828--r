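#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Standard 12-column tabular output: query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bitscore.
#'
#' @param path Path to the hit file.
#' @return `data.frame` with the 12 standard columns.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 12) stop("expected 12 tabular columns, got ", ncol(df))
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Write BLAST-tabular hits
#' @param hits `data.frame` in [read_blast_hits()] shape.
#' @param path Output path.
#' @export
write_blast_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default Rfam family-to-category mapping
#'
#' The shipped mapping generalizes structural-RNA family names to merged
#' display categories (rRNA, tRNA, snRNA, snoRNA, other_structural).
#'
#' @return `data.frame` with columns `family`, `category`.
#' @export
rfam_category_map <- function() {
  path <- system.file("extdata", "rfam_categories.tsv", package = "milrcurate")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Filter structural-RNA homology hits
#'
#' Retains hits with bitscore at or above the threshold (inclusive), keeps
#' the single best hit per locus, and maps the family name to a merged
#' category. Families missing from the mapping are labeled
#' `other_structural` with a warning. The subject field is interpreted as
#' `accession|family` or a bare family name.
#'
#' @param hits BLAST-tabular `data.frame` ([read_blast_hits()]) of hairpin
#'   queries against a structural-RNA (Rfam-derived) sequence set with
#'   small-RNA families already excluded.
#' @param threshold Minimum retained bitscore (default 50, inclusive).
#' @param category_map `data.frame` mapping `family` to `category`
#'   (default [rfam_category_map()]).
#' @return `data.frame` with one row per locus with a retained hit:
#'   `locus_id`, `family_accession`, `family_name`, `merged_category`,
#'   `bitscore`.
#' @export
classify_rfam <- function(hits, threshold = 50, category_map = rfam_category_map()) {
  keep <- hits[hits$bitscore >= threshold, , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(locus_id = character(), family_accession = character(),
                      family_name = character(), merged_category = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  keep <- keep[order(-keep$bitscore), , drop = FALSE]
  keep <- keep[!duplicated(keep$qseqid), , drop = FALSE]
  parts <- strsplit(keep$sseqid, "|", fixed = TRUE)
  acc <- vapply(parts, function(p) if (length(p) > 1) p[1] else NA_character_, character(1))
  fam <- vapply(parts, function(p) p[length(p)], character(1))
  cat_ <- category_map$category[match(fam, category_map$family)]
  if (anyNA(cat_)) {
    warning("unmapped structural-RNA family: ",
            paste(unique(fam[is.na(cat_)]), collapse = ", "),
            "; using category 'other_structural'")
    cat_[is.na(cat_)] <- "other_structural"
  }
  data.frame(locus_id = keep$qseqid, family_accession = acc, family_name = fam,
             merged_category = cat_, bitscore = keep$bitscore,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read gene-model features from GFF3
#'
#' Extracts gene, exon and CDS features of protein-coding genes into the
#' flat feature table used by the context classifier. Exons and CDS carry
#' their gene as `parent_id`.
#'
#' @param path GFF3 path.
#' @return `data.frame`: `chrom`, `start`, `end`, `strand`, `type`,
#'   `feature_id`, `parent_id`.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[mcols(gr)$type %in% c("gene", "mRNA", "exon", "CDS")]
  ids <- as.character(mcols(gr)$ID)
  parents <- vapply(as.list(mcols(gr)$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mcols(gr)$type),
    feature_id = ids, parent_id = parents, stringsAsFactors = FALSE)
  # resolve exon/CDS parents through mRNA to the gene
  mrna <- df[df$type == "mRNA", ]
  up <- stats::setNames(mrna$parent_id, mrna$feature_id)
  child <- df$type %in% c("exon", "CDS")
  via <- df$parent_id[child] %in% names(up)
  df$parent_id[child][via] <- up[df$parent_id[child][via]]
  df[df$type != "mRNA", , drop = FALSE]
}

#' Read transposable-element intervals from BED or GFF3
#' @param path BED6 (0-based half-open) or GFF3 path.
#' @return Feature `data.frame` with `type = "TE"` (1-based closed).
#' @export
read_te_features <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    ids <- as.character(mcols(gr)$ID)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- as.character(mcols(gr)$name)
  }
  if (!length(ids) || all(is.na(ids))) ids <- sprintf("TE%05d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = "TE", feature_id = ids, parent_id = NA_character_,
             stringsAsFactors = FALSE)
}

features_to_granges <- function(features) {
  GenomicRanges::GRanges(features$chrom,
                         IRanges::IRanges(features$start, features$end))
}

# Distance from a locus to every feature in a table (strand-agnostic;
# overlap or adjacency = 0), same-chromosome only.
feature_distances <- function(locus, features) {
  same <- features$chrom == locus$chrom
  d <- rep(NA_integer_, nrow(features))
  gap <- pmax(features$start[same] - locus$end - 1L,
              locus$start - features$end[same] - 1L, 0L)
  d[same] <- gap
  d
}

#' Closest gene/TE feature to a locus
#'
#' Reports the single closest feature across the protein-coding-gene and
#' transposable-element sets, strand-agnostic, with overlap counted as
#' distance 0 and TEs favored when a TE and a gene tie in distance
#' (including a tie of two overlaps).
#'
#' @param locus Row/list with `chrom`, `start`, `end`.
#' @param pcg_features,te_features Feature `data.frame`s (gene rows are
#'   used from the PCG set); either may be empty.
#' @return List: `feature_id`, `feature_type` (`"gene"`/`"TE"`/`NA`),
#'   `distance` (`NA` when no features exist).
#' @export
closest_feature <- function(locus, pcg_features, te_features) {
  genes <- pcg_features[pcg_features$type == "gene", , drop = FALSE]
  best <- function(tab) {
    if (!nrow(tab)) return(NULL)
    d <- feature_distances(locus, tab)
    if (all(is.na(d))) return(NULL)
    i <- which.min(d)
    list(feature_id = tab$feature_id[i], distance = d[i])
  }
  bg <- best(genes); bt <- best(te_features)
  if (is.null(bg) && is.null(bt))
    return(list(feature_id = NA_character_, feature_type = NA_character_,
                distance = NA_integer_))
  if (is.null(bt)) return(c(bg, feature_type = "gene")[c("feature_id", "feature_type", "distance")])
  if (is.null(bg)) return(c(bt, feature_type = "TE")[c("feature_id", "feature_type", "distance")])
  # TEs favored on a tie in distance (or intersect)
  if (bt$distance <= bg$distance)
    list(feature_id = bt$feature_id, feature_type = "TE", distance = bt$distance)
  else
    list(feature_id = bg$feature_id, feature_type = "gene", distance = bg$distance)
}

overlap_len <- function(locus, tab) {
  if (!nrow(tab)) return(0)
  same <- tab$chrom == locus$chrom
  sum(pmax(0, pmin(tab$end[same], locus$end) - pmax(tab$start[same], locus$start) + 1))
}

#' Classify the genomic context of a locus
#'
#' Applies the seven-way context classification: `TE` (overlapping a TE),
#' `near_TE` (within `near_threshold` nt of one), `PCG_CDS` / `PCG_UTR`
#' (more than `min_fraction` of the hairpin derived from CDS or,
#' failing that, exon sequence of the overlapped gene), `PCG_intron`
#' (inside the gene span without qualifying exonic overlap), `near_PCG`,
#' and `intergenic` (no feature within `near_threshold` nt). When a
#' hairpin overlaps two genes the gene with the larger overlap is used
#' (ties to the lexicographically smaller id); a gene without exon
#' children is treated as single-exon with a warning.
#'
#' @param locus Row/list with `chrom`, `start`, `end`.
#' @param pcg_features Gene/exon/CDS feature `data.frame`.
#' @param te_features TE feature `data.frame`.
#' @param near_threshold Distance at or below which a feature counts as an
#'   intersection (default 100 nt, inclusive).
#' @param min_fraction Hairpin fraction above which exon/CDS overlap
#'   assigns the class (default 0.15, strict `>`).
#' @return A list of class `ContextCall`: `context`, `nearest_feature_id`,
#'   `nearest_feature_type`, `distance`, `exonic_fraction`, `cds_fraction`.
#' @export
classify_context <- function(locus, pcg_features, te_features,
                             near_threshold = 100, min_fraction = 0.15) {
  nearest <- closest_feature(locus, pcg_features, te_features)
  llen <- locus$end - locus$start + 1L
  exonic_fraction <- cds_fraction <- 0
  make <- function(context) structure(
    list(context = context, nearest_feature_id = nearest$feature_id,
         nearest_feature_type = nearest$feature_type,
         distance = nearest$distance,
         exonic_fraction = exonic_fraction, cds_fraction = cds_fraction),
    class = "ContextCall")
  if (is.na(nearest$distance) || nearest$distance > near_threshold)
    return(make("intergenic"))
  if (nearest$feature_type == "TE")
    return(make(if (nearest$distance == 0L) "TE" else "near_TE"))
  if (nearest$distance > 0L) return(make("near_PCG"))
  # overlapping a gene body: pick the gene with the larger overlap
  genes <- pcg_features[pcg_features$type == "gene", , drop = FALSE]
  ov <- vapply(seq_len(nrow(genes)), function(i) overlap_len(locus, genes[i, ]), numeric(1))
  cand <- genes[ov > 0L, , drop = FALSE]
  ovc <- ov[ov > 0L]
  cand <- cand[order(-ovc, cand$feature_id), , drop = FALSE]
  gene <- cand[1, ]
  exons <- pcg_features[pcg_features$type == "exon" &
                          !is.na(pcg_features$parent_id) &
                          pcg_features$parent_id == gene$feature_id, , drop = FALSE]
  cds <- pcg_features[pcg_features$type == "CDS" &
                        !is.na(pcg_features$parent_id) &
                        pcg_features$parent_id == gene$feature_id, , drop = FALSE]
  if (!nrow(exons)) {
    warning("gene ", gene$feature_id, " has no exon children; treating gene span as one exon")
    exons <- gene
  }
  exonic_fraction <- overlap_len(locus, exons) / llen
  cds_fraction <- overlap_len(locus, cds) / llen
  if (cds_fraction > min_fraction) return(make("PCG_CDS"))
  if (exonic_fraction > min_fraction) return(make("PCG_UTR"))
  if (locus$start >= gene$start && locus$end <= gene$end) return(make("PCG_intron"))
  make("near_PCG")
}

#' Is a locus intergenic for conservation analysis?
#'
#' A locus enters the conservation search iff it has no retained
#' structural-RNA hit, its genomic context is intergenic, and its
#' sequencing re-assessment did not fail (confirmed, or no libraries
#' available).
#'
#' @param rfam_hit Logical: locus has a retained structural-RNA hit.
#' @param context Context class string from [classify_context()].
#' @param confirmation Confirmation status string.
#' @return Logical.
#' @export
call_intergenic <- function(rfam_hit, context, confirmation) {
  !rfam_hit & context == "intergenic" & confirmation != "failed"
}
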