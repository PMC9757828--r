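#' Configuration of a synthetic hairpin-RNA world
#'
#' Encodes the assumptions the pipeline makes about real data: stem-loop
#' precursors with mostly paired arms, small RNAs diced predominantly from
#' one arm position with high strand specificity, genes and transposons as
#' genomic context, structural-RNA decoys, and orthologous hairpins whose
#' variation is compensatory (structure-preserving) in related genomes.
#'
#' @param seed Master seed; every emitted file is a deterministic function
#'   of the config.
#' @param genome_length Length (nt) of the single-contig study genome.
#' @param n_hairpins Number of planted precursor loci.
#' @param stem_length,loop_length,arm_mismatches,mature_length Integer
#'   ranges `c(min, max)` for arm length, loop length, per-arm mismatch
#'   count (at least one mismatch falls in the mature-pairing region so
#'   the two arms are never exact reverse complements), and mature length.
#' @param read_depth Reads simulated per locus per library (fixed depth,
#'   so expression-rule boundary behavior is exact).
#' @param dicing_precision Fraction of locus reads that are the exact
#'   mature sequence; the rest are jittered within `jitter` nt.
#' @param strandedness Fraction of locus reads on the hairpin strand.
#' @param jitter Maximal positional jitter (nt) of imprecisely diced reads.
#' @param background_fraction Background reads (uniform over the genome,
#'   never overlapping planted hairpins) as a fraction of per-locus depth.
#' @param n_libraries Sequencing libraries simulated.
#' @param adapter 3' adapter appended to simulated reads (default: the
#'   standard Illumina small-RNA 3' adapter).
#' @param read_len Raw read length before trimming.
#' @param n_genes,n_tes Background gene and TE annotations placed away
#'   from planted hairpins.
#' @param planted_contexts Character vector of context classes recycled
#'   across hairpins (`"intergenic"`, `"near_PCG"`, `"PCG_intron"`,
#'   `"PCG_UTR"`, `"PCG_CDS"`, `"TE"`, `"near_TE"`).
#' @param n_decoys Structural-RNA decoy loci (these receive a high-scoring
#'   Rfam hit in the generated hit tables).
#' @param n_subject_genomes Companion genomes for conservation.
#' @param subject_genome_length Length of each companion genome.
#' @param conserved_fraction Fraction of (non-decoy) hairpins copied into
#'   the companion genomes.
#' @param ortholog_mutation_rate Per-position mutation rate of ortholog
#'   copies when `compensatory = TRUE` (paired positions are mutated with
#'   their partner so structure is preserved).
#' @param disruptive_rate Per-position one-sided mutation rate used when
#'   `compensatory = FALSE` (destroys both similarity and pairing).
#' @param compensatory Use compensatory (structure-preserving) ortholog
#'   mutations?
#' @return A list of class `ScenarioConfig`.
#' @export
scenario_config <- function(seed = 1, genome_length = 100000L, n_hairpins = 20L,
                            stem_length = c(50L, 60L), loop_length = c(4L, 8L),
                            arm_mismatches = c(1L, 3L), mature_length = c(20L, 24L),
                            read_depth = 1000L, dicing_precision = 0.9,
                            strandedness = 0.95, jitter = 2L,
                            background_fraction = 0.05, n_libraries = 2L,
                            adapter = "TGGAATTCTCGGGTGCCAAGG", read_len = 50L,
                            n_genes = 10L, n_tes = 6L,
                            planted_contexts = "intergenic", n_decoys = 2L,
                            n_subject_genomes = 3L, subject_genome_length = 30000L,
                            conserved_fraction = 1, ortholog_mutation_rate = 0.05,
                            disruptive_rate = 0.25, compensatory = TRUE) {
  cfg <- as.list(environment())
  rates <- c(cfg$dicing_precision, cfg$strandedness, cfg$background_fraction,
             cfg$conserved_fraction, cfg$ortholog_mutation_rate, cfg$disruptive_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            stem_length[1] <= stem_length[2], loop_length[1] <= loop_length[2],
            mature_length[1] <= mature_length[2],
            stem_length[1] >= mature_length[2] + 4L)
  structure(cfg, class = "ScenarioConfig")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
# sample() that never interprets a length-1 vector as 1:x
resample <- function(x, n = 1L, ...) x[sample.int(length(x), n, ...)]
comp_base <- c(A = "T", C = "G", G = "C", T = "A")
# bases that neither Watson-Crick- nor wobble-pair with the partner base
nonpairing_bases <- list(A = c("A", "C", "G"), C = c("C", "A", "T"),
                         G = c("G", "A"), T = c("T", "C"))

# Build one planted hairpin: 5' arm + loop + mutated reverse-complement arm.
build_hairpin <- function(cfg) {
  arm_len <- resample(cfg$stem_length[1]:cfg$stem_length[2])
  loop_len <- resample(cfg$loop_length[1]:cfg$loop_length[2])
  mat_len <- resample(cfg$mature_length[1]:cfg$mature_length[2])
  arm5 <- strsplit(rand_dna(arm_len), "")[[1]]
  # mature inside the 5' arm, clear of both arm ends
  m_off <- resample(3:(arm_len - mat_len - 1L))
  arm3 <- comp_base[rev(arm5)]
  # positions of the 3' arm pairing the mature (arm3 index k pairs arm5 index
  # arm_len+1-k); one mismatch always falls opposite the central part of the
  # mature that every jittered read covers, so no locus read has an exact
  # reverse complement on the star arm (reads stay uniquely mappable)
  j <- cfg$jitter
  core <- (m_off + j):(m_off + mat_len - 1L - j)
  core_pair <- arm_len + 1L - core
  n_mm <- resample(cfg$arm_mismatches[1]:cfg$arm_mismatches[2])
  n_mm <- max(n_mm, 1L)
  mm_pos <- resample(core_pair)
  if (n_mm > 1L)
    mm_pos <- unique(c(mm_pos, sample(seq_len(arm_len), n_mm - 1L)))
  for (k in mm_pos) {
    partner <- arm5[arm_len + 1L - k]
    opts <- nonpairing_bases[[partner]]
    arm3[k] <- resample(opts)
  }
  hairpin <- paste0(paste(arm5, collapse = ""), rand_dna(loop_len),
                    paste(arm3, collapse = ""))
  list(hairpin = hairpin, mature = paste(arm5[m_off:(m_off + mat_len - 1L)], collapse = ""),
       mature_offset = m_off, arm_len = arm_len, loop_len = loop_len)
}

mutate_ortholog <- function(hairpin, rate, compensatory) {
  bases <- strsplit(hairpin, "")[[1]]
  n <- length(bases)
  n_mut <- max(1L, round(rate * n))
  if (compensatory) {
    pairs <- parse_dotbracket(fold_fallback(hairpin))
    done <- logical(n)
    pos <- sample.int(n)
    mutated <- 0L
    for (i in pos) {
      if (mutated >= n_mut) break
      if (done[i]) next
      j <- pairs[i]
      if (!is.na(j)) {
        b <- sample(c("A", "C", "G", "T")[c("A", "C", "G", "T") != bases[i]], 1L)
        bases[i] <- b
        bases[j] <- comp_base[[b]]
        done[c(i, j)] <- TRUE
        mutated <- mutated + 2L
      } else {
        bases[i] <- sample(c("A", "C", "G", "T")[c("A", "C", "G", "T") != bases[i]], 1L)
        done[i] <- TRUE
        mutated <- mutated + 1L
      }
    }
  } else {
    pos <- sample.int(n, n_mut)
    for (i in pos)
      bases[i] <- sample(c("A", "C", "G", "T")[c("A", "C", "G", "T") != bases[i]], 1L)
  }
  paste(bases, collapse = "")
}

place_feature_rows <- function(locus, context, gene_id, te_id) {
  # realize the requested context class with features around a planted locus
  rows <- list()
  g <- function(type, start, end, id, parent = NA_character_)
    data.frame(chrom = locus$chrom, start = start, end = end, strand = "+",
               type = type, feature_id = id, parent_id = parent,
               stringsAsFactors = FALSE)
  s <- locus$start; e <- locus$end
  switch(context,
    near_PCG = {
      gs <- e + resample(1:100); ge <- gs + 499L
      rows <- list(g("gene", gs, ge, gene_id),
                   g("exon", gs, ge, paste0(gene_id, ".e1"), gene_id),
                   g("CDS", gs + 50L, ge - 50L, paste0(gene_id, ".c1"), gene_id))
    },
    PCG_intron = {
      gs <- s - 200L; ge <- e + 200L
      rows <- list(g("gene", gs, ge, gene_id),
                   g("exon", gs, gs + 99L, paste0(gene_id, ".e1"), gene_id),
                   g("exon", ge - 99L, ge, paste0(gene_id, ".e2"), gene_id),
                   g("CDS", gs + 10L, gs + 99L, paste0(gene_id, ".c1"), gene_id),
                   g("CDS", ge - 99L, ge - 10L, paste0(gene_id, ".c2"), gene_id))
    },
    PCG_UTR = {
      gs <- s - 300L; ge <- e + 100L
      rows <- list(g("gene", gs, ge, gene_id),
                   g("exon", gs, ge, paste0(gene_id, ".e1"), gene_id),
                   g("CDS", gs, s - 50L, paste0(gene_id, ".c1"), gene_id))
    },
    PCG_CDS = {
      gs <- s - 100L; ge <- e + 100L
      rows <- list(g("gene", gs, ge, gene_id),
                   g("exon", gs, ge, paste0(gene_id, ".e1"), gene_id),
                   g("CDS", gs, ge, paste0(gene_id, ".c1"), gene_id))
    },
    TE = {
      rows <- list(g("TE", s - 10L, e + 10L, te_id))
    },
    near_TE = {
      ts <- e + resample(1:100)
      rows <- list(g("TE", ts, ts + 299L, te_id))
    },
    intergenic = NULL)
  rows
}

#' Generate a synthetic study world
#'
#' Builds a random genome with planted stem-loop precursors, gene and TE
#' annotations realizing the requested context classes, structural-RNA
#' decoy loci, and companion genomes carrying ortholog copies, together
#' with the full ground truth of every planted element.
#'
#' @param config A [scenario_config()].
#' @return A list of class `Scenario`: `config`, `genome`
#'   ([genome_assembly()]), `loci` (locus table with truth columns
#'   `mature_offset`, `context_planted`, `is_decoy`, `rfam_family`,
#'   `conserved_planted`, `planted_tier`, `duplex_key`), `pcg_features`,
#'   `te_features`, `subject_genomes` (list of assemblies).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  with_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(cfg) {
  n_all <- cfg$n_hairpins + cfg$n_decoys
  slot <- cfg$genome_length %/% n_all
  max_hp <- 2L * cfg$stem_length[2] + cfg$loop_length[2]
  margin <- 700L
  if (slot < max_hp + 2L * margin)
    stop("config infeasible: genome_length too small to place ", n_all,
         " hairpins with ", margin, " nt margins (need >= ",
         n_all * (max_hp + 2L * margin), " nt)")
  genome_chars <- strsplit(rand_dna(cfg$genome_length), "")[[1]]
  contexts <- rep(cfg$planted_contexts, length.out = cfg$n_hairpins)
  conserved <- rep(FALSE, cfg$n_hairpins)
  if (cfg$conserved_fraction > 0 && cfg$n_hairpins > 0) {
    n_cons <- round(cfg$conserved_fraction * cfg$n_hairpins)
    if (n_cons > 0) conserved[sample.int(cfg$n_hairpins, n_cons)] <- TRUE
  }
  fam_pool <- c("U6", "5S_rRNA", "tRNA", "U2")
  loci <- list()
  pcg_rows <- list()
  te_rows <- list()
  for (i in seq_len(n_all)) {
    # plant only hairpins that pass the validity test under the built-in
    # fold: max-pairing occasionally branches the terminal loop, which the
    # single-stem criterion rejects
    for (try in 1:50) {
      hp <- build_hairpin(cfg)
      if (validate_hairpin(hp$hairpin, NULL, hp$mature)$valid) break
      if (try == 50) stop("could not build a valid hairpin under this config")
    }
    len <- nchar(hp$hairpin)
    lo <- (i - 1L) * slot + margin
    start <- lo + sample.int(slot - 2L * margin - len, 1L)
    end <- start + len - 1L
    strand <- sample(c("+", "-"), 1L)
    genome_chars[start:end] <- strsplit(
      if (strand == "+") hp$hairpin else revcomp(hp$hairpin), "")[[1]]
    is_decoy <- i > cfg$n_hairpins
    ctx <- if (is_decoy) "intergenic" else contexts[i]
    locus <- data.frame(
      locus_id = sprintf("PID%04d", i), species = "Synsp", assembly = "synasm1",
      chrom = "chr1", start = start, end = end, strand = strand,
      hairpin = hp$hairpin, mature1 = hp$mature, mature2 = NA_character_,
      source_pub = "synthetic", reporting_class = "coordinates",
      mature_offset = hp$mature_offset, context_planted = ctx,
      is_decoy = is_decoy,
      rfam_family = if (is_decoy) sample(fam_pool, 1L) else NA_character_,
      conserved_planted = if (is_decoy) FALSE else conserved[i],
      stringsAsFactors = FALSE)
    rows <- place_feature_rows(locus, ctx, sprintf("gene%04d", i), sprintf("TE%04d", i))
    for (r in rows) {
      if (r$type == "TE") te_rows[[length(te_rows) + 1L]] <- r
      else pcg_rows[[length(pcg_rows) + 1L]] <- r
    }
    loci[[i]] <- locus
  }
  loci <- do.call(rbind, loci)
  # background annotations, kept well clear of planted loci
  clear_of_loci <- function(start, end) {
    all(end < loci$start - 300L | start > loci$end + 300L)
  }
  occupied <- list()
  clear_of_occupied <- function(start, end) {
    !length(occupied) || all(vapply(occupied, function(o)
      end < o[1] | start > o[2], logical(1)))
  }
  place_bg <- function(n, len_range, maker) {
    for (k in seq_len(n)) {
      for (try in 1:200) {
        len <- sample(len_range[1]:len_range[2], 1L)
        st <- sample.int(cfg$genome_length - len, 1L)
        if (clear_of_loci(st, st + len - 1L) && clear_of_occupied(st, st + len - 1L)) {
          occupied[[length(occupied) + 1L]] <<- c(st - 300L, st + len + 299L)
          maker(k, st, st + len - 1L)
          break
        }
      }
    }
  }
  place_bg(cfg$n_genes, c(400L, 900L), function(k, st, en) {
    id <- sprintf("bgene%03d", k)
    pcg_rows[[length(pcg_rows) + 1L]] <<- data.frame(
      chrom = "chr1", start = st, end = en, strand = "+", type = "gene",
      feature_id = id, parent_id = NA_character_, stringsAsFactors = FALSE)
    pcg_rows[[length(pcg_rows) + 1L]] <<- data.frame(
      chrom = "chr1", start = st, end = en, strand = "+", type = "exon",
      feature_id = paste0(id, ".e1"), parent_id = id, stringsAsFactors = FALSE)
    pcg_rows[[length(pcg_rows) + 1L]] <<- data.frame(
      chrom = "chr1", start = st + 30L, end = en - 30L, strand = "+", type = "CDS",
      feature_id = paste0(id, ".c1"), parent_id = id, stringsAsFactors = FALSE)
  })
  place_bg(cfg$n_tes, c(100L, 400L), function(k, st, en) {
    te_rows[[length(te_rows) + 1L]] <<- data.frame(
      chrom = "chr1", start = st, end = en, strand = "+", type = "TE",
      feature_id = sprintf("bTE%03d", k), parent_id = NA_character_,
      stringsAsFactors = FALSE)
  })
  empty_features <- data.frame(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               type = character(), feature_id = character(),
                               parent_id = character(), stringsAsFactors = FALSE)
  pcg <- if (length(pcg_rows)) do.call(rbind, pcg_rows) else empty_features
  te <- if (length(te_rows)) do.call(rbind, te_rows) else empty_features
  genome <- genome_assembly(
    stats::setNames(paste(genome_chars, collapse = ""), "chr1"),
    assembly_id = "synasm1", species_tag = "Synsp")
  # companion genomes with planted ortholog copies
  subject_genomes <- list()
  if (cfg$n_subject_genomes > 0) {
    cons_idx <- which(loci$conserved_planted)
    for (gidx in seq_len(cfg$n_subject_genomes)) {
      sub_chars <- strsplit(rand_dna(cfg$subject_genome_length), "")[[1]]
      if (length(cons_idx)) {
        sslot <- cfg$subject_genome_length %/% length(cons_idx)
        for (k in seq_along(cons_idx)) {
          hp <- loci$hairpin[cons_idx[k]]
          ortho <- mutate_ortholog(hp, if (cfg$compensatory) cfg$ortholog_mutation_rate
                                       else cfg$disruptive_rate, cfg$compensatory)
          st <- (k - 1L) * sslot + max(1L, sslot %/% 4L)
          sub_chars[st:(st + nchar(ortho) - 1L)] <- strsplit(ortho, "")[[1]]
        }
      }
      subject_genomes[[gidx]] <- genome_assembly(
        stats::setNames(paste(sub_chars, collapse = ""), "chr1"),
        assembly_id = sprintf("subasm%02d", gidx),
        species_tag = sprintf("Sub%02d", gidx))
    }
  }
  # duplex truth and planted tier
  loci$duplex_key <- NA_character_
  loci$hairpin_valid_planted <- NA
  for (i in seq_len(nrow(loci))) {
    db <- fold_fallback(loci$hairpin[i])
    pairs <- parse_dotbracket(db)
    dup <- tryCatch(locate_duplex(loci$hairpin[i], pairs, loci$mature1[i]),
                    milrcurate_error = function(e) NULL)
    if (!is.null(dup))
      loci$duplex_key[i] <- paste(
        substr(loci$hairpin[i], dup$mature_arm[1], dup$mature_arm[2]),
        substr(loci$hairpin[i], dup$star_arm[1], dup$star_arm[2]), sep = "|")
    loci$hairpin_valid_planted[i] <- validate_hairpin(loci$hairpin[i], pairs,
                                                      loci$mature1[i])$valid
  }
  planted_conf <- if (cfg$n_libraries >= 2L) "confirmed_replicated"
                  else if (cfg$n_libraries == 1L) "confirmed" else "no_libraries"
  loci$planted_tier <- vapply(seq_len(nrow(loci)), function(i) {
    assign_tier(planted_conf, loci$context_planted[i], loci$is_decoy[i],
                loci$conserved_planted[i] && cfg$n_subject_genomes >= 2L,
                hairpin_valid = loci$hairpin_valid_planted[i])$tier
  }, integer(1))
  structure(list(config = cfg, genome = genome, loci = loci,
                 pcg_features = pcg, te_features = te,
                 subject_genomes = subject_genomes), class = "Scenario")
}

#' Simulate small RNA sequencing libraries from a scenario
#'
#' For every planted locus, `read_depth` reads are drawn per library: a
#' fraction `dicing_precision` are the exact mature sequence, the rest are
#' jittered within `jitter` nt (never the exact mature coordinates); a
#' fraction `1 - strandedness` are placed on the antisense strand.
#' Background reads are sampled uniformly from regions well clear of
#' planted hairpins. Reads are emitted with the 3' adapter appended and
#' padded/truncated to `read_len` nt, ready for [trim_reads()].
#'
#' @param scenario A [generate_scenario()] result.
#' @param n_libraries,depth,dicing_precision,strandedness,jitter,background_fraction
#'   Override the corresponding `ScenarioConfig` fields.
#' @return List with one element per library: `list(reads, truth)` where
#'   `reads` is a named character vector of raw reads and `truth` a
#'   per-read `data.frame` (`read_id`, `locus_id`, `class`
#'   (`mature`/`jittered`/`background`), `sense`).
#' @export
simulate_reads <- function(scenario, n_libraries = NULL, depth = NULL,
                           dicing_precision = NULL, strandedness = NULL,
                           jitter = NULL, background_fraction = NULL) {
  cfg <- scenario$config
  n_libraries <- n_libraries %||% cfg$n_libraries
  depth <- depth %||% cfg$read_depth
  p <- dicing_precision %||% cfg$dicing_precision
  s <- strandedness %||% cfg$strandedness
  j <- jitter %||% cfg$jitter
  bg <- background_fraction %||% cfg$background_fraction
  loci <- scenario$loci
  genome_seq <- as.character(scenario$genome$sequences[[1]])
  # jitter offsets exclude the exact mature coordinates
  shifts <- expand.grid(ds = -j:j, de = -j:j)
  shifts <- shifts[!(shifts$ds == 0 & shifts$de == 0), , drop = FALSE]
  lapply(seq_len(n_libraries), function(lib) {
    with_seed(cfg$seed + 1009L * lib, {
      read_chunks <- vector("list", nrow(loci))
      truth <- vector("list", nrow(loci))
      for (i in seq_len(nrow(loci))) {
        hp <- loci$hairpin[i]
        o <- loci$mature_offset[i]
        mlen <- nchar(loci$mature1[i])
        is_mat <- stats::rbinom(depth, 1L, p) == 1L
        sense <- stats::rbinom(depth, 1L, s) == 1L
        starts <- rep(o, depth); ends <- rep(o + mlen - 1L, depth)
        nj <- sum(!is_mat)
        if (nj) {
          pick <- sample.int(nrow(shifts), nj, replace = TRUE)
          starts[!is_mat] <- pmax(1L, o + shifts$ds[pick])
          ends[!is_mat] <- pmin(nchar(hp), o + mlen - 1L + shifts$de[pick])
        }
        seqs <- substr(rep(hp, depth), starts, ends)
        seqs[!sense] <- revcomp(seqs[!sense])
        read_chunks[[i]] <- seqs
        truth[[i]] <- data.frame(
          locus_id = loci$locus_id[i],
          class = ifelse(is_mat, "mature", "jittered"),
          sense = sense, stringsAsFactors = FALSE)
      }
      n_bg <- round(bg * depth * nrow(loci))
      if (n_bg > 0) {
        bseqs <- character(0)
        while (length(bseqs) < n_bg) {
          need <- n_bg - length(bseqs)
          lens <- sample(cfg$mature_length[1]:cfg$mature_length[2],
                         2L * need, replace = TRUE)
          st <- vapply(lens, function(l) sample.int(cfg$genome_length - l, 1L),
                       integer(1))
          en <- st + lens - 1L
          ok <- vapply(seq_along(st), function(k)
            all(en[k] < loci$start - 300L | st[k] > loci$end + 300L), logical(1))
          cand <- substring(genome_seq, st[ok], en[ok])
          flip <- stats::runif(length(cand)) < 0.5
          cand[flip] <- revcomp(cand[flip])
          bseqs <- c(bseqs, cand)
        }
        bseqs <- bseqs[seq_len(n_bg)]
        read_chunks[[length(read_chunks) + 1L]] <- bseqs
        truth[[length(truth) + 1L]] <- data.frame(
          locus_id = rep("background", n_bg), class = "background",
          sense = NA, stringsAsFactors = FALSE)
      }
      reads <- unlist(read_chunks, use.names = FALSE)
      truth <- do.call(rbind, truth)
      truth$read_id <- sprintf("lib%d_r%07d", lib, seq_along(reads))
      rownames(truth) <- NULL
      # raw reads: insert + adapter, padded/truncated to the read length
      padlen <- pmax(0L, cfg$read_len - nchar(reads) - nchar(cfg$adapter))
      pad <- rep("", length(reads))
      if (any(padlen > 0L)) {
        long <- rand_dna(sum(padlen))
        ends2 <- cumsum(padlen)
        pad <- substring(long, ends2 - padlen + 1L, ends2)
      }
      raw <- substr(paste0(reads, cfg$adapter, pad), 1L, cfg$read_len)
      names(raw) <- truth$read_id
      list(reads = raw, truth = truth)
    })
  })
}

#' Generate homology hit tables consistent with the planted truth
#'
#' Structural-RNA decoy loci receive a high-scoring hit against their
#' planted family (bitscore well above the retention threshold), and a few
#' non-decoy loci receive sub-threshold chatter so the filter is
#' exercised. Ortholog hits are computed honestly by running
#' [naive_hairpin_search()] for every locus against every companion
#' genome, so scores reflect the planted mutation load.
#'
#' @param scenario A [generate_scenario()] result.
#' @param top_k Sites reported per subject strand/chromosome.
#' @return List: `rfam_hits` (BLAST-tabular `data.frame`), `homolog_hits`
#'   (tblout-shaped `data.frame` of the best raw hits).
#' @export
generate_hit_tables <- function(scenario, top_k = 1) {
  loci <- scenario$loci
  cfg <- scenario$config
  rfam <- list()
  with_seed(cfg$seed + 7L, {
    for (i in seq_len(nrow(loci))) {
      if (loci$is_decoy[i]) {
        rfam[[length(rfam) + 1L]] <- data.frame(
          qseqid = loci$locus_id[i],
          sseqid = paste0("RF99999|", loci$rfam_family[i]),
          pident = round(stats::runif(1, 90, 100), 1),
          length = nchar(loci$hairpin[i]), mismatch = 2L, gapopen = 0L,
          qstart = 1L, qend = nchar(loci$hairpin[i]),
          sstart = 1L, send = nchar(loci$hairpin[i]),
          evalue = 1e-20, bitscore = round(stats::runif(1, 60, 120), 1),
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.2) {
        # sub-threshold chatter
        rfam[[length(rfam) + 1L]] <- data.frame(
          qseqid = loci$locus_id[i], sseqid = "RF99998|tRNA",
          pident = round(stats::runif(1, 70, 80), 1), length = 40L,
          mismatch = 8L, gapopen = 1L, qstart = 1L, qend = 40L,
          sstart = 1L, send = 40L, evalue = 0.5,
          bitscore = round(stats::runif(1, 20, 45), 1),
          stringsAsFactors = FALSE)
      }
    }
  })
  rfam <- if (length(rfam)) do.call(rbind, rfam) else NULL
  homol <- list()
  for (g in scenario$subject_genomes) {
    for (i in seq_len(nrow(loci))) {
      if (loci$is_decoy[i]) next
      h <- naive_hairpin_search(loci$hairpin[i], loci$locus_id[i], g, top_k = top_k)
      if (nrow(h)) homol[[length(homol) + 1L]] <- h[1, , drop = FALSE]
    }
  }
  homol <- if (length(homol)) do.call(rbind, homol) else NULL
  list(rfam_hits = rfam, homolog_hits = homol)
}

#' Write a scenario to disk in standard formats
#'
#' Emits genome and companion-genome FASTA, gene GFF3, TE BED, the locus
#' TSV, per-library FASTQ, truth TSV, and hit tables — byte-identical for
#' a given config.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created).
#' @param libraries Optional [simulate_reads()] result to write as FASTQ.
#' @param hit_tables Optional [generate_hit_tables()] result.
#' @return Invisibly, the named list of written paths.
#' @export
write_scenario <- function(scenario, dir, libraries = NULL, hit_tables = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                loci = file.path(dir, "loci.tsv"),
                genes = file.path(dir, "genes.gff3"),
                tes = file.path(dir, "tes.bed"))
  write_genome_fasta(scenario$genome, paths$genome)
  write_locus_table(scenario$loci, paths$loci)
  fx <- scenario$pcg_features
  gr <- GenomicRanges::GRanges(fx$chrom, IRanges::IRanges(fx$start, fx$end),
                               strand = fx$strand)
  mcols(gr)$type <- fx$type
  mcols(gr)$ID <- fx$feature_id
  mcols(gr)$Parent <- ifelse(is.na(fx$parent_id), "", fx$parent_id)
  mcols(gr)$phase <- ifelse(fx$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, paths$genes, format = "gff3")
  te <- scenario$te_features
  tegr <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start, te$end))
  mcols(tegr)$name <- te$feature_id
  rtracklayer::export(tegr, paths$tes, format = "bed")
  for (g in scenario$subject_genomes) {
    p <- file.path(dir, paste0(g$assembly_id, ".fa"))
    write_genome_fasta(g, p)
    paths[[g$assembly_id]] <- p
  }
  if (!is.null(libraries)) {
    for (l in seq_along(libraries)) {
      p <- file.path(dir, sprintf("lib%d.fastq", l))
      write_fastq(libraries[[l]]$reads, p)
      paths[[sprintf("lib%d", l)]] <- p
    }
  }
  if (!is.null(hit_tables)) {
    if (!is.null(hit_tables$rfam_hits)) {
      paths$rfam <- file.path(dir, "rfam_hits.tsv")
      write_blast_hits(hit_tables$rfam_hits, paths$rfam)
    }
    if (!is.null(hit_tables$homolog_hits)) {
      paths$homologs <- file.path(dir, "homolog_hits.tblout")
      write_tblout(hit_tables$homolog_hits, paths$homologs)
    }
  }
  invisible(paths)
}
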