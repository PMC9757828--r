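#' Pipeline configuration
#'
#' Collects every threshold of the curation pipeline, defaulted to the
#' published values: 80% strandedness, 0.5 RPM expression, 20 unpaired
#' duplex positions, structural-RNA bitscore 50, 100 nt adjacency
#' threshold, 15% exon/CDS fraction, and 0.4 bits/nt homology cutoff.
#'
#' @param seed Seed used for locality order and multimapper tie-breaks.
#' @param min_strandedness,min_rpm,max_unpaired,rfam_bitscore,near_threshold,min_fraction,min_bits_per_nt
#'   Rule thresholds (see the stage functions).
#' @param min_conserved_genomes Subject genomes required for the
#'   conservation criterion (default 2).
#' @param multimap_window Window for multimapper placement (nt).
#' @param fold_method `"fallback"` or `"rnafold"` ([fold_hairpin()]).
#' @param adapter 3' adapter to trim from raw reads; `NULL` for
#'   pre-trimmed input.
#' @param near_te_excludes Treat near-TE context as an exclusion
#'   (default `TRUE`).
#' @param skip_profiling,skip_context,skip_conservation Stage toggles;
#'   skipped stages report `not_evaluated` evidence.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 9182, min_strandedness = 0.8, min_rpm = 0.5,
                            max_unpaired = 20, rfam_bitscore = 50,
                            near_threshold = 100, min_fraction = 0.15,
                            min_bits_per_nt = 0.4, min_conserved_genomes = 2,
                            multimap_window = 250, fold_method = "fallback",
                            adapter = NULL, near_te_excludes = TRUE,
                            skip_profiling = FALSE, skip_context = FALSE,
                            skip_conservation = FALSE) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full curation pipeline
#'
#' Stages run in order: recover (loci lacking coordinates or hairpin) →
#' validate (three-criterion hairpin test) → profile (per-library
#' alignment, MAS, minimal rules, cross-library confirmation) → context
#' (structural-RNA homology and genomic adjacency) → conserve
#' (cross-genome homology filtering over intergenic loci) → tier.
#'
#' @param loci Locus table ([read_locus_table()] shape).
#' @param genome A [genome_assembly()].
#' @param libraries List of per-library reads: each element either a
#'   character vector of (raw or trimmed) reads or an alignment
#'   `data.frame` from [align_reads()] / [read_sam_alignments()]. Empty
#'   list means no sequencing evidence.
#' @param pcg_features,te_features Feature `data.frame`s (may be empty).
#' @param rfam_hits BLAST-tabular `data.frame` of structural-RNA hits, or
#'   `NULL` for none.
#' @param homolog_hits tblout-shaped homology hits; if `NULL` and
#'   `subject_genomes` are given, hits are computed with
#'   [naive_hairpin_search()].
#' @param subject_genomes List of companion [genome_assembly()] objects.
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, writes `evidence.tsv`, `loci.gff3`,
#'   `summary.json` and `run.log` there.
#' @return A list of class `PipelineResult`: `evidence` (one row per input
#'   locus with a terminal status), `profiles` (per locus × library),
#'   `summary` (category counts mirroring each stage), `config`.
#' @export
run_pipeline <- function(loci, genome, libraries = list(),
                         pcg_features = NULL, te_features = NULL,
                         rfam_hits = NULL, homolog_hits = NULL,
                         subject_genomes = list(),
                         config = pipeline_config(), out_dir = NULL) {
  empty_features <- data.frame(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               type = character(), feature_id = character(),
                               parent_id = character(), stringsAsFactors = FALSE)
  pcg_features <- pcg_features %||% empty_features
  te_features <- te_features %||% empty_features
  log_lines <- c(sprintf("milrcurate run: %d loci, %d libraries, seed %d",
                         nrow(loci), length(libraries), config$seed),
                 paste0("thresholds: ",
                        sprintf("strandedness>=%.2f rpm>=%.2f unpaired<=%d rfam>=%g near<=%d frac>%.2f bits/nt>%.2f",
                                config$min_strandedness, config$min_rpm,
                                config$max_unpaired, config$rfam_bitscore,
                                config$near_threshold, config$min_fraction,
                                config$min_bits_per_nt)))
  ev <- loci
  ev$status <- "pending"
  ev$recovery_status <- "not_needed"

  ## stage 1: recover missing hairpins/coordinates -------------------------
  for (i in seq_len(nrow(ev))) {
    has_coord <- !is_blank(ev$chrom[i]) && !is.na(ev$start[i]) && !is.na(ev$end[i])
    has_hairpin <- !is.na(ev$hairpin[i])
    if (has_coord && has_hairpin) next
    if (has_coord && !has_hairpin) {
      strand <- if (ev$strand[i] %in% c("+", "-")) ev$strand[i] else "+"
      ev$hairpin[i] <- genome_subseq(genome, ev$chrom[i], ev$start[i], ev$end[i], strand)
      ev$recovery_status[i] <- "extracted_from_coords"
      next
    }
    if (!has_coord && has_hairpin) {
      # infer coordinates by exact hairpin match
      placed <- FALSE
      for (chrom in names(genome$sequences)) {
        for (strand in c("+", "-")) {
          q <- if (strand == "+") ev$hairpin[i] else revcomp(ev$hairpin[i])
          hits <- Biostrings::matchPattern(q, genome$sequences[[chrom]])
          if (length(hits)) {
            ev$chrom[i] <- chrom
            ev$start[i] <- Biostrings::start(hits)[1]
            ev$end[i] <- Biostrings::end(hits)[1]
            ev$strand[i] <- strand
            ev$recovery_status[i] <- "coords_from_hairpin"
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (placed) next
    }
    rec <- recover_locus(ev[i, ], genome, seed = config$seed,
                         fold_method = config$fold_method)
    if (rec$status == "recovered") {
      w <- rec$window
      ev$chrom[i] <- w$chrom; ev$start[i] <- w$start; ev$end[i] <- w$end
      ev$strand[i] <- w$strand; ev$hairpin[i] <- w$seq
      ev$recovery_status[i] <- "recovered"
    } else {
      ev$recovery_status[i] <- "unrecoverable"
      ev$status[i] <- "unrecoverable"
    }
  }
  log_lines <- c(log_lines, sprintf("recovery: %d unrecoverable",
                                    sum(ev$status == "unrecoverable")))

  ## stage 2: validity -----------------------------------------------------
  ev$hairpin_valid <- NA
  ev$validity_reasons <- NA_character_
  ev$structure <- NA_character_
  active <- which(ev$status == "pending")
  for (i in active) {
    matures <- c(ev$mature1[i], ev$mature2[i])
    matures <- matures[!is.na(matures)]
    if (!length(matures)) {
      ev$hairpin_valid[i] <- FALSE
      ev$validity_reasons[i] <- "mas_absent"
      ev$status[i] <- "invalid"
      next
    }
    ev$structure[i] <- fold_hairpin(ev$hairpin[i], method = config$fold_method)
    rep_i <- validate_hairpin(ev$hairpin[i], ev$structure[i], matures,
                              max_unpaired = config$max_unpaired)
    ev$hairpin_valid[i] <- rep_i$valid
    ev$validity_reasons[i] <- paste(rep_i$reasons, collapse = ",")
    if (!rep_i$valid) ev$status[i] <- "invalid"
  }
  log_lines <- c(log_lines, sprintf("validity: %d invalid", sum(ev$status == "invalid")))

  ## stage 3: sRNA-seq profiling -------------------------------------------
  ev$mas_seq <- NA_character_; ev$mas_category <- "no_reads"
  ev$confirmation <- "no_libraries"; ev$n_libraries_passing <- 0L
  ev$mas_rpm_best <- NA_real_; ev$strandedness_best <- NA_real_
  ev$dicing_specificity <- NA_real_
  profiles <- list()
  if (!config$skip_profiling && length(libraries)) {
    aligned <- lapply(seq_along(libraries), function(l) {
      x <- libraries[[l]]
      if (is.data.frame(x)) return(x)
      reads <- x
      if (!is.null(config$adapter))
        reads <- trim_reads(reads, config$adapter)
      align_reads(reads, genome, window = config$multimap_window,
                  seed = config$seed + l, library_id = sprintf("lib%d", l))
    })
    active <- which(ev$status == "pending")
    for (i in active) {
      outcomes <- list()
      best_rpm <- -Inf; best_str <- -Inf
      for (l in seq_along(aligned)) {
        pr <- profile_locus(aligned[[l]], ev[i, ])
        profiles[[length(profiles) + 1L]] <- pr
        outcomes[[l]] <- apply_minimal_rules(pr, ev$hairpin[i], ev$structure[i],
                                             min_strandedness = config$min_strandedness,
                                             min_rpm = config$min_rpm)
        if (!is.na(pr$mas_rpm) && pr$mas_rpm > best_rpm) {
          best_rpm <- pr$mas_rpm
          ev$mas_seq[i] <- pr$mas_seq
          ev$mas_category[i] <- classify_mas(pr, ev$mature1[i])
          sp <- dicing_specificity(pr)
          if (!is.na(sp)) ev$dicing_specificity[i] <- sp
        }
        if (!is.na(pr$strandedness)) best_str <- max(best_str, pr$strandedness)
      }
      conf <- confirm_across_libraries(outcomes)
      ev$confirmation[i] <- conf$status
      ev$n_libraries_passing[i] <- conf$n_libraries_passing
      if (is.finite(best_rpm)) ev$mas_rpm_best[i] <- best_rpm
      if (is.finite(best_str)) ev$strandedness_best[i] <- best_str
    }
  } else if (config$skip_profiling) {
    ev$confirmation <- "no_libraries"
  }
  log_lines <- c(log_lines, sprintf(
    "profiling: %d confirmed_replicated, %d confirmed, %d failed",
    sum(ev$confirmation == "confirmed_replicated" & ev$status == "pending"),
    sum(ev$confirmation == "confirmed" & ev$status == "pending"),
    sum(ev$confirmation == "failed" & ev$status == "pending")))

  ## stage 4: structural-RNA homology + genomic context --------------------
  ev$rfam_hit <- FALSE; ev$rfam_category <- NA_character_
  if (!is.null(rfam_hits) && nrow(rfam_hits)) {
    rf <- classify_rfam(rfam_hits, threshold = config$rfam_bitscore)
    hit_idx <- match(ev$locus_id, rf$locus_id)
    ev$rfam_hit <- !is.na(hit_idx)
    ev$rfam_category <- rf$merged_category[hit_idx]
  }
  ev$context <- "intergenic"; ev$context_distance <- NA_integer_
  if (!config$skip_context) {
    active <- which(ev$status == "pending")
    for (i in active) {
      cc <- classify_context(ev[i, ], pcg_features, te_features,
                             near_threshold = config$near_threshold,
                             min_fraction = config$min_fraction)
      ev$context[i] <- cc$context
      ev$context_distance[i] <- cc$distance
    }
  } else {
    ev$context <- "not_evaluated"
  }

  ## stage 5: conservation --------------------------------------------------
  ev$intergenic_ok <- FALSE
  ev$n_subject_genomes <- 0L
  ev$conserved_two_plus_genomes <- FALSE
  if (!config$skip_conservation && !config$skip_context) {
    active <- which(ev$status == "pending")
    ev$intergenic_ok[active] <- call_intergenic(ev$rfam_hit[active],
                                                ev$context[active],
                                                ev$confirmation[active])
    q_ids <- ev$locus_id[ev$intergenic_ok]
    if (length(q_ids)) {
      if (is.null(homolog_hits) && length(subject_genomes)) {
        hh <- list()
        for (g in subject_genomes) {
          for (id in q_ids) {
            h <- naive_hairpin_search(ev$hairpin[ev$locus_id == id], id, g, top_k = 1)
            if (nrow(h)) hh[[length(hh) + 1L]] <- h[1, , drop = FALSE]
          }
        }
        homolog_hits <- if (length(hh)) do.call(rbind, hh) else NULL
      }
      if (!is.null(homolog_hits) && nrow(homolog_hits)) {
        qlen <- stats::setNames(nchar(ev$hairpin), ev$locus_id)
        qsp <- stats::setNames(ev$species, ev$locus_id)
        kept <- filter_homolog_hits(
          homolog_hits[homolog_hits$query_locus_id %in% ev$locus_id, , drop = FALSE],
          qlen, qsp, min_bits_per_nt = config$min_bits_per_nt)
        cons <- summarize_conservation(kept, q_ids,
                                       min_genomes = config$min_conserved_genomes)
        m <- match(ev$locus_id, cons$locus_id)
        ok <- !is.na(m)
        ev$n_subject_genomes[ok] <- cons$n_subject_genomes[m[ok]]
        ev$conserved_two_plus_genomes[ok] <- cons$conserved_two_plus_genomes[m[ok]]
      }
    }
  }

  ## stage 6: tiers ---------------------------------------------------------
  ev$tier <- NA_integer_; ev$criteria_met <- NA_character_; ev$exclusions_hit <- NA_character_
  active <- which(ev$status == "pending")
  if (length(active)) {
    ctx <- ev$context[active]
    if (config$skip_context) ctx <- rep("intergenic", length(active))
    for (k in seq_along(active)) {
      i <- active[k]
      ta <- assign_tier(ev$confirmation[i], ctx[k], ev$rfam_hit[i],
                        ev$conserved_two_plus_genomes[i],
                        hairpin_valid = TRUE,
                        near_te_excludes = config$near_te_excludes)
      ev$tier[i] <- ta$tier
      ev$criteria_met[i] <- paste(ta$criteria_met, collapse = ",")
      ev$exclusions_hit[i] <- paste(ta$exclusions_hit, collapse = ",")
      ev$status[i] <- "tiered"
    }
  }
  summary <- list(
    n_input = nrow(ev),
    status = as.list(table(ev$status)),
    validity = list(valid = sum(ev$hairpin_valid, na.rm = TRUE),
                    invalid = sum(!ev$hairpin_valid, na.rm = TRUE)),
    mas_categories = as.list(table(ev$mas_category[ev$status == "tiered"])),
    confirmation = as.list(table(ev$confirmation[ev$status == "tiered"])),
    context = as.list(table(ev$context[ev$status == "tiered"])),
    rfam_hits = sum(ev$rfam_hit),
    intergenic = sum(ev$intergenic_ok),
    conserved_two_plus_genomes = sum(ev$conserved_two_plus_genomes),
    tiers = as.list(table(factor(ev$tier, levels = 1:4,
                                 labels = paste0("tier", 1:4)))))
  log_lines <- c(log_lines, sprintf("tiers: %s",
                                    paste(names(summary$tiers), unlist(summary$tiers),
                                          sep = "=", collapse = " ")))
  res <- structure(list(evidence = ev, profiles = profiles, summary = summary,
                        config = config, log = log_lines),
                   class = "PipelineResult")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    drop_cols <- intersect("structure", names(ev))
    utils::write.table(ev[, setdiff(names(ev), drop_cols)],
                       file.path(out_dir, "evidence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    with_coords <- ev[!is.na(ev$start) & !is.na(ev$end), , drop = FALSE]
    write_locus_gff3(with_coords, file.path(out_dir, "loci.gff3"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("<PipelineResult>\n")
  cat(" ", x$summary$n_input, "input loci;",
      paste(names(x$summary$status), unlist(x$summary$status), collapse = ", "), "\n")
  cat("  tiers:", paste(names(x$summary$tiers), unlist(x$summary$tiers),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}
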