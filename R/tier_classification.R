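tier_contexts <- c("TE", "near_TE", "PCG_CDS", "PCG_UTR", "PCG_intron",
                   "near_PCG", "intergenic")
confirmation_levels <- c("no_libraries", "failed", "confirmed", "confirmed_replicated")

#' Assign a confidence tier from merged locus evidence
#'
#' Exclusion criteria are evaluated first; any of them sends the locus to
#' tier 4: genomic intersection with a TE (including near-TE by default,
#' since distances within the near threshold count as intersections) or a
#' protein-coding CDS, homology to a structural RNA, or failed sequencing
#' confirmation. Otherwise three support criteria are counted: (c1)
#' confirmed and replicated by sequencing, (c2) intergenic context
#' (relaxed, for tier 2, to near-PCG / PCG-UTR / PCG-intron), (c3)
#' conserved in two or more genomes. All three with strictly intergenic
#' context give tier 1; any two (with relaxed context) give tier 2;
#' everything else without exclusions is tier 3. Loci whose reported
#' hairpin is invalid are excluded from tiering entirely (`tier = NA`).
#'
#' @param confirmation One of `no_libraries`, `failed`, `confirmed`,
#'   `confirmed_replicated`.
#' @param context Context class from [classify_context()].
#' @param rfam_hit Logical: retained structural-RNA hit.
#' @param conserved_two_plus_genomes Logical.
#' @param hairpin_valid Logical (default `TRUE`).
#' @param near_te_excludes Should `near_TE` count as a TE intersection for
#'   exclusion (default `TRUE`)?
#' @return A list of class `TierAssignment`: `tier` (1-4, or `NA` for an
#'   invalid hairpin), `criteria_met` (subset of `confirmed_replicated`,
#'   `intergenic_ok`, `conserved`), `exclusions_hit` (subset of
#'   `TE_intersect`, `CDS_intersect`, `rfam_hit`, `seq_failed`).
#' @export
assign_tier <- function(confirmation, context, rfam_hit,
                        conserved_two_plus_genomes, hairpin_valid = TRUE,
                        near_te_excludes = TRUE) {
  stopifnot(confirmation %in% confirmation_levels, context %in% tier_contexts)
  if (!hairpin_valid)
    return(structure(list(tier = NA_integer_, criteria_met = character(),
                          exclusions_hit = "invalid_hairpin"),
                     class = "TierAssignment"))
  exclusions <- character()
  te_classes <- if (near_te_excludes) c("TE", "near_TE") else "TE"
  if (context %in% te_classes) exclusions <- c(exclusions, "TE_intersect")
  if (context == "PCG_CDS") exclusions <- c(exclusions, "CDS_intersect")
  if (isTRUE(rfam_hit)) exclusions <- c(exclusions, "rfam_hit")
  if (confirmation == "failed") exclusions <- c(exclusions, "seq_failed")
  if (length(exclusions))
    return(structure(list(tier = 4L, criteria_met = character(),
                          exclusions_hit = exclusions), class = "TierAssignment"))
  c1 <- confirmation == "confirmed_replicated"
  c2_strict <- context == "intergenic"
  c2_relaxed <- context %in% c("intergenic", "near_PCG", "PCG_UTR", "PCG_intron")
  c3 <- isTRUE(conserved_two_plus_genomes)
  criteria <- c(if (c1) "confirmed_replicated",
                if (c2_relaxed) "intergenic_ok",
                if (c3) "conserved")
  tier <- if (c1 && c2_strict && c3) 1L
          else if (sum(c(c1, c2_relaxed, c3)) >= 2L) 2L
          else 3L
  structure(list(tier = tier, criteria_met = criteria %||% character(),
                 exclusions_hit = character()), class = "TierAssignment")
}

#' Assign tiers for a whole evidence table
#'
#' @param evidence `data.frame` with columns `locus_id`, `confirmation`,
#'   `context`, `rfam_hit` (logical), `conserved_two_plus_genomes`
#'   (logical) and optionally `hairpin_valid`.
#' @inheritParams assign_tier
#' @return The input with added columns `tier`, `criteria_met` and
#'   `exclusions_hit` (comma-collapsed).
#' @export
assign_tiers <- function(evidence, near_te_excludes = TRUE) {
  need <- c("locus_id", "confirmation", "context", "rfam_hit",
            "conserved_two_plus_genomes")
  missing_cols <- setdiff(need, names(evidence))
  if (length(missing_cols))
    stop("evidence table lacks columns: ", paste(missing_cols, collapse = ", "))
  hv <- if ("hairpin_valid" %in% names(evidence)) evidence$hairpin_valid else TRUE
  res <- lapply(seq_len(nrow(evidence)), function(i)
    assign_tier(evidence$confirmation[i], evidence$context[i],
                evidence$rfam_hit[i], evidence$conserved_two_plus_genomes[i],
                hairpin_valid = if (length(hv) > 1) hv[i] else hv,
                near_te_excludes = near_te_excludes))
  evidence$tier <- vapply(res, function(r) r$tier, integer(1))
  evidence$criteria_met <- vapply(res, function(r) paste(r$criteria_met, collapse = ","), "")
  evidence$exclusions_hit <- vapply(res, function(r) paste(r$exclusions_hit, collapse = ","), "")
  evidence
}

#' Summarize tier assignments
#'
#' @param assignments Output of [assign_tiers()], optionally with `species`
#'   and `mas_length` columns.
#' @param typical_range MAS length range regarded as typical small-RNA
#'   sizes (default 19-25 nt); lengths outside it are flagged.
#' @return List with `by_tier` (counts incl. invalid), `top_tier_count`
#'   (tiers 1-2), and when available `by_species` and `mas_length_bins`.
#' @export
summarize_tiers <- function(assignments, typical_range = c(19L, 25L)) {
  tiers <- assignments$tier
  by_tier <- c(tier1 = sum(tiers == 1L, na.rm = TRUE),
               tier2 = sum(tiers == 2L, na.rm = TRUE),
               tier3 = sum(tiers == 3L, na.rm = TRUE),
               tier4 = sum(tiers == 4L, na.rm = TRUE),
               invalid = sum(is.na(tiers)))
  out <- list(by_tier = by_tier,
              top_tier_count = unname(by_tier["tier1"] + by_tier["tier2"]))
  if ("species" %in% names(assignments))
    out$by_species <- table(assignments$species, factor(tiers, levels = 1:4,
                                                        labels = paste0("tier", 1:4)))
  if ("mas_length" %in% names(assignments)) {
    len <- assignments$mas_length[!is.na(assignments$mas_length)]
    bins <- table(factor(pmin(pmax(len, typical_range[1] - 1L), typical_range[2] + 1L),
                         levels = (typical_range[1] - 1L):(typical_range[2] + 1L)))
    names(bins)[1] <- paste0("<", typical_range[1])
    names(bins)[length(bins)] <- paste0(">", typical_range[2])
    out$mas_length_bins <- bins
    out$atypical_mas_length <- sum(len < typical_range[1] | len > typical_range[2])
  }
  out
}
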