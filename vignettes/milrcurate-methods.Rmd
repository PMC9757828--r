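---
title: "Curating hairpin-derived small RNA loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating hairpin-derived small RNA loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milrcurate)
```

## The curation problem

Fungal miRNAs and miRNA-like RNAs (mi/milRNAs) are hairpin-derived small
RNAs: a single-stranded stem-loop precursor is diced into a short mature
sequence and its duplex partner (the star). Published annotations of such
loci are heterogeneous — some report full precursor coordinates, some only
a hairpin sequence, many only the mature sequence — and the supporting
evidence varies from deep replicated sequencing to a single library or
none at all. `milrcurate` re-assesses such loci uniformly: it validates or
reconstructs the precursor, re-tests each locus against small-RNA
sequencing data, classifies genomic context and structural-RNA homology,
screens for cross-genome conservation, and merges everything into a
four-tier confidence ranking. This vignette explains each model, the
tunable parameters, and the design decisions made where the method left
room for interpretation.

## Coordinates and alphabets

Internally all intervals are 1-based closed, the convention of the
Bioconductor containers (`IRanges`/`GenomicRanges`) this package builds
on. Conversions happen only at file boundaries: GFF3 in/out is 1-based
inclusive, BED input is 0-based half-open, and the locus TSV is 1-based
inclusive. Sequences are stored in the DNA alphabet; `U` is mapped to `T`
on input (matures are usually reported as RNA, genomes as DNA), so string
comparisons never straddle alphabets.

## Hairpin validity

A reported hairpin is folded (externally with RNAfold, whose dot-bracket
output `read_dotbracket_file()` parses, or with the built-in fold below)
and tested against three criteria:

1. **Mature containment** — every reported mature sequence must occur as a
   substring of the hairpin. If a mature occurs more than once the 5'-most
   occurrence is used, with a warning; this keeps the procedure
   deterministic.
2. **Single stem in the duplex region** — the minimal span covering both
   duplex arms must fold as one stem-loop. Operationally: every base pair
   with at least one end inside the span must belong to a single, totally
   nested helix chain. Enclosing pairs below the duplex (the precursor's
   lower stem) are part of that chain and are allowed; a second helix
   branching off side-by-side inside the span is not. This formalization
   was chosen because it is testable against an explicit enumeration
   oracle and matches the intuitive picture of a "secondary structure in
   the duplex": a multiloop or a side helix competing with the
   mature/star pairing.
3. **Unpaired-position budget** — at most 20 positions across both duplex
   arms may lack a partner on the opposite arm. The count is summed over
   both arms, not per arm, because the criterion is stated for "the
   duplex" as a whole.

### The duplex and the overhang convention

The duplex is anchored on the mature: the star arm is derived from the
pairing partners of the mature positions, extrapolated to the mature ends
(so bulged termini do not truncate the star) and offset by a 2-nt
overhang. Dicer products carry 2-nt 3' overhangs, so `three_prime` is the
default; the literature on fungal hairpins sometimes states a 5' overhang,
so `five_prime` is supported as an option and neither is asserted to be
universally correct. The two terminal overhang positions of each arm are
excluded from the unpaired-position count: they are unpaired by
convention, not structural defects. With this convention a perfect stem
with the full 5' arm as mature scores zero unpaired positions, which is
the behavior a curator expects.

### The built-in fold

`fold_fallback()` is a deterministic Nussinov-style dynamic program that
maximizes the number of base pairs (Watson–Crick plus G:U wobble, the
pairs a thermodynamic folder would also accept) subject to a minimum
hairpin-loop size of 3 nt. Ties are broken by pairing each 3' base with
its 5'-most admissible partner, so the output is reproducible. It is not
a thermodynamic model: it has no stacking energies, so on random sequence
it pairs more aggressively than RNAfold would. For the clean stem-loops
the validity test targets this difference is immaterial — the planted stem
dominates the pairing count — and the production path accepts RNAfold
output wherever energy-based folds are preferred. The implementation is
in C++ (O(n³) time, O(n²) int16 storage) so that folding ten 600-nt
candidate windows per locality stays in tens of milliseconds.

## Precursor recovery

Loci reported with only mature sequence(s) are recovered in three steps:

* **Locality finding** — exact matching of each mature (minimum 15 nt, as
  shorter queries match spuriously genome-wide) on both strands. With two
  matures (mature + star) only co-occurrences within a 600-nt joint
  window survive, 600 nt being the largest candidate hairpin — two matures
  farther apart cannot share a precursor. Multiple localities are tested
  in an order shuffled by a user-supplied seed (default 9182): the order
  is explicitly arbitrary, and a seed makes arbitrariness reproducible.
* **Candidate enumeration** — per locality, 10 windows each of 150, 300
  and 600 nt. The ten starts are evenly spaced (rounded) over the full
  admissible range that keeps the mature contained; windows are clipped
  at contig ends and deduplicated. Even spacing is the least-informative
  deterministic choice that guarantees mature containment.
* **Selection** — every candidate is folded and validated; among valid
  candidates the modal duplex sequence (mature arm + star arm) wins, and
  among its carriers the smallest window, then the leftmost, is returned
  (a minimal-precursor principle; both tie-breaks are deterministic). The
  first locality that yields a valid hairpin ends the search.

`evaluate_recovery()` benchmarks the procedure against loci with known
precursors by re-running it from the matures alone and scoring
locality-correct (window overlaps the true precursor) and duplex-correct
(identical duplex sequences) outcomes, as precision (over recovered loci)
and sensitivity (over all loci).

## Sequencing re-assessment

* **Trimming** (`trim_reads()`): the 3' adapter is removed on exact match
  — either a full internal occurrence (everything from the match on is
  dropped) or a read-suffix/adapter-prefix overlap of at least 4 nt.
  Reads are kept at 10–50 nt with no `N`. Unlike general trimmers no
  mismatches are tolerated; synthetic reads are error-free, and
  production users can supply pre-trimmed reads or SAM alignments
  (`read_sam_alignments()`, ungapped records).
* **Alignment** (`align_reads()`): exact matching of unique read
  sequences on both strands (grouped by width into Aho–Corasick
  dictionaries). Unique mappers are placed directly; each multimapper
  goes to the candidate site whose surrounding 250-nt window holds the
  most uniquely mapped reads — the weighted-placement idea of
  ShortStack-style aligners; the window width is not fixed by any
  published value and is configurable. Residual ties are broken by a
  seeded draw.
* **Profiles** (`profile_locus()`): reads fully inside the hairpin
  interval (closed containment; a read exactly spanning the hairpin is
  in-bounds) are counted per sequence; overlapping reads crossing a
  boundary are *out-of-bounds* — a diagnostic for mis-annotated
  precursor bounds. The MAS is the top in-bounds sequence (ties resolved
  lexicographically, with a warning). `mas_rpm` divides by all
  genome-aligned reads of the library, the stated RPM convention.
* **Minimal rules**: fn1 strandedness ≥ 0.80, fn2 MAS RPM ≥ 0.5, fn3 no
  secondary structure in the duplex of the *observed* MAS (re-evaluated
  because the observed MAS frequently differs from the reported mature;
  in that case the MAS substitutes for the mature downstream). Both
  numeric thresholds are inclusive; the strandedness denominator uses
  in-bounds reads only (whether out-of-bounds reads should count is
  unstated in the rule's sources; in-bounds-only is the conservative
  reading). Passing all rules in one library confirms a locus; in two or
  more, confirms and replicates it.
* **Strict rule sets** (`apply_strict_rules()`): plant-annotation-style
  predicates (duplex-read precision, star observed, duplex mismatch and
  bulge budgets, hairpin and MAS length ranges, replication). The shipped
  `shortstack.yaml` and `axtell2018.yaml` follow the cited tools'
  published criteria where stated; every threshold is an editable config
  value because the exact encodings differ between tool versions.

## Genomic context and structural RNAs

Structural-RNA hits (BLAST tabular, against an Rfam-derived set with
small-RNA families excluded) are retained at bitscore ≥ 50 (inclusive),
one best hit per locus, with family names merged into display categories
through a shipped, editable mapping table.

Adjacency uses the closest gene or TE on either strand, with overlap (and
touching intervals) counting as distance 0 and ties awarded to the TE —
TE-derived small RNAs are the more likely annotation error, so the tie
rule is conservative. Distances ≤ 100 nt are intersections; beyond that a
locus is intergenic with respect to that feature. Within a gene, a
hairpin deriving > 15% of its length (strictly) from CDS is `PCG_CDS`;
failing that, > 15% from exon is `PCG_UTR`; failing that, a hairpin
inside the gene span is `PCG_intron`. When two genes overlap a hairpin
the larger overlap wins (ties to the smaller gene id); a gene without
exon children is treated as single-exon with a warning. CDS precedence
over exon is assumed because CDS is the terminal class of the scheme.

A locus is *intergenic* for conservation purposes iff it has no retained
structural-RNA hit, its context is intergenic, and its sequencing
re-assessment did not fail outright — loci with no available libraries
remain eligible.

## Conservation

Homology hits (nhmmer `--tblout` format, or the built-in ungapped
scanner for offline use) are filtered in three steps: same-species hits
are dropped (species identity is the five-letter species tag; strains
collapse), one best hit per (query, subject species) is kept, and hits
are retained iff bitscore divided by query hairpin length exceeds 0.4
(strictly). The length normalization lets short animal-like hairpins
compete with long plant-like ones. A locus conserved in ≥ 2 subject
genomes (the source genome is never counted, since conspecific hits are
excluded) carries the top-conservation flag; the genome count is
configurable. The built-in scanner scores +1/−1 per position and halves
the raw score, so an exact L-nt copy scores 0.5 bits/nt — comfortably
above the 0.4 cutoff — while a copy with more than 10% mismatches falls
below it; this makes the filter's behavior on planted orthologs exactly
predictable.

## Tiers

Exclusions are evaluated first: TE intersection (including near-TE by
default, because ≤ 100 nt counts as intersection; configurable), CDS
intersection, a structural-RNA hit, or failed confirmation send a locus
to tier 4 regardless of other evidence. Otherwise three support criteria
are counted — confirmed-and-replicated, intergenic context (relaxed to
near-PCG/UTR/intron for tier 2), and conservation in ≥ 2 genomes. All
three with strictly intergenic context is tier 1; any two is tier 2;
anything else without exclusions is tier 3. Loci with `no_libraries`
are not "failed" — absence of evidence is not negative evidence — but
they cannot satisfy the replication criterion, so tier 2 is their
ceiling. The function is total over the 112 combinations of
confirmation × context × Rfam × conservation, monotone under evidence
downgrades, and absorbing at tier 4; the test suite enumerates all of
this. Loci whose reported hairpin fails validity are excluded from
tiering entirely and reported separately.

## The synthetic world

The generator exists so that every stage of the pipeline can be exercised
against known truth without downloads. It emulates:

* **Precursors**: arm + loop + mutated reverse-complement arm, arm length
  50–60 nt, loop 4–8 nt, mature 20–24 nt placed inside the 5' arm — the
  size regime of short fungal/animal-like hairpins, kept ≤ 150 nt so the
  smallest candidate window class can contain a precursor. Each arm
  carries 1–3 mismatches against its complement (real mi/milRNA duplexes
  are imperfect); one mismatch is always placed opposite the central part
  of the mature so that no locus read has an exact reverse complement on
  the star arm — otherwise reads would multimap across the two arms and
  contaminate strandedness estimates with placement noise. Hairpins are
  rejection-sampled until they pass the validity test under the built-in
  fold, making "planted implies valid" a construction guarantee.
* **Reads**: fixed depth per locus (so expression-rule boundaries are
  exact; the default 1000 reads/locus at the default library size gives
  unambiguous rule outcomes), dicing precision 0.9 (fraction of reads
  that are the exact mature; the rest jitter by ±2 nt, never landing on
  the exact mature coordinates), strandedness 0.95, 5% background reads
  sampled ≥ 300 nt away from any planted hairpin so truth profiles are
  uncontaminated, the standard Illumina small-RNA 3' adapter appended,
  and reads padded/truncated to 50 nt.
* **Annotation**: per-hairpin context classes are realized by placing
  gene models (gene/exon/CDS) and TE intervals at the distances and
  overlap fractions each class requires, plus background features kept
  well clear of planted loci.
* **Decoys and orthologs**: decoy loci receive high-scoring hits against
  structural-RNA families in the generated BLAST-style table; ortholog
  copies are written into companion genomes either with compensatory
  mutations (paired positions mutated together, preserving structure;
  rate 0.05, i.e. ~0.45 bits/nt under the scanner) or disruptive
  one-sided mutations (rate 0.25, ~0.25 bits/nt, below the filter).
  Ortholog hit tables are computed honestly by running the scanner, not
  synthesized from the truth labels.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: sequencing errors and quality scores,
isomiR-style heterogeneous dicing beyond uniform jitter, structure-biased
read coverage, repeat-rich genomes with pervasive multimapping, gapped or
mismatch-tolerant alignment, and thermodynamic folding subtleties. These
are exactly the places where production users should supply real
alignments (SAM) and real folds (RNAfold dot-bracket) through the
documented input paths.

## Numerical choices and degenerate inputs

* MAS ties: lexicographically smallest sequence, with a warning.
* Fold tie-breaks: 5'-most admissible partner.
* Modal-duplex ties in recovery: smallest window, then leftmost start.
* Degenerate duplexes (mature pairing only within itself) and absent
  matures are classed errors (`degenerate_duplex`, `mas_absent`) that
  validity reporting converts into reasons rather than crashes.
* Empty feature sets classify as intergenic; empty libraries give
  `no_libraries`; empty recovery input yields metrics reported as
  not-applicable rather than 0 or 1.
* All randomness (locality order, multimapper ties, scenario generation)
  flows from explicit seeds; reruns are bit-identical.

## Problem sizes used in the tests

The validity oracle comparison uses 500 random folded hairpins of
60–110 nt; recovery is benchmarked on 20 planted hairpins in a 100-kb
genome; parameter recovery uses 50 loci at 10,000 reads each; the
closest-feature oracle runs 1,000 randomized configurations including
forced distance ties; the tier truth table enumerates all 112 evidence
combinations. These sizes give the property checks enough resolution
(binomial standard errors well inside the asserted tolerances) while
keeping the default test run fast.

## Known limitations

* The built-in fold maximizes pairing, not free energy; marginal
  hairpins can fold differently under RNAfold, which is why external
  folds are the preferred production input.
* Exact-match alignment cannot place reads with sequencing errors or
  SNVs; supply pre-aligned SAM for real libraries.
* The recovery search assumes the mature matches its genome perfectly,
  as the original procedure did; cross-assembly recovery (a mature from
  one strain searched in another) may need relaxed matching upstream.
* Tier assignment treats evidence fields as categorical; it does not
  weight expression levels or conservation depth beyond the stated
  thresholds.
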