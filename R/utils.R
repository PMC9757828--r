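#' @useDynLib milrcurate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

# Classed error helper so callers can distinguish failure modes
# (e.g. mas_absent vs degenerate duplex) with tryCatch().
hp_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "milrcurate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Sequences are stored internally in the DNA alphabet (`ACGTN`), uppercase;
#' `U` is mapped to `T` at every input boundary so RNA-reported matures and
#' DNA genomes are directly comparable.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector, uppercase DNA alphabet.
#' @export
as_dna <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

#' Convert an internal DNA-alphabet sequence to RNA display form
#' @param x Character vector of DNA-alphabet sequences.
#' @return Character vector with `T` replaced by `U`.
#' @export
as_rna <- function(x) gsub("T", "U", toupper(as.character(x)), fixed = TRUE)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
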