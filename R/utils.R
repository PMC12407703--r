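#' @importFrom rlang .data
#' @importFrom methods as
#' @importFrom stats median p.adjust pnorm rbinom rnbinom rpois runif rnorm
#'   setNames var lm predict cor sd coef
#' @importFrom utils head write.table read.table
NULL

# Reverse complement for plain character vectors. NA propagates.
revcomp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

# Distinct k-mers of a single string (uppercased; windows containing a
# non-ACGT character are dropped: N never matches).
kmer_set <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (is.na(s) || n < k) return(character(0))
  km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  unique(km[!grepl("[^ACGT]", km)])
}

# +1/-1 nucleotide substitution matrix shared by the clip and guide aligners.
sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

# Local alignment returning the aligned strings (with "-" for gaps).
# Gap penalties follow the affine convention where a gap of length L costs
# gap_open + gap_extend * (L - 1), so a single-base gap costs `gap_open`.
align_local <- function(a, b, gap_open = 0.5, gap_extend = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = sub_matrix(),
    gapOpening = gap_open - gap_extend,
    gapExtension = gap_extend,
    type = "local"
  )
  list(
    pattern = as.character(Biostrings::alignedPattern(pa)),
    subject = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
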