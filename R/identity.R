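# Percent identity between protein sequences, shared by the tailoring
# cross-link and the known-cluster similarity score. The definition is
# pinned: a Needleman-Wunsch global alignment (BLOSUM62, gap opening 10,
# gap extension 0.5) and identity = identical columns / total alignment
# columns (gap columns included) * 100.

#' Global percent identity between two protein sequences
#'
#' @param a,b Amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Alignment length (columns) of the global alignment of two proteins
#' @param a,b Amino-acid strings.
#' @return Integer number of alignment columns.
#' @export
alignment_columns <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  nchar(as.character(Biostrings::alignedPattern(aln)))
}
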