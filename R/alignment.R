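# Global pairwise alignment of ortholog CDS pairs, percent identity, and the
# ortholog retention filters (reciprocal identity and dS/dN bounds).

#' Default alignment scoring parameters
#'
#' Mirrors the EMBOSS needle defaults for nucleotide sequences: match +5,
#' mismatch -4 (EDNAFULL diagonal), gap open 10, gap extend 0.5. A gap of
#' length L costs `gap_open + L * gap_extend`. End gaps are penalised
#' (true end-to-end global alignment).
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list of scoring parameters.
#' @export
align_scoring <- function(match = 5, mismatch = -4,
                          gap_open = 10, gap_extend = 0.5) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Global (Needleman-Wunsch) alignment of two nucleotide sequences
#'
#' End-to-end global alignment with affine gap penalties, computed with
#' Biostrings. The optimal score is unique even though the traceback may
#' not be; downstream statistics depend only on matched/mismatched columns.
#'
#' @param seq_a,seq_b Nucleotide strings (A/C/G/T/N).
#' @param scoring A list from [align_scoring()].
#' @return A `pairwise_alignment`: list with `id_a`, `id_b`, `aligned_a`,
#'   `aligned_b` (equal-length gapped strings) and `score`.
#' @export
global_align <- function(seq_a, seq_b, scoring = align_scoring()) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq_a),
    subject = Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  structure(list(
    id_a = NA_character_, id_b = NA_character_,
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment, score", format(x$score, digits = 6),
      "length", nchar(x$aligned_a), "\n")
  invisible(x)
}

#' Number of identically matching columns in a pairwise alignment
#' @keywords internal
#' @noRd
alignment_matches <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  sum(a == b & a != "-")
}

#' Reciprocal percent identity of an aligned ortholog pair
#'
#' Defined as the smaller of the two per-sequence identities,
#' `min(matches / length(seq_a), matches / length(seq_b)) * 100`, so a pair
#' is only as identical as its worse direction.
#'
#' @param aln A `pairwise_alignment`.
#' @return Percent identity in `[0, 100]`.
#' @export
reciprocal_identity <- function(aln) {
  m <- alignment_matches(aln)
  la <- nchar(gsub("-", "", aln$aligned_a))
  lb <- nchar(gsub("-", "", aln$aligned_b))
  min(m / la, m / lb) * 100
}

#' Percent identity over alignment columns, with the accession keep/drop rule
#'
#' Identity is matching columns divided by total alignment length (gapped
#' columns count against identity), times 100. Accession CDS reconstructions
#' whose identity to the reference falls below 75 are dropped; exactly 75
#' is kept (the rule drops strictly below threshold).
#'
#' @param reference_cds,accession_cds Nucleotide strings.
#' @param min_identity Drop threshold (percent), default 75.
#' @param scoring Alignment scoring, see [align_scoring()].
#' @return List with `identity` (percent) and `keep` (logical).
#' @export
check_accession_identity <- function(reference_cds, accession_cds,
                                     min_identity = 75,
                                     scoring = align_scoring()) {
  stopifnot(nchar(reference_cds) > 0, nchar(accession_cds) > 0)
  aln <- global_align(reference_cds, accession_cds, scoring)
  identity <- alignment_matches(aln) / nchar(aln$aligned_a) * 100
  list(identity = identity, keep = identity >= min_identity)
}

#' Ortholog pair retention filter
#'
#' Retains pairs with reciprocal identity at or above the identity threshold
#' and divergence estimates inside the stated bounds: `0.02 < dS < 2` and
#' `dN < 2`, all bounds strict. Pairs with undefined dS or dN are dropped.
#'
#' @param pairs A data.frame with columns `gene_id`, `reciprocal_identity`,
#'   `dS`, `dN` (e.g. from [divergence_table()] merged with identities).
#' @param min_identity Reciprocal identity threshold (percent), default 75.
#' @param ds_bounds Strict lower/upper bounds on dS, default `c(0.02, 2)`.
#' @param dn_max Strict upper bound on dN, default 2.
#' @return The retained subset of `pairs` (same columns).
#' @export
filter_orthologs <- function(pairs, min_identity = 75,
                             ds_bounds = c(0.02, 2), dn_max = 2) {
  keep <- !is.na(pairs$dS) & !is.na(pairs$dN) &
    pairs$reciprocal_identity >= min_identity &
    pairs$dS > ds_bounds[1] & pairs$dS < ds_bounds[2] &
    pairs$dN < dn_max
  pairs[keep, , drop = FALSE]
}
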