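#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment score between two protein sequences. A gap of
#' length L costs `gap_open + L * gap_extend` (the blastp convention, so the
#' defaults 11/1 with BLOSUM62 reproduce its scoring scheme). One optimal
#' alignment is reported; ties between equally scoring end cells are broken
#' towards the smallest query end, then the smallest subject end. Spans are
#' 1-based closed intervals; a score of 0 has empty spans.
#'
#' Used by the leakage filter ([find_similar_proteins()]) to flag database
#' proteins sharing a region of high similarity with a query peptide.
#'
#' @param q,p Protein records (or `list(id=, sequence=)`).
#' @param matrix A [substitution_matrix][sub_matrix]; default BLOSUM62.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A list of class `local_alignment`: `score` (integer, >= 0),
#'   `q_span` and `p_span` (integer length-2 closed intervals, `c(0, 0)`
#'   when empty), and `identity` (fraction of aligned columns with equal
#'   residues, `NA` for empty alignments).
#' @examples
#' pep <- protein_record("q", "PEPTIDE")
#' smith_waterman(pep, pep)$score  # 39 under BLOSUM62
#' @export
smith_waterman <- function(q, p, matrix = sub_matrix("BLOSUM62"),
                           gap_open = 11L, gap_extend = 1L) {
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive")
  q <- as_protein(q); p <- as_protein(p)
  if (!nzchar(q$sequence) || !nzchar(p$sequence))
    stop("sequences must be non-empty")
  r <- cpp_smith_waterman(encode_seq(q$sequence, matrix),
                          encode_seq(p$sequence, matrix),
                          matrix, as.integer(gap_open),
                          as.integer(gap_extend))
  structure(list(
    score = r$score,
    q_span = if (r$score > 0) c(r$q_start + 1L, r$q_end) else c(0L, 0L),
    p_span = if (r$score > 0) c(r$p_start + 1L, r$p_end) else c(0L, 0L),
    identity = r$identity
  ), class = "local_alignment")
}
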