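# Pairwise alignment front ends over the C++ affine-gap engine.

ALN_MODE <- c(local = 0L, global = 1L, overlap = 2L)

#' Optimal local protein alignment
#'
#' Exact Smith-Waterman alignment under BLOSUM62 with affine gaps
#' (defaults are the BLASTP defaults: open 11, extend 1; a length-L gap
#' costs `open + extend * L`). Percent identity uses the BLAST convention:
#' identical pairs over aligned columns *including* internal gaps.
#'
#' @param seq_a,seq_b Amino-acid sequences (20 residues plus `X`).
#' @param matrix Substitution matrix name (only `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return List of class `AlignmentResult`: `score`, `pct_identity`,
#'   `aln_len` (aligned columns), `qcov`, `scov` (aligned residues of each
#'   sequence over its full length), plus 1-based aligned span coordinates.
#' @export
local_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  sub <- aa_submatrix(matrix)
  enc <- encode_aa(c(seq_a, seq_b))
  st <- cpp_align_path(enc[[1]], enc[[2]], sub, gap_open, gap_extend, ALN_MODE[["local"]])
  structure(list(
    score = st$score,
    pct_identity = if (st$cols > 0) 100 * st$matches / st$cols else 0,
    aln_len = st$cols,
    qcov = st$q_res / nchar(seq_a),
    scov = st$s_res / nchar(seq_b),
    q_start = st$q_start, q_end = st$q_end,
    s_start = st$s_start, s_end = st$s_end
  ), class = "AlignmentResult")
}

#' Pairwise 16S rRNA identity
#'
#' Global end-gap-free (overlap) nucleotide alignment; identity is
#' `100 * matches / aligned columns`, terminal-gap columns excluded.
#' Sequences shorter than `min_len` trigger a warning (partial gene) but are
#' still compared.
#'
#' @param seq16s_a,seq16s_b Nucleotide sequences.
#' @param min_len Full-length threshold (default 500 nt).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return Percent identity in `[0, 100]`.
#' @export
rrna_identity <- function(seq16s_a, seq16s_b, min_len = 500,
                          match = 5, mismatch = -4,
                          gap_open = 10, gap_extend = 0.5) {
  if (nchar(seq16s_a) < min_len || nchar(seq16s_b) < min_len) {
    warning("16S sequence shorter than ", min_len,
            " nt: identity computed on a partial gene")
  }
  enc <- encode_dna(c(seq16s_a, seq16s_b))
  st <- cpp_align_path(enc[[1]], enc[[2]], dna_submatrix(match, mismatch),
                       gap_open, gap_extend, ALN_MODE[["overlap"]])
  if (st$cols == 0) return(0)
  100 * st$matches / st$cols
}

#' Square 16S identity matrix over a set of sequences
#'
#' @param seqs Named character vector of 16S sequences.
#' @param ... Passed to [rrna_identity()].
#' @return Symmetric matrix of percent identities (diagonal 100).
#' @export
rrna_identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- rrna_identity(seqs[[i]], seqs[[j]], ...)
    }
  }
  m
}
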