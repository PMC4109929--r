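# Sequence encoding and substitution matrices shared by the alignment engine.
#
# Sequences are encoded as 0-based integer vectors indexing the rows of the
# substitution matrix handed to the C++ DP routines.

AA_ALPHABET_20X <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                     "P","S","T","W","Y","V","X")
DNA_ALPHABET_ACGTN <- c("A","C","G","T","N")

#' @noRd
aa_submatrix <- function(name = "BLOSUM62") {
  if (!identical(name, "BLOSUM62")) {
    stop("unsupported substitution matrix: ", name, " (supported: BLOSUM62)")
  }
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET_20X, AA_ALPHABET_20X]
  storage.mode(m) <- "double"
  m
}

# match/mismatch scoring for rRNA identity; N scores 0 against everything
#' @noRd
dna_submatrix <- function(match = 5, mismatch = -4) {
  n <- length(DNA_ALPHABET_ACGTN)
  m <- matrix(mismatch, n, n, dimnames = list(DNA_ALPHABET_ACGTN, DNA_ALPHABET_ACGTN))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' @noRd
encode_seqs <- function(seqs, alphabet, what = "sequence") {
  codes <- integer(128)
  codes[] <- NA_integer_
  codes[utf8ToInt(paste(alphabet, collapse = ""))] <- seq_along(alphabet) - 1L
  codes[utf8ToInt(tolower(paste(alphabet, collapse = "")))] <- seq_along(alphabet) - 1L
  lapply(seqs, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty ", what, " cannot be aligned")
    v <- utf8ToInt(s)
    if (any(v > 127L)) stop("non-ASCII symbol in ", what)
    enc <- codes[v]
    if (anyNA(enc)) {
      bad <- unique(intToUtf8(v[is.na(enc)], multiple = TRUE))
      stop("invalid symbol(s) in ", what, ": ", paste(bad, collapse = ", "))
    }
    enc
  })
}

#' @noRd
encode_aa <- function(seqs) encode_seqs(seqs, AA_ALPHABET_20X, "protein sequence")

# DNA encoding maps IUPAC ambiguity codes to N
#' @noRd
encode_dna <- function(seqs) {
  cleaned <- chartr("RYSWKMBDHVryswkmbdhv", strrep("N", 20), seqs)
  encode_seqs(cleaned, DNA_ALPHABET_ACGTN, "nucleotide sequence")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
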