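# Progressive multiple alignment (the in-repo stand-in for MUSCLE) and
# concatenation of per-group alignments into a partitioned super-alignment.

#' Progressively align a group of protein sequences
#'
#' Pairs are aligned by exact global affine-gap DP; larger groups follow a
#' neighbor-joining guide tree built from 3-mer count distances, merging
#' profiles with BLOSUM62 sum-of-pairs scores. Fully deterministic.
#'
#' @param seqs Named character vector of protein sequences.
#' @param matrix,gap_open,gap_extend Scoring parameters.
#' @return Object of class `MSA`: named character vector of equal-length
#'   gapped rows; ungapping any row reproduces its input exactly.
#' @export
align_group <- function(seqs, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must be uniquely named")
  }
  seqs <- toupper(seqs)
  sub <- aa_submatrix(matrix)
  n <- length(seqs)
  if (n == 1L) return(as_msa(matrix(strsplit(seqs, "")[[1]], nrow = 1,
                                    dimnames = list(names(seqs), NULL))))
  if (n == 2L) {
    m <- align_two(seqs[1], seqs[2], names(seqs), sub, gap_open, gap_extend)
    return(as_msa(m))
  }
  dm <- kmer_distance_matrix(seqs, k = 3L)
  guide <- neighbor_joining(dm)
  guide <- ape::root(guide, outgroup = names(seqs)[1], resolve.root = TRUE)
  merged <- align_node(guide, length(guide$tip.label) + 1L, seqs, sub,
                       gap_open, gap_extend)
  as_msa(merged[names(seqs), , drop = FALSE])
}

#' @noRd
as_msa <- function(m) {
  rows <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  structure(rows, ncols = ncol(m), class = "MSA")
}

#' @export
print.MSA <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x), attr(x, "ncols")))
  invisible(x)
}

#' @noRd
align_two <- function(a, b, ids, sub, gap_open, gap_extend) {
  enc <- encode_aa(c(a, b))
  p <- cpp_align_path(enc[[1]], enc[[2]], sub, gap_open, gap_extend, ALN_MODE[["global"]])
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  m <- rbind(ifelse(is.na(p$path_a), "-", ca[p$path_a]),
             ifelse(is.na(p$path_b), "-", cb[p$path_b]))
  rownames(m) <- ids
  m
}

# recursive profile merge along the rooted guide tree
#' @noRd
align_node <- function(tree, node, seqs, sub, gap_open, gap_extend) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    id <- tree$tip.label[node]
    return(matrix(strsplit(seqs[[id]], "")[[1]], nrow = 1, dimnames = list(id, NULL)))
  }
  children <- tree$edge[tree$edge[, 1] == node, 2]
  mats <- lapply(children, align_node, tree = tree, seqs = seqs, sub = sub,
                 gap_open = gap_open, gap_extend = gap_extend)
  out <- mats[[1]]
  for (k in seq_along(mats)[-1]) {
    out <- merge_profiles(out, mats[[k]], sub, gap_open, gap_extend)
  }
  out
}

#' @noRd
profile_counts <- function(m) {
  alph <- AA_ALPHABET_20X
  counts <- matrix(0, length(alph), ncol(m), dimnames = list(alph, NULL))
  for (a in alph) counts[a, ] <- colSums(m == a)
  counts
}

#' @noRd
merge_profiles <- function(A, B, sub, gap_open, gap_extend) {
  pA <- profile_counts(A)
  pB <- profile_counts(B)
  S <- crossprod(pA, sub %*% pB) / (nrow(A) * nrow(B))
  steps <- cpp_profile_path(S, gap_open, gap_extend)
  ncols <- length(steps)
  out <- matrix("-", nrow(A) + nrow(B), ncols,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ia <- cumsum(steps != 3L) # A column consumed on steps 1, 2
  ib <- cumsum(steps != 2L)
  useA <- steps != 3L
  useB <- steps != 2L
  out[seq_len(nrow(A)), useA] <- A[, ia[useA], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), useB] <- B[, ib[useB], drop = FALSE]
  out
}

# fractional-common-k-mer distance used for the MSA guide tree
#' @noRd
kmer_distance_matrix <- function(seqs, k = 3L) {
  km <- seq_kmers(seqs, k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- length(intersect(km[[i]], km[[j]]))
      denom <- max(1L, min(length(km[[i]]), length(km[[j]])))
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

#' Concatenate per-group alignments into a partitioned super-alignment
#'
#' @param msas Named list of `MSA` objects (names = group ids); each must
#'   contain exactly one row per genome after mapping loci to genomes.
#' @param genome_of_locus Named character vector `locus_tag -> genome_id`.
#' @return Object of class `ConcatenatedAlignment`: `rows` (named by
#'   genome), `partitions` (`group_id`, `start`, `end` 0-based half-open)
#'   and `ncols`. Groups are joined in sorted group-id order.
#' @export
concatenate_msas <- function(msas, genome_of_locus) {
  if (is.null(names(msas))) stop("msas must be named by group id")
  msas <- msas[order(names(msas))]
  genomes <- sort(unique(genome_of_locus))
  pieces <- lapply(names(msas), function(gid) {
    m <- msas[[gid]]
    gmap <- genome_of_locus[names(m)]
    if (anyNA(gmap)) stop("group ", gid, ": locus without genome mapping")
    if (!setequal(gmap, genomes) || anyDuplicated(gmap)) {
      stop("group ", gid, ": must have exactly one sequence per genome")
    }
    setNames(unclass(m), gmap)[genomes]
  })
  widths <- vapply(pieces, function(p) nchar(p[[1]]), integer(1))
  ends <- cumsum(widths)
  rows <- setNames(do.call(paste0, pieces), genomes)
  structure(list(
    rows = rows,
    partitions = data.frame(group_id = names(msas),
                            start = ends - widths, end = ends,
                            stringsAsFactors = FALSE),
    ncols = sum(widths)
  ), class = "ConcatenatedAlignment")
}

#' @export
print.ConcatenatedAlignment <- function(x, ...) {
  cat(sprintf("ConcatenatedAlignment: %d genomes x %d columns, %d partitions\n",
              length(x$rows), x$ncols, nrow(x$partitions)))
  invisible(x)
}
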