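# Distance-based phylogeny: pairwise distances from a concatenated
# alignment, an in-repo neighbor-joining implementation with deterministic
# tie-breaking, and nonparametric bootstrap support by column resampling.

#' Pairwise distances from an alignment
#'
#' Distances are computed over columns where both rows are non-gap.
#' `p_distance` is the differing-column fraction; `poisson_corrected`
#' applies `-ln(1 - p)` (capped, with a warning, when `p >= 1`).
#'
#' @param alignment `ConcatenatedAlignment`, `MSA`, or a named character
#'   vector of equal-length gapped rows.
#' @param model `"p_distance"` or `"poisson_corrected"`.
#' @param max_dist Cap applied when the correction diverges.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, model = c("p_distance", "poisson_corrected"),
                            max_dist = 10) {
  model <- match.arg(model)
  rows <- alignment_rows(alignment)
  if (length(rows) < 2) stop("need >= 2 aligned rows")
  M <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(M) <- names(rows)
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(ok)) stop("rows ", names(rows)[i], " and ", names(rows)[j],
                         " share no aligned columns")
      p <- mean(M[i, ok] != M[j, ok])
      if (model == "poisson_corrected") {
        if (p >= 1) {
          warning("saturated distance (p >= 1) capped at ", max_dist)
          p <- NA
          d[i, j] <- d[j, i] <- max_dist
        } else {
          d[i, j] <- d[j, i] <- min(-log(1 - p), max_dist)
        }
      } else {
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  d
}

#' @noRd
alignment_rows <- function(alignment) {
  if (inherits(alignment, "ConcatenatedAlignment")) return(alignment$rows)
  if (inherits(alignment, "MSA")) return(unclass(alignment))
  if (is.character(alignment) && !is.null(names(alignment))) return(alignment)
  stop("unsupported alignment object")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration with deterministic tie-breaking (lowest active
#' index pair on equal Q). Negative branch lengths are clamped to zero with
#' the deficit moved to the sibling edge, preserving the joined pair's
#' distance. On additive matrices the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param dm Symmetric distance matrix with zero diagonal, `n >= 3`.
#' @return Unrooted `phylo` tree (trifurcating root node).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs >= 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(dm)
  # active node subtree representations as (newick_fragment) strings
  frag <- labels
  D <- dm
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    bi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- Dm[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[ai], fmt(bi), frag[aj], fmt(bj))
    # distances from the new node u to every other active node
    others <- active[-c(i, j)]
    du <- 0.5 * (D[ai, others] + D[aj, others] - D[ai, aj])
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, others] <- du
    D[others, u] <- du
    frag <- c(frag, new_frag)
    active <- c(others, u)
  }
  a <- active
  b1 <- (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]]) / 2
  b2 <- (D[a[1], a[2]] + D[a[2], a[3]] - D[a[1], a[3]]) / 2
  b3 <- (D[a[1], a[3]] + D[a[2], a[3]] - D[a[1], a[2]]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[a[1]], fmt(b1), frag[a[2]], fmt(b2), frag[a[3]], fmt(b3))
  ape::read.tree(text = nwk)
}

# canonical non-trivial splits of an unrooted tree: each split is the sorted
# tip subset NOT containing the alphabetically first tip, joined by "|"
#' @noRd
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  tr <- ape::root(tree, outgroup = ref, resolve.root = TRUE)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (s in pp) {
    side <- labs[s]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Bootstrap support for a concatenated-alignment NJ tree
#'
#' Columns are resampled with replacement (per replicate, across the whole
#' alignment, matching standard column-bootstrap behaviour), the tree is
#' rebuilt, and each internal split of the full-data tree is scored by the
#' percentage of replicates containing it.
#'
#' @param concat `ConcatenatedAlignment` (or named gapped rows).
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed; replicate `r` uses stream seed `seed + r`.
#' @param model Distance model passed to [distance_matrix()].
#' @return List: `tree` (full-data NJ `phylo` with internal `node.label`
#'   supports), `supports` (named vector, split -> percent).
#' @export
bootstrap_support <- function(concat, n_reps = 100, seed = 1,
                              model = "poisson_corrected") {
  rows <- alignment_rows(concat)
  M <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(M) <- names(rows)
  full <- neighbor_joining(dist_from_charmat(M, model))
  full_splits <- tree_splits(full)
  counts <- setNames(numeric(length(full_splits)), full_splits)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    idx <- sample.int(ncol(M), ncol(M), replace = TRUE)
    rep_tree <- neighbor_joining(dist_from_charmat(M[, idx, drop = FALSE], model))
    hit <- full_splits %in% tree_splits(rep_tree)
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_reps
  list(tree = annotate_supports(full, supports), supports = supports)
}

#' @noRd
dist_from_charmat <- function(M, model) {
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- M[i, ] != "-" & M[j, ] != "-"
      p <- mean(M[i, ok] != M[j, ok])
      d[i, j] <- d[j, i] <- if (model == "poisson_corrected") {
        if (p >= 1) 10 else -log(1 - p)
      } else p
    }
  }
  d
}

# write supports into node labels of the (arbitrarily rooted) full tree
#' @noRd
annotate_supports <- function(tree, supports) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  tr <- ape::root(tree, outgroup = ref, resolve.root = TRUE)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  node_lab <- character(tr$Nnode)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports)) node_lab[k] <- sprintf("%g", supports[[key]])
  }
  tr$node.label <- node_lab
  tr
}
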