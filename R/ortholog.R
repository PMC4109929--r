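# Ortholog grouping across genomes: connected components of the thresholded
# cross-genome RBH graph (a deterministic, inflation-free stand-in for Markov
# clustering on a BLAST graph), and the single-copy subset used for the
# concatenated phylogeny.
#
# Strict reciprocal-best edges alone can never place two paralogs from the
# same genome in one group, so recent duplicates are attached through
# in-paralog edges: a within-genome pair passing the same thresholds whose
# score is at least as high as either member's best cross-genome RBH score.

#' Build ortholog groups across a set of proteomes
#'
#' Edges are RBH pairs between every genome pair meeting the identity and
#' coverage thresholds (single-copy-ortholog defaults: 50% identity over
#' 70% of both protein lengths), plus within-genome in-paralog edges for
#' recent duplicates (see the source header); groups are the connected
#' components. Group ids are assigned deterministically from the sorted
#' member lists.
#'
#' @param proteomes List of `Proteome` objects (>= 2).
#' @param min_identity,min_cov RBH thresholds.
#' @param ... Passed to [reciprocal_best_hits()].
#' @return List of `OrthologGroup` objects: `group_id`,
#'   `members` (named list `genome_id -> locus_tags`), `single_copy`
#'   (exactly one member in every input genome). Attribute `genome_ids`
#'   records the input genome set.
#' @export
build_ortholog_groups <- function(proteomes, min_identity = 50, min_cov = 0.70, ...) {
  if (length(proteomes) < 2) stop("need >= 2 proteomes")
  ids <- vapply(proteomes, function(p) p$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids among proteomes")
  names(proteomes) <- ids
  ord <- order(ids)
  vertices <- unlist(lapply(proteomes, function(p) {
    paste0(p$genome_id, "\r", names(p$entries))
  }), use.names = FALSE)
  edges <- list()
  cross_best <- setNames(numeric(length(vertices)), vertices)
  for (i in seq_along(ord)[-length(ord)]) {
    for (j in seq(i + 1, length(ord))) {
      pa <- proteomes[[ord[i]]]
      pb <- proteomes[[ord[j]]]
      rbh <- reciprocal_best_hits(pa, pb, min_identity = min_identity,
                                  min_cov = min_cov, ...)
      if (nrow(rbh)) {
        va <- paste0(pa$genome_id, "\r", rbh$locus_a)
        vb <- paste0(pb$genome_id, "\r", rbh$locus_b)
        edges[[length(edges) + 1L]] <- data.frame(from = va, to = vb,
                                                  stringsAsFactors = FALSE)
        cross_best[va] <- pmax(cross_best[va], rbh$score)
        cross_best[vb] <- pmax(cross_best[vb], rbh$score)
      }
    }
  }
  for (p in proteomes) {
    pe <- in_paralog_edges(p, cross_best, min_identity = min_identity,
                           min_cov = min_cov, ...)
    if (nrow(pe)) edges[[length(edges) + 1L]] <- pe
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges) else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = vertices))
  comp <- igraph::components(g)
  members_by_comp <- split(vertices, comp$membership[vertices])
  keys <- vapply(members_by_comp, function(v) paste(sort(v), collapse = ";"), character(1))
  members_by_comp <- members_by_comp[order(keys)]
  groups <- lapply(seq_along(members_by_comp), function(gi) {
    v <- sort(members_by_comp[[gi]])
    parts <- strsplit(v, "\r", fixed = TRUE)
    gmem <- split(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
    structure(list(
      group_id = sprintf("g%05d", gi),
      members = gmem,
      single_copy = length(gmem) == length(ids) && all(lengths(gmem) == 1L)
    ), class = "OrthologGroup")
  })
  attr(groups, "genome_ids") <- sort(ids)
  groups
}

#' @noRd
in_paralog_edges <- function(proteome, cross_best, min_identity = 50,
                             min_cov = 0.70, prefilter = c("auto", "none", "kmer"),
                             k = 5L, min_shared = 2L, exhaustive_max = 40L,
                             matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  prefilter <- match.arg(prefilter)
  a <- proteome$entries
  empty <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  if (length(a) < 2) return(empty)
  cand <- if (prefilter == "none" ||
              (prefilter == "auto" && length(a) <= exhaustive_max)) {
    data.frame(ia = rep(seq_along(a), each = length(a)),
               ib = rep(seq_along(a), times = length(a)))
  } else {
    kmer_candidates(a, a, k = k, min_shared = min_shared)
  }
  cand <- cand[cand$ia < cand$ib, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  ea <- encode_aa(unname(a))
  st <- cpp_align_stats(ea[cand$ia], ea[cand$ib], aa_submatrix(matrix),
                        gap_open, gap_extend, 0L)
  vx <- paste0(proteome$genome_id, "\r", names(a)[cand$ia])
  vy <- paste0(proteome$genome_id, "\r", names(a)[cand$ib])
  identity <- ifelse(st[, "cols"] > 0, 100 * st[, "matches"] / st[, "cols"], 0)
  cov <- pmin(st[, "q_res"] / nchar(a)[cand$ia], st[, "s_res"] / nchar(a)[cand$ib])
  keep <- identity >= min_identity & cov >= min_cov &
    st[, "score"] >= pmax(cross_best[vx], cross_best[vy], 1)
  data.frame(from = vx[keep], to = vy[keep], stringsAsFactors = FALSE)
}

#' Select single-copy-per-genome ortholog groups (SCGO)
#'
#' @param groups Output of [build_ortholog_groups()].
#' @param genome_set Genome ids that must each contribute exactly one member
#'   (default: the set the groups were built over).
#' @return The single-copy groups; errors if none qualify (no tree can be
#'   built from an empty set).
#' @export
select_scgo <- function(groups, genome_set = attr(groups, "genome_ids")) {
  keep <- vapply(groups, function(g) {
    all(genome_set %in% names(g$members)) &&
      all(lengths(g$members[genome_set]) == 1L) &&
      length(g$members) == length(genome_set)
  }, logical(1))
  if (!any(keep)) stop("no single-copy ortholog groups across the genome set")
  out <- groups[keep]
  attr(out, "genome_ids") <- sort(genome_set)
  out
}

#' Tabulate ortholog groups
#'
#' @param groups List of `OrthologGroup` objects.
#' @return `data.frame` with one row per (group, genome, locus).
#' @export
ortholog_group_table <- function(groups) {
  do.call(rbind, lapply(groups, function(g) {
    data.frame(group_id = g$group_id,
               genome_id = rep(names(g$members), lengths(g$members)),
               locus_tag = unlist(g$members, use.names = FALSE),
               single_copy = g$single_copy,
               stringsAsFactors = FALSE)
  }))
}
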