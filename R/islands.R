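# Genomic-island and recombination hot-spot detection between two closely
# related genomes. The manual procedure (unique-gene clusters at synteny
# breaks, GC deviation from the genome average, tRNA integration sites,
# internal site-specific recombinases) is formalized as: a unique-gene
# segment is an island when corroborated by GC deviation OR an integration
# signature; thresholds live in island_config().

#' Island-caller configuration
#'
#' @param window,step GC sliding-window width and step (nt).
#' @param z_min Minimum absolute window GC z-score to count as deviant.
#' @param min_island_genes Minimum genes in a unique segment.
#' @param flank_dist Maximum distance (nt) from an island boundary to a
#'   flanking tRNA.
#' @param recombinase_keywords Case-insensitive product keywords marking
#'   integration machinery.
#' @param anchor_tol Synteny-block collinearity tolerance (allowed rank_b
#'   skip within a block).
#' @param require_evidence If `TRUE` (default) a unique segment is reported
#'   only with corroborating evidence (`|gc_z| >= z_min` OR tRNA flank OR
#'   recombinase); if `FALSE` every unique segment is reported.
#' @return Named list of parameters.
#' @export
island_config <- function(window = 5000L, step = 1000L, z_min = 2.0,
                          min_island_genes = 3L, flank_dist = 2000L,
                          recombinase_keywords = c("recombinase", "integrase",
                                                   "transposase", "phage"),
                          anchor_tol = 2L, require_evidence = TRUE) {
  list(window = window, step = step, z_min = z_min,
       min_island_genes = min_island_genes, flank_dist = flank_dist,
       recombinase_keywords = recombinase_keywords,
       anchor_tol = anchor_tol, require_evidence = require_evidence)
}

#' Sliding-window GC profile of a genome
#'
#' Windows tile each contig (`window` wide, every `step`; contigs shorter
#' than `window` get one full-contig window). The z-score compares each
#' window to the mean GC of the genome and the standard deviation of all of
#' the genome's windows; a zero-variance genome yields z = 0 everywhere.
#'
#' @param genome A `GenomeRecord`.
#' @param window,step Window width and step in nt.
#' @return `data.frame`: `contig_id`, `start`, `end` (0-based half-open),
#'   `gc`, `z`.
#' @export
gc_profile <- function(genome, window = 5000L, step = 1000L) {
  per_contig <- lapply(names(genome$contigs), function(cid) {
    seq <- genome$contigs[[cid]]
    len <- nchar(seq)
    starts <- if (len <= window) 0L else seq.int(0L, len - window, by = step)
    ends <- pmin(starts + window, len)
    x <- Biostrings::DNAString(seq)
    v <- Biostrings::Views(x, start = starts + 1L, end = ends)
    counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(counts)
    gc <- ifelse(denom > 0, (counts[, "C"] + counts[, "G"]) / denom, NaN)
    data.frame(contig_id = cid, start = starts, end = ends, gc = gc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_contig)
  s <- stats::sd(out$gc)
  out$z <- if (is.na(s) || s == 0) 0 else (out$gc - genome$mean_gc) / s
  rownames(out) <- NULL
  out
}

# CDS of a genome with per-contig gene-order rank and RBH partner flag
#' @noRd
cds_table <- function(genome, rbh_self_col, rbh) {
  f <- genome$features[genome$features$ftype == "CDS", , drop = FALSE]
  f <- f[order(match(f$contig_id, names(genome$contigs)), f$start), , drop = FALSE]
  f$cds_rank <- stats::ave(seq_len(nrow(f)), f$contig_id, FUN = seq_along)
  idx <- match(f$locus_tag, rbh[[rbh_self_col]])
  other <- if (rbh_self_col == "locus_a") "locus_b" else "locus_a"
  f$partner <- rbh[[other]][idx]
  f
}

#' Synteny map between two genomes
#'
#' Anchors are the RBH pairs ordered by gene rank in genome A; blocks are
#' maximal runs collinear in both genomes (consistent direction, rank_b
#' steps of at most `1 + tol`); breaks are block boundaries.
#'
#' @param genome_a,genome_b `GenomeRecord`s.
#' @param rbh RBH table oriented A -> B (see [reciprocal_best_hits()]).
#' @param tol Allowed rank_b skip within a block.
#' @return List of class `SyntenyMap`: `anchors` (`data.frame` with
#'   `locus_a`, `locus_b`, `rank_a`, `rank_b`, contigs, `block`),
#'   `n_blocks`, `n_breaks`.
#' @export
synteny_map <- function(genome_a, genome_b, rbh, tol = 2L) {
  fa <- cds_table(genome_a, "locus_a", rbh)
  fb <- cds_table(genome_b, "locus_b", rbh)
  anchors <- fa[!is.na(fa$partner),
                c("locus_tag", "contig_id", "cds_rank", "partner")]
  names(anchors) <- c("locus_a", "contig_a", "rank_a", "locus_b")
  bi <- match(anchors$locus_b, fb$locus_tag)
  anchors$contig_b <- fb$contig_id[bi]
  anchors$rank_b <- fb$cds_rank[bi]
  anchors <- anchors[order(match(anchors$contig_a, names(genome_a$contigs)),
                           anchors$rank_a), , drop = FALSE]
  n <- nrow(anchors)
  block <- integer(n)
  if (n) {
    block[1] <- 1L
    dir <- 0L
    for (i in seq_len(n)[-1]) {
      same <- anchors$contig_a[i] == anchors$contig_a[i - 1] &&
              anchors$contig_b[i] == anchors$contig_b[i - 1]
      delta <- anchors$rank_b[i] - anchors$rank_b[i - 1]
      ok <- same && abs(delta) >= 1 && abs(delta) <= 1 + tol &&
            (dir == 0L || sign(delta) == dir)
      if (ok) {
        block[i] <- block[i - 1]
        dir <- sign(delta)
      } else {
        block[i] <- block[i - 1] + 1L
        dir <- 0L
      }
    }
  }
  anchors$block <- block
  rownames(anchors) <- NULL
  structure(list(anchors = anchors,
                 n_blocks = if (n) max(block) else 0L,
                 n_breaks = if (n) max(block) - 1L else 0L),
            class = "SyntenyMap")
}

#' @export
print.SyntenyMap <- function(x, ...) {
  cat(sprintf("SyntenyMap: %d anchors, %d blocks, %d breaks\n",
              nrow(x$anchors), x$n_blocks, x$n_breaks))
  invisible(x)
}

#' Maximal runs of genes unique to genome A
#'
#' Consecutive CDS (by gene order; interspersed tRNA/rRNA do not break a
#' run) with no RBH partner in genome B, at least `min_island_genes` long.
#'
#' @param genome_a,genome_b `GenomeRecord`s.
#' @param rbh RBH table oriented A -> B.
#' @param min_island_genes Minimum run length in genes.
#' @return `data.frame`: `segment_id`, `contig_id`, `start`, `end` (nt,
#'   0-based half-open over the gene run), `n_genes`, `loci`
#'   (comma-separated), `first_rank`, `last_rank` (CDS ranks).
#' @export
unique_segments <- function(genome_a, genome_b, rbh, min_island_genes = 3L) {
  fa <- cds_table(genome_a, "locus_a", rbh)
  out <- list()
  for (cid in unique(fa$contig_id)) {
    fc <- fa[fa$contig_id == cid, , drop = FALSE]
    unq <- is.na(fc$partner)
    r <- rle(unq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_island_genes)) {
      run <- fc[starts[k]:ends[k], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig_id = cid,
        start = min(run$start), end = max(run$end),
        n_genes = nrow(run),
        loci = paste(run$locus_tag, collapse = ","),
        first_rank = min(run$cds_rank), last_rank = max(run$cds_rank),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(segment_id = character(), contig_id = character(),
                      start = integer(), end = integer(), n_genes = integer(),
                      loci = character(), first_rank = integer(),
                      last_rank = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$contig_id, names(genome_a$contigs)), res$start), ,
             drop = FALSE]
  res <- cbind(segment_id = sprintf("%s_seg%03d", genome_a$genome_id,
                                    seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Call genomic islands in genome A relative to genome B
#'
#' Each unique-gene segment is annotated with its GC z-score (mean z of
#' profile windows inside its span), tRNA flanking status, recombinase
#' content, and the syntenic gap hosting it (canonical id of the flanking
#' anchor pairs; `EDGE` marks a missing side at a contig end). Under the
#' default evidence rule a segment is reported when at least one
#' corroborating signal is present.
#'
#' @param genome_a,genome_b `GenomeRecord`s.
#' @param rbh RBH table oriented A -> B.
#' @param gc_windows Optional precomputed [gc_profile()] of genome A.
#' @param config [island_config()].
#' @return BED-like `data.frame`: `island_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `n_genes`, `loci`, `mean_gc`, `gc_z`, `trna_flank`
#'   (`left`/`right`/`both`/`none`), `has_recombinase`, `anchor_id`.
#' @export
call_islands <- function(genome_a, genome_b, rbh, gc_windows = NULL,
                         config = island_config()) {
  segs <- unique_segments(genome_a, genome_b, rbh,
                          min_island_genes = config$min_island_genes)
  cols <- c("island_id", "genome_id", "contig_id", "start", "end", "n_genes",
            "loci", "mean_gc", "gc_z", "trna_flank", "has_recombinase",
            "anchor_id")
  if (!nrow(segs)) {
    out <- data.frame(island_id = character(), genome_id = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), n_genes = integer(), loci = character(),
                      mean_gc = numeric(), gc_z = numeric(),
                      trna_flank = character(), has_recombinase = logical(),
                      anchor_id = character(), stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(gc_windows)) {
    gc_windows <- gc_profile(genome_a, window = config$window, step = config$step)
  }
  fa <- cds_table(genome_a, "locus_a", rbh)
  trna <- genome_a$features[genome_a$features$ftype == "tRNA", , drop = FALSE]
  rkw <- paste(config$recombinase_keywords, collapse = "|")
  prod_of <- setNames(genome_a$features$product, genome_a$features$locus_tag)

  segs$genome_id <- genome_a$genome_id
  segs$mean_gc <- vapply(seq_len(nrow(segs)), function(i) {
    gc_fraction(substr(genome_a$contigs[[segs$contig_id[i]]],
                       segs$start[i] + 1L, segs$end[i]))
  }, numeric(1))
  segs$gc_z <- vapply(seq_len(nrow(segs)), function(i) {
    w <- gc_windows[gc_windows$contig_id == segs$contig_id[i], , drop = FALSE]
    inside <- w$start >= segs$start[i] & w$end <= segs$end[i]
    if (!any(inside)) inside <- w$end > segs$start[i] & w$start < segs$end[i]
    if (!any(inside)) return(0)
    mean(w$z[inside])
  }, numeric(1))
  segs$trna_flank <- vapply(seq_len(nrow(segs)), function(i) {
    tc <- trna[trna$contig_id == segs$contig_id[i], , drop = FALSE]
    if (!nrow(tc)) return("none")
    left <- any(tc$start < segs$start[i] &
                  segs$start[i] - tc$end <= config$flank_dist)
    right <- any(tc$end > segs$end[i] &
                   tc$start - segs$end[i] <= config$flank_dist)
    if (left && right) "both" else if (left) "left" else if (right) "right" else "none"
  }, character(1))
  segs$has_recombinase <- vapply(strsplit(segs$loci, ","), function(loci) {
    any(grepl(rkw, prod_of[loci], ignore.case = TRUE))
  }, logical(1))
  segs$anchor_id <- vapply(seq_len(nrow(segs)), function(i) {
    fc <- fa[fa$contig_id == segs$contig_id[i], , drop = FALSE]
    prev <- fc[fc$cds_rank < segs$first_rank[i] & !is.na(fc$partner), , drop = FALSE]
    nxt <- fc[fc$cds_rank > segs$last_rank[i] & !is.na(fc$partner), , drop = FALSE]
    pid <- function(row) paste(sort(c(row$locus_tag, row$partner)), collapse = "=")
    left <- if (nrow(prev)) pid(prev[which.max(prev$cds_rank), ]) else "EDGE"
    right <- if (nrow(nxt)) pid(nxt[which.min(nxt$cds_rank), ]) else "EDGE"
    paste(sort(c(left, right)), collapse = "~")
  }, character(1))

  keep <- if (config$require_evidence) {
    abs(segs$gc_z) >= config$z_min | segs$trna_flank != "none" | segs$has_recombinase
  } else rep(TRUE, nrow(segs))
  segs <- segs[keep, , drop = FALSE]
  if (nrow(segs)) {
    segs$island_id <- sprintf("%s_isl%03d", genome_a$genome_id, seq_len(nrow(segs)))
  } else {
    segs$island_id <- character(0)
  }
  rownames(segs) <- NULL
  segs[, cols]
}

#' Swap an RBH table's orientation
#'
#' @param rbh RBH table oriented A -> B.
#' @return The same table oriented B -> A.
#' @export
swap_rbh <- function(rbh) {
  out <- rbh[, c("locus_b", "locus_a", "pct_identity", "min_cov", "score",
                 "scov", "qcov", "aln_len")]
  names(out) <- c("locus_a", "locus_b", "pct_identity", "min_cov", "score",
                  "qcov", "scov", "aln_len")
  out
}

#' Recombination hot spots shared by a genome pair
#'
#' Islands from both genomes are mapped to their syntenic gaps via flanking
#' anchors; a gap occupied in both genomes by (necessarily non-orthologous)
#' inserts is a hot spot with `both_occupied = TRUE`. Contig-edge islands
#' (anchor missing on one side) are excluded from pairing.
#'
#' @param islands_a Islands of A vs B ([call_islands()]).
#' @param islands_b Islands of B vs A (same pair, orientation swapped).
#' @return `data.frame`: `anchor_id`, `island_a`, `island_b`,
#'   `both_occupied`.
#' @export
find_hotspots <- function(islands_a, islands_b) {
  usable <- function(x) x[!grepl("EDGE", x$anchor_id), , drop = FALSE]
  ia <- usable(islands_a)
  ib <- usable(islands_b)
  gaps <- sort(unique(c(ia$anchor_id, ib$anchor_id)))
  collapse <- function(x, gap) paste(x$island_id[x$anchor_id == gap], collapse = ",")
  out <- data.frame(
    anchor_id = gaps,
    island_a = vapply(gaps, collapse, character(1), x = ia),
    island_b = vapply(gaps, collapse, character(1), x = ib),
    stringsAsFactors = FALSE)
  out$both_occupied <- nzchar(out$island_a) & nzchar(out$island_b)
  rownames(out) <- NULL
  out
}
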