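# GenomeRecord: the internal data model shared by every stage.
#
# contigs are plain named character vectors (converted to Biostrings objects
# at I/O and composition boundaries); features is a data.frame with one row
# per gene feature. Coordinates are 0-based half-open internally; GFF3 I/O
# converts at the boundary.

FEATURE_COLUMNS <- c("locus_tag", "contig_id", "start", "end", "strand",
                     "ftype", "product", "protein", "rank")

#' Construct a genome record
#'
#' Bundles contig sequences with typed gene features and a derived mean GC
#' fraction. This is the container every comparative operation consumes.
#'
#' @param genome_id Short unique genome label.
#' @param contigs Named character vector of nucleotide sequences.
#' @param features `data.frame` with columns `locus_tag`, `contig_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `ftype`
#'   (`CDS`, `tRNA`, `rRNA`, `other`), `product`, and optionally `protein`
#'   (CDS amino-acid sequence). Gene-order `rank` is (re)assigned per contig
#'   by coordinate sort.
#' @return An object of class `GenomeRecord` with elements `genome_id`,
#'   `contigs`, `features` and `mean_gc`.
#' @export
genome_record <- function(genome_id, contigs, features) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must be uniquely named")
  }
  contigs <- toupper(contigs)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"product" %in% names(features)) features$product <- ""
  if (!"protein" %in% names(features)) features$protein <- NA_character_
  miss <- setdiff(setdiff(FEATURE_COLUMNS, "rank"), names(features))
  if (length(miss)) stop("features lack column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(features$locus_tag)) {
    dup <- unique(features$locus_tag[duplicated(features$locus_tag)])
    stop("duplicate locus_tag: ", paste(dup, collapse = ", "))
  }
  bad <- !features$contig_id %in% names(contigs)
  if (any(bad)) {
    stop("feature(s) reference unknown contig: ",
         paste(features$locus_tag[bad], collapse = ", "))
  }
  if (any(features$start >= features$end)) {
    stop("feature with start >= end: ",
         paste(features$locus_tag[features$start >= features$end], collapse = ", "))
  }
  clen <- nchar(contigs)[features$contig_id]
  out_of_bounds <- features$start < 0 | features$end > clen
  if (any(out_of_bounds)) {
    stop("feature outside contig bounds: ",
         paste(features$locus_tag[out_of_bounds], collapse = ", "))
  }
  has_prot <- !is.na(features$protein) & nzchar(features$protein)
  if (any(has_prot & features$ftype != "CDS")) {
    stop("protein present on non-CDS feature: ",
         paste(features$locus_tag[has_prot & features$ftype != "CDS"], collapse = ", "))
  }
  ord <- order(match(features$contig_id, names(contigs)), features$start, features$end)
  features <- features[ord, , drop = FALSE]
  features$rank <- stats::ave(seq_len(nrow(features)), features$contig_id,
                              FUN = seq_along)
  rownames(features) <- NULL
  structure(list(genome_id = genome_id,
                 contigs = contigs,
                 features = features[, FEATURE_COLUMNS],
                 mean_gc = gc_fraction(contigs)),
            class = "GenomeRecord")
}

#' GC fraction of one or more sequences
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from both the
#' numerator and the denominator, so the statistic reflects composition, not
#' coverage.
#'
#' @param seqs Character vector of nucleotide sequences (pooled).
#' @return GC fraction in `[0, 1]`; `NaN` if no unambiguous base is present.
#' @export
gc_fraction <- function(seqs) {
  x <- Biostrings::DNAStringSet(toupper(paste(seqs, collapse = "")))
  counts <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))[1, ]
  denom <- sum(counts)
  if (denom == 0) return(NaN)
  unname((counts["G"] + counts["C"]) / denom)
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d contig(s), %s nt, GC %.4f\n",
              x$genome_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","), x$mean_gc))
  tab <- table(x$features$ftype)
  cat("  features:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Summary counts in genome-table style
#'
#' Reports total nucleotides, GC%, rRNA operon count (16S rRNA features as
#' the proxy), tRNA count and predicted protein (CDS) count.
#'
#' @param genome A `GenomeRecord`.
#' @return One-row `data.frame`.
#' @export
genome_stats <- function(genome) {
  f <- genome$features
  data.frame(genome_id = genome$genome_id,
             total_nt = sum(nchar(genome$contigs)),
             gc_pct = 100 * genome$mean_gc,
             rrna_operons = sum(f$ftype == "rRNA" & grepl("16S", f$product, ignore.case = TRUE)),
             trna = sum(f$ftype == "tRNA"),
             predicted_proteins = sum(f$ftype == "CDS"),
             stringsAsFactors = FALSE)
}
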