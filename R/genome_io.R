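# Reading and writing the standard formats the pipeline touches.
#
# GFF3 is handled through rtracklayer; FASTA through Biostrings; Newick
# through ape. Internal coordinates are 0-based half-open and are converted
# to/from GFF3's 1-based inclusive convention at this boundary only.

GFF3_TYPE_MAP <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA")

#' Read a genome from FASTA plus a feature table
#'
#' @param fasta_path Nucleotide FASTA of the genome's contigs.
#' @param features_path Feature file: GFF3 (`dialect = "gff3"`, attributes
#'   `ID`/`locus_tag`, `product`, `translation` honoured) or a GenBank-style
#'   TSV (`dialect = "genbank_table"`, columns `locus_tag`, `contig_id`,
#'   `start`, `end` 1-based inclusive, `strand`, `ftype`, `product`,
#'   optionally `protein`).
#' @param dialect `"gff3"` or `"genbank_table"`.
#' @param genome_id Genome label; default the FASTA basename sans extension.
#' @param translate_missing Translate CDS lacking a stored protein using the
#'   bacterial genetic code (table 11), strand-aware, terminal stop trimmed.
#' @return A [genome_record()].
#' @export
read_genome <- function(fasta_path, features_path,
                        dialect = c("gff3", "genbank_table"),
                        genome_id = NULL, translate_missing = TRUE) {
  dialect <- match.arg(dialect)
  contigs_set <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- setNames(as.character(contigs_set),
                      sub("\\s.*$", "", names(contigs_set)))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  }
  feats <- switch(dialect,
                  gff3 = read_features_gff3(features_path),
                  genbank_table = read_features_table(features_path))
  g <- genome_record(genome_id, contigs, feats)
  if (translate_missing) g <- translate_missing_proteins(g)
  g
}

#' @noRd
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  ftype <- as.character(mc$type)
  ftype[!ftype %in% GFF3_TYPE_MAP] <- "other"
  n <- length(gr)
  locus <- if (!is.null(mc$locus_tag)) as.character(mc$locus_tag) else rep(NA_character_, n)
  id <- if (!is.null(mc$ID)) as.character(mc$ID) else rep(NA_character_, n)
  locus <- ifelse(is.na(locus) | !nzchar(locus), id, locus)
  if (anyNA(locus)) stop("GFF3 feature(s) without ID or locus_tag attribute")
  product <- if (!is.null(mc$product)) as.character(mc$product) else ""
  product[is.na(product)] <- ""
  protein <- if (!is.null(mc$translation)) as.character(mc$translation) else NA_character_
  data.frame(locus_tag = locus,
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L, # 1-based inclusive -> 0-based half-open
             end = GenomicRanges::end(gr),
             strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
             ftype = ftype, product = product, protein = protein,
             stringsAsFactors = FALSE)
}

#' @noRd
read_features_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("locus_tag", "contig_id", "start", "end", "strand", "ftype")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  tab$start <- as.integer(tab$start) - 1L
  tab$end <- as.integer(tab$end)
  if (is.null(tab$product)) tab$product <- ""
  if (is.null(tab$protein)) tab$protein <- NA_character_
  tab
}

#' @noRd
translate_missing_proteins <- function(genome) {
  f <- genome$features
  todo <- which(f$ftype == "CDS" & (is.na(f$protein) | !nzchar(f$protein)))
  if (length(todo)) {
    f$protein[todo] <- vapply(todo, function(i) {
      translate_cds(genome$contigs[[f$contig_id[i]]], f$start[i], f$end[i], f$strand[i])
    }, character(1))
    genome$features <- f
  }
  genome
}

#' Translate a CDS span with the bacterial genetic code
#'
#' @param contig_seq Contig nucleotide sequence.
#' @param start,end 0-based half-open span.
#' @param strand `"+"` or `"-"`.
#' @return Amino-acid sequence, terminal stop trimmed, fuzzy codons as `X`.
#' @export
translate_cds <- function(contig_seq, start, end, strand = "+") {
  nt <- substr(contig_seq, start + 1L, end)
  dna <- Biostrings::DNAString(nt)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  usable <- 3L * (length(dna) %/% 3L)
  if (usable == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::subseq(dna, 1L, usable),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = FALSE))
  sub("\\*$", "", aa)
}

#' Extract the proteome of a genome
#'
#' One entry per CDS in gene order; CDS without a stored translation are
#' translated on the fly.
#'
#' @param genome A `GenomeRecord`.
#' @return Object of class `Proteome`: list with `genome_id` and `entries`
#'   (named character vector, `locus_tag -> protein`).
#' @export
extract_proteome <- function(genome) {
  genome <- translate_missing_proteins(genome)
  f <- genome$features[genome$features$ftype == "CDS", , drop = FALSE]
  if (!nrow(f)) stop("genome '", genome$genome_id, "' has no CDS: empty proteome")
  proteome(genome$genome_id, setNames(f$protein, f$locus_tag))
}

#' Construct a proteome
#'
#' @param genome_id Genome label.
#' @param entries Named character vector of protein sequences
#'   (`locus_tag -> sequence`), 20 amino acids plus `X`.
#' @return Object of class `Proteome`.
#' @export
proteome <- function(genome_id, entries) {
  if (is.null(names(entries)) || anyDuplicated(names(entries))) {
    stop("proteome entries must have unique locus_tag names")
  }
  if (any(!nzchar(entries))) stop("proteome contains empty sequence(s)")
  entries <- toupper(entries)
  invisible(encode_aa(unname(entries))) # validates alphabet
  structure(list(genome_id = genome_id, entries = entries), class = "Proteome")
}

#' @export
print.Proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s': %d proteins, mean length %.0f aa\n",
              x$genome_id, length(x$entries), mean(nchar(x$entries))))
  invisible(x)
}

#' Write a genome back to FASTA + GFF3
#'
#' @param genome A `GenomeRecord`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), fasta_path)
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$contig_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$source <- "ecotypeR"
  S4Vectors::mcols(gr)$type <- ifelse(f$ftype %in% GFF3_TYPE_MAP, f$ftype, "region")
  S4Vectors::mcols(gr)$phase <- ifelse(f$ftype == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- f$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- f$locus_tag
  S4Vectors::mcols(gr)$product <- ifelse(nzchar(f$product), f$product, NA_character_)
  S4Vectors::mcols(gr)$translation <- f$protein
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(genome)
}

#' Write an analysis object to disk
#'
#' Square matrices and tables go to TSV, island tables to BED-like TSV,
#' trees to Newick, concatenated alignments to relaxed PHYLIP with a
#' RAxML-style partition side file (`<path>.partitions`).
#'
#' @param obj Matrix/data.frame, `phylo`, or `ConcatenatedAlignment`.
#' @param path Output path.
#' @param format `"tsv"`, `"newick"` or `"phylip"`; default guessed from the
#'   object class.
#' @return Invisibly, `path`.
#' @export
write_report <- function(obj, path, format = NULL) {
  if (is.null(format)) {
    format <- if (inherits(obj, "phylo")) "newick"
              else if (inherits(obj, "ConcatenatedAlignment")) "phylip"
              else "tsv"
  }
  supported <- c("tsv", "newick", "phylip")
  if (!format %in% supported) {
    stop("unknown format '", format, "'; supported: ", paste(supported, collapse = ", "))
  }
  switch(format,
    tsv = {
      if (is.matrix(obj)) {
        obj <- data.frame(id = rownames(obj) %||% seq_len(nrow(obj)), obj,
                          check.names = FALSE, stringsAsFactors = FALSE)
      }
      utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    newick = ape::write.tree(obj, file = path),
    phylip = write_phylip(obj, path)
  )
  invisible(path)
}

#' Write a concatenated alignment as relaxed PHYLIP plus partitions
#'
#' Header is `ntaxa ncols`; one `name  sequence` line per taxon, no
#' interleaving. Partitions are written to `partition_path` as
#' `DATA, <group> = <start>-<end>` with 1-based inclusive column ranges.
#'
#' @param concat A `ConcatenatedAlignment`.
#' @param path Output `.phy` path.
#' @param partition_path Partition file path (default `<path>.partitions`).
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(concat, path, partition_path = paste0(path, ".partitions")) {
  rows <- concat$rows
  ncols <- unique(nchar(rows))
  stopifnot(length(ncols) == 1L)
  lines <- c(sprintf("%d %d", length(rows), ncols),
             sprintf("%-12s%s", names(rows), rows))
  writeLines(lines, path)
  p <- concat$partitions
  writeLines(sprintf("DATA, %s = %d-%d", p$group_id, p$start + 1L, p$end), partition_path)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path PHYLIP file written by [write_phylip()].
#' @return Named character vector of aligned rows.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- setNames(vapply(body, `[`, character(1), 2L),
                   vapply(body, `[`, character(1), 1L))
  stopifnot(length(rows) == hdr[1], all(nchar(rows) == hdr[2]))
  rows
}
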