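# Metabolic-module inventory from feature annotations, and taxonomic-rank
# zoning from AAI crossed with 16S identity.

#' Load metabolic-module definitions
#'
#' The package ships a default set covering methylotrophy (methanol and
#' methylamine oxidation, PQQ biosynthesis, H4MPT and RuMP formaldehyde
#' handling, formate dehydrogenases, methylcitric acid cycle) and nitrogen
#' metabolism (nitrate/nitrite/NO/N2O reduction, GS/GOGAT). A module is a
#' symbol list plus the fraction of symbols a gene cluster must contain;
#' single-gene rows report plain copy counts.
#'
#' @param path TSV with columns `module_id`, `symbols` (comma-separated),
#'   `min_fraction`, `single_gene`, `notes`; default the shipped table.
#' @return `data.frame` of module definitions.
#' @export
module_definitions <- function(path = system.file("extdata", "metabolic_modules.tsv",
                                                  package = "ecotypeR")) {
  defs <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("module_id", "symbols", "min_fraction", "single_gene")
  miss <- setdiff(need, names(defs))
  if (length(miss)) stop("module table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(defs$symbols))) stop("module without symbols or keywords")
  defs
}

#' Inventory metabolic modules in one genome
#'
#' A gene matches a symbol when its product string contains the symbol as a
#' word (case-insensitive). Multi-gene modules are counted as clusters:
#' matched genes within `max_gene_gap` gene ranks of each other form a
#' cluster, and a cluster counts as one module copy when it contains at
#' least `min_fraction` of the module's distinct symbols. Single-gene rows
#' report plain gene-copy counts.
#'
#' @param genome A `GenomeRecord`.
#' @param module_defs [module_definitions()] table.
#' @param max_gene_gap Maximum gene-rank gap inside a cluster (default 5).
#' @return Named integer vector, one count per module (a column of the
#'   inventory matrix).
#' @export
inventory_modules <- function(genome, module_defs = module_definitions(),
                              max_gene_gap = 5L) {
  f <- genome$features
  f <- f[order(match(f$contig_id, names(genome$contigs)), f$start), , drop = FALSE]
  f$gene_rank <- stats::ave(seq_len(nrow(f)), f$contig_id, FUN = seq_along)
  out <- setNames(integer(nrow(module_defs)), module_defs$module_id)
  for (r in seq_len(nrow(module_defs))) {
    symbols <- trimws(strsplit(module_defs$symbols[r], ",")[[1]])
    hits <- lapply(symbols, function(sym) {
      which(grepl(paste0("\\b", sym, "\\b"), f$product, ignore.case = TRUE))
    })
    names(hits) <- symbols
    if (isTRUE(module_defs$single_gene[r])) {
      out[r] <- length(unique(unlist(hits)))
      next
    }
    idx <- sort(unique(unlist(hits)))
    if (!length(idx)) next
    sym_of <- lapply(idx, function(i) symbols[vapply(hits, function(h) i %in% h, logical(1))])
    gap_break <- c(TRUE, diff(f$gene_rank[idx]) > max_gene_gap |
                     f$contig_id[idx][-1] != f$contig_id[idx][-length(idx)])
    cluster <- cumsum(gap_break)
    need <- ceiling(module_defs$min_fraction[r] * length(symbols))
    n_complete <- sum(vapply(split(sym_of, cluster), function(s) {
      length(unique(unlist(s))) >= need
    }, logical(1)))
    out[r] <- n_complete
  }
  out
}

#' Module inventory matrix over a genome panel
#'
#' @param genomes List of `GenomeRecord`s.
#' @param module_defs,max_gene_gap See [inventory_modules()].
#' @return Integer matrix, modules x genomes.
#' @export
inventory_matrix <- function(genomes, module_defs = module_definitions(),
                             max_gene_gap = 5L) {
  cols <- lapply(genomes, inventory_modules, module_defs = module_defs,
                 max_gene_gap = max_gene_gap)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(genomes, function(g) g$genome_id, character(1))
  m
}

#' Taxonomic-rank zoning thresholds
#'
#' Defaults follow the empirical zones of the AAI-vs-16S plane: pairs of
#' different named genera fall at AAI 62.9-67.3, an ambiguous genus/species
#' band at 69.0-74.3, and same-species pairs at AAI >= 86 (the lowest
#' printed same-species value being 86.3). 16S thresholds: >= 99% identity
#' for conspecifics, < 97% against all described taxa suggesting novelty.
#'
#' @param species_aai_min,genus_zone,ambiguous_zone,species_16s_min,novel_16s_max
#'   Override any default.
#' @return Named list of thresholds.
#' @export
rank_thresholds <- function(species_aai_min = 86.0,
                            genus_zone = c(62.9, 67.3),
                            ambiguous_zone = c(69.0, 74.3),
                            species_16s_min = 99.0,
                            novel_16s_max = 97.0) {
  stopifnot(genus_zone[1] < genus_zone[2],
            ambiguous_zone[1] < ambiguous_zone[2],
            genus_zone[2] <= ambiguous_zone[1],
            ambiguous_zone[2] <= species_aai_min)
  list(species_aai_min = species_aai_min, genus_zone = genus_zone,
       ambiguous_zone = ambiguous_zone, species_16s_min = species_16s_min,
       novel_16s_max = novel_16s_max)
}

#' Classify a genome pair's taxonomic rank from AAI (and 16S identity)
#'
#' Pure zoning function: `same_species` at `aai >= species_aai_min`,
#' `genus_or_species_ambiguous` inside the ambiguous zone, `different_genus`
#' inside the genus zone, `beyond_genus` below it. AAI values in the gaps
#' between zones receive the nearest zone's call flagged low-confidence. A
#' consistency flag is raised when the 16S and AAI signals disagree about
#' species rank.
#'
#' @param aai AAI value (0-100) or an `AAIResult`.
#' @param rrna_id Optional 16S percent identity.
#' @param thresholds [rank_thresholds()].
#' @return List of class `RankCall`: `aai`, `rrna_id`, `call`,
#'   `low_confidence`, `consistency_flag` (and genome ids when an
#'   `AAIResult` was supplied).
#' @export
classify_pair <- function(aai, rrna_id = NA_real_, thresholds = rank_thresholds()) {
  genome_a <- genome_b <- NA_character_
  if (inherits(aai, "AAIResult")) {
    genome_a <- aai$genome_a
    genome_b <- aai$genome_b
    aai <- aai$aai
  }
  if (is.na(aai)) stop("AAI undefined (no shared genes): cannot classify")
  t <- thresholds
  low_confidence <- FALSE
  if (aai >= t$species_aai_min) {
    call <- "same_species"
  } else if (aai >= t$ambiguous_zone[1] && aai <= t$ambiguous_zone[2]) {
    call <- "genus_or_species_ambiguous"
  } else if (aai >= t$genus_zone[1] && aai <= t$genus_zone[2]) {
    call <- "different_genus"
  } else if (aai < t$genus_zone[1]) {
    call <- "beyond_genus"
  } else if (aai > t$genus_zone[2] && aai < t$ambiguous_zone[1]) {
    low_confidence <- TRUE
    call <- if (aai - t$genus_zone[2] <= t$ambiguous_zone[1] - aai) {
      "different_genus"
    } else "genus_or_species_ambiguous"
  } else { # between ambiguous zone and species threshold
    low_confidence <- TRUE
    call <- if (aai - t$ambiguous_zone[2] <= t$species_aai_min - aai) {
      "genus_or_species_ambiguous"
    } else "same_species"
  }
  consistency_flag <- !is.na(rrna_id) &&
    xor(rrna_id >= t$species_16s_min, aai >= t$species_aai_min)
  structure(list(genome_a = genome_a, genome_b = genome_b,
                 aai = aai, rrna_id = rrna_id, call = call,
                 low_confidence = low_confidence,
                 consistency_flag = consistency_flag),
            class = "RankCall")
}

#' @export
print.RankCall <- function(x, ...) {
  cat(sprintf("RankCall: AAI %.1f -> %s%s%s\n", x$aai, x$call,
              if (x$low_confidence) " (low confidence: zone gap)" else "",
              if (isTRUE(x$consistency_flag)) " [16S/AAI inconsistent]" else ""))
  invisible(x)
}
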