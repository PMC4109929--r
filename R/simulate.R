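# Genome-pair simulator with planted ground truth.
#
# An ancestor genome is generated at a target GC; two descendants receive
# independent per-residue amino-acid substitutions (back-translated with the
# host GC preserved), gene-run deletions, optional family duplications, and
# planted gene islands at tRNA-adjacent sites with shifted GC and optional
# recombinase markers. Truth records everything the recovery tests need.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

#' Simulation configuration
#'
#' Defaults state a desk-scale world: 600 genes of geometric length around
#' 300 aa, host GC 0.45 (mid-range for ~2.5-3 Mb genomes at GC 42-55%),
#' per-branch divergence 0.05, ten planted islands of 6-40 genes with
#' |delta GC| >= 0.06 at tRNA sites, and light gene-loss noise.
#'
#' @param seed Integer seed; every random choice derives from it.
#' @param n_genes Ancestor CDS count.
#' @param gene_len_mean_aa Mean protein length (geometric spread, min 50).
#' @param host_gc Target genome GC fraction.
#' @param divergence Per-residue amino-acid substitution probability per
#'   descendant branch.
#' @param islands `data.frame` of planted islands: `n_genes`, `delta_gc`,
#'   `with_trna_flank`, `with_recombinase`, `descendant` (`"A"`/`"B"`),
#'   `site` (tRNA ordinal; `NA` = pick a free site). See
#'   [default_islands()], [hotspot_islands()].
#' @param loss_events Random 1-2 gene deletions per descendant.
#' @param family_duplications Near-identical gene duplications planted in
#'   descendant A (for ortholog-group truth tests).
#' @param trna_every One tRNA per this many genes.
#' @param spacer_range Intergenic spacer length range (nt).
#' @param rrna_16s Plant one slowly evolving 16S rRNA gene.
#' @return List of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 600L, gene_len_mean_aa = 300L,
                              host_gc = 0.45, divergence = 0.05,
                              islands = default_islands(),
                              loss_events = 2L, family_duplications = 0L,
                              trna_every = 50L, spacer_range = c(50L, 300L),
                              rrna_16s = TRUE) {
  stopifnot(host_gc > 0, host_gc < 1, divergence >= 0, divergence <= 1)
  if (!is.null(islands) && nrow(islands)) {
    stopifnot(all(islands$n_genes >= 1),
              all(islands$descendant %in% c("A", "B")))
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_len_mean_aa = gene_len_mean_aa, host_gc = host_gc,
                 divergence = divergence, islands = islands,
                 loss_events = as.integer(loss_events),
                 family_duplications = as.integer(family_duplications),
                 trna_every = as.integer(trna_every),
                 spacer_range = spacer_range, rrna_16s = rrna_16s),
            class = "SimulationConfig")
}

#' Default planted-island set
#'
#' Ten islands of 6-40 genes, |delta GC| >= 0.06, all tRNA-adjacent, half
#' carrying a recombinase, alternating between the two descendants.
#'
#' @return Island `data.frame` for [simulation_config()].
#' @export
default_islands <- function() {
  data.frame(n_genes = c(6L, 9L, 12L, 16L, 20L, 24L, 28L, 32L, 36L, 40L),
             delta_gc = rep(c(-0.08, 0.07), 5),
             with_trna_flank = TRUE,
             with_recombinase = rep(c(TRUE, FALSE), 5),
             descendant = rep(c("A", "B"), 5),
             site = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Island set planting recombination hot spots
#'
#' `k` tRNA sites each receive one island in descendant A and a different
#' one in descendant B, creating `k` both-occupied syntenic gaps.
#'
#' @param k Number of hot spots.
#' @param n_genes,delta_gc Island size and GC shift.
#' @return Island `data.frame` for [simulation_config()].
#' @export
hotspot_islands <- function(k, n_genes = 8L, delta_gc = -0.08) {
  data.frame(n_genes = n_genes, delta_gc = delta_gc,
             with_trna_flank = TRUE, with_recombinase = TRUE,
             descendant = rep(c("A", "B"), k),
             site = rep(seq_len(k), each = 2),
             stringsAsFactors = FALSE)
}

# -- codon machinery ---------------------------------------------------------

#' @noRd
codon_tables <- function() {
  code <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(code), unname(code))
  gc_count <- lapply(by_aa, function(cods) {
    vapply(strsplit(cods, ""), function(b) sum(b %in% c("G", "C")), numeric(1))
  })
  list(by_aa = by_aa, gc_count = gc_count)
}

# codon weights exp(beta * gc) tuned so expected coding GC hits the target
#' @noRd
solve_codon_beta <- function(aa_counts, target_gc, tables) {
  aas <- names(aa_counts)
  expected_gc <- function(beta) {
    num <- 0
    for (a in aas) {
      w <- exp(beta * tables$gc_count[[a]])
      num <- num + aa_counts[[a]] * sum(w * tables$gc_count[[a]]) / sum(w)
    }
    num / (3 * sum(aa_counts))
  }
  lo <- expected_gc(-30); hi <- expected_gc(30)
  if (target_gc < lo || target_gc > hi) {
    stop(sprintf("GC target %.3f unreachable with code constraints [%.3f, %.3f]",
                 target_gc, lo, hi))
  }
  stats::uniroot(function(b) expected_gc(b) - target_gc, c(-30, 30),
                 tol = 1e-8)$root
}

# back-translate proteins at a target coding GC; stop codon appended
#' @noRd
back_translate <- function(proteins, target_gc, tables = codon_tables()) {
  residues <- strsplit(paste0(proteins, "*"), "")
  all_aa <- unlist(residues)
  aa_counts <- table(all_aa)
  beta <- solve_codon_beta(aa_counts, target_gc, tables)
  codons <- character(length(all_aa))
  for (a in names(aa_counts)) {
    cods <- tables$by_aa[[a]]
    w <- exp(beta * tables$gc_count[[a]])
    idx <- which(all_aa == a)
    codons[idx] <- if (length(cods) == 1L) cods else {
      cods[sample.int(length(cods), length(idx), replace = TRUE, prob = w / sum(w))]
    }
  }
  ends <- cumsum(lengths(residues))
  starts <- ends - lengths(residues) + 1L
  vapply(seq_along(proteins), function(i) {
    paste(codons[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' @noRd
random_dna <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
random_proteins <- function(n, mean_len) {
  lens <- 50L + stats::rgeom(n, prob = 1 / (mean_len - 50 + 1))
  vapply(lens, function(L) {
    paste(c("M", sample(AA20, L - 1L, replace = TRUE)), collapse = "")
  }, character(1))
}

# -- ancestor ----------------------------------------------------------------

#' Simulate an ancestor genome
#'
#' @param config [simulation_config()].
#' @return A `GenomeRecord` (genome id `anc`) carrying the element plan as
#'   attribute `sim_plan`, as required by [evolve_pair()].
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  tables <- codon_tables()
  n <- config$n_genes
  proteins <- random_proteins(n, config$gene_len_mean_aa)
  # element plan: CDS with interspersed tRNA, one 16S rRNA mid-genome
  trna_names <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser")
  plan <- data.frame(type = rep("CDS", n), protein = proteins,
                     product = "hypothetical protein",
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  trna_after <- seq(config$trna_every, n - 1L, by = config$trna_every)
  rows <- vector("list", 0)
  ti <- 0L
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- plan[i, ]
    if (i %in% trna_after) {
      ti <- ti + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        type = "tRNA", protein = NA_character_,
        product = paste0("tRNA-", trna_names[(ti - 1L) %% length(trna_names) + 1L]),
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  if (config$rrna_16s) {
    mid <- nrow(plan) %/% 2L
    plan <- rbind(plan[seq_len(mid), ],
                  data.frame(type = "rRNA", protein = NA_character_,
                             product = "16S ribosomal RNA", strand = "+",
                             stringsAsFactors = FALSE),
                  plan[seq(mid + 1L, nrow(plan)), ])
  }
  is_cds <- plan$type == "CDS"
  nt <- character(nrow(plan))
  nt[is_cds] <- back_translate(plan$protein[is_cds], config$host_gc, tables)
  nt[plan$type == "tRNA"] <- vapply(seq_len(sum(plan$type == "tRNA")),
                                    function(i) random_dna(76L, config$host_gc),
                                    character(1))
  nt[plan$type == "rRNA"] <- if (any(plan$type == "rRNA")) {
    random_dna(1500L, config$host_gc)
  } else character(0)
  plan$nt <- nt # coding strand, stop included for CDS
  plan$spacer_after <- vapply(seq_len(nrow(plan)), function(i) {
    random_dna(sample(seq(config$spacer_range[1], config$spacer_range[2]), 1L),
               config$host_gc)
  }, character(1))
  plan$anc_id <- sprintf("anc_%05d", seq_len(nrow(plan)))
  plan$island_id <- NA_character_
  spacer0 <- random_dna(sample(seq(config$spacer_range[1],
                                   config$spacer_range[2]), 1L), config$host_gc)
  g <- assemble_genome("anc", plan, spacer0)
  attr(g$genome, "sim_plan") <- plan
  attr(g$genome, "sim_spacer0") <- spacer0
  attr(g$genome, "sim_config") <- config
  g$genome
}

# turn an element plan into a GenomeRecord; returns island spans as well
#' @noRd
assemble_genome <- function(genome_id, plan, spacer0) {
  n <- nrow(plan)
  oriented <- ifelse(plan$type == "CDS" & plan$strand == "-",
                     vapply(plan$nt, revcomp, character(1), USE.NAMES = FALSE),
                     plan$nt)
  pieces <- c(spacer0, as.vector(rbind(oriented, plan$spacer_after)))
  seq <- paste(pieces, collapse = "")
  widths <- nchar(oriented)
  gaps <- nchar(plan$spacer_after)
  starts <- integer(n)
  pos <- nchar(spacer0)
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + widths[i] + gaps[i]
  }
  locus <- sprintf("%s_%05d", genome_id, seq_len(n))
  feats <- data.frame(
    locus_tag = locus, contig_id = "chr1",
    start = starts, end = starts + widths,
    strand = plan$strand, ftype = plan$type,
    product = plan$product,
    protein = ifelse(plan$type == "CDS", plan$protein, NA_character_),
    stringsAsFactors = FALSE)
  genome <- genome_record(genome_id, c(chr1 = seq), feats)
  isl <- !is.na(plan$island_id)
  island_spans <- if (any(isl)) {
    do.call(rbind, lapply(split(which(isl), plan$island_id[isl]), function(ix) {
      data.frame(island_id = plan$island_id[ix[1]], genome_id = genome_id,
                 contig_id = "chr1",
                 start = starts[min(ix)], end = starts[max(ix)] + widths[max(ix)],
                 n_genes = length(ix),
                 loci = paste(locus[ix], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(island_id = character(), genome_id = character(),
               contig_id = character(), start = integer(), end = integer(),
               n_genes = integer(), loci = character(), stringsAsFactors = FALSE)
  }
  list(genome = genome, island_spans = island_spans, locus_of_row = locus)
}

# -- descendants -------------------------------------------------------------

#' Evolve a descendant pair from an ancestor
#'
#' Each descendant receives independent per-residue substitutions
#' (back-translated at the host GC; unchanged genes keep their ancestral
#' nucleotides, so zero divergence with no islands or losses reproduces the
#' ancestor byte-for-byte), its own island insertions and gene losses. The
#' returned truth records planted island spans, deletions, the ancestor
#' family map, and the realized per-gene identity between the descendants.
#'
#' @param ancestor Output of [simulate_ancestor()].
#' @param config The same [simulation_config()].
#' @return List of class `SimTruth` elements aside: `genome_a`, `genome_b`
#'   (`GenomeRecord`s, ids `A` and `B`) and `truth` (class `SimTruth`).
#' @export
evolve_pair <- function(ancestor, config) {
  plan <- attr(ancestor, "sim_plan")
  spacer0 <- attr(ancestor, "sim_spacer0")
  if (is.null(plan)) stop("ancestor lacks a sim_plan: use simulate_ancestor()")
  set.seed(config$seed + 1L)
  tables <- codon_tables()
  islands <- config$islands
  if (is.null(islands)) {
    islands <- default_islands()[0, ]
  }
  n_trna <- sum(plan$type == "tRNA")
  n_cds <- sum(plan$type == "CDS")
  # assign tRNA sites: explicit sites honoured, the rest drawn without
  # replacement so no accidental shared gap arises
  if (nrow(islands)) {
    islands$island_id <- sprintf("isl%02d_%s", seq_len(nrow(islands)),
                                 islands$descendant)
    need_site <- which(islands$with_trna_flank & is.na(islands$site))
    used <- islands$site[!is.na(islands$site)]
    free <- setdiff(seq_len(n_trna), used)
    if (length(need_site) > length(free)) {
      stop("island insertion positions exhausted: increase trna_every density")
    }
    if (length(need_site)) {
      islands$site[need_site] <- free[sample.int(length(free), length(need_site))]
    }
    if (any(islands$with_trna_flank & islands$site > n_trna)) {
      stop("island site exceeds tRNA count: increase trna_every density")
    }
  }
  cds_rows <- which(plan$type == "CDS")
  # duplications are recent (post-split): each descendant gains its own
  # near-identical copy (1% divergence) of the chosen source families, so
  # the copies are in-paralogs, closer to their sibling than to anything in
  # the partner genome
  dup_src <- if (config$family_duplications > 0) {
    sample(cds_rows, config$family_duplications)
  } else integer(0)

  mutate_proteins <- function() {
    prots <- plan$protein
    for (i in cds_rows) {
      p <- strsplit(prots[i], "")[[1]]
      hit <- which(stats::rbinom(length(p), 1L, config$divergence) == 1L)
      if (length(hit)) {
        p[hit] <- vapply(p[hit], function(old) {
          sample(setdiff(AA20, old), 1L)
        }, character(1))
        prots[i] <- paste(p, collapse = "")
      }
    }
    prots
  }

  make_descendant <- function(label) {
    d_plan <- plan
    d_plan$protein <- mutate_proteins()
    # deletions: runs of 1-2 CDS
    deleted <- integer(0)
    if (config$loss_events > 0) {
      for (k in seq_len(config$loss_events)) {
        len <- sample(1:2, 1L)
        s <- sample(length(cds_rows) - len, 1L)
        deleted <- union(deleted, cds_rows[s:(s + len - 1L)])
      }
    }
    # re-translate mutated genes; unchanged genes keep ancestral nt
    changed <- cds_rows[d_plan$protein[cds_rows] != plan$protein[cds_rows]]
    if (length(changed)) {
      d_plan$nt[changed] <- back_translate(d_plan$protein[changed],
                                           config$host_gc, tables)
    }
    # 16S drifts slowly (one tenth of the protein divergence, per site)
    rr <- which(d_plan$type == "rRNA")
    if (length(rr) && config$divergence > 0) {
      b <- strsplit(d_plan$nt[rr], "")[[1]]
      hit <- which(stats::rbinom(length(b), 1L, config$divergence / 10) == 1L)
      if (length(hit)) {
        b[hit] <- vapply(b[hit], function(o) sample(setdiff(c("A", "C", "G", "T"), o), 1L), character(1))
        d_plan$nt[rr] <- paste(b, collapse = "")
      }
    }
    # island blocks for this descendant
    d_islands <- islands[nrow(islands) > 0 & islands$descendant == label, , drop = FALSE]
    insert_after <- rep(list(NULL), nrow(d_plan))
    if (nrow(d_islands)) {
      trna_rows <- which(d_plan$type == "tRNA")
      for (k in seq_len(nrow(d_islands))) {
        isl <- d_islands[k, ]
        row_at <- if (isTRUE(isl$with_trna_flank)) {
          trna_rows[isl$site]
        } else {
          sample(setdiff(cds_rows, deleted), 1L)
        }
        gc_isl <- config$host_gc + isl$delta_gc
        prots <- random_proteins(isl$n_genes, 250L)
        block <- data.frame(
          type = "CDS", protein = prots, product = "hypothetical protein",
          strand = sample(c("+", "-"), isl$n_genes, replace = TRUE),
          nt = back_translate(prots, gc_isl, tables),
          spacer_after = vapply(seq_len(isl$n_genes), function(i) {
            random_dna(sample(seq(config$spacer_range[1], config$spacer_range[2]), 1L), gc_isl)
          }, character(1)),
          anc_id = sprintf("%s_g%02d", isl$island_id, seq_len(isl$n_genes)),
          island_id = isl$island_id, stringsAsFactors = FALSE)
        if (isTRUE(isl$with_recombinase)) {
          block$product[(isl$n_genes + 1L) %/% 2L] <-
            "tyrosine-type site-specific recombinase"
        }
        # trailing spacer at host composition
        block$spacer_after[isl$n_genes] <-
          random_dna(sample(seq(config$spacer_range[1], config$spacer_range[2]), 1L),
                     config$host_gc)
        insert_after[[row_at]] <- rbind(insert_after[[row_at]], block)
      }
    }
    src <- setdiff(dup_src, deleted)
    if (length(src)) {
      dup_rows <- d_plan[src, , drop = FALSE]
      dup_rows$anc_id <- paste0(dup_rows$anc_id, "_dup")
      dup_rows$island_id <- NA_character_
      dup_rows$protein <- vapply(dup_rows$protein, function(pr) {
        p <- strsplit(pr, "")[[1]]
        hit <- which(stats::rbinom(length(p), 1L, 0.01) == 1L)
        if (length(hit)) {
          p[hit] <- vapply(p[hit], function(o) sample(setdiff(AA20, o), 1L),
                           character(1))
        }
        paste(p, collapse = "")
      }, character(1))
      dup_rows$nt <- back_translate(dup_rows$protein, config$host_gc, tables)
      dup_rows$spacer_after <- vapply(seq_len(nrow(dup_rows)), function(i) {
        random_dna(sample(seq(config$spacer_range[1], config$spacer_range[2]), 1L),
                   config$host_gc)
      }, character(1))
      for (k in seq_along(src)) {
        at <- sample(setdiff(cds_rows, deleted), 1L)
        insert_after[[at]] <- rbind(insert_after[[at]], dup_rows[k, , drop = FALSE])
      }
    }
    keep <- setdiff(seq_len(nrow(d_plan)), deleted)
    final <- vector("list", 0)
    for (i in keep) {
      final[[length(final) + 1L]] <- d_plan[i, ]
      if (!is.null(insert_after[[i]])) {
        final[[length(final) + 1L]] <- insert_after[[i]]
      }
    }
    final <- do.call(rbind, final)
    built <- assemble_genome(label, final, spacer0)
    map <- setNames(built$locus_of_row, final$anc_id)
    list(genome = built$genome, islands = built$island_spans,
         deleted = plan$anc_id[deleted], map = map, plan = final)
  }

  A <- make_descendant("A")
  B <- make_descendant("B")

  anc_cds <- plan$anc_id[cds_rows]
  fam <- data.frame(anc_locus = anc_cds,
                    locus_a = unname(A$map[anc_cds]),
                    locus_b = unname(B$map[anc_cds]),
                    stringsAsFactors = FALSE)
  pa <- setNames(A$plan$protein, A$plan$anc_id)
  pb <- setNames(B$plan$protein, B$plan$anc_id)
  fam$identity <- vapply(seq_len(nrow(fam)), function(i) {
    if (is.na(fam$locus_a[i]) || is.na(fam$locus_b[i])) return(NA_real_)
    x <- strsplit(pa[[fam$anc_locus[i]]], "")[[1]]
    y <- strsplit(pb[[fam$anc_locus[i]]], "")[[1]]
    100 * mean(x == y)
  }, numeric(1))
  truth_islands <- rbind(A$islands, B$islands)
  if (nrow(truth_islands) && nrow(islands)) {
    truth_islands <- merge(
      truth_islands,
      islands[, c("island_id", "delta_gc", "with_trna_flank",
                  "with_recombinase", "site")],
      by = "island_id", sort = TRUE)
  }
  truth <- structure(list(
    family = fam,
    expected_aai = mean(fam$identity, na.rm = TRUE),
    islands = truth_islands,
    deletions = data.frame(
      descendant = rep(c("A", "B"), c(length(A$deleted), length(B$deleted))),
      anc_locus = c(A$deleted, B$deleted), stringsAsFactors = FALSE),
    duplications = plan$anc_id[dup_src],
    config = config
  ), class = "SimTruth")
  list(genome_a = A$genome, genome_b = B$genome, truth = truth)
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d families, expected AAI %.2f, %d islands, %d deletions\n",
              nrow(x$family), x$expected_aai, nrow(x$islands), nrow(x$deletions)))
  invisible(x)
}

# -- recovery scoring --------------------------------------------------------

#' Score island calls against planted truth
#'
#' A called island matches a true island when they share at least half of
#' the true island's genes and both boundaries are within `gene_tolerance`
#' genes. Matching is greedy one-to-one by overlap.
#'
#' @param called_islands [call_islands()] output for one descendant.
#' @param truth `SimTruth` from [evolve_pair()] (or its `$islands` table).
#' @param gene_tolerance Allowed boundary slack in genes.
#' @return List: `precision`, `recall`, `n_called`, `n_true`, `n_matched`,
#'   `precision_undefined` (`TRUE` when nothing was called: precision is
#'   reported as 1.0 with this flag).
#' @export
evaluate_recovery <- function(called_islands, truth, gene_tolerance = 2L) {
  truth_islands <- if (inherits(truth, "SimTruth")) truth$islands else truth
  gid <- unique(called_islands$genome_id)
  if (length(gid) == 1L) {
    truth_islands <- truth_islands[truth_islands$genome_id == gid, , drop = FALSE]
  }
  true_sets <- strsplit(truth_islands$loci, ",")
  called_sets <- strsplit(called_islands$loci, ",")
  n_true <- length(true_sets)
  n_called <- length(called_sets)
  matched_true <- logical(n_true)
  matched_called <- logical(n_called)
  # boundary slack: genes hanging off either end of the shared core, in
  # either the called or the true island, must stay within gene_tolerance
  matches <- function(called, true) {
    common <- intersect(called, true)
    if (length(common) < 0.5 * length(true)) return(FALSE)
    sc <- match(common, called)
    st <- match(common, true)
    lead <- max(min(sc), min(st)) - 1L
    trail <- max(length(called) - max(sc), length(true) - max(st))
    lead <= gene_tolerance && trail <= gene_tolerance
  }
  for (ci in order(-lengths(called_sets))) {
    for (ti in seq_len(n_true)) {
      if (matched_true[ti]) next
      if (matches(called_sets[[ci]], true_sets[[ti]])) {
        matched_true[ti] <- TRUE
        matched_called[ci] <- TRUE
        break
      }
    }
  }
  list(precision = if (n_called == 0) 1.0 else sum(matched_called) / n_called,
       recall = if (n_true == 0) 1.0 else sum(matched_true) / n_true,
       n_called = n_called, n_true = n_true, n_matched = sum(matched_called),
       precision_undefined = n_called == 0)
}
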