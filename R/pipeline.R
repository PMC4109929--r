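# End-to-end orchestration: genome panel in, reproducible report directory
# out (AAI and 16S matrices, SCGO list, concatenated alignment + partitions
# + supported tree, per-pair island and hot-spot tables, module inventory,
# rank calls, manifest and run log).

#' Pipeline configuration
#'
#' @param genomes Either a named list of `GenomeRecord`s or a `data.frame`
#'   with columns `genome_id`, `fasta`, `features`, `dialect`.
#' @param seed Integer seed for every stochastic stage.
#' @param aai_min_identity,aai_min_cov AAI qualifying-pair thresholds.
#' @param scgo_min_identity,scgo_min_cov Single-copy-ortholog thresholds.
#' @param island_cfg [island_config()].
#' @param thresholds [rank_thresholds()].
#' @param n_boot Bootstrap replicates for the concatenated tree.
#' @param stages Character subset of
#'   `c("aai", "rrna", "tree", "islands", "inventory", "classify")`.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(genomes, seed = 1L,
                            aai_min_identity = 30, aai_min_cov = 0.70,
                            scgo_min_identity = 50, scgo_min_cov = 0.70,
                            island_cfg = island_config(),
                            thresholds = rank_thresholds(),
                            n_boot = 100L,
                            stages = c("aai", "rrna", "tree", "islands",
                                       "inventory", "classify")) {
  structure(list(genomes = genomes, seed = as.integer(seed),
                 aai_min_identity = aai_min_identity, aai_min_cov = aai_min_cov,
                 scgo_min_identity = scgo_min_identity, scgo_min_cov = scgo_min_cov,
                 island_cfg = island_cfg, thresholds = thresholds,
                 n_boot = as.integer(n_boot), stages = stages),
            class = "PipelineConfig")
}

#' @noRd
load_pipeline_genomes <- function(genomes) {
  if (is.data.frame(genomes)) {
    missing <- !file.exists(genomes$fasta) | !file.exists(genomes$features)
    if (any(missing)) {
      stop("input file(s) not found for genome(s): ",
           paste(genomes$genome_id[missing], collapse = ", "))
    }
    genomes <- lapply(seq_len(nrow(genomes)), function(i) {
      read_genome(genomes$fasta[i], genomes$features[i],
                  dialect = genomes$dialect[i] %||% "gff3",
                  genome_id = genomes$genome_id[i])
    })
  }
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  setNames(genomes, ids)
}

#' Run the comparative pipeline
#'
#' Stages run in dependency order; any stage failure aborts with the stage
#' name, and the MANIFEST marks which outputs completed. Reruns with the
#' same config and seed into a fresh directory are byte-identical.
#'
#' @param config [pipeline_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "ecotypeR", seed = config$seed,
                   stages = config$stages, complete = FALSE, outputs = character(0))
  logf <- file.path(out_dir, "run_log.txt")
  note <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  emit <- function(obj, name, format = NULL) {
    write_report(obj, file.path(out_dir, name), format = format)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  cat("", file = logf)
  note("ecotypeR pipeline, seed %d", config$seed)

  stage <- "load"
  result <- try({
    genomes <- load_pipeline_genomes(config$genomes)
    if (length(genomes) < 2) stop("need >= 2 genomes for comparative stages")
    note("loaded %d genomes: %s", length(genomes), paste(names(genomes), collapse = " "))
    cfg_echo <- config
    cfg_echo$genomes <- names(genomes)
    jsonlite::write_json(cfg_echo, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA, pretty = TRUE)
    manifest$outputs <- c(manifest$outputs, "config.json")
    proteomes <- lapply(genomes, extract_proteome)
    ids <- names(genomes)

    if ("aai" %in% config$stages) {
      stage <- "aai"
      aai <- aai_matrix(proteomes, min_identity = config$aai_min_identity,
                        min_cov = config$aai_min_cov)
      emit(round(aai, 4), "aai_matrix.tsv", "tsv")
      note("AAI matrix over %d genomes", length(ids))
    }

    if ("rrna" %in% config$stages) {
      stage <- "rrna"
      seqs16 <- extract_16s(genomes)
      if (length(seqs16) >= 2) {
        m16 <- rrna_identity_matrix(seqs16)
        emit(round(m16, 4), "rrna_identity_matrix.tsv", "tsv")
        note("16S identity matrix over %d sequences", length(seqs16))
      } else {
        note("16S stage skipped: fewer than two 16S sequences found")
      }
    }

    groups <- NULL
    if ("tree" %in% config$stages) {
      stage <- "tree"
      groups <- build_ortholog_groups(proteomes,
                                      min_identity = config$scgo_min_identity,
                                      min_cov = config$scgo_min_cov)
      scgo <- select_scgo(groups)
      emit(ortholog_group_table(scgo), "scgo_groups.tsv", "tsv")
      note("%d ortholog groups, %d single-copy", length(groups), length(scgo))
      seq_of <- function(g) {
        loci <- unlist(g$members)
        setNames(vapply(names(g$members), function(gid) {
          unname(proteomes[[gid]]$entries[[g$members[[gid]]]])
        }, character(1)), unlist(g$members))
      }
      msas <- lapply(scgo, function(g) align_group(seq_of(g)))
      names(msas) <- vapply(scgo, `[[`, character(1), "group_id")
      genome_of_locus <- unlist(lapply(scgo, function(g) {
        setNames(rep(names(g$members), lengths(g$members)), unlist(g$members))
      }))
      concat <- concatenate_msas(msas, genome_of_locus)
      emit(concat, "concat.phy", "phylip")
      manifest$outputs <- c(manifest$outputs, "concat.phy.partitions")
      if (length(ids) >= 3) {
        bs <- bootstrap_support(concat, n_reps = config$n_boot, seed = config$seed)
        emit(bs$tree, "tree.nwk", "newick")
        note("NJ tree with %d bootstrap replicates", config$n_boot)
      } else {
        note("tree skipped: neighbor joining needs >= 3 genomes")
      }
    }

    if ("islands" %in% config$stages) {
      stage <- "islands"
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in seq(i + 1, length(ids))) {
          rbh <- reciprocal_best_hits(proteomes[[i]], proteomes[[j]],
                                      min_identity = config$aai_min_identity,
                                      min_cov = config$aai_min_cov)
          ia <- call_islands(genomes[[i]], genomes[[j]], rbh,
                             config = config$island_cfg)
          ib <- call_islands(genomes[[j]], genomes[[i]], swap_rbh(rbh),
                             config = config$island_cfg)
          hs <- find_hotspots(ia, ib)
          tag <- paste0(ids[i], "_vs_", ids[j])
          emit(rbind(ia, ib), paste0("islands_", tag, ".tsv"), "tsv")
          emit(hs, paste0("hotspots_", tag, ".tsv"), "tsv")
          note("pair %s: %d + %d islands, %d hot spots (%d both-occupied)",
               tag, nrow(ia), nrow(ib), nrow(hs), sum(hs$both_occupied))
        }
      }
    }

    if ("inventory" %in% config$stages) {
      stage <- "inventory"
      inv <- inventory_matrix(genomes)
      emit(inv, "inventory.tsv", "tsv")
      note("inventory over %d modules", nrow(inv))
    }

    if ("classify" %in% config$stages && "aai" %in% config$stages) {
      stage <- "classify"
      seqs16 <- extract_16s(genomes)
      calls <- list()
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in seq(i + 1, length(ids))) {
          r16 <- if (all(c(ids[i], ids[j]) %in% names(seqs16))) {
            rrna_identity(seqs16[[ids[i]]], seqs16[[ids[j]]])
          } else NA_real_
          rc <- classify_pair(aai[ids[i], ids[j]], r16, config$thresholds)
          calls[[length(calls) + 1L]] <- data.frame(
            genome_a = ids[i], genome_b = ids[j],
            aai = aai[ids[i], ids[j]], rrna_id = r16, call = rc$call,
            low_confidence = rc$low_confidence,
            consistency_flag = rc$consistency_flag, stringsAsFactors = FALSE)
        }
      }
      emit(do.call(rbind, calls), "rank_calls.tsv", "tsv")
      note("%d rank calls", length(calls))
    }
    TRUE
  }, silent = TRUE)

  if (inherits(result, "try-error")) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(attr(result, "condition"))
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", manifest$error)
  }
  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Extract 16S rRNA sequences from a genome panel
#'
#' @param genomes Named list of `GenomeRecord`s.
#' @return Named character vector (one, the first, 16S per genome).
#' @export
extract_16s <- function(genomes) {
  out <- character(0)
  for (g in genomes) {
    f <- g$features
    hit <- which(f$ftype == "rRNA" & grepl("16S", f$product, ignore.case = TRUE))
    if (length(hit)) {
      i <- hit[1]
      s <- substr(g$contigs[[f$contig_id[i]]], f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") s <- revcomp(s)
      out[g$genome_id] <- s
    }
  }
  out
}
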