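# Shared fixtures. Simulations are memoized so acceptance and module tests
# reuse the same genome pairs instead of regenerating them.

.sim_cache <- new.env(parent = emptyenv())

cached_pair <- function(key, config) {
  if (!exists(key, envir = .sim_cache)) {
    anc <- simulate_ancestor(config)
    assign(key, evolve_pair(anc, config), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_proteomes <- function(key, config) {
  pkey <- paste0(key, "_prot")
  if (!exists(pkey, envir = .sim_cache)) {
    pair <- cached_pair(key, config)
    assign(pkey, list(a = extract_proteome(pair$genome_a),
                      b = extract_proteome(pair$genome_b)),
           envir = .sim_cache)
  }
  get(pkey, envir = .sim_cache)
}

# small, fast world used across module tests: 150 genes, 4 planted islands
small_sim_config <- function(seed = 11) {
  simulation_config(
    seed = seed, n_genes = 150L, gene_len_mean_aa = 200L, host_gc = 0.45,
    divergence = 0.03,
    islands = data.frame(n_genes = c(4L, 6L, 8L, 5L),
                         delta_gc = c(-0.08, 0.07, -0.09, 0.08),
                         with_trna_flank = TRUE,
                         with_recombinase = c(TRUE, FALSE, TRUE, FALSE),
                         descendant = c("A", "B", "A", "B"),
                         site = NA_integer_, stringsAsFactors = FALSE),
    loss_events = 1L, trna_every = 25L)
}

small_pair <- function() cached_pair("small", small_sim_config())
small_prot <- function() cached_proteomes("small", small_sim_config())

# the default-world simulation used by island acceptance (shared with
# test-simulate's calibration property)
default_world_pair <- function(seed) {
  cached_pair(paste0("default", seed), simulation_config(seed = seed))
}
default_world_rbh <- function(seed) {
  key <- paste0("default", seed, "_rbh")
  if (!exists(key, envir = .sim_cache)) {
    pr <- cached_proteomes(paste0("default", seed), simulation_config(seed = seed))
    assign(key, reciprocal_best_hits(pr$a, pr$b, min_identity = 30, min_cov = 0.70),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# hand-built toy genome: contigs + feature rows from a compact spec list
toy_genome <- function(genome_id, contigs, rows) {
  feats <- do.call(rbind, lapply(rows, function(r) {
    data.frame(locus_tag = r[[1]], contig_id = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               strand = r[[5]], ftype = r[[6]],
               product = if (length(r) >= 7) r[[7]] else "",
               protein = if (length(r) >= 8) r[[8]] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  genome_record(genome_id, contigs, feats)
}

# proteome from bare sequences with generated locus tags
toy_proteome <- function(genome_id, seqs) {
  proteome(genome_id, setNames(seqs, sprintf("%s_p%03d", genome_id, seq_along(seqs))))
}
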