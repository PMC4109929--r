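# GC profile, synteny, unique segments, island calling, hot spots

test_that("gc_profile: homogeneous, planted, and degenerate sequences", {
  set.seed(51)
  host <- random_dna_str(100000, gc = 0.50)
  g <- genome_record("h", c(c1 = host),
                     data.frame(locus_tag = "g1", contig_id = "c1", start = 0L,
                                end = 9L, strand = "+", ftype = "other",
                                product = "", protein = NA, stringsAsFactors = FALSE))
  prof <- gc_profile(g)
  expect_true(max(abs(prof$z)) < 4)
  expect_equal(prof$start[1], 0L)
  # planted 10-kb low-GC segment: the minimum-z window lies inside it
  low <- random_dna_str(10000, gc = 0.38)
  planted <- paste0(substr(host, 1, 45000), low, substr(host, 55001, 100000))
  g2 <- genome_record("p", c(c1 = planted), g$features)
  prof2 <- gc_profile(g2)
  wmin <- prof2[which.min(prof2$z), ]
  expect_gte(wmin$start, 45000)
  expect_lte(wmin$end, 55000 + 5000)
  # constant-composition sequence: sd = 0 -> all z defined as 0
  g3 <- genome_record("c", c(c1 = strrep("AC", 30000)), g$features)
  expect_true(all(gc_profile(g3)$z == 0))
})

test_that("window GC equals direct recomputation for 100 random windows", {
  pair <- small_pair()
  prof <- gc_profile(pair$genome_a)
  set.seed(52)
  idx <- sample(nrow(prof), min(100, nrow(prof)))
  for (i in idx) {
    raw <- substr(pair$genome_a$contigs[[prof$contig_id[i]]],
                  prof$start[i] + 1L, prof$end[i])
    expect_equal(prof$gc[i], oracle_gc(raw))
  }
  # z recomputes from the window population
  z <- (prof$gc - pair$genome_a$mean_gc) / sd(prof$gc)
  expect_equal(prof$z, z)
})

test_that("unique segments: identical genomes empty; inserted cassette found", {
  pair <- small_pair()
  g <- pair$genome_a
  cds <- g$features$locus_tag[g$features$ftype == "CDS"]
  self_rbh <- data.frame(locus_a = cds, locus_b = cds, pct_identity = 100,
                         min_cov = 1, score = 1000, qcov = 1, scov = 1,
                         aln_len = 100L, stringsAsFactors = FALSE)
  expect_equal(nrow(unique_segments(g, g, self_rbh)), 0L)
  # drop 8 consecutive CDS from the partner map -> exactly one run of 8
  run <- cds[20:27]
  partial <- self_rbh[!self_rbh$locus_a %in% run, ]
  segs <- unique_segments(g, g, partial)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_genes, 8L)
  expect_equal(strsplit(segs$loci, ",")[[1]], run)
})

test_that("synteny map: collinear genomes are one block; islands break it", {
  pair <- small_pair()
  rbh <- reciprocal_best_hits(small_prot()$a, small_prot()$b,
                              min_identity = 30, min_cov = 0.70)
  sm <- synteny_map(pair$genome_a, pair$genome_b, rbh)
  expect_s3_class(sm, "SyntenyMap")
  expect_equal(nrow(sm$anchors), nrow(rbh))
  # no rearrangements are simulated: breaks come only from B-side island
  # insertions larger than the collinearity tolerance (small deletions and
  # A-side islands are absorbed)
  tr <- pair$truth$islands
  big_b <- sum(tr$genome_id == "B" & tr$n_genes > 2)
  expect_equal(sm$n_breaks, big_b)
  expect_equal(sm$n_blocks, big_b + 1L)
  # an artificial transposition splits blocks
  shuffled <- rbh
  n <- nrow(shuffled)
  shuffled$locus_b <- shuffled$locus_b[c((n %/% 2 + 1):n, 1:(n %/% 2))]
  sm2 <- synteny_map(pair$genome_a, pair$genome_b, shuffled)
  expect_gt(sm2$n_blocks, 1L)
})

test_that("call_islands annotates planted islands with the right evidence", {
  pair <- small_pair()
  truth <- pair$truth$islands
  rbh <- reciprocal_best_hits(small_prot()$a, small_prot()$b,
                              min_identity = 30, min_cov = 0.70)
  ia <- call_islands(pair$genome_a, pair$genome_b, rbh)
  ta <- truth[truth$genome_id == "A", ]
  expect_equal(nrow(ia), nrow(ta))
  ia <- ia[order(ia$start), ]
  ta <- ta[order(ta$start), ]
  # all planted islands were tRNA-adjacent with |delta GC| >= 0.06
  expect_true(all(ia$trna_flank != "none"))
  # islands spanning at least one full profile window carry a clear GC
  # signal in the planted direction (smaller ones may dilute below z_min)
  big <- ia$n_genes >= 6
  expect_true(all(abs(ia$gc_z[big]) >= 2))
  expect_equal(sign(ia$gc_z[big]), sign(ta$delta_gc[big]))
  expect_equal(ia$has_recombinase, ta$with_recombinase)
  # islands are disjoint and contain no gene with an RBH partner
  expect_true(all(ia$start[-1] >= head(ia$end, -1)))
  expect_false(any(unlist(strsplit(ia$loci, ",")) %in% rbh$locus_a))
})

test_that("the default evidence rule suppresses unsupported unique segments", {
  pair <- small_pair()
  rbh <- reciprocal_best_hits(small_prot()$a, small_prot()$b,
                              min_identity = 30, min_cov = 0.70)
  # strip evidence by neutralizing config: no segment passes a z of 999
  # unless tRNA-flanked or recombinase-marked; then forbid those too
  cfg <- island_config(z_min = 999, flank_dist = 0L,
                       recombinase_keywords = "never_matches_anything")
  suppressed <- call_islands(pair$genome_a, pair$genome_b, rbh, config = cfg)
  expect_equal(nrow(suppressed), 0L)
  # with require_evidence = FALSE the unique segments come back
  cfg2 <- island_config(z_min = 999, flank_dist = 0L,
                        recombinase_keywords = "never_matches_anything",
                        require_evidence = FALSE)
  open <- call_islands(pair$genome_a, pair$genome_b, rbh, config = cfg2)
  expect_gt(nrow(open), 0L)
})

test_that("A/B swap symmetry: island lists swap, hot-spot count unchanged", {
  pair <- small_pair()
  rbh <- reciprocal_best_hits(small_prot()$a, small_prot()$b,
                              min_identity = 30, min_cov = 0.70)
  ia <- call_islands(pair$genome_a, pair$genome_b, rbh)
  ib <- call_islands(pair$genome_b, pair$genome_a, swap_rbh(rbh))
  hs <- find_hotspots(ia, ib)
  hs_sw <- find_hotspots(ib, ia)
  expect_equal(nrow(hs), nrow(hs_sw))
  expect_equal(sum(hs$both_occupied), sum(hs_sw$both_occupied))
  expect_equal(sort(hs$anchor_id), sort(hs_sw$anchor_id))
})

test_that("find_hotspots: empty input, and distinct sites stay unpaired", {
  none <- find_hotspots(call_islands(small_pair()$genome_a,
                                     small_pair()$genome_a,
                                     data.frame(locus_a = "x", locus_b = "x",
                                                pct_identity = 100, min_cov = 1,
                                                score = 1, qcov = 1, scov = 1,
                                                aln_len = 1L))[0, ],
                        call_islands(small_pair()$genome_b,
                                     small_pair()$genome_b,
                                     data.frame(locus_a = "x", locus_b = "x",
                                                pct_identity = 100, min_cov = 1,
                                                score = 1, qcov = 1, scov = 1,
                                                aln_len = 1L))[0, ])
  expect_equal(nrow(none), 0L)
  # the small world plants all four islands at distinct tRNA sites:
  # gaps are occupied on one side only
  pair <- small_pair()
  rbh <- reciprocal_best_hits(small_prot()$a, small_prot()$b,
                              min_identity = 30, min_cov = 0.70)
  ia <- call_islands(pair$genome_a, pair$genome_b, rbh)
  ib <- call_islands(pair$genome_b, pair$genome_a, swap_rbh(rbh))
  hs <- find_hotspots(ia, ib)
  expect_false(any(hs$both_occupied))
})

test_that("explicitly shared sites become both-occupied hot spots", {
  cfg <- simulation_config(seed = 55, n_genes = 150L, gene_len_mean_aa = 150L,
                           divergence = 0.03, islands = hotspot_islands(2),
                           loss_events = 0L, trna_every = 25L)
  pair <- evolve_pair(simulate_ancestor(cfg), cfg)
  pa <- extract_proteome(pair$genome_a)
  pb <- extract_proteome(pair$genome_b)
  rbh <- reciprocal_best_hits(pa, pb, min_identity = 30, min_cov = 0.70)
  ia <- call_islands(pair$genome_a, pair$genome_b, rbh)
  ib <- call_islands(pair$genome_b, pair$genome_a, swap_rbh(rbh))
  hs <- find_hotspots(ia, ib)
  expect_equal(sum(hs$both_occupied), 2L)
})
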