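# ortholog grouping, SCGO selection, progressive alignment, concatenation,
# neighbor joining, bootstrap

test_that("ortholog groups: families across three genomes, duplicates flagged", {
  set.seed(31)
  famA <- random_protein(80)
  famB <- random_protein(90)
  make <- function(id, dup_famA = FALSE) {
    a <- mutate_protein(famA, 4)
    seqs <- c(a, mutate_protein(famB, 4))
    # an in-paralog is a copy of the genome's OWN gene, not of the ancestor
    if (dup_famA) seqs <- c(seqs, mutate_protein(a, 1))
    toy_proteome(id, seqs)
  }
  groups <- build_ortholog_groups(list(make("G1"), make("G2"), make("G3")))
  expect_length(groups, 2L)
  expect_true(all(vapply(groups, `[[`, logical(1), "single_copy")))
  # duplicate a family member in two genomes: in-paralogs join the group
  dupd <- build_ortholog_groups(list(
    make("G1", dup_famA = TRUE),
    make("G2", dup_famA = TRUE),
    make("G3")))
  sizes <- vapply(dupd, function(g) sum(lengths(g$members)), integer(1))
  expect_equal(sort(sizes), c(3L, 5L))
  big <- dupd[[which.max(sizes)]]
  expect_false(big$single_copy)
})

test_that("ortholog groups equal simulator family truth with planted duplications", {
  cfg <- simulation_config(seed = 33, n_genes = 50L, gene_len_mean_aa = 150L,
                           divergence = 0.03, islands = NULL, loss_events = 0L,
                           family_duplications = 5L, trna_every = 20L)
  pair <- evolve_pair(simulate_ancestor(cfg), cfg)
  pa <- extract_proteome(pair$genome_a)
  pb <- extract_proteome(pair$genome_b)
  groups <- build_ortholog_groups(list(pa, pb))
  expect_length(groups, 50L)
  expect_equal(sum(vapply(groups, `[[`, logical(1), "single_copy")), 45L)
  # every group's non-duplicate membership maps to exactly one truth family
  fam <- pair$truth$family
  fam_of <- c(setNames(fam$anc_locus, fam$locus_a),
              setNames(fam$anc_locus, fam$locus_b))
  for (g in groups) {
    base <- unique(stats::na.omit(fam_of[unlist(g$members)]))
    expect_length(base, 1L)
  }
})

test_that("select_scgo keeps exactly the all-genome single-copy groups", {
  pr <- small_prot()
  groups <- build_ortholog_groups(list(pr$a, pr$b))
  scgo <- select_scgo(groups)
  expect_true(all(vapply(scgo, `[[`, logical(1), "single_copy")))
  expect_equal(length(scgo),
               sum(vapply(groups, `[[`, logical(1), "single_copy")))
  # a genome with nothing shared kills every group
  set.seed(34)
  alien <- toy_proteome("Z", vapply(1:5, function(i) random_protein(80), character(1)))
  g3 <- build_ortholog_groups(list(pr$a, pr$b, alien))
  expect_error(select_scgo(g3), "no single-copy")
})

test_that("two-sequence alignment achieves the optimal global score", {
  set.seed(35)
  for (i in 1:8) {
    a <- random_protein(sample(20:50, 1))
    b <- mutate_protein(a, sample(1:8, 1))
    m <- align_group(c(x = a, y = b))
    # score the produced columns and compare with Biostrings' optimum
    sub <- oracle_blosum62()
    ca <- strsplit(m[["x"]], "")[[1]]
    cb <- strsplit(m[["y"]], "")[[1]]
    sc <- sum(vapply(seq_along(ca), function(k) {
      if (ca[k] == "-" || cb[k] == "-") 0 else sub[ca[k], cb[k]]
    }, numeric(1)))
    gaps <- rle(ifelse(ca == "-", "a", ifelse(cb == "-", "b", "m")))
    sc <- sc - sum(11 + gaps$lengths[gaps$values != "m"])
    opt <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = sub, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(sc, unname(opt))
  }
})

test_that("progressive MSA: identity, deletion fixture, ungap round-trip", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  m <- align_group(c(a = s, b = s, c = s))
  expect_equal(attr(m, "ncols"), nchar(s))
  expect_false(any(grepl("-", m)))
  # one internal 3-aa deletion -> exactly one 3-column gap run
  del <- paste0(substr(s, 1, 14), substr(s, 18, nchar(s)))
  m2 <- align_group(c(a = s, b = del, c = s))
  gaps <- rle(strsplit(m2[["b"]], "")[[1]] == "-")
  expect_equal(sum(gaps$values), 1L)
  expect_equal(gaps$lengths[gaps$values], 3L)
  # ungapping reproduces inputs exactly (property, random groups)
  set.seed(36)
  for (i in 1:5) {
    base <- random_protein(60)
    seqs <- setNames(vapply(1:4, function(j) mutate_protein(base, sample(0:10, 1)),
                            character(1)), paste0("s", 1:4))
    mm <- align_group(seqs)
    for (nm in names(seqs)) {
      expect_identical(gsub("-", "", mm[[nm]]), unname(seqs[nm]))
    }
  }
})

test_that("concatenation records partitions and preserves column content", {
  msas <- list(g2 = align_group(c(u = random_protein(20), v = random_protein(20),
                                  w = random_protein(20))),
               g1 = align_group(c(x = "MKLVAAPQRS", y = "MKLVAAPQRS",
                                  z = "MKIVAAPQRS")))
  gmap <- c(x = "GA", y = "GB", z = "GC", u = "GA", v = "GB", w = "GC")
  cc <- concatenate_msas(msas, gmap)
  expect_equal(cc$partitions$group_id, c("g1", "g2")) # sorted group order
  expect_equal(cc$partitions$start[1], 0L)
  expect_equal(cc$partitions$end[2], cc$ncols)
  # slicing a partition back out reproduces that group's MSA rows
  p1 <- cc$partitions[1, ]
  slice <- substr(cc$rows, p1$start + 1L, p1$end)
  expect_equal(unname(slice[gmap[names(msas$g1)]]), unname(unclass(msas$g1)),
               ignore_attr = TRUE)
  # single group concatenation is the MSA itself
  one <- concatenate_msas(msas["g1"], gmap)
  expect_equal(unname(one$rows), unname(unclass(msas$g1)[c("x", "y", "z")]))
  # genome missing from an MSA is a hard error naming the group
  expect_error(concatenate_msas(msas, gmap[names(gmap) != "u"]), "g2")
})

test_that("distance_matrix follows its definitions", {
  rows <- c(a = paste(rep("A", 100), collapse = ""),
            b = paste(c(rep("A", 90), rep("C", 10)), collapse = ""))
  expect_equal(distance_matrix(rows, "p_distance")["a", "b"], 0.10)
  expect_equal(distance_matrix(rows, "poisson_corrected")["a", "b"],
               -log(0.9), tolerance = 1e-9)
  same <- c(a = "MKLV", b = "MKLV")
  expect_equal(distance_matrix(same, "p_distance")["a", "b"], 0)
  sat <- c(a = "AAAA", b = "CCCC")
  expect_warning(d <- distance_matrix(sat, "poisson_corrected"), "capped")
  expect_equal(d["a", "b"], 10)
})

test_that("neighbor joining solves the three-point problem exactly", {
  dm <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.1, 0.2, 0.3), tolerance = 1e-9)
})

test_that("NJ recovers additive trees exactly and agrees with ape's NJ", {
  set.seed(37)
  for (i in 1:10) {
    true <- ape::rtree(6, rooted = FALSE, br = function(n) runif(n, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(true)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    mine <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(mine), true), 0, ignore_attr = TRUE)
    # branch lengths recovered: path distances reproduce the input matrix
    back <- ape::cophenetic.phylo(mine)[rownames(dm), colnames(dm)]
    expect_equal(back, dm, tolerance = 1e-8)
    # independent implementation agrees on topology
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ape::nj(dm))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap gives 100% to a forced split and <100% to a star", {
  set.seed(38)
  # two 4-taxon clades: within-clade identical, between-clade very different
  block <- function(ch, n) paste(rep(ch, n), collapse = "")
  cladeA <- paste0(block("A", 60), block("C", 60))
  cladeB <- paste0(block("A", 60), block("W", 60))
  rows <- setNames(c(rep(cladeA, 4), rep(cladeB, 4)), paste0("t", 1:8))
  # add mild row-specific noise so NJ has signal within clades
  rows <- vapply(seq_along(rows), function(i) {
    v <- strsplit(rows[i], "")[[1]]
    pos <- sample(length(v), 3)
    v[pos] <- sample(c("D", "E", "F"), 3, replace = TRUE)
    paste(v, collapse = "")
  }, character(1))
  names(rows) <- paste0("t", 1:8)
  bs <- bootstrap_support(rows, n_reps = 100, seed = 1)
  central <- paste(sort(paste0("t", 5:8)), collapse = "|")
  expect_equal(unname(bs$supports[central]), 100)
  # star-like noise alignment: no split should be certain
  noisy <- vapply(1:6, function(i) random_protein(120), character(1))
  names(noisy) <- paste0("n", 1:6)
  bs2 <- bootstrap_support(noisy, n_reps = 100, seed = 2)
  expect_true(all(bs2$supports < 100))
})

test_that("bootstrap supports are stable across seeds", {
  set.seed(39)
  seqs <- vapply(1:4, function(i) random_protein(150), character(1))
  rows <- setNames(c(seqs[1], mutate_protein(seqs[1], 8),
                     mutate_protein(seqs[1], 60), mutate_protein(seqs[1], 62)),
                   paste0("x", 1:4))
  s1 <- bootstrap_support(rows, n_reps = 200, seed = 5)$supports
  s2 <- bootstrap_support(rows, n_reps = 200, seed = 99)$supports
  expect_true(all(abs(s1 - s2[names(s1)]) <= 5))
})

test_that("SCGO count is monotone non-increasing as genomes are added", {
  cfg <- simulation_config(seed = 41, n_genes = 60L, gene_len_mean_aa = 150L,
                           divergence = 0.04, islands = NULL, loss_events = 2L,
                           trna_every = 25L)
  pair <- evolve_pair(simulate_ancestor(cfg), cfg)
  anc_p <- extract_proteome(simulate_ancestor(cfg))
  anc_p$genome_id <- "C"
  pa <- extract_proteome(pair$genome_a)
  pb <- extract_proteome(pair$genome_b)
  n2 <- length(select_scgo(build_ortholog_groups(list(pa, pb))))
  n3 <- length(select_scgo(build_ortholog_groups(list(pa, pb, anc_p))))
  expect_lte(n3, n2)
})
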