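# genome reading/writing, translation, coordinate conventions, reports

test_that("read_genome translates CDS with the bacterial code and counts features", {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(">c1", "ATGAAATGAGGGCCC"), fa)
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tCDS\t1\t9\t.\t+\t0\tID=gene1;product=demo protein",
    "c1\ttest\ttRNA\t10\t12\t.\t+\t.\tID=trna1;product=tRNA-Ala",
    "c1\ttest\trRNA\t13\t15\t.\t+\t.\tID=rrna1;product=16S ribosomal RNA"),
    gff)
  g <- read_genome(fa, gff, dialect = "gff3", genome_id = "toy")
  expect_s3_class(g, "GenomeRecord")
  f <- g$features
  # 1-based inclusive GFF3 -> 0-based half-open
  expect_equal(f$start[f$locus_tag == "gene1"], 0L)
  expect_equal(f$end[f$locus_tag == "gene1"], 9L)
  expect_equal(f$protein[f$locus_tag == "gene1"], "MK") # stop trimmed
  expect_equal(as.vector(table(f$ftype)[c("CDS", "rRNA", "tRNA")]), c(1L, 1L, 1L))
})

test_that("genbank-style feature table dialect reads equivalently", {
  fa <- tempfile(fileext = ".fasta")
  tab <- tempfile(fileext = ".tsv")
  writeLines(c(">c1", "ATGAAATGA"), fa)
  writeLines(c("locus_tag\tcontig_id\tstart\tend\tstrand\tftype\tproduct",
               "gene1\tc1\t1\t9\t+\tCDS\tdemo"), tab)
  g <- read_genome(fa, tab, dialect = "genbank_table")
  expect_equal(g$features$protein, "MK")
})

test_that("feature validation errors name the offending locus", {
  expect_error(
    toy_genome("bad", c(c1 = "ATGAAATGA"),
               list(list("g1", "c1", 0, 50, "+", "CDS"))),
    "outside contig bounds.*g1")
  expect_error(
    toy_genome("bad", c(c1 = "ATGAAATGAATGAAATGA"),
               list(list("g1", "c1", 0, 9, "+", "CDS"),
                    list("g1", "c1", 9, 18, "+", "CDS"))),
    "duplicate locus_tag.*g1")
})

test_that("strand-aware translation round-trips through minus-strand CDS", {
  pair <- small_pair()
  f <- pair$genome_a$features
  minus <- f[f$ftype == "CDS" & f$strand == "-", ][1, ]
  expect_equal(
    translate_cds(pair$genome_a$contigs[[minus$contig_id]],
                  minus$start, minus$end, "-"),
    minus$protein)
})

test_that("mean_gc matches brute-force counting on 1000 random sequences", {
  set.seed(101)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE),
               collapse = "")
    expect_equal(gc_fraction(s), oracle_gc(s))
  }
})

test_that("ambiguous bases are excluded from the GC statistic entirely", {
  expect_equal(gc_fraction("GGCCNNNN"), 1.0)
  expect_true(is.nan(gc_fraction("NNNN")))
})

test_that("extract_proteome yields one entry per CDS and translates on the fly", {
  g <- toy_genome("t", c(c1 = "ATGAAATGAATGCCCTGA"),
                  list(list("g1", "c1", 0, 9, "+", "CDS"),
                       list("g2", "c1", 9, 18, "+", "CDS")))
  p <- extract_proteome(g)
  expect_s3_class(p, "Proteome")
  expect_equal(unname(p$entries), c("MK", "MP"))
  # pre-translated input gives the identical result
  g2 <- g
  g2$features$protein <- c("MK", "MP")
  expect_equal(extract_proteome(g2)$entries, p$entries)
  g3 <- toy_genome("t3", c(c1 = "ATGAAATGA"),
                   list(list("r1", "c1", 0, 9, "+", "rRNA", "16S ribosomal RNA")))
  expect_error(extract_proteome(g3), "no CDS")
})

test_that("simulated genome round-trips through FASTA + GFF3", {
  pair <- small_pair()
  g <- pair$genome_a
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  g2 <- read_genome(fa, gff, dialect = "gff3", genome_id = g$genome_id)
  expect_identical(g2$contigs, g$contigs)
  expect_identical(g2$features$locus_tag, g$features$locus_tag)
  expect_identical(g2$features$start, g$features$start)
  expect_identical(g2$features$end, g$features$end)
  expect_identical(g2$features$strand, g$features$strand)
  expect_identical(g2$features$ftype, g$features$ftype)
  expect_identical(g2$features$protein, g$features$protein)
  expect_equal(g2$mean_gc, g$mean_gc)
})

test_that("genome_stats reports table-style counts from the simulator world", {
  pair <- small_pair()
  st <- genome_stats(pair$genome_a)
  f <- pair$genome_a$features
  expect_equal(st$predicted_proteins, sum(f$ftype == "CDS"))
  expect_equal(st$trna, sum(f$ftype == "tRNA"))
  expect_equal(st$rrna_operons, 1L)
})

test_that("write_report handles matrices, empty tables, trees, and alignments", {
  d <- tempfile(); dir.create(d)
  # identical genomes (perfect self-RBH) -> empty island table, header only
  g <- small_pair()$genome_a
  cds <- g$features$locus_tag[g$features$ftype == "CDS"]
  self_rbh <- data.frame(locus_a = cds, locus_b = cds, pct_identity = 100,
                         min_cov = 1, score = 1000, qcov = 1, scov = 1,
                         aln_len = 100L, stringsAsFactors = FALSE)
  empty <- call_islands(g, g, self_rbh)
  expect_equal(nrow(empty), 0L)
  p1 <- file.path(d, "islands.tsv")
  write_report(empty, p1, "tsv")
  expect_length(readLines(p1), 1L)
  # tree Newick round-trip preserves topology
  tr <- ape::read.tree(text = "((a:1,b:2):0.5,c:3);")
  p2 <- file.path(d, "tree.nwk")
  write_report(tr, p2, "newick")
  tr2 <- ape::read.tree(p2)
  expect_equal(sort(tr2$tip.label), c("a", "b", "c"))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_error(write_report(tr, p2, "xlsx"), "supported")
})

test_that("PHYLIP export writes contiguous partitions covering all columns", {
  msas <- list(
    g1 = align_group(c(x = "MKLV", y = "MKIV", z = "MKLV")),
    g2 = align_group(c(u = "MPEWHEAGAW", v = "MPEWHEAGAW", w = "MPEWHEGGAW")))
  gmap <- c(x = "G1", y = "G2", z = "G3", u = "G1", v = "G2", w = "G3")
  cc <- concatenate_msas(msas, gmap)
  phy <- tempfile(fileext = ".phy")
  write_report(cc, phy, "phylip")
  rows <- read_phylip(phy)
  expect_identical(unname(rows[names(cc$rows)]), unname(cc$rows))
  part <- readLines(paste0(phy, ".partitions"))
  expect_length(part, 2L)
  rng <- regmatches(part, regexec("= (\\d+)-(\\d+)", part))
  lo <- as.integer(vapply(rng, `[`, character(1), 2))
  hi <- as.integer(vapply(rng, `[`, character(1), 3))
  expect_equal(lo[1], 1L)
  expect_equal(lo[2], hi[1] + 1L) # contiguous, non-overlapping
  expect_equal(hi[2], cc$ncols)   # full coverage
})
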