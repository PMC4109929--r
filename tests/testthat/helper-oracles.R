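# Independent oracles: plain-R dynamic programming (no shared code with the
# package's C++ engine) and Biostrings::pairwiseAlignment as a second,
# external reference implementation.

oracle_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

# plain-R affine-gap Smith-Waterman score (gap of length L costs open + L*ext)
oracle_sw_score <- function(a, b, open = 11, ext = 1) {
  sub <- oracle_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Biostrings local alignment score (second independent engine)
oracle_bs_local <- function(a, b, open = 11, ext = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = oracle_blosum62(), gapOpening = open,
    gapExtension = ext, scoreOnly = TRUE)
}

# exhaustive all-vs-all RBH oracle built on Biostrings alignments
oracle_rbh <- function(pa, pb, min_identity, min_cov, open = 11, ext = 1) {
  sub <- oracle_blosum62()
  A <- pa$entries; B <- pb$entries
  stats <- expand.grid(ia = seq_along(A), ib = seq_along(B))
  res <- lapply(seq_len(nrow(stats)), function(k) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(unname(A)[[stats$ia[k]]]),
      Biostrings::AAString(unname(B)[[stats$ib[k]]]),
      type = "local", substitutionMatrix = sub,
      gapOpening = open, gapExtension = ext)
    p <- as.character(Biostrings::alignedPattern(al))
    s <- as.character(Biostrings::alignedSubject(al))
    cols <- nchar(p)
    matches <- Biostrings::nmatch(al)
    qres <- nchar(gsub("-", "", p))
    sres <- nchar(gsub("-", "", s))
    c(score = Biostrings::score(al), identity = 100 * matches / cols,
      cov = min(qres / nchar(A[[stats$ia[k]]]), sres / nchar(B[[stats$ib[k]]])))
  })
  res <- do.call(rbind, res)
  stats <- cbind(stats, res)
  stats$locus_a <- names(A)[stats$ia]
  stats$locus_b <- names(B)[stats$ib]
  stats <- stats[stats$score > 0, , drop = FALSE]
  pick_best <- function(df, by, partner) {
    ord <- order(df[[by]], -df$score, -df$identity, df[[partner]])
    d <- df[ord, ]
    d[!duplicated(d[[by]]), c("ia", "ib")]
  }
  ba <- pick_best(stats, "ia", "locus_b")
  bb <- pick_best(stats, "ib", "locus_a")
  key <- paste(stats$ia, stats$ib)
  rbh <- stats[key %in% intersect(paste(ba$ia, ba$ib), paste(bb$ia, bb$ib)), ]
  rbh <- rbh[rbh$identity >= min_identity & rbh$cov >= min_cov, ]
  rbh[order(rbh$ia), c("locus_a", "locus_b")]
}

# brute-force GC by character counting
oracle_gc <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  sum(v %in% c("G", "C")) / sum(v %in% c("A", "C", "G", "T"))
}

random_protein <- function(len) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

random_dna_str <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mutate a protein at a fixed number of positions (never to the original aa)
mutate_protein <- function(seq, n_subs) {
  v <- strsplit(seq, "")[[1]]
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  pos <- sample(length(v), n_subs)
  v[pos] <- vapply(v[pos], function(o) sample(setdiff(aa, o), 1), character(1))
  paste(v, collapse = "")
}
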