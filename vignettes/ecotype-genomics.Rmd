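---
title: "Delineating bacterial ecotypes from genome pairs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating bacterial ecotypes from genome pairs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecotypeR)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

Panels of bacterial isolates from a single environment often contain
lineages that are indistinguishable by 16S rRNA (> 99% identity) yet differ
sharply in gene content and phenotype — ecotypes. Resolving them requires
whole-proteome relatedness (AAI), a multi-gene phylogeny, and a comparison
of what each genome uniquely carries. `ecotypeR` packages that chain so
each stage is reproducible and testable against simulated ground truth.

## Pairwise alignment and AAI

BLASTP is replaced by exact affine-gap Smith–Waterman (BLOSUM62, gap open
11, extend 1 — the BLASTP defaults; a length-*L* gap costs `11 + L`).
Percent identity uses the BLAST convention: identical pairs over aligned
columns *including internal gaps*. Coverage of a hit is
`min(qcov, scov)` — both proteins must be aligned over at least the
threshold fraction of their own length. This is the stricter of the two
possible readings of "over at least 70% of the protein length"; it
prevents a fragment from inheriting full marks from a long partner.

Reciprocal best hits break score ties deterministically: higher score,
then higher identity, then lexicographically smallest partner locus tag.
AAI is the unweighted mean of qualifying RBH identities (identity ≥ 30%,
coverage ≥ 0.70); SCGO selection uses the stricter 50%/70%. AAI is made
exactly symmetric by canonicalizing the alignment orientation per genome
pair (sorted genome ids), so `aai(a,b) == aai(b,a)` to the last bit.
`aai(a,a)` is 100 with one pair per protein. Zero qualifying pairs yield
an explicit "no shared genes" result with `aai = NA` — never 0.

Exhaustive all-vs-all alignment is quadratic; above 40 proteins per
proteome a k-mer prefilter (k = 5, ≥ 2 shared k-mers) selects candidate
pairs that are then aligned *exactly*. Two random 300-residue proteins
share ≥ 2 5-mers with probability ~`3e-5`, while homologs above ~40%
identity share dozens, so the prefilter is lossless for any pair that
could pass the AAI thresholds in practice. Its one known blind spot —
true best hits below ~30% identity with no 5-mer in common — sits below
the qualifying cutoffs. The ≤ 40-protein path is exhaustive and is the
path the oracle-equality tests exercise.

## Ortholog groups and the single-copy set

Groups are connected components of the cross-genome RBH graph at 50%/70%.
Strict reciprocal-best edges are one-to-one per genome pair and therefore
can never place two paralogs from one genome in the same group; recent
duplicates would always split off. We therefore add *in-paralog* edges:
a within-genome pair passing the same thresholds whose alignment score is
at least as high as either member's best cross-genome RBH score — i.e.
the two copies are closer to each other than either is to anything
abroad. This is the standard in-paralog criterion and keeps the clustering
deterministic and inflation-free (no Markov-clustering granularity
parameter to tune). SCGO are the groups with exactly one member in every
genome; group ids derive from sorted member lists, so they are stable
across runs.

## Alignment, concatenation, tree

Per-group multiple alignments are progressive: a neighbor-joining guide
tree from fractional-common-3-mer distances, then profile–profile merges
scored by BLOSUM62 sum-of-pairs (gap columns contribute zero), all
deterministic. Two-sequence groups reduce to exact global DP; the test
suite verifies the produced columns achieve the independent optimum.

Concatenation joins groups in sorted id order and records each group's
column span; the PHYLIP + `DATA, group = start-end` partition export is
bit-stable so an external maximum-likelihood run can reproduce the same
matrix. Maximum likelihood itself is deliberately out of scope: the
in-repo tree is neighbor joining on Poisson-corrected distances
(`d = −ln(1−p)` over columns where both rows are non-gap; saturated
`p ≥ 1` capped at 10 with a warning). NJ tie-breaks take the lowest
active index pair; negative branch lengths are clamped to zero with the
deficit moved to the sibling edge, preserving the joined distance. On
additive matrices the generating topology and branch lengths are recovered
exactly (tested on random 6-taxon trees against an independent NJ
implementation). Bootstrap resamples alignment columns with replacement
(replicate *r* seeds its own stream at `seed + r`), rebuilds the NJ tree
and scores each internal split of the full-data tree.

## Genomic islands and hot spots

The classic manual procedure looks for synteny breaks, GC deviation from
the genome average, and integration signatures. The algorithmic version:

1. **Unique segments** — maximal runs of consecutive CDS (gene order; a
   tRNA/rRNA inside a run does not break it) with no RBH partner in the
   paired genome, at least `min_island_genes = 3` long. Unique gene
   content is the primary evidence.
2. **Corroboration** — a segment is reported as an island when at least
   one of: mean window GC z-score `|z| ≥ 2` over its span; a tRNA within
   `flank_dist = 2000` nt of either boundary; a contained product matching
   the recombinase keyword set (`recombinase`, `integrase`, `transposase`,
   `phage`, case-insensitive). All thresholds live in `island_config()`.
3. **Hot spots** — each island maps to its syntenic gap via the nearest
   partnered CDS on each side (the flanking anchor pairs, canonicalized so
   both orientations agree); a gap occupied in both genomes by necessarily
   non-orthologous inserts is a both-occupied hot spot. Contig-edge
   islands lack a defined gap and are excluded from pairing.

GC windows are 5,000 nt every 1,000 nt — wide enough for a stable
composition estimate, narrow enough to resolve a 6-gene island; the
z-score is taken against the genome's own window distribution, and a
zero-variance genome defines `z = 0` everywhere. Reference island counts
in real genome pairs were produced by expert curation, so agreement there
is a tolerance check, not a unit test; the unit-testable claim is recovery
of planted islands (precision and recall ≥ 0.9 at ±2-gene boundary
tolerance in the default simulated world).

## Rank zoning

Empirically, pairs of different named genera fall at AAI 62.9–67.3 and an
ambiguous band at 69.0–74.3 carries both genus- and species-rank pairs;
the lowest printed same-species AAI is 86.3, so the species threshold sits
at 86.0. Values in the gaps (67.3–69.0, 74.3–86.0) receive the nearest
zone's call flagged `low_confidence` rather than an error — AAI genuinely
does not fully discriminate ranks there. A consistency flag marks pairs
where 16S (≥ 99%) and AAI (≥ 86) disagree about species rank. The
classifier is a pure function; a sweep of the axis in 0.1 steps is tested
to hit every class exactly once.

## Module inventory

A gene matches a module symbol when its product string contains the symbol
as a word (case-insensitive). Multi-gene modules are counted as clusters:
matched genes within 5 gene ranks form a cluster, and a cluster counts
when it contains ≥ `min_fraction` of the module's distinct symbols
(1.0 for small operons, relaxed for long pathways where annotation
vocabularies vary). Single-gene rows report plain copy counts. The
shipped table covers the methylotrophy and nitrogen-metabolism module set;
expert-curated special cases (a lone NorB subunit, laterally transferred
extra pqqDE copies) are noted in the table but not automated.

## The simulator: what it emulates, what it does not

`simulation_config()` states the world once: 600 genes (desk-scale stand-in
for ~2,500-gene, 2.5–3 Mb genomes; a paper-scale run is just `n_genes =
2600`), geometric protein lengths around 300 aa (min 50), host GC 0.45
(mid-range of 0.42–0.55), per-branch amino-acid substitution probability
0.05, one tRNA per 50 genes, spacers 50–300 nt, ten planted islands of
6–40 genes with `|ΔGC| ≥ 0.06` at tRNA sites (half carrying a
recombinase), two 1–2-gene losses per descendant. Substitutions are
applied at the amino-acid level and back-translated through codon weights
solved (by root-finding on a one-parameter exponential tilt) to hit the
target GC, so AAI truth is exact while the GC signal stays clean.
Unchanged genes keep their ancestral nucleotides: zero divergence with no
events reproduces the ancestor byte-for-byte. Island content is novel
random sequence, matching the unique-gene evidence definition.

Deliberately not emulated: codon-usage bias, within-gene indels,
rearrangements/inversions, horizontal transfer of *homologous* genes, and
rRNA operon multiplicity. A green recovery test therefore establishes
that the pipeline finds what its evidence model defines — not that the
evidence model captures every real island (e.g. an ancient island with
ameliorated GC and no retained integrase would be missed by design unless
tRNA-adjacent).

## Numerical and engineering choices

- Internal coordinates are 0-based half-open; GFF3 converts at the I/O
  boundary only. Ambiguous bases are excluded from both numerator and
  denominator of GC. Translation uses bacterial code table 11, terminal
  stop trimmed, fuzzy codons as `X`.
- rRNA "operon" counts use 16S features as the proxy.
- All randomness flows from a single integer seed; bootstrap replicates
  and simulator stages use fixed offsets, so results are identical across
  runs and platforms, and pipeline reruns are byte-identical.
- Pipeline configs serialize to JSON (the environment provides no YAML
  parser); the output directory carries the config echo, a manifest with
  completion state, and a run log.
- 16S identity uses end-gap-free (overlap) alignment, match 5/mismatch −4,
  identity over aligned columns excluding terminal gaps; sequences under
  500 nt warn as partial genes but are still compared.

## Known limitations

- RBH + components is not Markov clustering; on real proteomes the SCGO
  set can differ by a few families from an OrthoMCL-based count, so
  external-data comparisons carry tolerance.
- The island caller is pairwise by construction; it cannot call islands
  in a genome without a comparator, and shared (orthologous) mobile
  content is invisible to it.
- NJ topology at deep divergence is not a substitute for ML; export the
  PHYLIP + partitions and rerun externally when branch support matters.
- The identity of co-optimal alignments is not unique; identity/coverage
  of a hit can differ between exact aligners by a column or two, which
  only matters within a hair of a threshold.
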