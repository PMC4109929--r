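# ecotypeR

Comparative genomics of closely related bacterial genomes, built for the
situation where a panel of newly sequenced isolates from one environment
must be resolved into ecotypes: lineages that look nearly identical by 16S
rRNA yet differ in gene content and niche-relevant metabolism.

The package implements the full desk-side analysis chain:

- **AAI** — genome-wide average amino-acid identity over reciprocal-best-hit
  (RBH) protein pairs, with exact Smith–Waterman alignment (BLOSUM62,
  affine gaps 11/1) instead of a heuristic search engine. For a pair of
  proteomes *A*, *B*, qualifying RBH pairs (identity ≥ 30%, both proteins
  covered ≥ 70%) give `AAI = mean(pct_identity)`.
- **Phylogenomics** — ortholog families as connected components of the
  thresholded RBH graph (50% identity / 70% coverage) plus in-paralog
  edges; single-copy-per-genome ortholog (SCGO) selection; deterministic
  progressive alignment; concatenation with partition bookkeeping; neighbor
  joining on Poisson-corrected distances (`d = −ln(1 − p)`); nonparametric
  bootstrap by column resampling. PHYLIP + partition export lets you rerun
  the concatenated alignment through external maximum-likelihood software.
- **Taxonomic-rank zoning** — classification of genome pairs from AAI
  crossed with 16S identity: same species at AAI ≥ 86, an ambiguous
  genus/species band at 69.0–74.3, different named genera at 62.9–67.3.
- **Genomic islands and hot spots** — an algorithmic version of the classic
  manual procedure: maximal runs of genes without an RBH partner in the
  paired genome, corroborated by sliding-window GC deviation (z-score
  against the genome's own window distribution), flanking tRNA integration
  sites, or internal site-specific recombinase/integrase annotations;
  syntenic gaps occupied by different inserts in both genomes are reported
  as recombination hot spots.
- **Metabolic-module inventory** — methylotrophy and nitrogen-metabolism
  modules (methanol/methylamine oxidation, PQQ biosynthesis, H4MPT and RuMP
  formaldehyde handling, formate dehydrogenases, denitrification steps,
  GS/GOGAT) counted from product annotations as gene clusters.
- **Simulator** — genome pairs with known divergence, planted GC-shifted
  islands at tRNA sites, gene losses and duplications, emitting ground
  truth for end-to-end recovery tests.

## Worked example

```r
library(ecotypeR)

cfg  <- simulation_config(seed = 7)            # 600 genes, 10 planted islands
pair <- evolve_pair(simulate_ancestor(cfg), cfg)
pa <- extract_proteome(pair$genome_a)
pb <- extract_proteome(pair$genome_b)

compute_aai(pa, pb)
#> AAI A vs B: 90.38% over 593 RBH pairs (sd 2.19)
pair$truth$expected_aai                        # simulator's own counting oracle
#> [1] 90.28202

rbh <- reciprocal_best_hits(pa, pb, min_identity = 30, min_cov = 0.70)
ia  <- call_islands(pair$genome_a, pair$genome_b, rbh)
ib  <- call_islands(pair$genome_b, pair$genome_a, swap_rbh(rbh))
nrow(ia); nrow(ib)
#> [1] 5
#> [1] 5
evaluate_recovery(ia, pair$truth)[c("precision", "recall")]
#> $precision [1] 1
#> $recall    [1] 1

classify_pair(compute_aai(pa, pb))
#> RankCall: AAI 90.4 -> same_species
```

The AAI lands within 0.11 of the simulator's realized truth; all five
planted islands per genome are recovered exactly; an AAI of 90.4 falls in
the same-species zone.

For a full run (AAI + 16S matrices, SCGO tree with bootstrap, island and
hot-spot tables, inventory, rank calls):

```r
run_pipeline(pipeline_config(list(pair$genome_a, pair$genome_b), seed = 1), "out/")
```

## Layout

- `R/` — implementation; `src/` — affine-gap alignment engine (Rcpp)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/ecotype-genomics.Rmd` — methods notes: model, parameters,
  defaults, what the simulator does and does not emulate
- `inst/extdata/metabolic_modules.tsv` — shipped module definitions
- `inst/cli/ecotyper.R` — command-line entry point (simulate / run-all)
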