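# regulonet

Headless R toolkit for two everyday jobs in comparative systems biology and
bacterial regulatory genomics:

1. **Synchronous multi-network selection.** Load several interaction
   networks (SIF, XGMML, or a zipped session archive) into one *session*
   where nodes are identified by a **shared name** (gene symbol, locus tag).
   A selection made in one network propagates to all others — through
   user-supplied many-to-many identity maps (e.g. human↔mouse homologs) if
   the name spaces differ — and exports as a flat file. Per-node
   differential topology (degree, local clustering coefficient
   `C_v = 2e_N / (k_v(k_v-1))`, connected components, exclusive edge sets)
   supports condition-vs-condition network comparison.

2. **Regulatory motif exploration.** Starting from a gene selection and a
   GenBank genome: extract upstream regions, discover motifs under a ZOOPS
   (zero-or-one occurrence per sequence) EM model, scan the whole genome
   with each position weight matrix against an order-3 Markov background
   (exact DP p-values, Benjamini–Hochberg q-values with *m* = scored
   windows), reject occurrences inside genes, aggregate intergenic hits per
   downstream gene with hit counts, and — because genes the scan implicates
   but the discovery never saw are flagged with a `-1` index — iteratively
   expand the selection until the top of the table is free of `-1`: the
   fixed point is the inferred regulon.

Deterministic synthetic generators (planted-motif genomes with GenBank
output, homologous network pairs) make every stage testable offline; all
analyses are pure functions of their inputs and a seed.

For the model details, parameter rationale and known limitations, see the
methods vignette (`vignettes/regulonet-methods.Rmd`).

## Worked example: recovering a planted regulon

A 30-gene synthetic genome, a 14-nt palindromic motif planted upstream of 12
genes (5% per-base mutation), and expansion started from only half of them:

```r
library(regulonet)
g0 <- generate_genome(30, gene_len = 300, intergenic_len = 200, seed = 77)
regulon <- g0$genes$locus_tag[seq(1, 23, 2)]              # 12 true regulon genes
pl <- plant_motif(g0, planted_motif_spec(regulon = regulon), seed = 78)

state <- expand_regulon(pl$genome, regulon[1:6], nmotifs = 1, seed = 42)
state
#> <exploration: 14 genes after 2 expansion round(s), converged>
state$history
#> [1]  6 13 14
consensus(state$motifs[[1]]$pwm)
#> [1] "AGGGNCTTAAGTCCCN"
head(state$tables$m1[, c("downstream_gene", "sequence", "index_downstream",
                         "pvalue", "hit_count", "relative_position")], 6)
#>   downstream_gene         sequence index_downstream       pvalue hit_count relative_position
#> 1           g0009 AGGGACTTAAGTCCCC                1 2.301519e-10         2               -37
#> 2           g0001 AGGGACTTAAGTCCCA                2 6.956939e-10         2               -98
#> 3           g0021 TGGGACTTAAGTCCCC                3 1.155998e-09         2               -97
#> 4           g0019 AGGGCCTTAAGTCCCC                4 1.611122e-09         2               -39
#> 5           g0015 AGGGCCTTAAGTCCCT                5 2.767120e-09         2               -59
#> 6           g0011 TGGGACTTAAGTCCCG                6 3.457576e-09         2               -99
all(regulon %in% state$selection)
#> [1] TRUE
```

Reading the output: the discovered consensus contains the planted word
`GGGACTTAAGTCCC`; the expansion grew the selection 6 → 13 → 14 and stopped
*converged*, i.e. every downstream gene in the top of the best motif's table
now carries a non-negative index into the discovery input. The final
selection covers all 12 planted genes (plus two background hits the scan
also implicated). `hit_count = 2` because the planted word is palindromic,
so every site matches on both strands and the duplicate merges into its
gene's row; `relative_position` is the site's offset from the downstream
gene's start (negative = upstream).

The same loop runs from the shell:

```sh
regulonet simulate genome --n-genes 30 --regulon-size 12 --seed 77 --out sim/
regulonet regulon --genbank sim/genome.gbk --genes my_selection.txt \
    --iterate --top-k 20 --seed 42 --out results/
```

and the network side:

```sh
regulonet select --sif human.sif,mouse.sif --map homologs.tsv \
    --names selected.txt --out out/
regulonet metrics --sif human.sif,mouse.sif --out metrics.tsv
```

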