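---
title: "regulonet: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regulonet: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

regulonet couples two work flows that share one identity convention. On the
network side, interaction networks imported from SIF or XGMML live in a
*session*; nodes are identified by their **shared name**, and a selection made
in one network is propagated to all others by intersecting the closure of the
selected names — under any registered homolog maps — with each network's node
set. On the sequence side, a gene selection (typically exported from such a
session as a flat file) seeds a motif-exploration loop on a bacterial genome:
upstream regions are extracted, motifs are discovered de novo, the genome is
scanned with each motif, intergenic occurrences are aggregated per putatively
regulated gene, and genes that the scan implicates but the discovery input
lacked are fed back in until the gene list is self-consistent.

# Selection propagation

A selection is a set of shared names. Propagation computes the transitive,
symmetric closure of that set under all identity maps (a↔b plus b↔c selects
c) and then intersects with each network. Closure semantics is this package's
contract: it matches what a user chaining homolog tables expects, and it makes
the idempotence, symmetry and monotonicity properties provable. Matching is
exact and case-sensitive by default. That is deliberate: human and mouse
symbols often differ only by case (SOCS3 vs Socs3), and silently folding case
would make results indistinguishable from "a homolog map is loaded". An
explicit `ignore_case` flag exists for identifier spaces where case is noise.

Mapping files are two-column delimited text. A header row is skipped only
when its two cells equal the declared space labels case-insensitively;
anything else on the first line is treated as data, so headers can never be
silently eaten as gene names or vice versa.

# Topology metrics

`node_metrics()` works on the undirected simple view: parallel edges are
collapsed and self-loops dropped, because the differential-association use
case (which edges exist under condition A but not B) is about the presence of
an association, not its multiplicity or direction. Degree is neighbour count;
clustering is `2 e_N / (k(k-1))` with 0 assigned below degree 2; components
come from the usual union of paths, with isolated nodes forming singleton
components. Edge identity in `exclusive_edges()` is the unordered name pair,
ignoring interaction labels, for the same reason.

# Genome handling

Coordinates are 0-based half-open internally; GenBank's 1-based inclusive
convention appears only at the flat-file boundary, and `complement(...)`
locations get strand −1. Upstream extraction takes, for a forward-strand
gene, `[max(0, start − L), start)` read forward, and the mirror image
reverse-complemented for a reverse-strand gene, so returned sequences always
read 5′→3′ toward the start codon.

Two parameters matter here:

* **Upstream window, default 300 nt.** The source narrative never states the
  window MEME saw; 300 nt is a standard bacterial promoter window (σ-factor
  and TF sites concentrate within a few hundred bases of the start).
* **Neighbour truncation, default on.** Regions are clipped so they never
  overlap another annotated gene. Discovering "motifs" inside coding
  sequence would contradict the scan stage's genic-rejection rule, so the
  discovery input is held to the same standard. Both behaviours are exposed
  because the original analysis may have used fixed-length windows.

The Markov background is estimated from (k+1)-mer counts on **both strands**
(matching the strand-symmetric scanner), order 3 by default, with a
pseudocount of 0.1 per cell so all 4^k contexts exist. Windows containing N
are excluded from counting.

# Motif discovery (ZOOPS EM)

The model: each input sequence contains zero or one site of width w. With
site prior γ (re-estimated every M-step and clamped to [0.001, 0.999]), the
likelihood of sequence t is

    (1 − γ) · bg(t)  +  (γ / (2 m_t)) · Σ_{i,strand} site(i, strand)

where m_t is the number of windows and the site term scores the window under
the PWM and the rest under the background. All LLRs quoted by the package
are against the background-only model.

Numerical and procedural choices:

* **Seeding.** Every input w-mer is a candidate seed, subsampled
  deterministically by stride to at most 500. Seeds are first ranked by the
  LLR of their own alignment (one E pass); the top 20 receive one full EM
  step; the best of those is refined until the LLR gain drops below 1e-4 or
  200 iterations. Determinism: no randomness anywhere in seeding or EM.
* **Seed sharpness 0.7.** A seed PWM puts probability 0.7 on the observed
  base. Sharper seeds converge to the planted optimum in fewer steps;
  flatter ones blur neighbouring seeds together.
* **Pseudocounts.** M-steps add 0.1 (background-weighted) to expected
  counts; log-odds scoring adds 0.01 per cell. Both merely avoid −∞.
* **Erasure.** After a motif is accepted, each position's erase weight is
  multiplied by one minus the posterior of every accepted-motif window
  covering it; subsequent searches weight windows by the product over their
  positions. This is the standard probabilistic erasure that lets a second
  motif be found without rediscovering the first.
* **E-values by shuffling.** The motif E-value is `(x + 1) / n_shuffles`,
  where x counts composition-preserving shuffles of the input whose best
  re-searched single motif of the same width reaches the observed LLR
  (20 shuffles by default, seeded). The null search uses a reduced profile
  (100 seeds, 30 refinement iterations): the null optimum is broad and flat,
  so a shallower search estimates it well at a tenth of the cost; the
  observed statistic always comes from the full search. A real motif gets
  the minimum 0.05; a motif indistinguishable from shuffled input gets ≥ 1.
* **Width selection.** Candidate widths (8–20 nt, even) are searched
  independently; the lowest E-value wins. Because the Monte-Carlo E-value
  has granularity 1/20, ties are frequent and are broken by a BIC-penalized
  LLR, `LLR − (3/2) w log n`: raw LLR always prefers the widest candidate
  (uninformative flanking columns still overfit a little), whereas the
  penalty per column is exactly the expected overfit of three free
  parameters. This is the one place the package deviates from "largest
  likelihood wins".

What a green planted-motif test establishes: that EM recovers a strongly
planted, length-matched consensus from uniform-background sequences. It does
not establish performance on real promoters, whose backgrounds are skewed,
whose sites vary in information content, and whose regulons are partially
overlapping.

# Scanning, p-values and q-values

Scan scores are integer-scaled log2-odds (`round(1000 · log2(p/bg))`) against
the background's **order-0 marginal**. P-values are exact: a position-wise
dynamic-programming convolution yields the full null distribution of the
integer score, and the reported p-value is the tail at the observed score.
Using the order-0 marginal (rather than the order-3 conditionals) keeps the
null a product measure, which is what makes the DP exact and lets a 4^w
enumeration verify it to 1e-12. The order-3 model still shapes the analysis
through background estimation and the synthetic generator.

Q-values are Benjamini–Hochberg step-up with the number of tests `m` set to
the number of scored windows on both strands — not the number of reported
occurrences — so q-values are invariant to the report threshold (default
p ≤ 1e-4, the conventional scanner default; the source narrative states
none). Windows containing N are not scored and not counted.

# Aggregation and regulon expansion

Occurrences overlapping any gene by ≥ 1 nt, on either strand, are rejected —
the strictest reading of "within a known gene", chosen to avoid boundary
artifacts. Each surviving occurrence is assigned a **downstream gene**: the
flanking gene it faces (the site lies 5′ of that gene's start on the gene's
strand). For divergent flank pairs the nearer start wins; for convergent
pairs the nearer gene; missing flanks at contig edges yield NA. The first
(best-p) occurrence per downstream gene creates its table row; later ones
only increment the hit count, so hit counts conserve the number of assigned
occurrences. Distinct sites upstream of the same gene are therefore merged
into one row — the source leaves this open, and one-row-per-gene is what the
index bookkeeping needs.

The index columns locate the downstream/upstream gene in the discovery
stage's score-ordered per-sequence list; −1 flags genes the discovery never
saw. Expansion adds all −1 genes among the top-k rows (k = 20 by default;
"the top hits" is otherwise unquantified) of the best motif's table, then
reruns the pipeline with the same seed and a cached background (it depends
only on the genome). Convergence means a top-k window free of −1; the
selection grows monotonically and the loop is bounded by `max_iter`.

# Synthetic data

The generators are pure functions of (parameters, seed) with a private RNG
stream. `generate_genome()` lays out genes and intergenic spacers
alternately (default 300/200 nt — compact, bacterial-like) with random
strands. `plant_motif()` writes one instance per regulon gene on the gene's
sense strand, entirely intergenic, at 20–100 nt from the gene start. The
offset cap of half the spacer keeps sites promoter-proximal, as real
bacterial TF sites are, and guarantees that a planted site is nearer its own
gene's start than any divergent neighbour's — without that, the facing rule
would occasionally assign the neighbour and the generator's own ground truth
would be wrong by construction. The documented strong-planting acceptance
profile is 20 regulon genes, 200-nt spacers, per-base mutation rate 0.05.
The default planted word, GGGACTTAAGTCCC, is a 14-nt palindrome of the kind
dormancy-regulator binding sites exhibit; being palindromic it matches both
strands at every site, which exercises the hit-count merging path.

Not emulated: operon structure, overlapping genes, GC skew, heterogeneous
site strength. Green end-to-end tests therefore certify the machinery, not
biological recall on real genomes.

# Command line and reproducibility

The CLI mirrors the R API (`import`, `select`, `metrics`, `regulon`,
`simulate`). Options may come from a JSON config file with precedence
flags > config > defaults; JSON stands in for YAML because no YAML parser is
available in the supported dependency set. Outputs are written atomically
(temp file + rename), never embed wall-clock data, and a run manifest echoes
the effective parameters, so identical inputs and seed give byte-identical
outputs; timestamps appear only in stderr logs.

# Known limitations

* Single-record genomes only; plasmids are separate runs.
* Compound (join) GenBank locations are skipped with a warning.
* The Monte-Carlo E-value floor is 1/n_shuffles; motifs cannot be ranked
  below that resolution except through the penalized-LLR tie-break.
* The scanner's p-values assume positional independence under the order-0
  marginal; order-3 conditioning of window scores is not implemented beyond
  background estimation.
* Session-archive import recognizes any zip member that parses as XGMML;
  archives whose networks are stored in other serializations are not
  supported.
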