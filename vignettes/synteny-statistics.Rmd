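---
title: "Synteny conservation and gene colinearity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny conservation and gene colinearity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenica)
library(dplyr)
```

## The problem

When two related genome assemblies are compared gene by gene, two distinct
levels of conservation must be separated. *Synteny* is conservation of gene
content between homologous chromosomes or chromosomal segments: orthologs of
the genes on one scaffold tend to sit together on one (or a few) scaffolds of
the other species, regardless of their order. *Colinearity* is conservation
of gene order within such segments. Compact genomes of unicellular green
algae turn out to separate these two levels sharply — scaffold-level gene
content can be well conserved while the order of genes within scaffolds is
almost completely reshuffled, the signature expected when intra-chromosomal
rearrangements (inversions, transpositions) outpace inter-chromosomal ones
(translocations, fusions, fissions). syntenica implements the statistics
that quantify both levels, their randomization null models, and a genome-pair
rearrangement simulator that generates data with known ground truth so every
claim the statistics make can be tested.

## Orthology: reciprocal best hits

The substrate of every statistic is a one-to-one ortholog map. From two
all-vs-all protein similarity tables (BLAST tabular layout, directions
A→B and B→A), `reciprocal_best_hits()` pairs genes *g* and *h* when *h* is
*g*'s highest-bitscore hit and *g* is *h*'s. Ties are broken by lower
e-value, then lexicographically smaller subject identifier; the ordering is
fixed so results are identical across platforms. No score threshold is
applied by default — the criterion is reciprocity, and genes without a
reciprocal best hit simply remain unpaired — but `min_bitscore` and
`max_evalue` filters are available. Duplicate (query, subject) rows in the
input collapse to the highest-scoring record at ingestion.

## The synteny correlation

Let scaffold *i* of species A share $n_{ij}$ ortholog pairs with scaffold
*j* of species B, with row totals $n_{i\cdot}$, column totals $n_{\cdot j}$
and grand total $n$. Under independent scattering of orthologs the expected
count is $e_{ij} = n_{i\cdot} n_{\cdot j} / n$. The synteny correlation of
Housworth and Postlethwait is the chi-square-derived association measure

$$\rho \;=\; \sum_{i=1}^{r}\sum_{j=1}^{c}
  \frac{(n_{ij} - e_{ij})^2}{n\,\min\{r-1,\,c-1\}\;e_{ij}},$$

which equals 0 exactly at independence and 1 at perfect association — every
row and every column carrying a single nonzero cell — whatever the block
sizes. It is invariant under row and column permutations, so scaffold
naming and ordering are irrelevant.

Two numerical points. First, scaffolds with no mapped ortholog would give
$e_{ij} = 0$ and an undefined term; they carry no orthology information and
are dropped, with $r$ and $c$ shrinking accordingly (fewer than two
informative scaffolds on either side leaves the statistic undefined and
raises an error rather than returning a number). Second, the sum is
evaluated as $\chi^2 = n \sum_{ij} n_{ij}^2/(n_{i\cdot} n_{\cdot j}) - n$,
algebraically identical but exact in floating point for integer counts at
perfect association, so a genome pair differing only by within-scaffold
rearrangements reports $\rho = 1$ exactly, not $1 - 10^{-16}$.

## Null models and Z-scores

Two distinct randomizations serve as the "non-syntenic model", and they are
deliberately different:

* **Re-association null** (for $\rho$ and the pairwise scaffold Z-scores):
  the genome-B members of the ortholog pairs are permuted uniformly among
  the pairs (`randomize_ortholog_assignment()`). Every gene keeps its
  scaffold, so the number of orthologs per scaffold — all contingency
  marginals — is conserved by construction; only the pairing is destroyed.
* **Gene-order reshuffling null** (for CPAO counts): the order of *all*
  genes, orthologs and non-orthologs alike, in one genome is permuted
  genome-wide, keeping per-scaffold gene counts fixed. This preserves the
  scaffold assignment structure of the contingency table while destroying
  adjacency, which is exactly what a colinearity null must do.

For each statistic the null mean and standard deviation are estimated from
`replicates` randomized datasets (default 1,000, configurable) and reported
with $z = (\mathrm{observed} - \mathrm{null\ mean})/\mathrm{null\ sd}$. The
population (divide-by-$R$) standard deviation is used, so repeated runs with
the same seed are bit-reproducible. A pair whose count is constant under the
null (for example, the single cell of a one-scaffold-versus-one-scaffold
comparison) has null sd 0; its Z is reported as *undefined*, never as 0 or
infinity. The significance convention used throughout is one-sided:
$z > 3$ marks counts significantly *higher* than the non-syntenic model,
corresponding to a normal-tail probability below 0.01. Every stochastic
result records its seed and replicate count.

## Conserved pairs of adjacent orthologs (CPAOs)

A CPAO is an unordered pair of genes adjacent in genome A — consecutive
ordinals on the same scaffold — both carrying orthologs, whose orthologs
are adjacent in genome B. Orientation and strand are ignored (an inverted
but intact segment conserves its internal adjacencies), adjacency never
spans a scaffold boundary, and each pair counts once; the count is symmetric
in the two genomes. Adjacency is computed over *all* annotated genes by
default, so an unpaired gene sitting between two orthologs breaks their
adjacency. This is the stricter, more literal reading of "adjacent genes";
because reasonable implementations differ here, an
`adjacency_mode = "orthologs_only"` variant that ranks only mapped genes is
provided, and the mode is echoed in every result.

On genomes small enough to enumerate every gene-order permutation, the
reshuffling null's Monte-Carlo moments agree with exhaustive enumeration;
this is checked in the test suite with an independent brute-force counter.

## The rearrangement simulator

`simulate_pair()` evolves two genomes from a common simulated ancestor by
applying an `event_plan()` on each branch: inversions (segment reversed,
strands flipped), transpositions (segment moved within its scaffold),
translocations (segment moved to another scaffold, one-way by default —
the simplest operator producing an inter-chromosomal signal), fusions,
fissions, per-gene loss (genes leave the truth map) and gain (genes enter
without orthologs). Segment lengths are geometric in gene units (default
mean 3 genes) — a minimal one-parameter size model, since nothing stronger
is known about true rearrangement sizes. Every event is logged with its
parameters; `replay_events()` re-applies a log deterministically and must
reproduce the derived gene order exactly, which is the simulator's own
correctness oracle in the test suite.

The simulator defines the study conditions for all in-silico checks:
ancestors default to 1,500 bp mean gene length and 3,500 bp mean intergenic
gap (about 5 kb per gene, the density typical of compact green-algal
genomes). Derived coordinates are re-laid out with a fixed intergenic
spacing rather than tracked through breakpoints: every statistic in scope
depends on gene order and scaffold membership only, so exact base-pair
positions after rearrangement carry no information.

`simulate_similarity()` emulates what an RBH criterion actually consumes:
reciprocal top-scoring records for every true pair (bitscores normal around
400), low-scoring background records between random gene pairs (around 80),
and a `confusion_rate` fraction of pairs whose A→B best hit is redirected to
a random decoy — the paralog-confusion failure mode. Each confusion breaks
at most the confused pair itself, so recovery degrades gracefully (about
90% of pairs at 10% confusion).

`simulate_landscape_sequences()` generates i.i.d. scaffold sequence at 53%
GC with planted repeat-cluster segments at 61% GC — the contrast observed
between nested LINE-type retrotransposon clusters and their host genome —
plus tandem telomere-motif arrays at both scaffold ends. Planted clusters
are emitted as BED-style element intervals with sub-merge-gap spacing, and
placement slots keep at least 5 kb between clusters so distinct planted
clusters never merge under the default clustering gap. What the generator
does **not** model: sequence-level divergence between the two genomes (the
similarity table is simulated directly), nested repeat structure beyond
interval placement, real paralog families, assembly gaps, and GC
heterogeneity beyond the planted segments. Passing tests therefore
demonstrate the statistics' behaviour under their own assumptions, not
robustness to every artefact of real draft assemblies.

## Landscape analyses

* `gc_windows()` reports (G+C)/(A+C+G+T) in sliding windows (defaults 10 kb
  window, 2 kb step); N and ambiguity codes are excluded from numerator and
  denominator — draft assemblies contain runs of N — and all-N windows are
  `NA`, not 0.
* `detect_telomere_arrays()` scans the outer 1 kb of each scaffold end for
  gap-free tandem arrays of the telomere motif on either strand, calling an
  end present at 5 or more copies. The default motif is the plant-type
  heptamer TTTAGGG, the natural choice for a green alga, but it is a
  configurable assumption, not an observation. Five tandem heptamers in
  random sequence have negligible false-positive probability (about
  $10^{-17}$ per position), which the suite confirms empirically.
  `telomere_status()` classifies scaffolds with arrays at both ends as
  complete chromosomes.
* `cluster_repeats()` merges same-scaffold repeat intervals separated by at
  most `max_gap` (default 2 kb) and discards clusters spanning less than
  `min_span` (default 1 kb). The defaults are chosen so that the smallest
  biologically reported clusters of the motivating family (1.5 kb) survive;
  both are configurable, and merging is idempotent.
* `summarize_clusters()` classifies a cluster as sub-telomeric when its
  midpoint lies within 5% of scaffold length of either end. A relative rule
  is used because scaffold lengths span more than an order of magnitude; an
  absolute cutoff sensible for a 4 Mb scaffold would swallow a 112 kb one.

## Coordinates and other conventions

All coordinates inside the package are 1-based inclusive — the GFF3 and
R/Bioconductor convention — and BED input/output converts at the boundary.
Gene ordinals are 0-based ranks within a scaffold ordered by start position,
with ties broken by end then gene id; overlapping genes are allowed and
ranked by the same rule. Gene identity comes from a configurable GFF3
attribute (default `ID`) since annotation dialects differ. Dot plots anchor
each gene at its midpoint on cumulative base-pair axes with scaffolds in
decreasing size order; box shading uses the three classes *undefined*,
*z ≤ 3* and *z > 3*.

## Worked example

```{r example}
pair <- simulate_pair(
  plan_b = event_plan(n_inversions = 30, n_translocations = 3),
  n_scaffolds = 6, genes_per_scaffold = 25, seed = 7
)
rho <- synteny_correlation_significance(
  pair$truth, pair$genome_a, pair$genome_b,
  replicates = 500, seed = 8
)
rho
cpao <- cpao_significance(
  pair$truth, pair$genome_a, pair$genome_b,
  replicates = 500, seed = 9
)
cpao
```

Thirty inversions leave almost all orthologs on their ancestral scaffolds,
so $\rho$ stays near 1 while the CPAO count falls far below the
$6 \times 24 = 144$ of a perfectly colinear pair — conserved synteny with
poor gene colinearity. Both statistics remain far above their nulls.

```{r dotplot, fig.width = 6, fig.height = 6}
z <- scaffold_pair_significance(
  pair$truth, pair$genome_a, pair$genome_b,
  replicates = 500, seed = 10
)
plot_dotplot(pair$truth, pair$genome_a, pair$genome_b, z)
```

## Problem sizes and runtime choices

The test suite and the acceptance script run entirely on simulated data at
deliberately modest sizes: genomes of 3–10 scaffolds with 8–60 genes each,
null models at 150–4,000 replicates, exhaustive CPAO enumeration at 6 genes
(720 permutations), and false-positive calibration over 10,800 scaffold-pair
null replicates. These sizes were chosen so that Monte-Carlo standard errors
are small relative to every tested effect; all statistics scale linearly in
replicates and in map size, and the defaults (1,000 replicates) are intended
for genome-scale use.

## Known limitations

The package computes scaffold-level statistics, not synteny block
coordinates: there is no segmentation or chaining of colinear runs. Only
pairwise (two-genome) comparisons are supported. The RBH criterion yields
one-to-one pairs and cannot represent many-to-many ortholog families;
lineage-specific duplications will leave one copy unpaired. The synteny
correlation is undefined for single-scaffold genomes, and Z-scores are
Monte-Carlo estimates whose precision is governed by the replicate count —
with 1,000 replicates, tail probabilities much below $10^{-3}$ are
extrapolations of the normal approximation rather than measured quantities.
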