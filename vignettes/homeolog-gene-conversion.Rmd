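---
title: "Detecting homeologous gene conversion from colinear quartets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homeologous gene conversion from colinear quartets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoconv)
```

## The problem and the model

Allopolyploid genomes such as hexaploid bread wheat (AABBDD) carry two or
three homeologous copies of most genes, one per subgenome.  The copies are
similar enough that illegitimate recombination between homeologous
chromosomes occasionally overwrites one copy with the sequence of the
other — gene conversion, with a *donor* (the template) and an *acceptor*
(the overwritten copy).  Conversion leaves a phylogenetic fingerprint.
For a gene with copies on subgenomes X and Y, and orthologs in the extant
diploid (or tetraploid) relatives of the X and Y progenitors, the four
sequences form a quartet with an expected unrooted topology

```
(out_x, hex_x | out_y, hex_y)
```

each polyploid copy siding with its own progenitor's ortholog, because the
progenitor lineages diverged millions of years before the polyploid
formed.  A converted pair instead shows the aberrant topology

```
(hex_x, hex_y | out_x, out_y)
```

the two homeologs anomalously similar to each other.  `homeoconv`
implements this inference end to end:

1. **Colinearity** — homologous colinear (synteny) blocks between each
   genome and a chosen reference genome are detected by
   dynamic-programming chaining of protein homology hits over gene ranks,
   and scored by a rank-permutation test.
2. **Quartets** — blocks against the shared reference are stacked into a
   reference-anchored alignment table (one row per reference gene, one
   column per genome); every row whose four role cells are filled yields a
   quartet.  Self-comparison blocks of one subgenome yield ancient
   within-subgenome paralog quartets instead.
3. **Conversion calling** — each quartet's proteins are aligned, filtered,
   and classified by the neighbor-joining split of their distance matrix
   with bootstrap support; donors are assigned from cross distances;
   Nei–Gojobori Ks/Ka annotate each call.
4. **Summaries** — per-comparison conversion counts, percentages and donor
   splits, ortho-group support of colinear pairs, and hypergeometric
   (Fisher exact) GO enrichment of converted genes against the colinear
   background.
5. **Synthetic data** — a simulator of the whole genome panel with known
   conversion truth, so every stage is testable without real genome
   downloads.

## Colinear block detection

Hits are first restricted to E-value $\le 10^{-5}$.  Within a chromosome
pair, hit $(i, j)$ may extend hit $(i', j')$ in a chain when both rank
differences lie in $(0, G+1]$ with $G$ = `max_gap` (default 50 intervening
non-colinear genes); for antiparallel blocks the second-genome ranks must
decrease.  Chain score is the number of pairs — a block is a run of
colinear *genes*, so no bitscore weighting — and chains shorter than
`min_block_genes` (default 5) are discarded.  Blocks are extracted
greedily by descending chain length so that each hit pair belongs to at
most one block; the deterministic tie-break scans chain endpoints in rank
order.  Tandem arrays are collapsed before chaining: among hits from one
gene to a run of near-adjacent genes (rank gaps $\le$ `tandem_window`,
default 1), only the best bitscore survives, preventing single-gene
fan-outs from inflating chains.

Significance is a within-chromosome permutation test: the second genome's
ranks on the block's chromosome are shuffled, the best chain length on the
chromosome pair (either orientation) is recomputed, and the add-one
smoothed tail probability

$$p = \frac{1 + \#\{\text{permutation best} \ge n_\text{pairs}\}}{1 + n_\text{perm}}$$

is reported.  This realises the same null (random gene order) as the
analytic block statistics used by classical synteny tools, is exactly
reproducible under a seed, and never returns 0.  Blocks with $p \le 0.05$
enter the alignment table.

## The alignment table and quartets

The table has one row per reference gene in rank order.  When overlapping
blocks of one genome claim the same reference gene — or one subject gene is
claimed by two rows — the pair from the block with the smaller p-value wins,
then the larger block, then the lexicographically smaller block id.  Rows
with any gap in the four role columns are skipped entirely: triplets with
one lost gene are not called, because the topology test needs all four
leaves.  For comparisons lacking a diploid outgroup (the B lineage), a
tetraploid subgenome fills the outgroup role; the wiring is a
`comparison_spec`, not hard-coded taxa.

## Conversion calling

**Alignment.** Quartets are aligned with an internal progressive aligner
under fixed parameters (BLOSUM62, affine gaps: open 10, extend 0.5 per
residue): six global pairwise alignments choose the most similar pair as
the first join, the remaining two sequences form the second profile, and a
profile–profile merge completes the four-way alignment.  Column scores are
mean substitution scores over row pairs with gap–residue contributing 0.
An internal aligner rather than an external multiple-alignment binary
keeps runs byte-reproducible; externally produced alignments can be
imported via `quartet_alignment()`.  The CDS is threaded codon-by-codon
through the protein alignment.

**QC.** An alignment is discarded (`filtered`) when any sequence has more
than `max_gap_fraction` (default 50%) gap sites, or when the *minimum* of
the six pairwise amino-acid identities is below `min_identity` (default
40%).  Taking the minimum is the strictest reading of the identity rule;
identity counts matches over columns where both sequences are non-gap.

**Topology.** Distances are p-distances by default (`"poisson"` applies
$-\ln(1-p)$, capped at $p = 1 - 10^{-6}$ with a warning).  The NJ split is
the first join of the neighbor-joining Q-criterion, which for four taxa
coincides with the four-point-condition minimizer of
$d(i,j) + d(k,l)$ over the three pairings — the test suite checks this
equivalence against an independent enumeration oracle and against
`ape::nj`.  Exact ties are flagged and broken toward the split containing
the lexicographically smallest role pair, but a tied quartet is never
called converted.

**Support and calling.** Bootstrap support resamples alignment columns
with replacement (alignment-length draws, default 1000 replicates,
200 in the validation runs for speed) and counts replicates whose untied
split equals the observed one; tied replicates count as unsupported, so
four identical sequences get support 0.  The expected split gives status
`expected`; the homeolog split with support strictly greater than
`min_support` (default 0.70) gives `converted`; everything else — low
support, the outgroup-crossing split, ties, an undetermined donor — is
`unresolved`.  Calls are made on protein distances; Ks is an annotation,
not a calling criterion.

**Donor.** The acceptor was overwritten by the donor, so it resembles the
donor's outgroup ortholog: donor = hex_x when
$d(\text{hex}_y, \text{out}_x) < d(\text{hex}_x, \text{out}_y)$, and
vice versa; exact equality downgrades the call to `unresolved`.

**Ks/Ka.** Nei–Gojobori counting: per-codon synonymous site fractions
averaged over the two sequences, observed differences averaged with equal
weight over all substitution orders of multi-difference codons (pathways
through stop codons are excluded; if every pathway passes through a stop,
all are used), changes to stop codons counted as nonsynonymous, and the
Jukes–Cantor correction $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ with
$p \ge 3/4$ reported as saturated (NA).  Codon columns containing any gap
are dropped first.

## Summaries

Percentages are rendered half-away-from-zero at two decimals, matching
the convention of published conversion tables (note one well-known printed
value, 253/12,770 shown as 1.99%, recomputes to 1.98% under any standard
rounding; the recomputed value is reported).  GO enrichment uses the
two-sided Fisher exact test — for a fixed-margin 2×2 table this *is* the
hypergeometric tail — with raw p-values as the headline output and a
clearly labelled Benjamini–Hochberg column as an extension.  The
enrichment background is a parameter (typically all colinear genes, or
one subgenome's colinear genes for per-subgenome spectra).

## The simulator and what passing tests mean

`simulate_dataset()` emulates the wheat panel: a reference diploid (Dd), a
diploid outgroup (Ad), a tetraploid subgenome (Bt) and three hexaploid
subgenomes (Ah, Bh, Dh), with colinear gene order, lineage-specific
substitutions, sparse gene loss, and imposed whole-gene conversions with
known truth.  Key choices:

* **Substitution process** — Poisson number of events per sequence,
  uniform site, uniform alternative base (Jukes–Cantor-like); events
  creating stop codons are rejected and redrawn.  The expected fraction of
  changed sites at branch length $b$ is $\tfrac{3}{4}(1 - e^{-4b/3})$.
  This is deliberately simple: it creates exactly the distance contrasts
  the topology test consumes, nothing more.
* **Divergence scales** — defaults `deep_divergence = 0.3` (between the A,
  B, D progenitor lineages, million-year scale),
  `shallow_divergence = 0.02` (outgroup vs polyploid copy) and
  `post_conversion_divergence = 0.005`, encoding the separation between
  progenitor divergence (millions of years) and polyploid formation
  (thousands of years) that makes the inference reliable.
* **Conversion model** — whole-gene: the acceptor is overwritten by the
  contemporary donor sequence at the polyploid-formation point, then both
  copies accrue `post_conversion_divergence` independently.  Tract-level
  (partial-gene) conversion, indels, transposons and recombination
  hotspots are not modelled.  Events are imposed on the Ah–Dh homeolog
  pair of the canonical quartet with `donor_bias = 0.62` toward the Dh
  copy; the other genomes exercise the remaining comparisons.
* **Gene length** — `codons_per_gene = 400`, the typical plant CDS length
  (~1.2 kb).  This matters: discrimination of the aberrant from the
  outgroup-crossing topology rests on the handful of sites mutated on the
  acceptor-side terminal branches, whose expected number scales with gene
  length.  Short genes (≲100 codons) are intrinsically underpowered at
  these divergences — on real data, short or fast-evolving genes will
  likewise yield `unresolved` calls rather than false positives.
* **Homology hits** are emitted from known common ancestry with identities
  computed from the simulated proteins, not recomputed by an aligner —
  running BLAST is out of scope, its tabular output is the consumed
  interface.

The validation suite recovers imposed conversions on 500 loci at the
divergences above (200 bootstrap replicates, 200 permutation replicates):
sensitivity and donor accuracy ≥ 0.95, false-call rate ≤ 0.01 on
non-converted loci, and a recovered donor split within binomial bounds of
the configured bias.  Passing these tests shows the machinery is correct
and well calibrated *for this generative model*; it does not certify
performance on real genomes, where unequal rates among lineages,
alignment error from indels, partial-gene conversion tracts, and
reference-annotation artifacts all add noise that the simulator
deliberately omits.

## A small worked example

```{r example}
cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 40,
                  codons_per_gene = 120, gene_loss_rate = 0.02, seed = 5)
params <- pipeline_params(bootstrap_replicates = 100, seed = 5)
res <- run_pipeline(cfg, params, n_permutations = 100)
res$summary
str(res$truth_scores)
```

## Known limitations

* Conversion is called per whole gene; tract boundaries within genes are
  not mapped.
* Triplets (quartets with one member lost) are skipped, which biases
  against loci with post-conversion gene loss.
* The permutation p-value is granular at $1/(n_\text{perm}+1)$; with the
  default 200 permutations the smallest achievable p is ~0.005.
* NJ with p-distances is the deliberately conventional tree engine;
  maximum-likelihood trees are out of scope.
* Whether colinear pairs should additionally require ortho-group support
  is left as an annotation (`orthogroup_support_percent`), not a filter.
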