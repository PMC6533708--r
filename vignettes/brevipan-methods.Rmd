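---
title: "Pan-genome construction and niche screens: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome construction and niche screens: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`brevipan` re-implements, as a reusable and testable pipeline, the
comparative-genomics workflow used to characterise closed bacterial genome
collections such as the 19-strain *Lactobacillus brevis* set: ortholog
family construction from filtered protein similarity, pan/core-genome
accumulation with an open/closed verdict, presence/absence screens for
niche-associated (beer-spoiler) genes on chromosomes and plasmids, plasmid
gene-content comparison, per-genome summary statistics, and a
single-copy-core supertree.  This vignette records the models, the tunable
parameters, and the design decisions taken where the original protocol left
room for interpretation.

## Similarity model

All-against-all protein comparison uses an internal Smith–Waterman aligner
(affine gaps, BLOSUM62, gap open 11 / extend 1 — the BLAST defaults) so
that internally computed hits live on the same scale as externally supplied
BLAST tabular files, which can be ingested instead.  No E-value is computed
internally: Karlin–Altschul calibration is out of scope, and the E-value
threshold (1e-4) is applied only to ingested hits that carry one.

A pair of proteins becomes an edge of the similarity graph when **both**
directed comparisons pass the filter: identity ≥ 30% and query coverage
≥ 80% of the sequence length.  Two readings of "80% of the sequence
length" are possible (query vs. subject vs. shorter sequence); coverage is
computed against the query, and because both directions must pass, the
filter is effectively symmetric — the strictest of the defensible
readings.  Whether the original analysis demanded both directions to pass
or merely the existence of a reciprocal hit is not stated; both-pass is
implemented (configurable in `run_config()`).

*Edge weight.* MCL needs a weight; the protocol does not state one.  We
use `pct_identity/100 × min(query_cov, subject_cov)`, best hit per
direction, averaged over the two directions.  It is monotone in both
filtered quantities and bounded in (0, 1].

*k-mer prefilter.* Aligning all ~80 M ordered pairs of a 12-genome
universe is wasteful: unrelated proteins essentially never reach 30%
identity across 80% of their length.  A pair is aligned only when the two
sequences share at least `max(2, ceil(0.02 × min(#k-mers)))` distinct
k-mers (k = 4).  At the divergence the filter must tolerate (per-site
substitution rate ≤ 0.2, i.e. ≈ 64% expected identity) a true pair
preserves ≈ 17% of its k-mers — an order of magnitude above the cutoff —
while unrelated pairs of typical length share well below the threshold.
The prefilter is configurable and can be disabled outright
(`all_vs_all(..., prefilter = FALSE)`); the test suite verifies at rate
0.2 that the filtered edge set is identical with and without it.

## Markov clustering

`mcl()` is an in-house implementation of the standard iteration: add
self-loops (weight = maximum incident edge weight, floored at 1e-3),
column-normalise, then alternate expansion (matrix squaring) with
inflation (entrywise power 1.5 followed by re-normalisation) and pruning
(entries < 1e-5 dropped, columns re-normalised) until the largest
entrywise change drops below 1e-6 or 100 iterations elapse.  Clusters are
the connected components of the attractor support of the limit matrix;
with nodes processed in sorted id order this deterministically assigns a
node attracted to several attractors to the cluster of its smallest
attractor.  Inflation defaults to 1.5, the customary setting for protein
families (the original protocol does not state its value).  Near-uniform
cliques — exactly what near-identical gene families produce — drift toward
a single attractor very slowly, so the iteration cap can be reached before
the entrywise tolerance; the interpretation of the current matrix is
already stable at that point, a warning is emitted, and cluster recovery
is unaffected (the suite verifies exact ground-truth recovery).  Column
stochasticity is tracked after every normalisation and is tested to 1e-9.

## Pan/core accumulation and fits

For each genome ordering, `pan[k]` counts families present in at least one
of the first *k* genomes and `core[k]` those present in all of them.  With
≤ 7 genomes all orderings are enumerated; otherwise 100 random orderings
are sampled (both configurable).  The central curve is the mean across
orderings (the median is also emitted); fits use the mean, since the
original figure's convention is unstated.

The pan curve is fitted by least squares in log–log space to
P(n) = a·nᵇ, and the pan-genome is called **closed** when b < 0.5.  The
published phrase "exponential value lower than 0.5" is read as this
power-law exponent — the convention of the pan-genome tool used in the
original analysis; the threshold is exposed in `run_config()`.  The core
curve is fitted by nonlinear least squares to C(n) = c·e^(d·n) + k₀,
initialised from (C(1)−C(max), a log-slope estimate, C(max)), with k₀ the
asymptotic core size.  An exactly constant core curve has no identifiable
(c, d); the degenerate fit (c = 0, d = 0, k₀ = mean) is returned instead.

## Niche screens

The beer-spoiler screens are deterministic set rules, not statistical
tests: a family is reported when it occurs in at least `min_pos` genomes
of the positive group (4 for the chromosomal screen, 3 for the
plasmid-only screen) and in at most `max_neg` of the negative group
(default 0 — "specifically only present").  The published chromosomal list
says only "present in at least four beer-spoiling strains"; the
acquired-gene framing elsewhere implies absence from non-spoilers, so
`max_neg = 0` is the default.  The shipped fixture tables carry only the
seven spoiler strains' columns, so their reproduction is insensitive to
this choice.

Functional categorisation replaces a COG database search with ordered
case-insensitive keyword rules over product strings
(`default_category_rules()`); the first matching rule wins and unmatched
products fall into `hypothetical/unknown`.  The rules are configuration,
not biology: they are meant to be edited per study.

## Plasmid comparison

Plasmid relatedness is measured as directional shared gene content: the
fraction of one plasmid's genes whose family has a member on the other
plasmid.  The published "at least 90% identity" between whole plasmids was
plausibly a nucleotide-level measure; since this pipeline operates on
annotated proteins, the gene-content proxy is the implemented contract
(thresholds: similar ≥ 0.90 in both directions, unique < 0.10 against
every other plasmid).

## Supertree

Universal single-copy families (exactly one member in every genome,
outgroup included) are each aligned with a center-star progressive
aligner — the center maximises the summed pairwise global score, others
are merged under "once a gap, always a gap" — after which **all columns
containing any gap are removed**.  That is the only reading of an
"ungapped alignment" consistent with concatenating variable-length
orthologs.  Concatenation yields a supermatrix; p-distances feed
neighbor-joining (negative branches clamped to zero with the deficit moved
to the sister branch); columns are bootstrap-resampled (uniformly by
default, per-family blocks optionally) and internal-edge supports are
bipartition counts out of the replicates; the tree is rooted at the
midpoint of the outgroup's pendant edge.  Distance + NJ stands in for the
original maximum-likelihood step: ML tree search is out of scope here, and
the package's test surface is topology recovery on synthetic data, which
NJ passes exactly on additive matrices.  Supports below the display
threshold (250 of 1000 by convention) are flagged, never removed.

## The synthetic pan-genome generator

`simulate_pangenome()` plants a known family structure so every stage can
be validated against ground truth: core families in every genome, shell
families with occupancy drawn uniformly over 2..(n−1) genomes, five
strain-unique families per genome, and niche families present only in
spoiler genomes (each in at least `min_pos` of them).  Defaults mirror the
validated study conditions: 12 genomes, 7 spoilers, 800 core + 300 shell +
20 niche families, substitution rate 0.02, paralog probability 0.1 per
family per genome, protein lengths from a clipped normal (mean 300, sd 60,
min 50 aa) with uniform residue usage.

Design choices worth recording:

* **Star phylogeny by default** — every genome copy is mutated
  independently from the family ancestor.  This decouples clustering
  validation from phylogeny; `simulate_on_tree()` provides the guide-tree
  mode (substitutions accumulating along branches) used for the phylogeny
  tests.
* **Identifiable niche truth** — shell family genome sets are
  rejection-sampled so that none accidentally matches the niche-screen
  pattern (≥ `min_pos` spoilers and zero non-spoilers).  Without this,
  roughly 1% of shell families would satisfy the screen by chance and the
  planted truth would not be exactly recoverable.
* **Niche genes sit on the chromosome** unless `niche_on_plasmid = TRUE`,
  mirroring the chromosomal vs. plasmid-only screens.
* Two copies of a family ancestor agree per site with probability
  (1−r)² + r²/19; the suite checks the empirical identity against this
  within three binomial standard deviations over ≥ 5000 aggregate sites.

What the simulator does **not** emulate: biological residue composition,
indels within families, gene gain/loss along a phylogeny, rearrangement or
synteny, and nucleotide sequences.  Passing tests therefore demonstrate
algorithmic correctness against the planted model, not robustness to every
property of real annotations — in particular, real ortholog families
diverge non-uniformly and may fragment or merge at any fixed threshold.

## Problem sizes and determinism

The validation suite exercises the full study-scale configuration (12
genomes, ≈ 13 000 proteins, ≈ 1180 families) once — it completes in about
two minutes — and otherwise uses smaller universes chosen so each property
is still forced (e.g. exhaustive enumeration of all 120 orderings for
5-genome accumulation, brute-force alignment oracles on strings of at most
8 residues, additive matrices from random 4–8 taxon trees).  All
randomness flows from explicit integer seeds: identical `sim_spec()`s
produce byte-identical universes, and bootstraps with the same seed are
bit-reproducible.

## Known limitations

* Gene-content plasmid similarity saturates for small plasmids (a 2-gene
  plasmid can only score 0, 0.5, 1).
* The center-star aligner is exact for the star objective, not a full
  progressive aligner; with the gap-column removal step this is
  immaterial for near-full-length orthologs but degrades on families with
  long indels.
* `fit_core_exponential()` requires a decaying curve; increasing "core"
  curves (impossible for true accumulation data) fail the fit with an
  informative error.
* The open/closed verdict is threshold-based on a fitted exponent; near
  the 0.5 boundary the call is sensitive to the permutation sample, which
  is why the fitted value, not only the verdict, is reported.
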