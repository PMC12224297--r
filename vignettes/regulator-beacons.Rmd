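---
title: "Regulator beacons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulator beacons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regBeacons)
```

# The analysis

Bacterial natural-product pathways are encoded in biosynthetic gene clusters
(BGCs), and their expression is typically controlled by cluster-situated
regulators — transcription factors encoded inside or near the cluster.
`regBeacons` quantifies that colocalization and turns it around: regulator
subclasses that are strongly enriched inside predicted BGC regions become
markers ("beacons") for biosynthetic regions that rule-based predictors
missed, because rule-based detection requires canonical core genes that
non-canonical clusters lack.

The pipeline has five stages, each an independently testable module:
domain-hit processing, domain co-occurrence network with Markov Clustering,
rule-based subclass classification, in/out-BGC association statistics, and
beacon-based candidate discovery. A synthetic-genome generator supplies all
inputs with known ground truth.

# Domain hits

Inputs follow the per-domain tabular layout of profile-HMM searches
(domtblout). Envelope coordinates define a hit's extent — envelopes bound
the domain's true location, whereas alignment coordinates can undercall it —
and each hit's bitscore is divided by the profile's curated gathering (GA)
threshold to give a dimensionless normalized bitscore comparable across
profiles. Hits at exactly the GA threshold (normalized score 1.0) are kept:
the threshold is inclusive.

Regulatory profiles are selected by case-insensitive substring match of
configurable keywords against profile descriptions, after normalizing en/em
dashes to hyphens and collapsing whitespace; a keyword with a parenthesized
abbreviation such as "helix-turn-helix (HTH)" also matches through the bare
phrase and the abbreviation. The shipped keyword list carries only five
example keywords and is deliberately incomplete; real runs should supply a
full curated list.

Overlapping hits on one protein are resolved greedily: sort by normalized
bitscore descending — ties broken by lower start, then lexicographic
accession, making the procedure deterministic — and accept any hit that does
not share an amino-acid position with an already-accepted hit. The greedy
procedure is idempotent and is validated in the tests against an exhaustive
subset oracle on instances of up to eight hits.

# Co-occurrence network and MCL

Every protein contributes one count to each unordered pair of distinct
domains it contains. Node frequencies are counted over all proteins
regardless of which edges survive; edges observed fewer than 100 times are
dropped (the default keeps only common association patterns and is the
analysis's stated operating point). Edge "containment" — count divided by
the smaller endpoint frequency — expresses how consistently the rarer domain
travels with the commoner one.

Markov Clustering is implemented natively on the count-weighted adjacency
matrix:

* **Self-loops** equal each node's maximum incident weight (1 for isolated
  nodes). This is the standard MCL regularization that prevents oscillation
  on bipartite-like structures; whether the original analysis's external MCL
  binary added loops is not recoverable, so cluster memberships may differ
  marginally from any published network file.
* **Iteration**: expansion (matrix power 2), inflation (elementwise power,
  default 6, then column renormalization), pruning of entries below 1e-8.
  Pruning keeps the matrix sparse without affecting attractors at inflation
  6. Column sums are tracked every iteration and stay within 1e-9 of 1.
* **Convergence** when the maximum absolute change drops below 1e-9, capped
  at 200 iterations; non-convergence is reported on the result object and
  collected as a warning in the pipeline manifest.
* **Interpretation**: attractors are rows with positive diagonal mass;
  attractors supporting each other form one cluster; any other node joins
  the attractor system with the largest weight on its column, ties going to
  the lexicographically smallest cluster label. The tests verify exact
  recovery of planted modules (three 8-cliques joined by weight-1 bridges)
  and that clusters always refine connected components.

# Subclass classification

Classification is a declarative rule table (YAML), evaluated in priority
order; the first matching rule wins, so classification is a total function
and a partition. A rule lists alternative required domain sets, a forbidden
set, and an exactness flag. "Consists solely of" in the small-SARP
definition is implemented as exactness over the domain *set*: duplicate
copies of a required domain are allowed, any additional domain disqualifies
the match. Specific rules (large SARP, SARP-LAL) are evaluated before
general ones (medium, then small); the source material implies but does not
state an evaluation order, and most-specific-first is the order under which
the published subclass examples come out right.

Non-SARP subclasses are not fully specified by architecture in the main
description of the analysis; the shipped rules encode them as
single-required-domain or documented-guess definitions, marked editable in
the YAML file. The PAS-LuxR small/large boundary, numerically undefined in
the source, is encoded structurally: "large" requires an additional AAA
ATPase domain. Replace the file to match your own curation.

# BGC association

* **Membership** is full containment of the gene interval in the region
  interval (0-based, half-open). Predicted regions extend beyond core genes
  by design, so partial overlap at an edge is treated as outside; this is
  the conservative reading of "within the range".
* **Ratios** are kept unrounded internally; reports use half-up rounding to
  one decimal (864/1053 prints as 82.1%), matching the presentation
  convention of the field's tables (base R's round-half-even would disagree
  on exact halves).
* **Nearest core gene**: distance is the interval gap in nucleotides (0 when
  overlapping), robust to very long core genes, with ties broken by the
  smaller core start. Regions without core genes fall back to their first
  listed product class and are flagged.
* **Function filters**: associations count only genes in regions matching a
  known characterized cluster at >= 50% similarity (inclusive), and
  (subclass, activity) pairs seen fewer than 10 times are removed
  (inclusive at 10). Genes failing the similarity filter feed the
  unknown-function fraction. Both filters are monotone, which the tests
  assert property-style.
* **Upper quartile**: the 75th percentile of subclass ratios with linear
  interpolation (quantile type 7), inclusive at the threshold; subclasses
  with fewer than 20 genes are excluded before the percentile is computed so
  tiny subclasses can neither be selected spuriously nor distort the
  threshold. The pipeline reports however many subclasses pass the rule — the
  source material itself gives slightly different subclass counts in
  different places, so no fixed count is enforced.
* Ratios are computed **per gene**, not per domain hit; a per-domain variant
  would weight multi-domain regulators more heavily and make the ratio
  depend on annotation density, so it was rejected.

# Beacon discovery

Out-of-BGC genes of the target subclass qualify as beacons when their
interval gap to every region on the contig is at least 20 kb (inclusive) —
one approximate BGC length, so that genes merely sitting past an imprecise
region edge are excluded. The distance is measured from the gene itself, the
simplest defensible reading. Candidate windows of 20 kb total are centered
on the beacon gene's midpoint (centering is not defined by the source
sideloading convention; the midpoint is symmetric and parameter-free) and
clipped at contig edges with a flag.

Windows are scored by counting, with multiplicity, domain hits from an
editable biosynthesis-associated PFAM list (condensation, ketosynthase,
AMP-binding, methyltransferase, P450, aminotransferase — a stand-in for a
curated set). Window similarity is the equal-weight mean of the Jaccard
index of domain sets and an adjacency index (Jaccard of adjacent ordered
domain pairs of the two domain strings) — a documented re-implementation of
the two shared-content components of the external cluster-similarity tool,
not an emulation of it; published candidate cluster counts are therefore not
exactly reproducible and are not asserted anywhere. When both regions carry
a single domain the adjacency index is undefined and falls back to the set
Jaccard. Clustering is connected components over the >= cutoff (default
0.3) graph.

The repeat scanner enumerates all position pairs with spacers in a
configurable range, exact match by default (mismatch budget 0): the spaced
direct repeat TTGCAGT-N10-TTGCAGT is the reproducible core of the SARP
binding pattern, whereas de novo motif discovery is out of scope. N never
matches, units shorter than 4 nt are rejected as uninformative, both strands
are scanned with reverse hits mapped to forward coordinates, and a hit found
on both strands at one site (always, for exact direct repeats, which are
their own mirror image) is reported once on "+". Degenerate inputs
(homopolymers) legitimately hit at every offset.

# The synthetic generator

`generateGenomes()` emulates the statistical structure of the real inputs:
one contig per genome (complete genomes; multi-contig assemblies add edge
cases without structure), disjoint BGC regions with at least 1 nt gap
(predicted regions are disjoint per contig), genes placed fully inside a
region with a per-family probability, and domain hits drawn from per-family
architecture grammars. Decoy hits overlap a true hit by at least one
residue with a normalized bitscore strictly below every hit they overlap,
so overlap resolution has a deterministic right answer. Defaults encode the
emulated study conditions: 20 kb regions, a 0.146 background in-BGC
probability for unlabeled genes, an 8 Mb contig with 25 regions (a typical
streptomycete chromosome), and family probabilities of 0.82 (small SARP),
0.576 (medium SARP) and 0.976 (large PAS-LuxR) matching the reported
associations of those subclasses; per-genome family counts (20/10/5/10
labeled genes plus 200 background genes) are scaled-down desk-size choices.
Known-cluster similarities default to uniform on [0, 100] and class labels
to a fixed weight table — the empirical distributions are not published, so
these are configuration, not claims.

The generator does **not** emulate sequence-level realism (no codon usage or
GC structure, no protein sequences — hits are drawn directly), gene-density
autocorrelation, operon structure, or multi-contig assemblies. Passing tests
therefore demonstrate correctness of the statistical machinery and the
interval logic, not performance on real annotation noise; with real inputs
the keyword list, subclass rules and biosynthetic-PFAM set should all be
replaced by curated versions.

Promoters are built as flank–unit–spacer–unit–flank with random parts
rejection-sampled so no *additional* copy of the unit touches them; extra
occurrences forced by self-overlap of a periodic unit (AA in AAAA) are
tolerated by construction, and shifted repeats of other k-mers can still
arise by chance, so ground truth is defined in terms of the planted unit.

# Determinism and problem sizes

All randomness flows from integer seeds; each stage derives a fixed
substream, so identical configuration and seed reproduce byte-identical
outputs and an identical run manifest (config hash, input checksums, stage
counts, collected warnings). The test-suite and acceptance problem sizes —
50 genomes and ~1000 focal genes for parameter recovery, 2000 genes for
binomial-bound checks, 8-hit instances for the exhaustive overlap oracle,
24-node planted networks for MCL — were chosen so that binomial standard
errors are a few tenths of a percentage point and exhaustive oracles stay
enumerable; they are the package's own choices.

# Known limitations

* Non-SARP subclass rules are approximations pending a curated table.
* The region-similarity measure shares components with, but is not, the
  external clustering tool; absolute cluster counts are not comparable.
* Genome-scale headline counts from any particular genome collection
  (numbers of regulators, profiles, candidate regions) depend on database
  and predictor versions and are out of scope; the package asserts worked
  examples and recovery properties instead.
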