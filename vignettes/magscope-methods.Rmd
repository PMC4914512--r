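---
title: "Methods: recovering population-level genomes with magscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recovering population-level genomes with magscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Shotgun metagenomes of mixed microbial communities assemble into fragments
(contigs) whose population of origin is unknown. *Binning* groups contigs
(or genes) into clusters presumed to derive from a single population, so
that taxonomic identity and functional potential can be linked at the
population level. magscope implements two complementary,
reference-independent workflows at desk scale:

1. **Canopy + inspection.** Genes are clustered by the covariation of
   their fold-coverage profiles across many samples; large clusters
   ("metagenomic species", MGS) are then inspected in a 2D embedding of
   k-mer genomic signatures and refined by polygon selection.
2. **Targeted (beacon) recovery.** Taxon-diagnostic marker genes are
   filtered by annotation confidence, grouped by sequence identity, and
   the contigs carrying them ("beacon contigs") are highlighted in the
   embedding to locate the population's cluster without any prior
   clustering.

Both end with the same quality-control and refinement stages: essential
single-copy-gene completeness/contamination counting, gene-wise %GC
diagnostics, and robust coverage-outlier exclusion.

## Models and statistics

### Co-abundance canopy clustering

The substrate is a genes x samples fold-coverage matrix. Genes shorter
than 100 nt, or never reaching 2x coverage in any sample, are removed
first. The distance is the Pearson correlation distance `d = 1 - r` on
the raw coverage vectors (the input is the raw fold-coverage matrix; no
log transform). Canopies are grown from seed genes: all unassigned genes
within `max_canopy_dist = 0.1` of the origin profile join; the center is
recomputed as the element-wise median and the gather/recenter step
repeats until the center moves less than `min_step_dist = 0.005` (or 10
iterations, a safety bound). Genes within `max_close_dist = 0.4` of the
final center are recorded as close members. Canopies whose centers lie
within `max_merge_dist = 0.1` are merged by single linkage. Canopies with
at least 700 member genes are called MGS; on desk-scale simulations the
threshold is scaled down (the tests use 50).

Choices the published parameterization leaves open, and what this package
does:

* **Seeding order** — descending total coverage with lexicographic
  tie-breaks, making runs deterministic; a random order remains available
  behind `order = "random"`.
* **Membership semantics** — only still-unassigned genes join a canopy's
  member set, so members form a partition after merging; close members
  may overlap canopies. This is the strictest reading consistent with the
  stated member/close-member distinction.
* **Center statistic** — element-wise median (robust); mean available.
* **Zero-variance profiles** — correlation is undefined for them; they
  are excluded up front and reported via an attribute.

### Genomic signatures and 2D embedding

Contigs shorter than 1,000 nt are omitted; longer contigs are cut left to
right into 5,000 nt chunks while the remainder is at least 5,000 nt, the
entire remainder forming the final chunk. Chunking normalizes cluster
size and density: a well-assembled genome would otherwise be a handful of
points. The literal rule can emit a very short tail (a 5,001 nt contig
gives 5,000 + 1 nt); `merge_tail = TRUE` folds sub-threshold tails into
the previous chunk, default off for fidelity.

Each chunk is summarized by canonical k-mer frequencies (`k = 5`;
reverse-complement pairs pooled, ambiguous windows skipped), zero-replaced
multiplicatively (0.65 x smallest nonzero value), closed, and centered
log-ratio transformed. The published workflow delegates these choices to
the visualization tool it wraps and does not state them; `k = 5` matches
that tool's convention and all are configurable. The CLR-transformed matrix is reduced
by PCA (50 dimensions by default) and embedded to 2D by an exact
t-distributed stochastic neighbor embedding (perplexity 30, 1,000
iterations, early exaggeration 12). No t-SNE package is assumed: the
embedding is implemented in the package, O(n^2) per iteration, adequate
for desk-scale inputs (hundreds to a few thousand chunks) and
deterministic given the seed. Perplexity is lowered automatically to
`floor((n - 1) / 3)` for tiny inputs.

Coordinates are unitless and run-specific: polygons are only valid
against the embedding run that produced them, so the run id travels with
the points table. When coverage annotation is enabled, point opaqueness
is `log(1 + coverage)` scaled by the set maximum, clipped below at 0.05.

### Greedy identity clustering

Used for catalog dereplication (95% identity over 90% of the shorter
sequence) and marker grouping (95% over 50%). Sequences are sorted by
descending length (ties by id) and assigned first-fit to the earliest
representative they match; unmatched sequences found new clusters. The
identity denominator is the length of the *shorter* sequence, mirroring
the `-c` convention of the cited tool; coverage is the aligned span on
the shorter sequence over its length. Alignment is local (match +2,
mismatch -3, gap open -5, gap extend -2). Best-fit assignment is
available behind a flag; no k-mer prefilter is applied at desk scale.
The test suite replays the procedure with an independent pure-R
Smith-Waterman oracle and requires identical partitions.

### Bin quality control and refinement

*Completeness / contamination*: the number of distinct essential
single-copy families (107 by convention) present on the bin's contigs,
and the number present in two or more copies.

*Coverage outliers*: all contigs of one population should show similar
fold-coverage in a given sample. Per-contig mean coverages are scored by
the modified Z-score `M = 0.6745 (x - median) / MAD`; when the MAD is
zero the canonical fallback `M = (x - median) / (1.253314 MeanAD)`
applies, and when both vanish all scores are zero. Contigs with
`|M| > 3.5` (strict inequality, both tails) are discarded in a single
pass — the filter is deliberately not iterated, matching the single
refine-then-reassemble step of the workflow it implements. Scores are
computed on raw (not log) mean coverages, consistent with the
untransformed coverage distributions the workflow inspects. Whether the
original study used raw or log coverage, and which MAD-zero fallback, is
not stated; the canonical formulation is adopted.

*Polygon selection*: even-odd (ray-casting) membership with inclusive
boundaries; self-intersecting polygons are rejected. Chunk selections are
promoted to whole contigs by majority (> 50% of a contig's chunks; exact
ties excluded), with an `"any"` rule available. How the original
chunk-level manual selections were promoted to contigs is unstated;
majority is this package's convention.

*%GC diagnostics*: per-sequence %GC excludes ambiguous bases from the
denominator; distribution comparisons report medians, IQRs, and the 1D
Wasserstein (earth-mover) distance, which equals the shift for a pure
location shift.

## The synthetic community

`simulate_community()` generates the stated world every test runs in:

* **Genomes** are i.i.d. base sequences with a target GC content
  (order-0 model; sufficient for composition-based separability, and
  deliberately simpler than a Markov chain — extensible if ever needed).
* **Contigs** tile each genome without gaps (lognormal lengths, mean
  4 kb, minimum 1 kb). The 4 kb mean emulates typical metagenomic
  assembly fragmentation; an early 8 kb draft produced ~9 contigs per
  genome, on which a robust Z-score over per-contig coverages is
  statistically meaningless (real bins in this setting hold tens to
  hundreds of contigs).
* **Genes** tile each genome end-to-end, 0-based half-open, mapped to the
  contig containing their midpoint.
* **Coverage**: genome abundance per sample is lognormal (meanlog 3,
  sdlog 1 — fold-coverages spanning roughly 1-100x, the dynamic range
  marker-gene screens observe); each gene inherits its genome's abundance
  times `max(0, 1 + eps)`, `eps ~ N(0, cv)` with `cv = 0.05` by default.
  Abundances are independent across samples and genomes; the clustering
  input is just a coverage matrix, so richer correlation structure would
  add nothing the method could exploit.
* **Markers**: 107 distinct essential families per genome, in single
  copy; requested contamination plants duplicate-family copies on extra
  genes of the same genome, so a genome's own bin scores exactly that
  contamination count.
* **Target-taxon markers** are near-identical (~98%) copies of one anchor
  gene, emulating cross-sample assemblies of the same marker — scattered
  unrelated genes could never co-cluster at the 95% identity threshold.
  A few sub-threshold decoy annotations exercise the confidence filter.

What the generator does *not* emulate: read-level noise and chimeras,
strain mixtures, repeat-induced misassembly, GC-dependent coverage bias,
and between-sample correlation structure. A green end-to-end test
therefore establishes that the implementation realizes the stated method
on data satisfying the method's own assumptions — not that the method
succeeds on arbitrary real communities.

## Test scaffolding for manual steps

Interactive polygon drawing is replaced by polygon JSON files. For
automated end-to-end tests, a helper derives a polygon as the convex hull
of truth-labeled (or MGS-flagged) points, padded 5% outward from the
centroid. This is test scaffolding, not a scientific claim: it answers
"would a perfectly informed selection recover the planted genome", which
is the property the pipeline's correctness can be tested against.

The automatic truth-hull selection assumes the embedding separates the
target from its neighbors, which holds when GC differences are at least
about 0.15 (the regime asserted by the embedding separability invariant).
In the targeted-recovery acceptance world the target genome (GC 0.28)
keeps that margin from every background genome (0.45-0.75); backgrounds
may be closer to each other. Outside that regime a hull drawn around
truth points swallows neighboring clusters and the coverage-outlier
filter then removes whichever coverage mode is in the minority — a real
failure mode of loose selections, documented here rather than hidden.

## Numerical and degenerate-input choices

* All randomness is routed through a local-seed helper: identical seeds
  give bit-identical outputs regardless of ambient RNG state; global RNG
  state is restored afterwards.
* Correlation distances require nonzero variance; zero-variance profiles
  are excluded and reported rather than silently scored.
* `clr_transform` errors on all-zero vectors; `kmer_frequencies` errors
  when every window is ambiguous; the embedding refuses fewer than 4
  points.
* Boundary conventions, all inclusive where the workflow says "at
  least"/"≥": 700-gene MGS threshold, 0.75 annotation confidence, 95%
  identity; the 3.5 outlier threshold is strict ("greater than").
* Scale-downs for test budgets (embedding iterations 300-600 instead of
  1,000, `min_genes = 50`) are parameter choices the tests state
  explicitly, never silent.

## Known limitations

* O(n^2) embedding and alignment-based clustering limit inputs to desk
  scale (thousands of chunks, hundreds of sequences); the cluster-scale
  catalogs of the source workflow are out of scope by design.
* The canopy recenter/merge semantics follow this package's documented
  reading; the cited implementation's exact rules are not public in the
  source text.
* Identity is claimed equivalent to this package's own alignment oracle,
  not to any specific external clustering binary or version.
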