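---
title: "Methods: piRNA cluster profiling with pirnatools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA cluster profiling with pirnatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnatools)
```

# Scope and model

`pirnatools` quantifies piRNA production from genomic piRNA clusters in
paired small RNA libraries (typically wild-type versus a biogenesis-factor
knockout) and locates, within single precursors, where production is
lost. The underlying biological model: each cluster is transcribed as one
long single-stranded, TSS-anchored precursor that is fragmented into
mature 24–32 nt piRNAs; mature piRNAs carry a 5′ uridine (1U) signature;
25–28 nt piRNAs load onto MILI and 29–32 nt piRNAs onto MIWI; and
protein–RNA contacts on precursors can be read out by CLIP fragments,
which instead carry a 5′ A signature left by endogenous nucleases.

The pipeline makes three structural assumptions worth stating explicitly:

* **Clusters are contiguous sense-strand sequences anchored at their
  transcription start site.** The 5′-window analysis counts reads with
  mapped start `< window_nt` from offset 0 of the supplied cluster
  sequence, so cluster FASTA/BED records must be TSS-anchored.
  Bidirectional (divergently transcribed) clusters should be supplied as
  two separate records; merging them would smear the 5′ window across
  both arms.
* **A read's 5′ start position is its positional feature.** Density
  tracks and metagene profiles count read starts, not coverage, because
  the 5′ end is the biogenesis-defined coordinate (it carries the 1U
  signature) and because start counting makes bin conservation exact:
  metagene bins sum to the number of cluster-assigned reads. Coverage
  tracks are available (`density_track(..., coverage = TRUE)`) for
  figure-style plots only.
* **Qualities are irrelevant.** FASTQ qualities are parsed for
  structural validity and discarded; no stage is quality-aware.

# Annotation: sequential exclusion with one mismatch

Reads are matched ungapped with at most one mismatch (no indels),
mirroring Bowtie `-v 1` semantics, against an ordered category
hierarchy — piRNA clusters, coding RNA, non-coding RNA, repeats, intron —
with unmatched reads labeled `other`. The order is a priority: a read is
assigned to the first category in which it has any qualifying placement,
so later categories only ever see the leftovers. This makes per-category
counts depend on the stated order, which is therefore recorded in the
library's parameter digest.

Decisions the matching model had to take where reasonable tools differ:

* **Multimappers.** Each read is counted once, at a single deterministic
  placement: fewest mismatches, then lexicographically smallest target
  name, then smallest start, then sense before antisense. Fractional
  weighting was rejected for auditability — every read in the output TSV
  has exactly one row, and tallies are integers that must reconcile.
* **Strandedness.** Cluster, coding and non-coding references are
  transcript-sense sequences of single-stranded transcripts, so matching
  is sense-only there; repeats and intron are matched on both strands
  (repeat content is not stranded in the same sense). Per-category
  overrides are available in the hierarchy configuration.
* **N handling.** A read `N` counts as a mismatch wherever it lands, so
  one `N` consumes the single allowed mismatch and two make a read
  unmappable.
* **Coordinates.** 0-based, half-open everywhere internally; bedGraph
  exports follow the same convention via rtracklayer.

The matcher is implemented in C++ (`src/matcher.cpp`) and scans
candidates in exactly the tie-break order, so the first exact hit is
final; the test suite holds it to read-for-read agreement with an
independent exhaustive Hamming-scan oracle written in R.

# Normalization and fold changes

Total small RNA libraries are made comparable through their **miRNA-proxy
counts**: the number of 21–23 nt reads in the adapter-clipped,
pre-window library. miRNAs are a genotype-independent reference
population, so the scale factor `s = mirna_ref / mirna_alt` corrects for
sequencing depth without assuming piRNA levels are constant. The proxy
is defined purely by length, matching how such normalizations are
usually reported; an annotated-miRNA restriction would change the count
but not the ratio materially and is deliberately not required. For IP
(MILI/MIWI-bound) libraries, where the miRNA fraction is itself depleted
by the IP, total retained reads are the normalizer
(`mode = "total_reads"`). A zero proxy count is an error, never a silent
infinity. The choice to count the proxy before the 24–32 nt window (not
after, which would remove it entirely) is recorded in the run report.

Per-cluster fold changes use an additive pseudocount (default 1.0,
applied to normalized counts) so that zero-count clusters yield finite
ratios; pseudocount 0 is permitted and exact when all counts are
positive, in which case `FC(ref/alt) × FC(alt/ref) = 1` per cluster.
Cluster ranking always uses the reference (wild-type) library and is
invariant to the scale factor. Fold-change aggregates report both the
geometric mean (the primary one — fold changes are ratios) and the
arithmetic mean.

# The 5′-window statistic

For the top-k wild-type-ranked clusters (defaults `window_nt = 300`,
`top_k = 50`; the acceptance analyses use `top_k = 10` on the 20-cluster
desk preset), `window_vs_full()` computes the paired fold change
restricted to reads starting in the 5′ window, over the full cluster,
and beyond the window. The window/full uncoupling is tested with a
two-sided paired t-test on `log2(FC_full) − log2(FC_window)` across
clusters; the log scale makes the paired differences symmetric in ratio
space and is the natural scale for fold changes (the underlying report
of a "paired t-test" leaves the scale open; log2 is this package's
choice). Degenerate inputs are handled explicitly: all-zero differences
return `t = 0, p = 1` with a warning rather than `NaN`; with fewer than
two clusters the test is undefined and reported as `NA`; a window at
least as long as a cluster uses the whole cluster (logged, not an
error), making `fc_window == fc_full` exactly for that cluster.

Under 5′-sparing depletion with factor `f`, a cluster whose fraction of
reads starting inside the window is `w` has expected full-length fold
change `1/(w + (1−w)/f)` — the closed form the simulator's truth tables
let the tests verify.

# Metagene profiles and co-density

Each cluster is rescaled to `n_bins = 100` equal fragments; a read
starting at offset `p` on a cluster of length `L` contributes to bin
`floor(p·n_bins/L)`, and bins are summed over clusters. The map is total
on `[0, L)` with image in `[0, n_bins)`, so bin totals conserve read
counts exactly; clusters shorter than `n_bins` map many positions to few
bins and are logged. CLIP/piRNA co-density reports per-cluster count
pairs (log10-scaled for scatter plots) and the Pearson R² of the two
100-bin metagene vectors; a constant vector makes the correlation
undefined and is an error rather than an `NA`.

# What the simulator emulates — and what it does not

`scenario_config()` + `make_reference()` + `simulate_library()` generate
random references, read libraries and truth tables with the statistical
structure of adult-testis small RNA libraries:

* **Heavy-tailed cluster abundances**: weights proportional to
  `rank^−1.5`, under which the top quarter of clusters produces > 90% of
  cluster reads (both at 20 and at 214 clusters), matching the
  observation that a top subset of clusters dominates production.
* **Within-cluster hotspots**: per cluster, a Dirichlet(α = 0.3) weight
  vector over 50 uniformly placed candidate start sites plus a 10%
  uniform background. This yields the spiky density tracks real
  precursors show while keeping every metagene bin populated. The true
  within-cluster start distribution of real precursors is unknown; all
  recovery properties are stated against the truth table, not against
  biology.
* **Length mixture**: 50% MILI-like (25–28 nt, unimodal peaked at
  26 nt) and 50% MIWI-like (29–32 nt, peaked at 30 nt), giving a bimodal
  length histogram with one mode per class.
* **1U / 1A signatures**: the first nucleotide of a cluster read is
  overwritten — U with probability `u1_prob` (default 0.8), otherwise
  uniform over A/C/G — so the observed first-nt U fraction is an
  unbiased estimator of `u1_prob`. CLIP reads use A with `a1_prob`
  (default 0.5) against C/G/T. (Leaving the genomic base in the
  complementary case would shift the observed fraction to
  `u1 + (1−u1)/4` and make "recover the configured probability"
  ill-posed.)
* **Genotypes as binomial thinning**: uniform depletion keeps every
  cluster read with probability `1/factor`; 5′-sparing keeps reads
  starting at or beyond `window_nt` in the top-k clusters with
  probability `1/factor` (optionally thinning the MIWI-like class
  everywhere, for the phenotype where 29–32 nt piRNAs are globally
  reduced). Thinning per read makes every recovery bound an exact
  binomial statement.
* **Pairing**: wild-type and mutant libraries are independent draws
  (distinct derived sub-seeds) over the same reference and hotspot
  model, as two sequenced animals would be; the miRNA-proxy block
  depends only on the top-level seed and is therefore identical across
  genotypes by construction.

Not emulated: sequence realism (codon structure, repeat families),
transcription dynamics, ping-pong secondary biogenesis, trimming
intermediates, ligation biases, or sequencing errors beyond the
deliberate first-nt overwrite. Passing recovery tests therefore
demonstrates that the pipeline's arithmetic and bookkeeping are correct
under a known model — not that the model captures every feature of real
libraries.

# Problem sizes and numerical conventions

The desk preset — 20 clusters of 500–2,000 nt, 40,000 cluster reads,
5,000 non-cluster reads, 5,000 miRNA-proxy reads — is sized so the whole
pipeline (simulation, preprocessing, annotation of both libraries, all
positional analyses) completes in well under a minute, which is what the
package's own tests and `scripts/acceptance.R` run. The full-scale
preset (214 clusters of 2–20 kb) matches the geometry of a real
adult-testis experiment for qualitative figure-style runs; the native
matcher's scan cost grows with
total reference length, so it is noticeably slower and is not exercised
by the tests. At desk scale the shortest clusters (500 nt) have windows
covering up to 60% of the precursor, so full-length fold changes
understate the depletion factor far more than in the 2–20 kb regime —
the closed form above accounts for this exactly, and the beyond-window
fold change is the clean estimator of the depletion factor at any
geometry.

Numerical conventions collected in one place: composition fractions must
sum to 1 within 1e-9; fold-change pseudocount defaults to 1.0 with 0
allowed; rank ties break by cluster id in byte order; all RNG flows from
one top-level seed through `derive_seed(seed, tag)` sub-streams; run
reports capture every policy default so any two runs can be compared by
their JSON.

# Known limitations

* Gapped alignment, splicing and genome-scale indexing are out of scope;
  references are transcript/locus sequences, not whole genomes.
* Multimapper handling is a declared single-winner convention; the run
  report records the annotation digest so sensitivity to that convention
  can be assessed by re-running with a permuted hierarchy, but no
  fractional-assignment mode exists.
* The 300 nt window is taken as given, anchored at offset 0; the package
  does not infer the window boundary from the data (no changepoint
  detection).
* CLIP analysis covers length/nucleotide signatures, annotation and
  co-density; peak calling and crosslink-induced mutation analysis are
  not implemented.
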