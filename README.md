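# pirnatools

Quantitative profiling of pachytene piRNA production from genomic piRNA
clusters in small RNA sequencing libraries, with a CLIP-seq branch and a
fully seeded scenario simulator.

## The scientific problem

Adult mouse testes express millions of distinct PIWI-interacting RNAs
(piRNAs), 24–32 nt small RNAs produced by fragmentation of long
single-stranded precursor transcripts from a few hundred genomic loci
("piRNA clusters"). Two length classes coexist — 25–28 nt piRNAs bound by
MILI and 29–32 nt piRNAs bound by MIWI — and mature piRNAs carry a strong
uridine bias at position 1 (the 1U signature). Genetic studies of piRNA
biogenesis factors compare a wild-type and a knockout library and ask:
how much piRNA does each cluster still produce, and *where* along the
precursor is production lost?

`pirnatools` implements that comparison as a reusable, testable pipeline
for computational biologists analyzing small RNA-seq and HITS-CLIP
libraries from germline samples:

1. **Preprocessing** — 3′ adapter clipping and length-window filtering
   (24–32 nt for mature piRNAs; ≥ 15 nt for CLIP fragments).
2. **Hierarchical annotation** — ungapped matching with at most one
   mismatch (Bowtie `-v 1` semantics, implemented natively in C++)
   against an ordered category hierarchy: piRNA clusters → coding RNA →
   non-coding RNA → repeats → intron → "other". Each read is assigned to
   the *first* category in which it aligns (sequential exclusion), and to
   a single deterministic placement within it.
3. **Normalization and fold change** — paired libraries are scaled by
   their 21–23 nt miRNA-proxy counts (or by total reads for IP
   libraries); per-cluster fold changes `FC_c = (n_ref + pc)/(n_alt·s + pc)`
   are ranked by wild-type abundance.
4. **Positional analysis** — per-position 5′-start density tracks
   (bedGraph export), the 5′-window versus full-length fold-change
   statistic with a paired two-sided t-test on log2 fold changes, and
   100-bin metagene profiles aggregated over all clusters
   (`bin = floor(p · n_bins / L)`).
5. **CLIP branch** — permissive length filtering, fragment length /
   first-nucleotide signatures (nuclease fragments show a 5′ A bias,
   mature piRNAs a 5′ U bias), and CLIP-versus-piRNA co-density
   (per-cluster scatter and Pearson R² of the binned metagene vectors).
6. **Simulator** — seeded scenario generator producing reference
   sequences, read libraries and per-read truth tables with the
   statistical structure of adult-testis libraries: heavy-tailed cluster
   abundances, bimodal MILI/MIWI length mixture, 1U bias, hotspot-shaped
   within-cluster start positions, and knockout genotypes (uniform
   depletion; 5′-window-sparing depletion of the top clusters).

## Worked example

Simulate a paired wild-type / conditional-knockout experiment in which
the knockout retains piRNA production only from the first 300 nt of the
top 10 precursors (7-fold depletion elsewhere), then run the pipeline:

```r
library(pirnatools)

cfg <- desk_scenario(seed = 11,
                     genotype = genotype_five_prime_sparing(window_nt = 300,
                                                            factor = 7,
                                                            top_k = 10))
ref  <- make_reference(cfg)
pair <- simulate_pair(cfg, ref)

pp     <- preprocess_params(min_len = 24, max_len = 32, keep_unclipped = TRUE)
wt_pre <- preprocess_reads(pair$wt$reads, pp)
ko_pre <- preprocess_reads(pair$ko$reads, pp)

wt <- annotate_sequential(wt_pre$reads, ref$hierarchy,
                          mirna_count = wt_pre$mirna_count)
ko <- annotate_sequential(ko_pre$reads, ref$hierarchy,
                          mirna_count = ko_pre$mirna_count)
wt
#> annotated_library: 45000 reads, miRNA proxy 5000
#>   piRNA_clusters     40000
#>   coding_RNA          1500
#>   noncoding_RNA       1000
#>   repeats             1000
#>   intron              1000
#>   other                500

cmp <- paired_comparison(wt, ko, mode = "mirna_proxy")
head(cluster_fold_change(cmp, pseudocount = 1), 3)
#> # A tibble: 3 × 5
#>   cluster_id ref_rank ref_norm alt_norm fold_change
#> 1 cluster_03        1    18390    10171        1.81
#> 2 cluster_09        2     6485     3575        1.81
#> 3 cluster_01        3     3606     1000        3.60

window_vs_full(cmp, window_nt = 300, top_k = 10, pseudocount = 1)
#> window_analysis: top 10 clusters, 5' 300 nt window (ref_over_alt)
#>   mean FC window 1.015 | full 2.702 | beyond 6.764
#>   paired t = 6.189, p = 0.000161
```

The readout is the uncoupling signature: the mean fold change within the
5′ 300 nt window is ~1 (production preserved), while beyond the window
the wild-type/knockout ratio recovers the simulated 7-fold depletion;
the paired t-test on log2 fold changes confirms the window and
full-length estimates differ. The per-cluster fold changes illustrate
why full-length ratios understate the depletion: a cluster's full-length
fold change is `1/(w + (1-w)/f)` where `w` is its fraction of reads
starting inside the spared window.

A command-line interface wrapping the same functions is installed at
`inst/cli/profiler` (subcommands `simulate`, `preprocess`, `annotate`,
`quantify`, `positional`, `clip`, `report`); every run writes a JSON
run report with the parameters in force, per-stage read counts, and file
digests, and `profiler report --dir <dir>` audits count consistency
across a chain of reports.

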