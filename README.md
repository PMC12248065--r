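# apamap

Integrative analysis of 3'UTR isoform regulation from targeted 3'-end
sequencing and eCLIP data, with a fully deterministic synthetic-data
module so that every stage can be verified against planted ground truth
without any external downloads.

## Who this is for

Computational biologists studying alternative polyadenylation (APA):
how RNA-binding proteins (RBPs) shift usage between the proximal (pPAS)
and distal (dPAS) polyadenylation sites of a terminal exon, and how
binding position and cis-element architecture (UGUA enhancer, AAUAAA /
AUUAAA hexamer, downstream U/G-rich element) relate to that regulation.

## What it computes

**PAS cluster calling with internal-priming filters.** Read 3' termini
are pooled over all samples; clusters are maximal runs of positions with
pooled coverage > 10, clusters with < 20 pooled reads are dropped, and
each cluster's PAS is the coverage argmax (3'-most on ties). Four
filters remove artifacts: a run of > 6 genomically encoded adenosines
directly downstream of the PAS; > 7 A within the 10 nt downstream of
the cluster; absence of AAUAAA/AUUAAA within the cluster; absence from
a reference PAS database (PolyA_DB-like BED).

**Differential PAS usage.** Per terminal exon and sample, a cluster's
usage is its reads over the exon total. A cluster changes upon
knockdown iff |Δusage| ≥ 10% in ≥ 2 of 3 matched replicate pairs with a
common sign and no pair in the opposite direction. Confident
non-changing exons need ≥ 10 reads in every sample and all |Δusage| ≤
5%. Nuclear/cytoplasmic calls are compared into shared and
compartment-specific sets.

**Tandem-APA classification.** DaPars-style tables are thresholded on
dPDUI = PDUI(control) − PDUI(knockdown): |dPDUI| ≥ 20% with adjusted
p < 0.05 is changing (dPDUI > 0: the RBP lengthens the 3'UTR);
|dPDUI| < 5% with p > 0.05 is non-changing.

**Positional binding analytics.** Per-nucleotide RNA maps of the
fraction of PAS with same-strand peak coverage in a ±500 nt window; a
per-position two-tailed Fisher exact test between regulated and control
PAS sets (reported as signed −log10 p); expressed-3'UTR binding
fractions under a TPM filter; priority-based peak-to-feature
assignment; base-pair Jaccard overlap between peak sets.

**Motif architecture.** Sliding-window motif frequency maps (10-nt
windows for 4-mers, 20-nt for 6-mers; running means of 5 and 10 nt),
UGUA→hexamer spacing CDFs around bound PAS (gap between the upstream
motif's 3' end and the downstream motif's 5' start), reverse-complement
proximity, and GC-content profiles.

**Synthetic data.** `simulate_genome()` plants PAS blocks (UGUA at a
configurable gap, hexamer 10–15 nt upstream of a CA cleavage site,
A-free downstream element), A-run internal-priming decoys, usage shifts
per condition/compartment, peaks at configurable offsets, and dPDUI
tables — all recorded as ground truth and byte-reproducible under a
fixed seed.

## Worked example

```r
library(apamap)

cfg <- sim_config(n_genes = 50, depth = 500, rng_seed = 42)
sim <- simulate_genome(cfg)
manifest <- sim_manifest(replicates = 3)
ends <- simulate_endseq(sim, manifest)

clusters <- filter_clusters(call_clusters(ends), sim$genome,
                            reference_pas(sim))
clusters
#> end_clusters: 105 clusters, 12 samples
#>   surviving after filters: 100

usage <- compute_usage(assign_to_exons(surviving_clusters(clusters),
                                       sim$models, flank = 50))
m_nuc <- manifest[manifest$compartment == "nuclear", ]
head(diff_usage(usage, m_nuc), 3)
#>    exon_id     call  direction
#> 1:    g001 changing shortening
#> 2:    g002 changing shortening
#> 3:    g003 changing shortening
```

105 clusters are called from the pooled pileup; the filter battery
removes the five A-rich decoy clusters (10% of 50 genes), leaving
exactly one surviving cluster per planted PAS (2 per gene). Exons
whose knockdown samples shift ≥ 10% towards the proximal PAS in ≥ 2 of
3 replicates are called `changing` with direction `shortening` (the
knockdown shortens the 3'UTR, i.e. the RBP normally lengthens it).

```r
peaks <- simulate_peaks(sim)
tg <- sim$truth$genes
fi <- positional_fisher(peaks,
                        pas_anchors(sim, 1, tg$gene_id[tg$changing]),
                        pas_anchors(sim, 1, tg$gene_id[!tg$changing]),
                        window = c(200, 100))
fi$position[which.max(fi$signed_neglog10p)]
#> [1] -54
```

The enrichment profile peaks within a few nucleotides of the planted
−50 nt peak offset upstream of regulated proximal PAS.

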