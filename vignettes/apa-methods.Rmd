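---
title: "Methods: PAS cluster calling, differential 3'UTR isoform usage and positional binding analysis"
author: "apamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAS cluster calling, differential usage and positional binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

apamap implements the analysis layer for a targeted 3'-end sequencing +
eCLIP study of alternative polyadenylation (APA): which polyadenylation
sites (PAS) exist in terminal exons, how their relative usage shifts
when an RNA-binding protein (RBP) is depleted, where the RBP binds
relative to regulated PAS, and what the cis-element architecture
(UGUA enhancer, AAUAAA/AUUAAA hexamer, downstream U/G-rich element)
looks like around those sites. Upstream steps — read trimming,
alignment, TPM quantification, DaPars' internal regression and
CLIPper/IDR peak calling — are out of scope; their outputs are consumed
as standard files (BED/narrowPeak/GTF/TSV).

## Coordinate and strand conventions

All intervals are held in `GRanges`, 1-based and closed, the native
convention of the R/Bioconductor interval stack; BED-family files are
converted on read/write by rtracklayer, so round-trips are lossless.
Every "upstream/downstream" in the package is transcript-strand
relative: windows anchored on minus-strand PAS are mirrored and
sequence windows reverse-complemented before any motif or composition
work. Peak-versus-feature overlap always requires matching strands,
because eCLIP and 3'-end sequencing are stranded assays.

# PAS cluster calling

Because cleavage is imprecise, site usage is quantified on clusters of
read 3' termini rather than single positions. Read ends are pooled
across **all** samples of the run so cluster boundaries are shared;
a cluster is a maximal run of consecutive positions each with pooled
coverage strictly greater than `min_per_base` (default 10), and
clusters with fewer than `min_cluster_reads` (default 20) pooled reads
are removed. The thresholds are read literally: "more than 10" keeps
positions with 11+, "fewer than 20" keeps totals of exactly 20. The
cluster's PAS is the position of maximal pooled coverage; ties break
towards the transcript 3' end (highest coordinate on plus, lowest on
minus).

## Internal-priming filter battery

Oligo-dT mispriming on genomically encoded A-stretches creates false
3'-end signal. Four independent, order-commuting filters are applied;
a cluster survives only if all pass:

1. **A-run** — more than 6 consecutive sense-strand adenosines directly
   downstream of the PAS. The inspection window is not specified by the
   rule itself; we use 10 nt (mirroring the A-content window) and make
   it configurable.
2. **A-content** — more than 7 A within the 10 nt directly downstream
   of the cluster's 3' boundary.
3. **Hexamer** — the cluster must contain AAUAAA or AUUAAA (DNA sense
   AATAAA/ATTAAA) *fully within* its interval. Strict containment is a
   deliberate choice; a hexamer straddling the boundary does not count.
   The identity found is recorded.
4. **Reference** — the cluster must overlap (same strand, ≥ 1 nt) a
   record of a curated PAS database supplied as BED. Interval overlap
   rather than exact coordinate match is used because such databases
   store clustered coordinates.

At contig edges the filters inspect whatever sequence exists.

# Differential usage

Per terminal exon and sample, a cluster's usage is its read count over
the exon's total; exons with zero reads in a sample yield `NA` usage,
never 0/0. Clusters are attached to a terminal exon when their PAS
falls inside it, optionally extended downstream (default 50 nt in the
pipeline driver) because 3'-end clusters commonly extend slightly past
annotated ends.

A cluster is *changing* upon knockdown iff at least ⌈2k/3⌉ of its k
matched replicate pairs (default k = 3) show |Δusage| ≥ 10% with a
common sign **and** no pair moved in the opposite direction at any
magnitude; exact zeros are neutral. Δ is knockdown minus control,
paired by (compartment, replicate). An exon is changing iff any cluster
is (two or more clusters required); its direction is taken from the
distal cluster: positive distal Δ means the knockdown lengthens the
3'UTR (the RBP normally shortens it), negative means shortening. The
10% threshold is an absolute usage-fraction change, consistent with
PDUI-style deltas.

*Confidently non-changing* exons need ≥ 10 total reads in every sample
and every cluster |Δ| ≤ 5% in every replicate pair. Compartment
comparison then classifies exons changing in both compartments as
shared; changing in one and confidently non-changing in the other as
compartment-specific; changing/indeterminate pairs belong to no
category. This stringency is intentional and has a measurable cost: at
depth 500 and usage 0.3/0.7, the multinomial noise of a usage delta has
SD ≈ 0.029, so a single replicate exceeds the 5% band with probability
≈ 8.5%, and a genuinely silent exon passes all six cluster × replicate
checks only ≈ 60% of the time. Compartment-specific recovery is
therefore conservative — correct when made, incomplete by design.

# Tandem-APA classification

dPDUI tables (DaPars-style) are thresholded, not re-tested: dPDUI =
PDUI(control) − PDUI(knockdown), so positive values mean depletion
shifted usage towards the proximal PAS, i.e. the RBP lengthens the
3'UTR. |dPDUI| ≥ 20% with adjusted p < 0.05 is changing; |dPDUI| < 5%
with adjusted p > 0.05 is non-changing; everything else, including rows
with missing p, is "other". "FDR" and "adjusted p-value" are treated as
the same provided column. Gene-level summaries count a gene once no
matter how many of its exons change. A simplified coverage-ratio PDUI
estimator (`estimate_pdui`) is provided purely as plumbing for
synthetic coverage; it does not reimplement DaPars' regression.

# Positional binding analytics

RNA maps report, per transcript-relative position in a window (default
±500 nt), the fraction of anchors (PAS) covered there by at least one
same-strand peak; "bound at a position" means the peak interval covers
that nucleotide. Anchors can be pre-filtered by read support (default
≥ 100 reads) to restrict to well-expressed PAS. Between a regulated and
a control anchor set, each position's 2×2 bound/unbound table is tested
with the standard two-tailed Fisher exact test (sum of conditional
table probabilities not exceeding the observed table's), reported as
−log10 p signed by the direction of enrichment. No multiple-testing
correction is applied by default, matching how such profiles are
plotted; Benjamini-Hochberg across positions is available behind a
flag. The per-table p is delegated to `stats::fisher.test`; the test
suite verifies it against an independent full-enumeration
hypergeometric oracle for every margin combination up to n = 30.

Peak-to-feature assignment uses a fixed priority (3'UTR > 5'UTR > CDS >
non-coding exon > intron > downstream flank > other) so fractions sum
to one; the priority is configurable because no single convention is
universal. Jaccard overlap between peak sets is computed in covered
base pairs over strand-aware merged intervals.

# Motif architecture

Motifs are declared in the RNA alphabet and scanned in DNA. Frequency
maps use a sliding window — 10 nt for 4-mers (UGUA class), 20 nt for
6-mers (hexamer class) — counting, per position, the fraction of
sequences with an occurrence *starting* inside the window centred
there, then smooth with a running mean of 5 nt; nucleotide-composition
profiles use a 10-nt running mean. Running means shrink to the valid
range at the edges, keeping profile length constant and conserving the
mean. For even window widths the window is left-heavy by one position;
this is documented rather than hidden because it shifts nothing by more
than half a window.

Spacing distributions measure, per anchor, the minimum gap in
nucleotides between the 3' end of an upstream motif occurrence and the
5' start of a downstream one (0 = abutting), within ±150 nt of the
anchor, optionally restricted to anchors with a peak center within
100 nt. Pairs are strictly ordered (UGUA upstream of the hexamer),
following the upstream-enhancer biology; anchors lacking a pair are
censored and counted. Ties between equal-gap pairs resolve towards the
pair whose downstream motif is nearest the anchor. Reverse-complement
proximity applies the same gap convention in either order; the
conventional printed form UUUAUU is used for the hexamer complement
class.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and were fixed before the downstream checks were written.
Each gene is single-exon with a 200-nt CDS and a terminal exon carrying
two PAS blocks laid out as: UGUA — linker of `ugua_gap` nt (default 50;
the canonical enhancer-to-hexamer spacing is ~40–60 nt) — hexamer
(AATAAA 75% / ATTAAA 25%) — 10–15 nt — CA cleavage dinucleotide —
20-nt A-free U/G-rich downstream element (a CstF-like DSE, which also
guarantees true PAS can never trip the A-content filter). Half the
genes are on each strand.

**Read model.** Per exon and sample, total reads are Poisson(depth,
default 500), split across PAS by the condition's usage vector
(control 0.3/0.7, knockdown 0.6/0.4 in changing genes: a planted 30%
shift towards the proximal site). Each read's 3' end is the cleavage
site plus an offset drawn from a mixture: a triangular jitter of at
most ±5 nt (weight 0.5) and a uniform upstream heterogeneity tail over
−26..−1 (weight 0.5). The tail models the well-known microheterogeneity
of cleavage and is what makes pooled clusters span ≈ 32 nt — wide
enough to contain the hexamer, as real 3'-end clusters do; with tight
jitter alone, no cluster of cleavage positions could ever contain a
hexamer that sits 10+ nt upstream, and the hexamer filter would be
unsatisfiable by construction. The hexamer-to-cleavage offset is drawn
from 10–15 nt so the hexamer always sits several nucleotides inside
the observed cluster span.

**Decoys.** A configurable fraction of genes (default 10%) carries one
internal-priming decoy: a planted 15-nt genomic A-run with reads
(0.3 × depth) jittered at most ±2 nt just upstream of it. The run
length guarantees that both A filters trigger regardless of jitter;
decoys are never placed in the reference PAS set.

**Background hygiene.** Outside planted elements the sequence is
generated at a configurable GC (default 0.5) and sanitized: AATAAA,
ATTAAA, TGTA, TACA, UUUAUU's DNA form, and A/T homopolymer runs ≥ 5 are
mutated away, and piece junctions are C/G-guarded so no forbidden
pattern can straddle them. This is what makes recovered spacing CDFs
exact step functions and lets the A-run invariant hold genome-wide;
real 3'UTRs of course contain chance motifs, so spacing CDFs on real
data are mixtures of signal and background that this generator
deliberately does not emulate.

**Compartments, peaks, dPDUI.** Changing genes are partitioned into
shared (80%), cytoplasmic-only and nuclear-only (10% each) shifts.
Changing genes receive one peak centred −50 ± 10 nt from their proximal
PAS; half of the non-changing genes receive a background peak at a
random CDS position. Simulated dPDUI tables derive PDUI from the
planted usage with Gaussian noise (default SD 0.01); adjusted p-values
are *generated*, not computed — below 0.01 for planted events and
Uniform(0.2, 1) for nulls. The null p floor of 0.2 (rather than
Uniform(0, 1)) is deliberate: the table models the post-thresholding
contract of a DaPars run, and a uniform null would by construction
scatter ~5% of genuinely silent exons into the "other" class, making
exact class recovery on noiseless tables impossible for reasons that
have nothing to do with the classifier under test.

**Determinism.** All sampling derives from `rng_seed`; a fixed seed
reproduces FASTA bytes, read tables, peaks and dPDUI tables exactly.
Sample draws are sequential over the manifest, so replicates share a
stream but never a read set.

## What passing tests do and do not show

The simulator plants clean geometry: motif spacings are exact, decoys
are unambiguous, read depth is generous and uniform across exons, and
there is no sequencing error, mappability structure, batch effect or
expression-level variation. Passing recovery tests therefore
demonstrates the *correctness of the algorithms and thresholds*, not
expected performance on real libraries, where cluster boundaries,
hexamer variants beyond the top two, and reference-database coverage
all degrade gracefully rather than exactly.

# Problem sizes and numerical choices

The shipped test-and-verification scenarios use 200–500 genes at depth
500 with 12 samples (2 conditions × 2 compartments × 3 replicates),
sizes at which every stochastic margin in the checks (binomial SEs,
Poisson coverage floors) is comfortably clear of its threshold while a
full run of suite plus verification script stays in the minutes range
on a single core. Interval arithmetic is exact integer work throughout;
the only floating-point comparisons are usage fractions and p-values,
checked to 1e-9 where exactness is claimed. Degenerate inputs are
defined, not special-cased: empty pileups give empty cluster sets, an
empty reference fails all clusters with a warning, zero-read exons give
`NA` usage, and positions bound in neither anchor set have p = 1.

# Interfaces

The package's functions are its interface; `run_pipeline()` drives a
whole scenario from one YAML config (keys = `sim_config()` arguments)
and writes every declared table (clusters, usage, per-compartment
calls, compartment overlap, dPDUI calls, RBP summary, RNA map, Fisher
map, spacing) as commented TSV alongside the simulated FASTA, GTF, BED
and narrowPeak inputs. `scripts/acceptance.R` recomputes the headline
recovery quantities from scratch and writes them as JSON.

# Known limitations

- One transcript per gene in the annotation reader's derived models;
  multi-isoform 3'UTR structures are represented only through their
  terminal exons.
- IDR, CLIPper and DaPars internals are consumed, never recomputed; the
  `reproducible` peak tier is whatever high-confidence file the user
  supplies.
- The change-calling rule is deliberately rule-based (as in the
  targeted 3'-end assay it models), not a statistical test; no p-values
  are attached to usage calls.
- The replicate-consistency rule generalizes as ⌈2k/3⌉ for k ≠ 3, a
  natural but not unique extension.
- Compartment-specific recovery is stringency-censored, as quantified
  above.
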