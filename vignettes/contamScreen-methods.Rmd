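---
title: "Reference-free contamination screening: models and methods"
author: "contamScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free contamination screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A bacterial sequencing run rarely contains only the organism of interest.
Saliva-derived samples, co-cultures and environmental isolates mix the
target species' reads with reads from unintended organisms — contamination
— and the standard remedy, mapping against reference genomes, is
unavailable precisely when it is most needed: for newly sequenced or
poorly characterised species, often all that is known is a handful of
marker genes. `contamScreen` implements a reference-free screen built on
three observations:

1. contigs assembled from a mixed community can be grouped into
   species-level clusters using only their tetranucleotide composition and
   read depth;
2. a few clade-specific marker genes suffice to decide *which* cluster is
   the target species; and
3. once target contigs are known, the raw reads can be rescued by mapping
   them back onto those contigs.

The pipeline is: quality trimming → de Bruijn assembly → contig
length-window preparation → mixture-model binning at a fixed cluster
number K → marker-gene target calling → read rescue, with K supplied
either manually or by counting taxa hit by small-subunit rRNA reads.

## Stage models and parameters

**Trimming** (`trimReads`) removes leading and trailing bases whose
quality falls below a phred threshold (default 3), one base at a time,
then discards reads shorter than 50 bp. Both mates of a pair are dropped
when either fails: the assembler and the pair-aware rescue logic assume
intact pairs, and the ledger arithmetic stays simple. An optional
fixed-cut mode removes a constant number of terminal bases instead, for
data whose quality strings are unreliable. Trimming is idempotent, and
raising the threshold can only shrink the surviving set.

**Assembly** (`buildUnitigs`) is a minimal node-centric de Bruijn
assembler for low-error reads: canonical k-mers (k odd, default 31) are
counted, k-mers seen fewer than `min_count = 2` times are discarded as
likely sequencing errors, and maximal non-branching paths are emitted as
unitigs in canonical orientation. k = 31 sits comfortably above the
uniqueness threshold for genomes in the megabase range while fitting in a
64-bit word; it is a parameter, so smaller values remain available for
comparison. The assembler does no error correction beyond the abundance
filter and no scaffolding — it exists so the pipeline is self-contained
and exactly analysable on simulated data; contigs from any external
assembler can be substituted (`externalContigs`) and flow through the
identical downstream stages.

**Preparation** (`prepareContigs`) keeps the binning substrate
statistically homogeneous: contigs below 1,000 bp are dropped (their
4-mer profiles are too noisy), contigs above 10,000 bp are cut into
10,000 bp pieces, and an undersized final piece is merged into its
predecessor rather than discarded so no base of a surviving contig is
lost. A 600 bp floor is sometimes used in the field; the floor is a
parameter.

**Binning** (`contigFeatures` + `fitClusters`) follows the
composition-plus-coverage paradigm. Per contig the features are the 136
canonical tetranucleotide frequencies (pseudocount 1, normalised,
log-transformed) and log(depth + 1) per sample. Every dimension is
standardised, and each block is then scaled by the square root of its
dimension count so composition (136 dims) and coverage (often 1 dim)
carry equal total variance; without this, a real depth difference between
two genomes of similar composition is invisible among 136 noise-scaled
dimensions. PCA keeps the leading components explaining 90% of variance,
and a K-component diagonal-covariance Gaussian mixture is fitted by EM
from kmeans-seeded restarts (default 10), one restart seeded from each
feature block alone, and coarser kmeans seedings that start with fewer
than K occupied components. The winning restart is chosen by BIC with
the parameter count restricted to non-empty components: K — supplied by
the rRNA species count or set manually — is a component *budget*, not a
mandate. This matters when the community is unbalanced: with a 95%
target, contaminant genomes are barely assembled, the data hold fewer
real groups than K, and a pure maximum-likelihood fit at full K shreds
the one big target cluster across surplus components, after which
marker-based calling loses every unmarked fragment. Letting surplus
components stay empty keeps real clusters whole while fully separated
communities still occupy all K components. Component variances are
floored at 1% of each dimension's global variance — an absolute floor
would let a component collapse onto duplicated contigs and win the
likelihood with a spike. Hard assignments take the maximum
responsibility, ties to the lowest cluster id for determinism.

**Species counting** (`countSpecies`) plays the role of a 16S survey
without a database download: reads are locally aligned against a
user-supplied rRNA FASTA (seed-and-extend, identity ≥ 0.95 over ≥ 90% of
the read), each read is credited to its best-matching taxa (ties credited
to all, which can only add taxa), and K is the number of taxa with at
least `min_hits = 5` assigned reads — the hit floor suppresses spurious
single-read assignments. Zero passing taxa degrades to K = 1 with a
warning rather than an error.

**Target calling** (`alignMarkers` + `callTargetClusters`) aligns the
marker genes to the prepared contigs with an ungapped seed-and-extend
aligner (exact 15-mer seeds, match +1 / mismatch −2, x-drop 20) and
scores each hit with the standard Karlin–Altschul expectation
`E = K·m·n·exp(−λS)` (λ ≈ 1.33 for +1/−2 at uniform composition,
K = 0.621); hits above `E = 1e-20` are discarded. A cluster is called
target when at least `min_markers` (default 1) distinct markers hit any
of its contigs — calling is cluster-level because the whole cluster is
the unit the evaluation counts, and several clusters may be called when
markers scatter. External tabular hit files are accepted in place of the
built-in aligner. No qualifying cluster yields an explicit `NO_TARGET`
result (exit status 2 at the command line), never an exception.

**Rescue** (`mapReads` + `rescueReads`) maps reads end-to-end onto
contigs via an exact 21-mer seed table with full-length verification
(identity ≥ 0.95, ties to the lexicographically smallest contig id, then
position, then forward strand). Rescued reads are those whose best
alignment lands on a target contig; when writing FASTQ a pair is kept if
either mate qualifies, and both mates are emitted, preserving as much of
the target's genomic information as possible.

## Evaluation

With a truth table (read → species, species → role) the run is scored by:
per-cluster **purity** at contig and read level (reads inherit their
contig's label; the dominant species is chosen by contig count, ties by
read count then lexicographically), with cumulative 100/90+/80+ tiers;
**target concentration**, the distribution of target-species contigs and
reads across the truth-defined target clusters (any cluster holding ≥ 1
target contig), summing to 100%; **sensitivity and specificity** of the
marker-identified clusters at contig and read level, where the "all
target" denominators are the target items still present after contig
preparation, so the score isolates the binning and marker stages while
the preparation cost is charged separately by the data-loss ledger;
**base coverage**, the fraction of target-genome positions covered at
least once by rescued reads (interval union via `IRanges::reduce`); and
**gene coverage**, the fraction of annotated genes overlapped by ≥ 1 bp
of an aligned target contig (the interval-intersection step a
practitioner would run through bedtools, done here with
`GenomicRanges`). The two target-cluster notions — truth-defined (for
concentration) and marker-identified (for sensitivity/specificity) — are
deliberately distinct objects in the code because they answer different
questions.

The data-loss **ledger** records reads (and truth-target reads) entering
and surviving each stage — trimming, assembly (reads mappable to raw
unitigs), binning (reads mappable to prepared contigs), marker rescue —
and `dataLoss` reports marginal and cumulative percentages whose
survival fractions compose multiplicatively.

## The simulator and what it does and does not emulate

`simulateReads` draws error-free (by default) 120 bp read pairs on
constant 200 bp fragments, fragment starts uniform, mate 2
reverse-complemented, qualities constant phred 40. The pair count is
`N = coverage × Σ genome lengths / (2 × read length)`, i.e. coverage is
quoted against the whole genome pool, and each pair's genome is drawn
with its configured read proportion — this reproduces pool-coverage
bookkeeping in which ~30 Mb of genomes at 100X yields ~12 million pairs.
A `tiled` mode fragments each genome deterministically every 200 bp for
tests that need exact tilings, and a uniform-substitution error mode
exercises the abundance filter; indels, quality ramps, chimeras and
platform artifacts are deliberately out of scope. `communityPreset`
builds the standard benchmark community: a 200 kb target at GC 0.50 with
five planted 600 bp markers and fifty 900 bp annotated genes, plus ten
100 kb contaminants on the GC grid 0.25–0.75 (step 0.05, the target's
0.50 excluded) — a scaled-down stand-in for one target plus ten oral
contaminant genomes whose compositions differ. Marker sequences are
rejection-sampled until they share no 15-mer with any contaminant, making
marker specificity a property the simulator guarantees rather than hopes
for. Real genomes have repeats, shared k-mers, uneven composition and
real rRNA operons; passing on this simulator therefore demonstrates the
pipeline's mechanics and bookkeeping, not its performance on real mixed
communities.

## Numerical choices and degenerate inputs

Phred+33 is required; quality characters above 'K' abort parsing rather
than being rescaled. K-mers containing N are skipped wherever k-mers are
taken. All interval work uses `GRanges`/`IRanges` (1-based closed)
internally, converting GFF3 (1-based) and BED (0-based half-open) only at
file boundaries; the converters are involution-tested. Unitigs, marker
hits, mapped placements and cluster hard assignments all carry explicit
deterministic tie-breaks (sorted k-mers, lexicographic contig ids, lowest
cluster id), so a fixed seed and config reproduce every output file
byte-for-byte. Empty inputs degrade predictably: an empty read set
assembles to an empty contig set with a warning; an empty marker hit
list gives `NO_TARGET`; an empty cluster gets `NA` purity.

## Problem sizes

The bundled benchmark (`gradientExperiment`) runs the full pipeline on
~250,000 read pairs per proportion (1.2 Mb of genomes at 50X) in a few
minutes on one core; unit tests use kilobase-scale genomes where
brute-force oracles (path enumeration over the k-mer graph, per-base
coverage bitmaps, exhaustive 15-mer intersection) remain exact and fast.

## Known limitations

One target species per run; single-sample coverage (the multi-sample
feature pathway exists but the simulator emits one sample); no automatic
K selection; the built-in assembler and mappers assume low-error reads
and are not competitive with production tools on real data; genus-level
taxonomic benchmarking and database-driven species identification are
out of scope.
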