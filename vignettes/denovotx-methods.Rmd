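---
title: "Reference-free transcript reconstruction from noisy long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free transcript reconstruction from noisy long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovotx)
```

# Overview

`denovotx` reconstructs a transcriptome from error-prone long cDNA/dRNA
reads without a genome or annotation. The pipeline is
`cluster genes -> split isoforms -> correct -> polish/quantify`, with a
bundled simulator and evaluation metrics. This vignette explains the
model behind each stage, the tunable parameters and their defaults, the
numerical choices made where the procedure left room, and what the
simulation-based tests do and do not establish.

# Read-pair similarity

All clustering rests on an alignment-free similarity for a pair of
reads, computed in two steps.

**Bit-vector screen (k = 6).** Each k-mer is hashed with the positional
base code $H(A)=0, H(C)=1, H(G)=2, H(T)=3$,
$H(b_1 \dots b_k) = 4^{k-1}H(b_1) + \dots + H(b_k)$, an injective map
into $[0, 4^k)$, and the read becomes a presence bit-vector. The screen
score is the shared k-mer count over the larger of the two distinct
k-mer counts. At k = 6 the 4096-slot vector is dense enough that two
reads from one gene share many slots even at 7–10% error, while the
score stays cheap (one set intersection). k is capped at 15 so the hash
fits a 32-bit integer. Ambiguous bases are substituted by `A` *for
hashing only*: they are rare after quality filtering, and a 2-bit
alphabet keeps the hash positional; output sequences keep the original
symbols.

**LIS chain score (k = 10 gene stage, k = 11 isoform stage).** Shared
k-mers with their positions in both reads form triplets $(s, p_1, p_2)$,
sorted by $(p_1, p_2)$. The longest subsequence strictly increasing in
*both* coordinates — the longest collinear chain — is found by dynamic
programming. The score is the total length of the union of the chain's
$[p_1, p_1+k)$ intervals divided by the length of the shorter read, so a
clean truncated copy of a read still scores 1. Strict increase in both
coordinates prevents a k-mer repeated in one read from matching twice at
one position; among equal-length chains we return the lexicographically
smallest in $(p_1, p_2)$, which makes the output platform-independent.
Coverage is measured on read 1's coordinates; for exact matches chain
intervals have the same total length on both reads, so the score is
symmetric.

For cDNA libraries the strand of each read is unknown, so both relative
orientations of the second read are evaluated and the orientation with
the higher LIS score wins; `rna_mode = TRUE` (direct RNA, stranded)
tests only the given strand.

# Greedy gene clustering

Reads are sorted by decreasing length (ties broken by read id — every
ordering in the package has a deterministic tie-break) and processed
once per threshold of the schedule. The schedule descends from
`B_init = 0.4` to `b_final = 0.2` in steps of `f_step = 0.05`, then
appends a final 0.0 pass in which the bit-vector gate is open and only
the LIS score decides. The LIS threshold `s_lis = 0.2` is fixed over the
whole procedure.

Within a pass, each unclustered read is compared against the
*representative* of every existing cluster in cluster-creation order and
joins the first one passing both thresholds; otherwise it founds a new
cluster. "First passing wins" (rather than best-scoring) is the greedy
reading; it costs O(#clusters) per read and is deterministic because
the scan order is fixed. After the assignment sweep, representatives
are compared pairwise and clusters that match are merged transitively
within the pass, the surviving cluster keeping the smaller id; strand
flags are propagated along the merge edges so all members of a cluster
stay on one strand. Representatives are recomputed after each pass, not
after every insertion — recomputing mid-pass would make results depend
on insertion order and costs more for no observed accuracy gain.

The representative is the member at 0-based index
$\lfloor p \cdot N \rfloor$ of the descending-length ranking with
`p_repr = 0.15` — long enough to span the transcript, but not the very
longest read, which is disproportionately likely to be chimeric or to
carry unusual ends.

# Isoform splitting

Let the chain for a read pair be $(p_1^{(i)}, p_2^{(i)})$ and define
adjacent gap differences
$d_i = (p_1^{(i+1)} - p_1^{(i)}) - (p_2^{(i+1)} - p_2^{(i)})$. For reads
from the same isoform, indels only jitter $d_i$ by a few bases; an
internal exon of length $L$ present in one read only contributes a
single $d_i \approx \pm L$, inflating the variance of $\{d_i\}$ by
roughly $L^2/m$ for a chain with $m$ gaps. Reads are separated into
different transcript clusters when this variance exceeds
`iso_max_variance` (default 25 nt²). We use the *population* variance:
with short chains the $n-1$ denominator of the sample variance blows up
exactly where the estimate is weakest, and the criterion is a threshold
on a descriptive statistic, not an inference.

The pairwise criterion leaves the grouping algorithm open; we reuse the
greedy representative scheme of the gene stage (stage parameters
k = 11, LIS ≥ 0.30, variance ≤ threshold), which keeps the pipeline's
semantics uniform. A read whose comparison against *every* sub-cluster
representative yields a chain of fewer than 3 members — too short for
any variance estimate — joins the best-scoring sub-cluster if it passes
the LIS threshold, avoiding spurious singletons from short or noisy
reads. Whether the variance criterion should be applied over the full
pairwise graph instead of representatives only is not determined by the
procedure's description; the representative form is consistent with the
rest of the pipeline and O(N) per cluster.

# Error correction

Transcript clusters with more than `min_cluster_reads = 5` members are
corrected; smaller clusters are routed unchanged to the uncorrected
output (the bound is strict: a 5-read cluster is skipped). A cluster of
N reads is cut into blocks of `block_size = 200`: one block if N < R,
two halves if R ≤ N < 2R, else $K = \lceil N/R \rceil$ blocks (the
K ≥ 3 case is pinned only implicitly; the ceiling keeps every block at
most R). Blocks are filled round-robin from the length-sorted members
so each block spans the cluster's length range rather than stratifying
by length.

**MSA engine.** Each block is multiply aligned. The engine is pluggable
behind `build_msa()`; the default drives the external MAFFT aligner
(deterministic, order-preserving, single-threaded here), and a trivial
gap-free engine covers identical-sequence blocks and unit tests. The
engine contract is checked after every call: rows de-gap exactly to
their input reads.

**Terminal trimming.** Noisy reads often have a few bases aligned far
from the read body. Per aligned row and per end, a terminal block
(maximal run whose internal gap runs are ≤ 3 columns) is erased when
its aligned length is < 10 nt and it is separated from the rest by
≥ 20 gap columns, repeating until stable. Trimming runs *before*
column correction so the islands cannot vote.

**Column correction.** For each column, counts are taken over the rows
*spanning* it (first and last aligned base bracket the column) — a
read's terminal gaps say nothing about its sequence, but internal gaps
do. When the consensus symbol reaches `consensus_freq = 0.60` of the
spanning rows, each discordant spanning row is edited: a mismatched
base is substituted *unless* its own error probability (from the FASTQ
quality) is at most `err_ratio_guard = 1/3` times the mean error
probability of the consensus-carrying bases in that column — a
confident outlier base is more likely a real variant than an error.
Insertions (row gap under base consensus) and deletions (row base under
gap consensus) are applied without the quality guard, since a gap
carries no quality. Three conservative choices where the procedure is
silent: the "average quality of the consensus" is the mean *error
probability* (not mean PHRED), keeping the guard's units consistent;
inserted bases receive the column's mean consensus PHRED; and columns
spanned by fewer than 3 rows never trigger corrections — two reads
cannot outvote one.

The block consensus is the per-column argmax symbol (ties broken in
fixed A,C,G,T,gap order; gap-consensus columns dropped) with per-base
quality the rounded mean PHRED of the aligned bases in the column,
clamped to [0, 93]. Block consensi are realigned with the same engine
and the final cluster consensus extracted the same way.

# Polishing and quantification

The greedy gene-stage clustering is re-run on the cluster consensi (the
corrected consensus serves as the cluster's representative read — it is
more accurate than any raw member). Groups that merge are unioned;
abundance is the total member-read count; when a merge spans gene
clusters, the gene with more transcript clusters absorbs all
transcripts of the smaller one, ties going to the smaller gene id.
Reads of skipped (≤ 5-read) clusters are not counted into any
transcript's abundance — counting unretained reads would require an
assignment step the pipeline does not perform. Transcript ids are
assigned in descending abundance order so outputs diff cleanly.

# The simulator

The simulator exists to exercise every algorithmic path with known
truth, at desk scale. `make_gene()` draws uniform-random exon sequences;
`make_skipped_exon_pair()` builds the two-isoform design (flank + exon +
flank vs flank + flank) used for the separability experiments;
`generate_dataset()` simulates reads with truth labels and can emit a
GTF of the synthetic models plus idealized truth alignments (PAF with
`cg:Z:` cigars) for closed-loop evaluation of the feature metrics.

Defaults, chosen once as typical of an R9.4 cDNA run and not revisited:
7% total error split as 3.5% substitutions, 1.75% insertions, 1.75%
deletions; geometric 5' truncation with mean 15 nt (the 5' ends of
mRNAs are typically under-recovered); per-base PHRED scores drawn as
$\mathrm{round}(\mathcal{N}(q_0, 2))$ clamped to [1, 41] with
$q_0 = -10\log_{10}(\text{total rate})$; forward strand unless
`frac_reverse` is set. All randomness is seeded and the caller's RNG
state is restored.

What the simulator does *not* model — and hence what passing tests do
not show about real data: basecaller-specific error profiles
(homopolymer compression, systematic miscalls), the correlation between
a base's quality score and whether it is actually erroneous, empirical
read-length distributions, chimeras and adapter remnants, and shared
sequence between genes (paralogy); simulated genes are unrelated random
sequences, so gene clustering on real paralog families is harder than
these tests suggest.

# Evaluation metrics

Clustering is scored against truth labels with the adjusted Rand index
and entropy-based homogeneity $h$, completeness $c$ and V-measure
$2hc/(h+c)$, implemented from their definitions (reference
implementations serve as test oracles only). Exon–intron accuracy
follows the feature-set approach: introns, intron chains (ordered
intron tuples), internal and external exons, as 1-based inclusive
stranded coordinates, compared by exact equality — no positional slack,
matching the exact-match convention for spike-in annotations. Recall is
the fraction of unique annotated features found; precision the fraction
of unique predicted features annotated; read-precision weights each
predicted feature by its read support. `support_sweep()` recomputes the
metrics as predictions are filtered by minimum read support;
`support_threshold()` reports the smallest threshold reaching a target
precision (operationalizing "approximately 0.95" as the first threshold
with precision ≥ 0.95, for determinism). Intron extraction from PAF
requires the `cg:Z:` cigar; records without it are rejected rather than
guessed at.

# Problem sizes and test design

The test suite and the acceptance script run at sizes chosen to
exercise every path with comfortable statistical margins: clustering
recovery uses 10–20 genes with 5–500 reads per transcript (log-uniform
mixture for the abundance-recovery check, Pearson r ≥ 0.95); the
isoform-separability experiment sweeps skipped-exon lengths 25–145 nt
in 10-nt steps with 400-nt flanks and 50 reads per isoform at variance
threshold 5, reporting the smallest length with > 90% of reads on the
correct side of a best one-to-one cluster/isoform matching; consensus
accuracy is checked at ≥ 99.5% identity on clusters with ≥ 20 reads.
LIS correctness is verified against exhaustive search on ≥ 1000 random
instances of ≤ 15 triplets.

# Known limitations

* Isoforms differing only at their 5'/3' termini are confounded with
  truncation and are not separated (no claim is made for them).
* The gap-variance criterion needs the alternative exon to be long
  enough relative to chain noise; below ~35–45 nt (simulator
  conditions) pairs are not reliably split.
* Quantification counts only reads in retained (> 5-read) clusters;
  very low-abundance transcripts are reported as absent rather than
  guessed.
* Greedy first-match assignment is order-dependent by design;
  determinism is guaranteed, globally optimal clustering is not.
* The MAFFT engine, not a partial-order aligner, builds the MSAs; for
  blocks of a few hundred reads at 7–10% error the column consensus is
  robust to this choice, and the engine seam (`build_msa()`) is the
  single point of replacement.
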