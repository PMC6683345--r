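---
title: "Methods and design choices in bartkit"
author: "bartkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in bartkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bartkit)
```

# Overview

`bartkit` implements the computational side of targeted amplicon sequencing
with combinatorial dual DNA barcoding: every well of a plate receives primers
carrying one of *m* forward and one of *n* reverse 8-mer barcodes, so a single
pooled sequencing run resolves *m x n* samples. The package covers the whole
loop:

1. **Panel design** — select mutually dissimilar barcodes and adapters by
   simulated annealing, and screen their ligations against a reference.
2. **Primer design** — generate 3'-T candidate primer pairs per locus and
   pick one pair per locus minimizing cross-dimer stability of the fully
   barcoded oligo set.
3. **Simulation** — emit paired-end reads with the exact read structure,
   plus a per-read ground truth, so all downstream steps are testable
   without sequencing data.
4. **Demultiplexing** — assign reads to wells (single-mismatch tolerant) and
   amplicons, and tabulate forward x reverse count matrices.
5. **Normalization and filtering** — spike-in scaling factors, per-barcode
   spike bias correction, empty-well and doublet filters.
6. **Genotyping** — wild-type/mutant allele counting and the ratio rule.

# Read structure

Both mates share the same 5' layout:

```
R1: [protection (CCA)] [fwd barcode (8)] [fwd adapter (10)] [fwd primer] [insert ...]
R2: [protection (CCA)] [rev barcode (8)] [rev adapter (10)] [rev primer] [revcomp(insert) ...]
```

The protection group is a trinucleotide prepended to each barcode during
enzymatic assembly to shield its 5' end from exonuclease trimming; `CCA` is
the default because it is the empirically best-surviving prefix, and
`protectionScan()` reproduces exactly that kind of experiment (tabulating
all 64 trinucleotides seen 5' of each barcode).

# Panel design

## Candidate enumeration

All 4^L sequences of length L (8 for barcodes, 10 for adapters) are filtered
to a GC window and repeat rules. "50--60% GC" is interpreted on the integer
scale as `ceiling(0.5 L) <= GC <= floor(0.6 L)`; for 8-mers that means
exactly 4, for 10-mers 5--6. Repeats are read as *tandem* runs: homopolymers
of 3+, and any immediate duplication of a 2-mer or 3-mer motif, are
forbidden (forbidding any second occurrence of a base anywhere would empty
the candidate space). Both filters are configurable in
`panelDesignConfig()`.

## Objective

Similarity between two candidates is the global (Needleman--Wunsch)
alignment score maximized over the four orientation combinations
\{a, revcomp(a)\} x \{b, revcomp(b)\} (Biostrings' aligner does the scoring;
an independent dynamic-programming oracle checks it in the test suite). The
scoring parameters default to match = 1, mismatch = 0, no gap penalty —
i.e., a longest-common-subsequence--like similarity — and are configurable.
The set objective is the **mean** pairwise score: a raw sum grows
quadratically with set size and would make grow moves self-penalizing, so
the mean is used together with explicit size bounds; `normalizeObjective =
FALSE` restores the raw sum.

## Simulated annealing

From a random subset, moves shrink the set (10%), exchange a member (36%)
or grow it (54%), within the size bounds. Improvements are always accepted;
worsening moves with the standard Metropolis probability `exp(-delta/T)`
(the alternative literal reading — accepting when that quantity is *lower*
than a uniform draw — inverts the usual rule and is not used). The
temperature falls linearly from 10,000 to 0 over 300 iterations; both the
schedule shape (linear) and the initial set size were design choices.

Two robustness details matter in practice. First, the best state *seen*,
not the final state, is returned. Second, because the default temperature
scale is large relative to a mean-pairwise-score objective, the walk
explores broadly and only quenches late; the optimizer therefore keeps a
small elite pool (the ten best distinct states encountered) and finishes
with a deterministic best-improvement exchange descent from each, returning
the best local optimum found. On pools small enough to brute-force
(20 candidates, choose 6; C(20,6) = 38,760 subsets) this matches the
exhaustive optimum in essentially every seeded run, which the acceptance
suite verifies at a >= 90%-of-20-runs bar.

With `demuxSafe = TRUE` every pair in the selected set must be at Hamming
distance >= 3, which guarantees that single-substitution variants never
collide between barcodes (unambiguous single-mismatch demultiplexing).

## Role split and reference screen

The optimized set is dealt into forward and reverse roles alternately after
sorting by each member's summed similarity to the rest (balancing the
roles); a seeded random split is available. Each barcode+adapter 18-mer and
its reverse complement is then screened for exact 14-mer seeds against a
user-supplied reference FASTA (`screenAgainstReference()`); this replaces
an external alignment search with a deterministic, dependency-free
substring screen and errs on the conservative side at that seed length. An
external tool can be substituted upstream since the screen is a plain
filter on the panel object.

# Primer design

## Candidates

Primer windows (18--27 nt by default) must end in 3' thymine because the
fill-in polymerase appends a template-independent adenine during barcode
assembly; enforcing a template A at the position 3' of the primer keeps the
extended primer matching the template. Windows are ranked by a penalty
`|Tm - 60| + 50 * GC-deviation-from-[0.4, 0.6] + 0.5 * |len - 22.5|`, with
Tm from a standard nearest-neighbor two-state model at a single default
condition set (250 nM oligo, 50 mM monovalent salt). Up to five
primer-distinct pairs per locus whose amplicon covers the target interval
at 80--250 nt are returned, deterministically.

## Duplex energies

Cross-dimer stability is scored by an internal nearest-neighbor model: for
two oligos, every antiparallel Watson--Crick stretch of >= 2 bp (equivalent
to an exact common substring of `a` and `revcomp(b)`) is scored as the sum
of its stack delta-G(37 C) values plus two terminal initiation penalties,
and the minimum over all stretches and all orientation combinations is the
duplex energy. The parameter table is the unified DNA nearest-neighbor set
(1 M NaCl reference); a 10-bp perfect duplex hand-summed from the table
(-10.69 kcal/mol for `ACGTACGTAC`) is frozen in the tests. The backend is
pluggable (`registerDuplexBackend()`) so an external thermodynamics tool
can replace it; no runtime dependency is required. Hairpins (self-folds)
are out of scope — only pairwise duplexes are screened.

## Per-locus selection

`annealPrimerSets()` selects one candidate pair per locus. Each candidate
contributes its *fully ligated* sequences (protection + barcode + adapter +
primer for every barcode of the matching role), and the objective sums
duplex energies over all sequence pairs of the selection, so barcode and
adapter context is part of the energy landscape. Two readings of the
optimization direction exist — stable dimers have *low* delta-G, so
"minimize the summed minimum free energy" taken literally would *prefer*
stable dimers; `bartkit` minimizes dimer stability — i.e., maximizes the
summed delta-G — by default, and `literalObjective = TRUE` selects the
literal low-energy objective instead.
The schedule runs 15,000 -> 0 over 500 iterations with an 80% single-locus
alter move (the remaining moves re-draw the selection), plus the same
best-improvement polish as the panel optimizer. Pair-interaction energies
are precomputed once per run, so the annealing itself only sums a small
matrix.

## Assembly oligos

For every barcode the ordering sheet contains `protection + barcode +
adapter`, and for every selected primer `revcomp(adapter + primer)` with a
5'-phosphate flag: the phosphorylated strand is the preferred exonuclease
substrate, so after fill-in and digestion only the barcoded sense primer
survives. `simulateAssembly()` actually simulates the fill-in/digestion on
sequence level, and the round-trip identity (emitted pair -> assembled
primer equals the concatenation) is a tested invariant for random panels.

# The simulator

`simulateReads()` emits 2 x 150 nt reads (insert-padded, Phred+33, constant
quality by default) with per-(well, amplicon, allele) counts Poisson around
the design abundances, or exactly equal to them in `fixedCounts` mode —
the mode used wherever a test needs bit-exact expectations. The error model
covers per-base substitutions, 5' truncation of the read start (emulating
exonuclease shortening of unprotected barcodes), and index switching: each
read independently swaps its forward or reverse barcode for another active
one with the configured probability, so the artifact spreads in proportion
to well read counts — i.e., primarily from the most concentrated wells.
Ground truth records provenance per read and per-well true counts.

What it deliberately does **not** emulate: sequencing indels, PCR
duplicates and chimeras, UMI structure, position-dependent quality, or
non-uniform switching destinations. Passing round-trip tests therefore
demonstrate the correctness of the bookkeeping and the matching rules, not
robustness to every artifact of real instruments.

`simulateDilutionSeries()` builds plate designs in which gene abundances
fall fourfold per step (the 4--256 pg pattern) while spike-ins stay
constant, plus spike-only negative controls; a log-log regression of
simulated counts on input recovers slope 1 within 0.05, which is a tested
generator property.

# Demultiplexing

A `VariantIndex` per role maps every barcode and all its single-substitution
variants (optionally single-indel variants; substitutions-only is the
default reading of "single nucleotide-mutated") to the owning barcode,
*excluding* variants reachable from two or more barcodes. Because all
patterns have equal width, multi-pattern matching reduces to a dictionary
lookup of the read window at each allowed offset (0--3 extra leading bases;
a nonzero offset sets the `bases_before_protection` flag) — functionally
equivalent to a multi-pattern automaton and verified read-for-read against
a brute-force Hamming-distance matcher on random and adversarial reads.
Exact hits always outrank variant hits; two distinct barcodes at equal rank
leave the read unassigned with `multiple_barcodes`. All failures are flags,
never errors, and every read pair lands in exactly one category (assigned /
barcode unassigned / amplicon unassigned) — a conservation law asserted in
the tests.

Amplicon assignment matches each amplicon's primers against the
post-adapter region of both mates with at most 2 mismatches per primer plus
an exact insert k-mer seed (12 nt); ties yield no assignment, and
primer-only reads (no insert evidence) are assigned when unambiguous and
flagged. This replaces a spliced aligner: amplicons are short, fully known,
and anchored at fixed offsets, so bounded-mismatch matching is exact enough
and dependency-free; a full aligner can be slotted in upstream of
`countMatrices()` if reads are expected to contain indels.

Count matrices are built over the *full* panel grid, so barcodes excluded
from the experiment ("dummy" barcodes) appear as rows/columns whose
near-zero counts measure demultiplexing specificity.

Quality trimming is a 3' sliding-window trimmer (window 5, threshold Q20)
that never cuts into the structural prefix; with the simulator's constant
qualities it is a no-op and is exercised on constructed fixtures.

# Normalization and well filtering

Per well the scaling factor is the geometric mean of pseudocounted spike
reads,

$$\mathrm{RNA}_x = 2^{\frac{1}{n}\sum_1^n \log_2(\mathrm{spike}_n + 1)},$$

optionally over spikes and genes together. Factors more than 10-fold from
their median are removed (over-correction guard), the rest are
median-centered by division (the median retained factor is exactly 1), and
raw counts are divided by the centered factors. The +1 pseudocount makes
all-zero spike wells give factor 1; such wells are caught by the empty-well
filter instead.

Before normalization, per-barcode spike biases are tested: for each spike
and each barcode (forward and reverse axes separately) a two-sided Welch
t test compares the barcode's wells against all others, both groups
restricted to the 5th--95th percentile window of that spike's pooled
distribution. Rejections at `alpha` replace the combination with the median
of the remaining barcodes. Two details were genuinely open and were fixed
as follows: (i) the percentile window is computed on the *pooled* per-spike
data and applied to both groups — trimming each group by its own sample
percentiles discards its observed extremes and biases the variance
estimates, inflating the null rejection rate well above `alpha`, whereas
the pooled window calibrates correctly (the null replacement rate ~ alpha
is an acceptance property); (ii) all tests run against the original data
and replacements are applied afterwards, so detections do not cascade
within one pass. Wells whose total spike signal is more than 100-fold from
the plate *median* are flagged and removed first — an automated,
reproducible stand-in for manual heatmap curation (the median, not the
mean, so the outlier cannot mask itself).

**Empty wells**: a well is empty when its log2 spike-to-total ratio
(normalized counts) is at or above the negative-control reference; the
reference defaults to the *minimum* over negative controls — the strictest
faithful reading of "same or higher than the negative controls" — and is
configurable to a quantile. A negative control always flags itself, which
the boundary test asserts.

**Doublets**: among wells sorted as single cells, the log2 gene sum is
bimodal when some wells received two cells (the second mode near twice the
first). Automatic thresholding fits a two-component Gaussian mixture
(`mclust`) and places the cut at the mixture-density valley between the
component means; if the components are not separated (separation < 2 pooled
SDs or a vanishing component) the data are treated as unimodal — warning,
no flags. A manual threshold always overrides, and a gene subset (e.g.
housekeeping genes only) can restrict the sum.

**One-cell values** for multi-cell wells are normalized counts divided by
the sorted cell count — the simplest formula consistent with how the
quantity is used; it is linear, so halving twice equals dividing by four
(a tested identity).

# Genotyping

Reads are assigned to the wild-type or mutant reference by smaller edit
distance (ties unassigned) — for short, fully known amplicons this is the
same decision an alignment top-hit makes, without an external aligner. The
genotype rule: mutation iff `mut/wt > 0.20` *strictly* (21/100 is a
mutation, 20/100 is not; `wt = 0, mut > 0` counts as +Inf), subject to a
minimum depth of 20 reads (below: `no_call`). The depth floor is a safety
addition — set `minDepth = 0` for the literal threshold-only behavior.
Calls are monotone in the mutant count, and a planted cross-contamination
(mutant reads of one sample relabeled into another) surfaces as a second
mutant allele in the victim sample, mirroring how such contamination is
diagnosed in practice.

# Problem sizes and numerical choices

The test and acceptance suites run entirely on simulated data at these
scales, chosen to exercise the study-scale structure while staying
desk-sized: 96-well plates (8 x 12 active barcodes, with additional dummy
panel members), 10 amplicons with ~80 nt inserts, per-well abundances of
5--100 reads, coverage 100 per heterozygous sample for genotyping, and
20-candidate pools (choose 6) where annealing is compared against complete
enumeration. Floating-point comparisons of annealing objectives use a 1e-9
tolerance; all count comparisons are exact. Seeds are explicit everywhere;
`annealPanel()` and `annealPrimerSets()` are bit-reproducible given a seed.

# Known limitations

- The duplex model scores contiguous perfect stacks only (no internal
  mismatches, bulges or dangling-end corrections); energies are relative
  guides for optimization rather than calibrated physical predictions.
- The Tm estimate uses one default salt/oligo-concentration correction.
- The k-mer reference screen is exact-match; a divergent off-target with no
  shared 14-mer passes.
- Amplicon assignment assumes structurally intact reads (fixed offsets);
  heavy indel errors would require plugging in a real aligner.
- Heterozygous and homozygous mutations are not distinguished by default;
  the ratio rule only detects the presence of the mutant allele.
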