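---
title: "Core-sequence bin curation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-sequence bin curation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corebin)
```

This vignette explains the statistical machinery behind `corebin`, the
assumptions it rests on, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The problem

Automated metagenomic binners cluster assembled contigs into putative
genomes using composition and differential coverage. Running several
binners (or one binner at several thresholds, or over several assemblies)
raises sensitivity but yields overlapping bin sets: the same genome
recovered twice with slightly different contig membership and different
apparent depth, bins carrying a few foreign contigs, and genuine genome
fragments left un-binned. `corebin` consolidates such bin sets in four
stages — hybrid merging, redundancy removal, outlier refinement with
link-based retrieval, and restrained overlap–layout–consensus (rOLC) gap
filling.

## 2. Core-sequence identification and redundancy removal

**Inlier fences.** For a bin's per-contig coverage values the interquartile
fence `[Q1 − k·IQR, Q3 + k·IQR]` defines inliers. Quartiles use the
linear-interpolation (type 7) percentile convention, the most common one;
the brute-force oracle tests pin it. Core-contig identification uses
`k = 0`, i.e. the central half of the coverage distribution — the contigs
whose depth is most typical for the bin.

*Inclusive versus strict bounds.* With tied quartiles (IQR = 0, the normal
situation for a uniform-coverage bin) strict inequalities would classify
every contig as an outlier and void the bin. Comparisons are therefore
inclusive by default; a `strict` flag restores literal strict inequalities
for fidelity experiments.

*Coverage scalar.* The coverage entering the fences and the ratio
statistics is each contig's across-sample mean depth. Using one scalar per
contig matches the scalar algebra of the downstream statistics and averages
per-sample noise down by the sample count; the per-sample structure is
exploited separately by the CCC dimensions (section 3).

**Depth normalization.** Within an ANI group (ANI ≥ 99 %, aligned fraction
≥ 50 %, either direction suffices; groups are single-linkage components),
inlier contigs of a bin pair are matched one-to-one (pair ANI ≥ 99 %, both
≥ 1000 bp, greedy by descending ANI). Matched pairs estimate the
depth-normalization ratio `X̄ = mean(cov_a / cov_b)`; zero denominators are
floored at a pseudocount of 0.01. Because both copies of a genome recovered
from different assemblies or samples see different effective depth, this
ratio — not raw depth equality — is the right yardstick. The delta coverage
`Δ = |μ_a − X̄·μ_b|`, over all inliers of both bins, is near zero exactly
when the two bins are coverage-proportional, i.e. redundant recoveries of
one genome.

**The decision.** `Δ < w` declares redundancy. The decision threshold is
deliberately exposed in two forms:

* *threshold mode* (default): a fixed `w = 5` (coverage units). At typical
  community depths (tens of ×) a genuine duplicate's Δ sits well below 1
  after normalization, while coverage-distinct bins that nevertheless group
  at ANI ≥ 99 % are rare; the margin is wide and transparent.
* *model mode*: a single-hidden-layer fully connected classifier
  (`nnet::nnet`, 4 hidden units, weight decay 0.01) over the features
  (Δ, Δ/μ_a, X̄, n_pairs, log bin-size ratio, coverage dispersions),
  trained on labeled synthetic pairs and thresholded at probability 0.5.
  The trainable decision boundary is useful when depth scales or noise
  differ from the defaults; the training procedure ships with the package
  (`train_redundancy_model` on the `redundancy40` fixture).

With zero matched inlier pairs there is no evidence either way and both
bins are kept (`no-evidence`), which biases the stage against destroying
genuine genomes. Within a redundant pair the bin with the smaller total
inlier length is removed; which member survives is not dictated by the
statistics, and retaining the larger core keeps more sequence available
downstream. Removed bins are archived — their inliers later serve as gap
filling donors — never deleted.

## 3. Refinement

**Multidimensional IQR.** Outlier contigs are detected per bin over these
dimensions: the Euclidean distance of each contig's canonical
tetranucleotide frequency vector (136 dimensions after folding
reverse-complement pairs; windows containing N are skipped) to the bin's
length-weighted TNF centroid; every pairwise coverage ratio
`CCC_ab = cov_a / cov_b` between samples (pseudocount 0.01 on both terms,
so ratios are finite and positive; with a single sample these dimensions
are empty); and the across-sample mean depth. Treating TNF as one
distance-to-centroid dimension rather than 136 independent fences is
deliberate: the fence machinery is scalar, and 136 separate tests at any
reasonable k would flag nearly every contig by multiplicity alone. The
centroid is length-weighted so long, reliable contigs dominate it.

Fences are computed at k ∈ {0, 0.5, 1, 2} for diagnostics; removal uses
the most conservative listed value, k = 2, to keep the false-flag rate low.
A contig is an outlier when it falls outside the fence of *any* dimension
at the operative k. Bins with fewer than 4 contigs have no meaningful
quartiles and are never pruned.

Flagged contigs are pooled, not discarded. This is what preserves genuine
multi-copy sequence: a contig whose depth is double its bin's core (two
collapsed copies) may be flagged by the depth fence, but it remains a
retrieval candidate rather than being destroyed.

One known limitation follows directly from fence mechanics: on perfectly
clean bins a few extreme-but-genuine contigs (typically short contigs,
whose TNF estimates are noisiest) can still be flagged — quartile fences at
finite n flag a small, distribution-shape-dependent fraction regardless of
data quality. The planted-contamination tests therefore check both
directions: ≥ 80 % of planted contaminants flagged *and* ≤ 10 % of native
contigs lost.

**Sequence retrieval.** Un-binned contigs (flagged outliers plus anything
never binned) are assigned through read-link evidence: a contig joins a bin
when its summed link support to the bin's current members is at least 3, the
bin is the unique support maximizer (strict ties never assign), and the
contig passes the bin's composition + coverage screen at k = 2. The support
minimum of 3 suppresses chimeric read-pair noise at typical simulated link
rates. Assignments are decided against the membership frozen at the start
of each iteration, so a contig linked only through another retrieved contig
enters one iteration later; iteration stops at a fix point (guard: 20
iterations). The admission screen reuses the removal k; link evidence is
thus necessary but never sufficient. A final core-sequence-identification
pass re-checks the refined set for redundancy.

Bins whose retained length falls below 50 kb are dissolved into the pool —
below any plausible MAG size a stub bin serves retrieval better as free
fragments. The floor is configurable.

## 4. Restrained overlap–layout–consensus

Donors are the outlier-filtered inliers of archived redundant bins, scoped
to the ANI group of their source bin (sequence from a redundant recovery of
genome G should only patch bins of G's group), plus leftover un-binned
contigs, which are unscoped. Overlaps are detected by exact 21-mer
anchoring followed by banded edit-distance scoring; identity counts gaps as
mismatches, and `N` never matches, so low-quality donor stretches masked
with N cannot inflate identity.

The Layout step accepts two event types, both under thresholds of overlap
length ≥ 300 bp (round 1) / ≥ 500 bp (round 2) at identity ≥ 99 %:

* *extend*: the donor overlaps exactly one contig end and protrudes past
  exactly one target end;
* *bridge*: the donor covers the tail of one contig and the head of
  another, each overlap meeting the threshold.

Two restrictions guard against chimeric over-extension: a donor protruding
beyond the target at **both** ends is rejected outright, and the merged
sequence must stay below 105 % of the summed target length(s). The second
bound is applied to both event kinds; for bridges it caps the donor-derived
gap at 5 % of the joined contigs, for extensions it caps the appended
flank. The Consensus step keeps the target base at every overlap
disagreement — targets have passed refinement QC, donors by definition have
not. Events apply greedily by descending total overlap length (ties:
identity, then donor id); each donor and each target contig participates in
at most one event per round, and donors consumed in round 1 are not reused
in round 2. Merged contigs inherit the length-weighted mean depth of their
source contigs for the final redundancy re-check.

Between the two rounds the original toolchain would re-assemble with an
external assembler; orchestrating assemblers is out of scope here, so the
shipped pipeline performs rOLC → rOLC and documents the hook.

## 5. Reference-based evaluation

Each bin contig is fragmented (1 kb; a terminal remainder under 500 bp is
merged into the previous fragment so no query base is lost) and mapped to
the reference set by shared 16-mers plus banded alignment. A contig belongs
to the reference receiving most of its aligned bases; the bin's majority
reference maximizes total aligned bp. Completeness counts each covered
majority-reference position once (interval union); contamination divides
aligned bp on non-majority references by all aligned bp — novel sequence
aligning nowhere is not punished as contamination, matching the semantics
of "contaminating" against a closed reference set. Quality is
completeness − 5·contamination; the three named tiers are baseline
(completeness ≥ 35, contamination ≤ 20), MAG (quality ≥ 50) and high
(completeness ≥ 90, contamination ≤ 5). They are independent definitions —
a bin at completeness 50 / contamination 20 has quality −50 yet still
counts as baseline on the inclusive boundary — so the evaluator reports all
three flags alongside the best label. ORF-level contamination screening
would require a gene caller and is documented as a hook only.

## 6. The synthetic generator: what it emulates, what it does not

Genomes are sampled from per-genome order-3 Markov chains perturbed from
one shared base transition matrix by a multiplicative lognormal factor of
scale `divergence` (default 0.1) — enough compositional separation that
between-genome TNF distance exceeds within-genome distance (a property the
test suite checks), while staying far from trivially separable. Defaults:
10 genomes of 60–100 kb, 3 samples, lognormal abundances (median ~30×,
sdlog 0.6), negative-binomial read-count noise (dispersion 0.03, i.e.
~17 % depth CV per sample at typical depth), lognormal contig lengths
(median ~4 kb, minimum 1 kb — matching the 1 kb pairing threshold regime).

Planted defects mirror the failure modes the statistics must resolve.
Duplicate bins copy a genome's bin under new contig ids, drop a random
10–30 % of contigs, and re-draw depths at a coverage scale factor from
[0.5, 2] — emulating the same genome binned from a second assembly, which
is exactly the situation the depth-normalization ratio addresses (and why
duplicates are not removed earlier by id-based hybrid merging).
Contaminants are contigs moved across genomes; withheld contigs move to the
un-binned pool. Links connect genome-adjacent contigs with
depth-proportional Poisson support (floor 1) plus a 2 % rate of false
cross-genome links; link simulation is adjacency-based, not read-level,
because retrieval consumes link tables, not reads.

What the generator does **not** emulate: real genomic repeat structure,
strain-level micro-diversity, assembly chimerism and fragmentation biases,
GC-dependent coverage bias, and read-level error profiles. Passing the
planted-defect benchmarks therefore demonstrates that the statistics
recover the planted structure under controlled noise — not that the
pipeline handles every pathology of real assemblies.

Determinism: all randomness flows from the spec's single seed (the defect
planter continues from seed + 1); the same spec reproduces every artifact
byte for byte, which the checkpointing and acceptance machinery relies on.

## 7. Numerical choices and degenerate inputs

* Percentiles: linear interpolation (type 7); fences inclusive (see
  section 2).
* Pseudocount 0.01 for zero coverages in ratio statistics.
* ANI fragments: 1 kb, seed k-mer 16, alignment band 5 % of the fragment;
  a fragment counts as aligned when its best target window covers ≥ 80 % of
  it; identity is edit-distance based (gaps count as mismatches), the
  strictest common convention. An empty aligned set reports ANI as `NA`,
  never a fake 0.
* Overlap anchors: exact 21-mers; candidate ties break by overlap length,
  then identity, then lexicographic target id — all orderings in the
  package are total, so outputs are reproducible.
* Degenerate inputs: sequences without a valid 4-mer get the all-zero TNF
  vector; single-sample data has no CCC dimensions and is screened on TNF
  and depth alone; bins under 4 contigs are never pruned; empty link tables
  make retrieval a no-op; an empty donor set makes gap filling a no-op.

## 8. Problem sizes used by the tests

The shipped benchmarks are sized for quick, repeatable runs: `redundancy40`
uses 20 genomes of 30–50 kb (40 labeled pairs); `contamination10x5` and
`retrieval10` use the default 10-genome community; `gapfill5` uses one
30 kb genome in 5 contigs with 100 bp gaps and three 900 bp spanning
donors; the coverage-scale recovery fixture uses one 300 kb genome so the
ratio estimate rests on ~10 inlier pairs. The full-pipeline benchmark runs
the default community with redundancy 0.3, contamination 0.05 and withheld
0.1 — the "standard defect community" reported by `scripts/acceptance.R`.
These sizes are scaled-down analogues of real communities; the statistics
themselves are size-free.
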