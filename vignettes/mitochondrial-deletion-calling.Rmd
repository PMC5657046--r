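---
title: "Detecting and quantifying mitochondrial DNA deletions from split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying mitochondrial DNA deletions from split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosplit)
```

## The model

The mitochondrial chromosome is circular, 16,569 bp, numbered 1-based
along the light strand. A deletion removes bases `s+1 .. e−1` and fuses
base `s` to base `e`; we call `(s, e)` the *fusion point*. In a cell the
deleted molecule usually coexists with the intact one at a low fraction
`p` (heteroplasmy). A sequencing read that spans the fusion cannot align
contiguously to the reference: a standard seed-and-extend aligner either
leaves it unmapped or clips it, which is precisely the signal this
package collects.

For a read of length `l` spanning the fusion, let `x` be the position in
the light-strand-oriented read that carries genome base `s`. The read
then decomposes into segments `(1..x)` and `(x+1..l)` mapping to genome
intervals `(s−x+1 .. s)` and `(e .. e+l−x−1)`. A *deletion call* is a set
of split reads that all decompose this way with exactly the same
(canonicalized) `(s, e)`.

### Why two filters

Two independent evidence filters control false positives:

* **Support** `n ≥ n_min` (default 10): the number of split reads with
  exactly this fusion point. A tuning parameter — raising it trades
  sensitivity for specificity, and the package reports flags rather than
  dropping rows so it can be retuned.
* **Offset diversity** `|{x₁..xₙ}| ≥ u_min` (default 5): a genuine
  junction is sampled at many positions within reads, while PCR
  artifacts and reads split on a single substitution recur at one or
  two offsets.

### Heteroplasmy estimation

Among `r` mitochondrial reads, the number supporting a fusion is modelled
as `Bin(r, q)`. A read from a deleted copy harbors the junction with
probability `l/L` (there are `L` equally likely start positions on the
circle, `l` of which overlap a given junction), so heteroplasmy is
estimated as

    q_hat = n / r        het_hat = q_hat * L / l

with an exact (Clopper–Pearson) `1 − α` interval on `q` obtained from
F-distribution quantiles and transformed by the same `L/l` factor. The
estimator can exceed 1 for small `r`; values are truncated at 100% and
flagged. `n = 0` yields a lower bound of exactly 0, `n = r` an upper
bound of 1.

The *effective* read length matters: published read counts sometimes
treat a pair as one unit, making the effective `l` twice the nominal
read length. The estimator therefore takes `l` explicitly, and the
pipeline documents the value it used in its run report.

### Capture correction in the pipeline

The plain estimator assumes any of the `l` overlapping start positions
makes a junction countable, but a split aligner can only place a read
whose shorter segment has at least `min_overhang` bases (20 by default).
Only `l − 2·min_overhang + 1` start positions produce countable split
reads, so the pipeline scales `q̂` by `L / (l − 2·min_overhang + 1)`
rather than `L/l`. With 150-nt reads this is a 26% correction; without
it the pipeline's estimates would be biased low by exactly that factor
(we verified the corrected estimator is unbiased against simulation
truth). When quoting counts obtained from another split mapper whose
effective minimum overhang is unknown, pass your own `read_length` to
`estimate_heteroplasmy()` and judge the correction yourself.

### Theoretical sensitivity

For an experiment with `M` total reads and mitochondrial enrichment `E`
(fraction of DNA that is mitochondrial; ~0.002 without laboratory
enrichment), the expected per-base depth is `N ≈ M·E·l/L`, and support
for a deletion at heteroplasmy `p` is `Bin(round(M·E), p·l/L)`. The tail
probability is evaluated exactly with `pbinom` — stable well past
`r ~ 10⁶` — and `min_detectable_heteroplasmy()` inverts it by bisection
to a relative tolerance of 1e−6. For a 50M-read run at 60% enrichment
and the default threshold of 10 supporting reads, the 95%-probability
detection limit computed this way is ~0.0058%.

## Design choices

**Coordinates and notation.** All public output is 1-based, inclusive,
light-strand. Deletion names follow the HGVS-style inclusive convention:
`m.<A>_<B>del<len>` deletes `A..B` with `len = B − A + 1`. Published
deletion names are not consistent about whether the stated length is
`B − A` or `B − A + 1`; rather than guessing per name, the parser trusts
the coordinates and warns when a stated length disagrees with the span.

**Breakpoint canonicalization.** When the junction is flanked by a
direct repeat (as for the common deletion), several `(s, e)` pairs
describe the same molecule. All placements are shifted maximally 5′
(minimal `s`) before clustering, so equivalent split reads always land
in one cluster; clustering itself is then by exact `(s, e)` with no
breakpoint windowing.

**Split alignment search.** The reference is only 16.6 kb, so the
aligner can afford an *exhaustive* search over all placements of both
segments (vectorized prefix/suffix mismatch counts per diagonal of the
doubled circular sequence), rather than trusting seed anchoring alone: a
20-nt overhang carrying one sequencing error need not contain any exact
16-mer seed, and a purely seed-anchored search would miss such reads.
Seeds (k = 16) still shortlist placements — an error-free split is
provably found on the shortlist because `k ≤ min_overhang` — and the
exhaustive scan runs only when mismatches are in play. The reported
split is therefore a true optimum: maximum matched bases, ties broken
toward the smallest canonical `s`, then the larger minimum overhang,
then the `+` orientation, making output deterministic under repeat
ambiguity. Only two-segment, same-strand splits implying a non-origin-
spanning deletion are reported; inversions, duplications and
multi-segment chains are out of scope.

**Defaults.** `min_overhang = 20` and `max_mismatch = 1` per segment
make spurious placements on 16.6 kb vanishingly rare while tolerating
one sequencing error per segment; `clip_min = 20` keeps clipped segments
long enough to place uniquely; `indel_min = 5` catches deletions small
enough for the aligner to absorb into a CIGAR. Candidate reads mapped to
nuclear contigs without such CIGAR features are *not* candidates — in
whole-genome alignments this is what keeps NUMT (nuclear-embedded
mitochondrial segment) reads out. The FASTQ (aligner-free) mode has no
such guard and is intended for synthetic or mitochondria-enriched
libraries; there, `r` is the number of reads the package itself
classifies as full-length matches.

**Degenerate inputs.** Origin-spanning deletions are not representable
as `(s, e)` fusion points and are rejected everywhere, consistently:
split placements implying them are discarded during alignment. An
alignment file without the mitochondrial contig, an empty FASTA, `r = 0`
and unreachable power targets all fail loudly rather than returning
empty results.

## The read simulator

`simulate_reads()` emulates a paired-end experiment over a two-haplotype
mixture: fragments are sampled uniformly around each circular haplotype
(the deleted haplotype is circular after excision), with fragment length
`2l + gap`, `gap ~ N(300, 100²)` truncated at 0 — interpreted as the
inner mate distance, since simulator conventions for "distance between
reads" vary. Substitution errors are injected independently per base
(default 0.001) with flat quality strings; indel errors, quality
profiles and PCR duplicates are deliberately not modelled, since the
calling logic never uses quality values. Every read carries ground
truth: haplotype of origin, orientation, and the fusion offset `x` when
it spans the junction with at least one base on each side.
`write_pseudo_sam()` renders a simulation the way a whole-genome aligner
would: non-fusion reads as mapped records (origin-crossing reads
soft-clipped at the contig end), fusion reads as unmapped records.

Because the real revised Cambridge Reference Sequence cannot be bundled
here, simulations use a seeded random 16,569-bp genome, which the
package labels synthetic. The procedure depends on coordinates and
length, not base content, with one caveat: real mtDNA contains direct
repeats (the common deletion is flanked by a 13-bp one), which a random
sequence mostly lacks, so repeat-driven breakpoint ambiguity is
exercised only to the extent that short repeats arise by chance (2–3 bp
repeats do occur and are absorbed by canonicalization). Passing tests on
synthetic genomes therefore demonstrate the coordinate algebra, search
optimality and statistics, not robustness to long NUMT-like homology.

## Problem sizes used in the test suite

The validation experiments run at a deliberately chosen scale: single
replicates at 70× deleted / 630× intact coverage for end-to-end checks,
and ten seeded replicates at 70× deleted / 6930× intact (1%
heteroplasmy, ~770,000 reads each) for the recovery experiment, where
the expected support per replicate is ~52 reads — far enough above the
threshold of 10 that exactly one passing call per replicate is the
overwhelmingly probable outcome under the model, which is what the suite
asserts. Interval coverage is checked with 2,000 draws from the
estimator's own sampling model at an operating point matching the
package's worked example (`r` ≈ 1.1M reads, heteroplasmy 1%), where the
exact Clopper–Pearson coverage is 95.4%; brute-force oracle comparisons
for the split aligner use toy genomes (L ≤ 500) where exhaustive
enumeration over every split point and placement pair is feasible.

## Known limitations

* Only simple deletions: no duplications, inversions, multi-segment
  events, or origin-spanning deletions.
* Exact-breakpoint clustering assumes canonicalization absorbs all
  ambiguity; breakpoints blurred by sequencing errors at the junction
  produce satellite singleton clusters (filtered out by design).
* The binomial model ignores overdispersion between molecules and any
  mapping bias; intervals are exact for the model, not for every
  real-library artifact.
* Heteroplasmy below ~0.01% requires read depths where duplicate
  removal and error modelling beyond uniform substitutions start to
  matter; neither is modelled here.
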