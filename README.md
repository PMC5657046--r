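# mitosplit

Split-read detection and quantification of mitochondrial DNA deletions
from next-generation sequencing data.

## The problem

The human mitochondrial chromosome is a 16,569-bp circle present at
hundreds to thousands of copies per cell. Large deletions — such as the
~4,977-bp "common deletion" seen in aging tissue — typically affect only
a small fraction of those copies (*heteroplasmy* well below 1%), which
puts them out of reach of structural-variant callers built for diploid
nuclear genomes. A deletion fuses two normally distant positions `s` and
`e`; any read spanning that *fusion point* either fails to align to the
reference or aligns only after clipping. mitosplit mines exactly those
reads.

The pipeline, given a whole-genome alignment (SAM/BAM with a chrM
contig) or raw FASTQ:

1. **Candidate extraction** — collect unmapped reads plus mapped reads
   whose CIGAR shows clips ≥ 20 nt or indels ≥ 5 nt, and count `r`, the
   reads aligned to the mitochondrial contig.
2. **Split alignment** — for each candidate, find the optimal
   two-segment placement on the circular reference consistent with a
   deletion: prefix `1..x` at `(s−x+1 .. s)`, suffix `x+1..l` at
   `(e .. e+l−x−1)`, at most one mismatch per segment, at least 20 bases
   on each side of the junction.
3. **Clustering and filtering** — group split reads by their (repeat-
   canonicalized) fusion point; report clusters with support `n ≥ 10`
   whose fusion offsets `{x₁..xₙ}` contain at least 5 unique values
   (screening out PCR/alignment artifacts).
4. **Quantification** — since a read from a deleted copy harbors the
   junction with probability `l/16569`, heteroplasmy is estimated as
   `q̂ × 16569/l` with `q̂ = n/r`, and an exact binomial
   (Clopper–Pearson) confidence interval on `q` is transformed to the
   heteroplasmy scale.

A binomial power model answers the design question "how deep must I
sequence": with `M` total reads at mitochondrial enrichment `E`, support
for a deletion at heteroplasmy `p` is `Bin(round(M·E), p·l/16569)`, and
the package inverts the tail probability to give the minimum detectable
heteroplasmy. A paired-end read simulator with per-read ground truth
reproduces validation experiments end to end.

## Worked example

Heteroplasmy from printed counts (96 supporting reads, 1,115,366
mtDNA-aligned reads, effective read length 200 nt):

```r
library(mitosplit)
estimate_heteroplasmy(n = 96, r = 1115366, read_length = 200)
#> Heteroplasmy estimate: 0.71% (95% CI 0.58%-0.87%)
#>   n = 96 fusion reads / r = 1,115,366 mtDNA reads, l = 200 nt, L = 16569 bp
```

Design sensitivity for a 50M-read MiSeq run at 60% enrichment:

```r
100 * min_detectable_heteroplasmy(5e7, 0.6, 150, n_min = 10, target_power = 0.95)
#> [1] 0.00578266
```

i.e. deletions down to ~0.006% heteroplasmy are detectable with 95%
probability at the default threshold of 10 supporting reads.

End-to-end on simulated data (a 200-bp deletion at 10% heteroplasmy):

```r
set.seed(42)
g   <- mt_genome(paste(sample(c("A","C","G","T"), 16569, TRUE), collapse = ""))
sim <- simulate_reads(g, parse_deletion_notation("m.5000_5199del200"),
                      coverage_deleted = 70, coverage_intact = 630, seed = 41)
sam <- tempfile(fileext = ".sam")
write_pseudo_sam(sim, g, sam)
calls <- call_deletions(sam, g)
tidy(calls)[, c("notation", "support_n", "unique_offsets",
                "heteroplasmy_pct", "ci_low_pct", "ci_high_pct")]
#> # A tibble: 1 × 6
#>   notation          support_n unique_offsets heteroplasmy_pct ci_low_pct ci_high_pct
#>   <chr>                 <int>          <int>            <dbl>      <dbl>       <dbl>
#> 1 m.4998_5197del200        55             40             10.6       8.02        13.8
```

The spiked junction (deleting 5000..5199) is reported at its 5′-most
equivalent placement, `m.4998_5197del200`: this random reference happens
to carry a 2-bp repeat flanking the breakpoint, and 55 split reads at 40
distinct fusion offsets support the call, giving 10.6% heteroplasmy
(95% CI 8.0–13.8%) against the simulated 10%.

A thin command-line interface over the same functions is installed at
`exec/mitosplit` (subcommands `call`, `simulate`, `estimate`, `power`).

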