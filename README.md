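# shatterscan

Detection and classification of shattered chromosomes from short-read
dosage, for genome-elimination experiments in hybrid plants.

When two *Arabidopsis* lines expressing diverged centromeric histones
(CENH3) are crossed, chromosomes of the haploid-inducer parent missegregate
and are either lost (haploid progeny) or retained in damaged form. A
lagging chromosome trapped in a micronucleus can be fragmented and
religated by non-homologous end joining (NHEJ), producing a single
chromosome whose copy number oscillates among states 1-4 — the plant
counterpart of chromothripsis and chromoanasynthesis. `shatterscan`
implements the sequencing side of that analysis as a tested, reproducible R
pipeline:

- **Dosage profiling** — reads are binned (100 kb conventionally), the
  per-bin read percentage is divided by a control or cohort-mean reference
  and anchored so the diploid background reads 2; profiles are segmented
  into integer copy states and every chromosome is classified *euploid*,
  *numerical* (whole-chromosome gain/loss), *truncated* (one or two
  breaks), or *shattered* (oscillating states).
- **Parental-origin assignment** — diagnostic SNPs are discovered from a
  hybrid control plus the two parents (hybrid depth >= 25 with two alleles
  at >= 40% each; parents >= 97% homozygous at >= 6x / >= 1x), each read is
  assigned to a parent at the SNPs it covers, and parentage is pooled in
  1 Mb bins. Copy-gain regions built from the haploid inducer show the
  tell-tale 2:1 and 3:1 inducer-allele mixtures in state-3 and state-4
  blocks.
- **Junction reconstruction** — breakpoints are detected on a 500 bp dosage
  profile, reads within 2000 bp of each breakpoint (plus their mates) are
  assembled by a greedy exact-overlap assembler, contigs are split-aligned
  to the reference, and each junction is classified as *microhomology*
  (2-15 bp shared), *blunt*, or *insertion*, with inversion orientation
  (head-to-head / tail-to-tail) and chimeric-gene potential.
- **Breakpoint feature enrichment** — occupancy of genes, transposons,
  replication origins, DHS or chromatin states in 1000/10,000 bp windows
  around breakpoints versus the rest of the aneuploid chromosome, with
  empirical p-values from 1000 uniform shuffles of breakpoint positions.
- **Cohort statistics** — karyotype tallies across samples and exact
  (Fisher) tests on cross-outcome tables such as haploid-induction
  frequencies and micronuclei counts.
- **A synthetic truth-tracked simulator** — parental haplotypes differing
  only at planted SNPs, a shattered chromosome assembled from blocks at
  copy states 1-4 with fully specified junction chemistry, and error-free
  single- or paired-end reads, so every stage is testable end to end
  without any external data.

## Worked example

Simulate a hybrid with one shattered chromosome (5 chromosomes of 300 kb,
20 planted junctions, 50x error-free 2x100 bp reads) and run the whole
pipeline:

```r
library(shatterscan)
res <- run_pipeline(default_config(seed = 1))
res$karyotype
#>   chrom     class n_segments n_breakpoints  states
#> 1  chr1   euploid          1             0       2
#> 2  chr2   euploid          1             0       2
#> 3  chr3 shattered         13            12 1,2,3,4
#> 4  chr4   euploid          1             0       2
#> 5  chr5   euploid          1             0       2
```

chr3 (the planted shattered chromosome) is recognised by its twelve
copy-state transitions over states 1-4; the other chromosomes stay at the
diploid background. Junction recovery against the planted truth:

```r
m <- match_junctions(res$junctions, res$truth$junctions, tol = 1)
sum(m$matched & m$called_type == m$type)   # 20 of 20 junctions,
#> [1] 20                                  # exact type and signature
res$state_fractions[, c("state", "pct_a")]
#>   state    pct_a
#> 1     1 17.75510
#> 2     2 49.88592
#> 3     3 67.65653
#> 4     4 75.11430
```

The parent-A (haploid inducer) allele fraction rises from ~0% expected at
loss-of-heterozygosity (state 1; residual calls here sit at block edges)
through 50% in the diploid background to the expected 2/3 at state 3 and
3/4 at state 4 — duplications and triplications originate from the inducer
genome. Exact test on a published-style cross table (progeny counts by
outcome, wild-type vs NHEJ-deficient pollen):

```r
tab <- matrix(c(236, 123, 370, 25), nrow = 2)
contingency_test(tab)$p
#> [1] 4.257594e-23
```

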