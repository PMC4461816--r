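---
title: "Detecting and classifying shattered chromosomes: models and methods"
author: "shatterscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying shattered chromosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological setting

Crossing an *Arabidopsis* haploid-inducer line (a variant-CENH3 strain in a
Col-0 background) to a polymorphic wild type (Ler) destabilises the
inducer's centromeres: its chromosomes missegregate during the first
embryonic mitoses. Progeny are haploid when the inducer genome is lost
entirely, diploid when it is retained, and aneuploid in between. A
missegregated chromosome sequestered in a micronucleus can be fragmented
and re-ligated by non-homologous end joining, yielding a single heritable
chromosome whose copy number oscillates along its length — chromothripsis
(breakage plus ligation) and chromoanasynthesis (replication-fork collapse
with microhomology-mediated template switching) in a plant system.

`shatterscan` implements the sequencing analysis for such experiments:
dosage profiling and karyotype classification, parental-origin assignment
from hybrid-diagnostic SNPs, breakpoint-junction reconstruction and
classification, feature enrichment at breakpoints, and cohort-level
contingency statistics — together with a synthetic data generator that
plants every structure the pipeline must recover.

# Dosage model

Reads are assigned to consecutive non-overlapping bins by their start
coordinate and converted to the percentage of all mapped reads per bin.
Relative coverage is

$$\mathrm{rel}_{b} = 2 \cdot \frac{\mathrm{pct}^{\mathrm{sample}}_{b}}
                               {\mathrm{pct}^{\mathrm{ref}}_{b}},$$

with the reference taken from a control individual (default when one is
supplied) or the cohort mean. The factor 2 anchors the diploid background;
because the scale is relative, a uniform whole-genome change is invisible —
a haploid normalised against itself still reads 2 (the class label, not the
scale, conveys ploidy), and a whole-chromosome trisomy is only visible
against euploid chromosomes that absorb the percentage renormalisation.
Bins where the reference percentage is zero are masked rather than divided.

Segmentation deliberately avoids an HMM: the per-bin state is the nearest
integer of the running-median-smoothed relative coverage (window 5 bins,
clamped to 0..6), and runs shorter than `min_run` (3 bins) are merged into
the flanking state with the closer mean. This mirrors how dosage blocks
are read off a plot by eye, is free of tuning beyond two interpretable
knobs, and leaves segment boundaries within one bin of the planted truth
for blocks of at least five bins.

Karyotype classes follow the segment pattern per chromosome: *euploid* =
one segment at state 2; *numerical* = one segment at another state;
*shattered* = at least `shatter_min` (default 5) state transitions or at
least three distinct states; everything else — a background plus a single
altered arm reachable with one or two breaks — is *truncated*. The
shatter threshold separates "at most two breaks" from "many oscillations";
five transitions is a deliberate, configurable middle ground since no
published cut-off exists. Multi-segment two-state chromosomes with three
or four transitions fall into *truncated*; on our simulations this
boundary case does not occur because shattered plans always mix three or
more states.

Bin sizes: 100 kb is the conventional genome-scale choice (25 kb, 150 kb
and 500 bp profiles are also standard); on the 300 kb synthetic
chromosomes the pipeline uses 2 kb coarse and 500 bp fine bins, preserving
the bins-per-chromosome order of magnitude of a 30 Mb chromosome at 100 kb
while keeping planted blocks at least five bins wide.

# SNP discovery and parentage

Diagnostic positions are discovered from three pileups — a diploid hybrid
control and the two parents — under fixed thresholds: hybrid depth >= 25
with exactly two alleles above a 5% noise floor, each at >= 40% of calls;
each parent >= 97% homozygous, with depth >= 6 (inducer parent) and >= 1
(the other); parental alleles must differ and match the hybrid's two
alleles. The 5% noise floor operationalises "two alleles" in the presence
of stray calls; it is the only threshold not fixed by convention and is
configurable. Positions are discovered from the *control* hybrid, so
copy-number skew in an aneuploid sample cannot suppress discovery.

Each read of the analysed sample yields one call per covered SNP (A, B, or
`na` when the base matches neither allele). A read supporting both parents
at different SNPs is set to `na` at all its SNPs — a conservative rule
against chimeric molecules; the cost is negligible at 100 bp reads and one
SNP per kilobase. Calls are pooled in 1 Mb bins (50 kb at simulation
scale) and, for copy-variant interpretation, grouped by the copy state of
the containing segment. In a diploid plus one extra inducer-derived copy,
the expected inducer allele-call fraction is 1/2 at state 2, 2/3 at state
3, 3/4 at state 4, and 0 in state-1 loss-of-heterozygosity regions; the
package reports allele-call fractions (not rescaled "genome fractions"),
which makes those expectations exact and testable.

# Mapping

The built-in mapper reports a read iff its full sequence or reverse
complement occurs exactly once in the reference — sufficient for
error-free synthetic reads, and deliberately not a general aligner; real
data enters as SAM (primary mapped records, MAPQ < 20 flagged
non-unique). Because the two parental haplotypes differ only by
substitutions they share one coordinate system, and hybrid samples are
mapped against both references with uniqueness judged on distinct
(chromosome, position, strand) placements. This recovers reads carrying
either parent's alleles without mismatch tolerance; its known bias is
that reads spanning more SNPs than none are never lost (exact match
against the correct haplotype), while reads spanning a junction are
deliberately unmapped — they are the assembler's substrate.

# Junction reconstruction

Breakpoints are placed at bin boundaries of copy-state transitions on the
500 bp profile. For every breakpoint (plus the two chromosome ends of any
non-euploid chromosome, since terminal block edges carry junctions without
a dosage transition), all reads starting within 2000 bp and their mates
are extracted. Junction-spanning reads are exactly the unmapped mates, and
they seed a greedy assembler that extends by exact suffix–prefix overlaps
of at least 31 bp, both orientations, preferring the longest extension;
contigs below twice the read length or supported by fewer than 2 distinct
reads are discarded.

A contig is then *chained* against the reference: the longest exact prefix
match is anchored, and the next reference segment is found by
suffix-anchoring a chunk just past the current segment and extending it
maximally. Each adjacent segment pair is one junction; a contig assembled
across several nearby junctions therefore resolves into all of them. The
contig overlap between consecutive segments gives the chemistry: overlap
>= 2 is microhomology (the overlap length is the tract), overlap 0 or 1 is
blunt (a 1 bp overlap is below the conventional 2-15 bp microhomology
band), and a gap is an insertion whose unaligned middle is the inserted
sequence. A junction is inverted when its anchors align to opposite
strands. Anchoring and extension accept a base matching either parental
haplotype, so contigs assembled from mixed-parent read pools are not
broken at SNPs. Equally long ambiguous placements are resolved toward the
detected dosage breakpoint; surviving ties are flagged and excluded from
summaries. Junctions are deduplicated on canonical anchor order plus
chemistry — two distinct planted junctions may share both anchors (two
copies of the same block joined to the same partner edge with different
insertion sequences), so chemistry belongs in the key.

The chimeric-gene rule is an explicit operationalisation: a junction is
chimeric-capable iff each anchor's retained side lies inside a gene body
and the two genes read in the same direction across the junction after
applying the anchors' strand relation.

# Enrichment at breakpoints

Windows of 1000 or 10,000 bp are centred on each breakpoint, clipped to
the chromosome and **unioned** before occupancy sums, so clustered
breakpoints are not double-counted (occupancy-in and occupancy-elsewhere
then recompose the whole-chromosome occupancy exactly — a tested
invariant). The enrichment ratio is occupancy-in divided by
occupancy-elsewhere on the same chromosome; the shuffle null redraws the
breakpoint positions uniformly over that chromosome (the elsewhere
denominator defines the domain), 1000 times by default, and two one-sided
empirical p-values use the add-one estimator $p = (1 + \#\{r_{\mathrm{shuf}}
\ge r_{\mathrm{obs}}\})/(1 + n)$, which cannot return 0. Duplicated-block
(state 3) and triplicated-block (state 4) breakpoints are analysed
separately, reproducing the contrast design in which genic DNA associates
with duplication borders and replication origins with triplication
borders.

The empirical p is discrete and conservative under ties; with few
breakpoints and a sparse feature, the event "no window touches the
feature" creates an atom at p = 1. The calibration check therefore uses
enough breakpoints (12 on a 50 kb domain at ~12% feature occupancy) that
this atom is negligible; with very small breakpoint sets the p-values
remain valid but conservative.

# The synthetic generator

The generator is the package's study design, not a fixture. Defaults
emulate the experimental conditions: five 300 kb chromosomes; SNP rate
1e-3 per bp (about one diagnostic SNP per kilobase, the density of a
Col/Ler-like hybrid); one source chromosome partitioned into 14 blocks of
>= 5 kb assigned copy states 1-4 uniformly with adjacent blocks forced to
differ (the oscillating profile); a derived chromosome of 21 fragments (20
junctions) in shuffled order, each block appearing state − 1 times, with
inversion probability 0.5 (about half of junctions inverted); junction
chemistry drawn uniformly from microhomology (length uniform 2-15 bp),
blunt, and insertion (length uniform 1-125 bp, matching the conventional
25 bp-binned histogram support); hybrid coverage 50x as 2x100 bp pairs
(insert 400 +/- 40), control hybrid at the same depth, parents at 15x and
8x single-end; errors off; qualities constant Q40, which makes quality
trimming a no-op on clean data. The nucleus model is: parent B intact,
parent A minus the source chromosome, plus the derived chromosome — so
copy state equals 1 + the number of derived fragments covering a base, and
state-1 regions show loss of heterozygosity toward parent B, as observed
in real shattered individuals.

Three constraint layers make the planted truth exact. (1) *Layout*:
fragment orders that would place two reference-adjacent blocks
colinearly are repaired (the seam would rebuild the reference and no
junction would exist), fold-back adjacencies (same block, opposite
strands) never receive microhomology (the overlap would need to be a
palindrome), and no adjacency (or its mirror image) repeats, since such
junctions could be indistinguishable. (2) *Microhomology planting*: the
acceptor fragment's first k bases are edited in the reference — in both
parents identically, so no off-plan SNPs arise; a planted SNP inside the
edited k-mer is removed from the truth table. (3) *Accidental-homology
suppression*: single flanking bases that would extend a junction's
apparent overlap are edited (or, for insertions, the inserted sequence's
end bases are resampled), so the realized signature equals the planted
one. A fix-point loop resolves interactions between edits; as a final
guarantee the generator *measures* each junction's realized signature by
walking the built sequence against the reference with exactly the maximal
extension convention a split aligner uses, and records the measured type,
tract length and anchors as truth (with the planted values kept
alongside and a `realized_exact` flag). Measured and planted values
disagree only at rare pinned-edit conflicts, and the recorded truth is
what an ideal detector reports either way.

What the generator does not emulate: sequencing errors beyond optional
uniform substitution, indels, GC or mappability bias, repetitive DNA
(genomes are i.i.d. uniform, so unique mapping is almost surely possible),
organellar contamination, and pericentromeric repeats. Passing tests
therefore demonstrate the correctness of the algorithms on clean,
mappable data — not robustness to the alignment artefacts of real
pericentromeric regions, which is why real/noisy data must come in as
externally aligned SAM.

# Cohort statistics

Cross-outcome tables (haploid/diploid/aneuploid counts, micronuclei
presence) are compared with Fisher's exact test; published tables of this
kind are sometimes labelled with a t-test on proportions, but on 2x2
counts exact inference is well defined and the printed significance bound
is the reproducible claim. The continuity-corrected chi-square p is
reported alongside, and the sample odds ratio uses the Haldane 0.5
correction only when a zero cell exists. Published tables that print a
total with class percentages are reconstructed by nearest-integer rounding
(flagged as reconstructed in the result). Karyotype tallies count a
sample once: samples mixing classes go to a *combined* category, and
numerical aneuploids are broken down by the number of whole-chromosome
changes (single/double/triple/quadruple).

# Numerical and design choices

- Intervals are 1-based closed throughout (the IRanges convention);
  coordinates convert only at SAM ingest (already 1-based) and BED output
  (0-based half-open).
- All randomness flows through per-stage seeds derived from one run seed;
  reruns are byte-identical, and `with_seed` restores the caller's RNG
  state so library calls never perturb user code.
- The test suite and the acceptance script run the full study design — 5 x
  300 kb, 20 junctions, 50x paired reads — once (a few minutes on one
  CPU); unit tests use smaller worlds (10-100 kb) chosen so every binomial
  tolerance is a 3-4 sigma band at the simulated depth.
- `assemble_local` prefers the longest extension (smallest verified
  overlap >= 31 bp); for error-free reads any exact 31-mer overlap is a
  true adjacency up to genuine repeats, which the random genomes make
  vanishingly unlikely.
- Degenerate inputs: empty pileups, empty SNP tables and reference-zero
  bins return empty/masked results rather than errors where the quantity
  is well defined as absent; zero mapped reads, empty genomes and
  malformed SAM records are hard errors naming the offending input.

# Known limitations

- The exact unique mapper is not a variant-tolerant aligner; real data
  must be aligned externally.
- Junctions whose both anchors fall outside any dosage transition and away
  from chromosome ends (possible only for copy-neutral rearrangements,
  which the generator does not produce) would not be sought.
- Enrichment windows larger than the chromosome degenerate (the elsewhere
  domain vanishes); at simulation scale only the 1000 bp window is
  meaningful, and the 10 kb window is reserved for genome-scale data.
- The per-state allele fractions are allele-call fractions; converting to
  "fraction of genome derived from the inducer" would require a read-level
  mixture model that the data do not demand.
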