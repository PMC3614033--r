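---
title: "Pooled-segregant identification of causal mutations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-segregant identification of causal mutations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolseg)
```

## The inference problem

A haploid budding-yeast clone evolved under strong selection with an
elevated mutation rate accumulates many mutations, nearly all of them
passengers: neutral or mildly deleterious alleles that hitchhike on the
lineages carrying the few strongly beneficial ("causal") mutations. Bulk
segregant analysis separates the two classes by recombination. The clone
is backcrossed to its ancestor; the diploid is sporulated; a large spore
population is selected for the evolved phenotype; and the selected pool is
sequenced. In the pool, a causal allele approaches fixation while an
unlinked neutral allele stays near 1/2, so the per-variant read fraction
`f = mutant_reads / total_reads` is the test statistic.

`poolseg` implements this classifier and everything around it. The three
criteria for a putative causal mutation are:

1. the variant is new in the evolved clone — alleles already present in
   the time-zero strain are excluded whatever their pool frequency
   (`call_clone_mutations()` marks them `excluded_timezero`);
2. the variant is protein-altering or regulatory — missense, nonsense,
   frameshift, or a substitution in the promoter window up to 500 bp
   upstream of the coding start; synonymous and intergenic variants are
   excluded regardless of frequency;
3. `f > 0.9`, a strict inequality ("more than 90% of reads"). The
   fraction is kept as an exact division so a variant at exactly 90% is
   not called.

The threshold is a hard rule, not a significance test: at ~90x coverage a
fully swept allele (true `f` near 0.96 under the default selection model)
fails the cut only through binomial sampling, with probability on the
order of 1%. Variants with fewer than `min_depth = 10` total reads are
reported `uncallable` rather than risking a tiny-denominator pass.

## Genome representation and effect annotation

Gene models are single-exon (intronless), the appropriate idealization
for budding-yeast coding genes: one CDS per gene with 1-based inclusive
genomic coordinates, a strand, and a promoter window (default 500 bp).
CDS coordinates are signed: `+p` is the p-th coding base in coding
orientation, `-k` the k-th base upstream of the coding start; there is no
position 0, and the window is inclusive at -500 (-501 is intergenic).
Minus-strand genes are annotated in coding orientation with complemented
alleles; the test suite checks that annotating a minus-strand gene is
identical to annotating its reverse-complemented plus-strand construct.

Substitution effects come from translating the reference and mutated
codon (`codon_index = ceiling(p/3)`); translation is a lookup into the
standard genetic code as shipped by Biostrings. Indels whose length is
not a multiple of 3 are frameshifts. The new stop is found by translating
the shifted frame through the CDS plus up to 300 nt of downstream genomic
sequence; if no stop appears in that span the protein-level name ends in
`fs?`. The 300 nt bound is this package's choice — long enough that a
random frame (stop density ~3/64 per codon) almost always terminates
within it. The first affected codon is defined as the first position
where the mutant translation departs from the reference protein, which
reproduces names such as `G227Vfs249` where a deletion's immediate codon
happens to be preserved. Two further conventions: in-frame coding indels
are classed as missense (protein-altering, frame preserved) because the
effect vocabulary has no separate category for them, and stop-loss /
start-loss substitutions are likewise missense. A variant inside one
gene's CDS and another gene's promoter window belongs to the CDS gene;
overlapping CDSs resolve to the gene whose coding start is nearest.

Nucleotide-level names are `703G->T` (CDS position, negative for
promoter), `675_675delG`, `2494_2495insT`; protein-level names are
`E235*`, `T2996S`, `G227Vfs249`, or `Promoter`. `parse_nomenclature()`
inverts the nucleotide-level format exactly, and the suite round-trips
1000 random variants through format-then-parse.

## The synthetic experiment

`sim_config()` fixes the study conditions; `simulate_bsa_experiment()`
runs them from a single seed. Defaults emulate the scale of the real
design the package targets:

* **Genome**: 8 chromosomes x 250 kb of uniform random A/C/G/T. This is
  ~1/6 of a real yeast genome — large enough that 115 mutations are
  sparse, small enough to simulate quickly.
* **Map density** `cM_per_bp = 4e-4` (0.4 cM/kb), the budding-yeast
  scale, giving 100 cM per chromosome.
* **Mutations**: 5 causal mutations (one per designated gene; 20%
  promoter, the rest nonsynonymous CDS substitutions by construction),
  110 neutral hitchhikers (30% steered into decoy-gene CDSs so the
  coding/noncoding mix is realistic; the rest uniform), and 5 time-zero
  background variants. 5 + 110 matches an evolved clone with 115
  mutations after ~273 nominal generations. A `mutation_rate` option
  draws the hitchhiker count as Poisson(generations x rate) instead.
* **Selection coefficients** default to `s = 0.1` per causal allele.
  True per-mutation coefficients are not observable in the motivating
  experiments; 0.1 is chosen once so that 34 generations of selection
  drives a heterozygously segregating allele to
  `0.5 * 1.1^34 / (0.5 * 1.1^34 + 0.5) = 0.962`, comfortably past the
  90% threshold — matching the observed behaviour that causal alleles
  segregate above 90%.
* **Meiosis**: crossover breakpoints are a Poisson process at 1 per
  100 cM with no interference, which yields the Haldane mapping function
  `r(d) = (1 - exp(-2d/100))/2` exactly; different chromosomes assort
  independently. Gene conversion and crossover interference are not
  modelled. Mating-type selection of spores is absorbed into "spores"
  being the selectable haploid set, since it is orthogonal to autosomal
  allele frequencies.
* **Selection on spores** is deterministic exponential weighting: spore
  weight proportional to the product over carried causal alleles of
  `(1+s)^g` with `g = 34` (one 100:1 dilution plus three 500:1 dilutions;
  `generations_from_dilutions()` reproduces the 34). This matches the
  expectation of a serial-dilution competition and is testable in closed
  form; it deliberately omits drift during the passages.
* **Sequencing**: per-variant total depth Poisson(coverage = 90), mutant
  count binomial with success `f(1-e) + (1-f)e`, error rate `e = 0.001`.
  No read-level or base-quality modelling.

What passing tests on this generator do **not** show about real data:
alignment and variant-calling artefacts, repetitive sequence, uneven
coverage, clumpy-phenotype selection efficiency, and real linkage
geometry are all outside the model. The simulator validates the
*inference logic* under the stated statistical assumptions, not the
upstream bioinformatics.

## Hitchhiker flagging and its failure mode

Among putative causal calls on the same chromosome within `linkage_cM`
(default 25 cM — the field asserts linkage without giving a radius, so
this is a package choice, configurable), the lower-fraction member of
each pair is flagged as the likely hitchhiker, recording the
higher-fraction gene in `linked_to`. Exact ties flag neither and warn.
The flag does not remove the causal classification; reports separate
flagged rows. The rule can misfire: when a tightly linked neutral allele
samples a higher read fraction than its causal neighbour, the flag lands
on the causal allele. The simulated worked example in the README shows
one such case; resolving it requires reconstruction experiments, which is
exactly how the motivating study treated its borderline calls.
`causal_margin()` lists calls within 2% of the threshold for the same
reason.

## Copy-number logic

Depth tracks are 1 kb windows (0-based half-open), median-normalized per
profile before ratios to remove library-size effects. Segmentation is a
plain run-length rule: at least `min_windows = 3` consecutive windows
beyond 1.5 (gain) or 0.75 (loss). These thresholds are package choices —
the events of interest (tens of kb at ratio 2.0 or 2/3) are unambiguous
at default noise, and the suite checks invariance to 5% window noise. No
HMM or circular binary segmentation is attempted. Causality assessment
compares the pool ratio to the two expectations — `(clone_ratio + 1)/2`
for neutral heterozygous segregation versus `clone_ratio` for a retained
event — and picks the closer one.

## Sanger time courses

Allele frequencies from trace peak heights are `h_mut / (h_mut + h_anc)`.
In time-course mode values below 5% (trace background) become 0 and above
95% become 1; the boundaries themselves are left unclamped (a literal
reading of "below"/"above"). Segregation mode reports raw values. No
smoothing, interpolation, or chromatogram parsing.

## Small quantitative procedures

`adjusted_wald_ci()` adds two successes and two failures before the Wald
formula (z fixed at 1.96 for 95%); `ddct_fold_change()` is
`2^-ddCt`; `generations_from_dilutions()` sums `log2(factor)`;
`score_competition()` bands mean elimination cycles into the ++++/----
symbols, rounding the mean half-up before banding (the averaging rule
leaves rounding open; this choice is documented rather than discovered),
and requires a >75% majority in two of three full-length replicates for
+/-.

## Numerical and degenerate-input choices

* Pool fractions are plain double divisions of integer counts; the
  strict `>` at 0.9 is exact for any counts below ~2^52.
* Zero-depth variants are `uncallable`, never causal.
* Deterministic tie-breaks throughout: gene assignment (nearest coding
  start), hitchhiker ties (neither flagged, warning), equal-distance
  causality assessment (non-causal, the conservative reading).
* All randomness flows from explicit seeds; identical seeds give
  identical outputs, which the suite asserts.

## Problem sizes used by the test suite

Monte-Carlo checks use 10,000 spores where a closed form is compared
(binomial 99.9% bands), and 20 simulated experiments at 2,000 spores and
coverage 90 for the parameter-recovery check (&ge;95% of planted causal
mutations recovered; <5% of unlinked hitchhikers called causal). These
sizes make the suite fast while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

Single-exon gene models only; substitutions are single-base; no BAM/FASTQ
ingestion (the pipeline consumes variant and count tables); no
statistical test on pool fractions (the classifier is the field's hard
threshold by design); hitchhiker flagging is pairwise and transitive
chains are resolved greedily by fraction.
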