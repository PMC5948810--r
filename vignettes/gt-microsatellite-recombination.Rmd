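---
title: "Measuring homologous recombination at GT microsatellites from cloned amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring homologous recombination at GT microsatellites from cloned amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtrecomb)
```

## The measurement problem

GT-dinucleotide microsatellites are prone to replication stalling and
slippage, which makes them candidate initiation sites for double-strand
breaks (DSBs) and hence for homologous recombination (HR) between the two
homologous chromosomes of a heterozygote. In an intraspecific heterozygote
whose two parental haplotypes differ at diagnostic markers flanking the
repeat tracts — an indel upstream, SNPs and a small indel downstream,
further diversified markers around two shorter downstream motifs — every
cloned, Sanger-sequenced PCR amplicon can be read as a haplotype: a chain of
parental-origin calls plus repeat-length measurements. A clone whose markers
are all paternal or all maternal is a wild-type parental molecule; a clone
that switches parental origin once or twice is a recombinant; a clone with a
uniparental marker pattern but a contracted or expanded repeat tract is the
signature of PCR template switching and must be excluded from HR statistics.

`gtrecomb` implements this measurement end to end: a two-parent locus model,
anchor-based marker calling and repeat genotyping, clone classification with
breakpoint localization, DSB-origin inference, HR-frequency estimation with
artifact exclusion, and half-tetrad genotyping of gynogenetic diploid
progeny. A synthetic-data generator emulating the heterozygous goldfish
promoter locus that motivated the design provides ground-truth datasets, so
every stage is validated without external data.

## The locus model

`default_locus_spec()` encodes a ~2.6 kb promoter amplicon with three GT
motifs and eight diagnostic markers:

* **motif 1** — long and imperfect, 84 GT units (168 nt) on the paternal
  haplotype versus 36 units (72 nt) on the maternal one, with one
  interrupting substitution per parent;
* **motif 2** — 12 units, reverse-oriented relative to the reference strand
  (its tract reads as (AC)~n~ on that strand);
* **motif 3** — 10 units;
* markers — a 39-bp indel upstream of motif 1 (insertion allele on the
  paternal haplotype by default; the polarity is configurable because it is
  a property of the emulated strains, not of the method), two SNPs and a
  3-bp indel between motifs 1 and 2, three diversified markers between
  motifs 2 and 3, and one marker downstream of motif 3.

Unit counts for motifs 2 and 3 and the interruption positions are
configurable; the defaults are plausible values for short flanking GT
tracts. Conserved spacer sequences are generated once from a fixed seed so
the default locus is bit-reproducible. Every marker and motif is delimited
by 20-nt *anchors*: conserved k-mers immediately flanking the element,
identical in both parents and validated to occur exactly once per parental
sequence. Twenty is long enough that a random ~2.6 kb sequence essentially
never duplicates an anchor, and short enough that a single sequencing error
is tolerated by approximate matching.

All coordinates are 0-based and half-open. Breakpoint intervals are
reported in the *anchor frame* — coordinates on the rendered paternal
sequence, whose anchors are shared with the maternal one — so the 39-bp
length difference between parents does not shift interval semantics.

```{r locus}
locus <- load_locus_spec(default_locus_spec())
locus
```

## Marker calling and repeat genotyping

Each clone is first orientation-checked (a reverse-complemented insert is
flipped), then every anchor is located by exact k-mer search, falling back
to approximate matching (at most 2 mismatches, unique hit required) and
finally to coordinates projected through a global Needleman–Wunsch alignment
to the closer parental reference. The substring between an element's two
anchors is its observed allele:

* SNP alleles must match a parental allele exactly;
* indel alleles may carry one substitution provided the length matches, so
  a sequencing error cannot flip an indel call;
* a call is `ambiguous` when both anchors are found but the allele matches
  neither parent (or both), and `missing` when an anchor cannot be located —
  failures stay local to the affected marker.

Repeat tracts are genotyped by length: the unit count is the anchor-to-anchor
distance divided by the unit length, discarding a trailing odd nucleotide.
This makes the count invariant to the interrupting substitutions that make
motif 1 "imperfect", and strand-symmetric for the reverse-oriented motif 2.

The alignment fallback (rather than pure column reading of a three-way
alignment) was chosen because the 39-bp indel makes naive coordinate
transfer between parents fragile; anchors sidestep that entirely. Equal-score
alignments resolve deterministically (Biostrings' leftmost-gap convention),
and alignment identity is computed over *all* alignment columns, so a
truncated clone scores low instead of hiding behind a perfect partial match.

## Clone classification

Classification is minimal-switch parsimony over the ordered usable calls
(non-missing, non-ambiguous), which formalizes the visual linkage-pattern
reading used at the bench:

| switches | placement | class |
|---|---|---|
| 0 | repeat count matches the calls' parent | `PD` / `MD` |
| 0 | repeat count matches neither parent | `INTRA_ALLELIC` (excluded) |
| 1 | interval contains motif 1 | `CO_I` |
| 1 | interval between motifs 2 and 3 | `CO_II` |
| 2 | one interval of each kind, flanks from one parent | `CO_I_II` |
| otherwise | — | `AMBIGUOUS` (excluded) |

A clone with more than a third of its markers unusable is `AMBIGUOUS` — a
safeguard against degraded reads; clean Sanger clones essentially never
trigger it. A single switch in the proximal, motif-free region is also
`AMBIGUOUS` rather than a new crossover class, since no HR was observed
there. One deliberate edge case: a zero-switch clone carrying the *other*
parent's exact repeat count fits neither the parental nor the artifact
signature and is classified `AMBIGUOUS` rather than guessed.

The breakpoint interval of a switch is the open gap between the last marker
before it and the first marker after it. For a crossover-I clone the repeat
tract reports the repair template: a clone with the maternal unit count
implies a DSB on the paternal homolog repaired from the maternal chromosome
(`infer_dsb_origin()`), and counts matching neither parent leave the origin
indeterminate (`contracted` below both counts, `expanded` otherwise).

## Statistics

`estimate_frequencies()` tabulates classes per sample (samples are never
pooled implicitly), excludes `INTRA_ALLELIC` and `AMBIGUOUS` clones from
both numerator and denominator, and reports the HR fraction with a 95%
Wilson score interval — chosen for its behavior at the small per-sample
clone counts typical of cloned-amplicon studies (20–150 clones). No
hypothesis tests are added because the measurement design reports
proportions, not contrasts. Percentages are rounded to two decimals.

`genotype_gynogenote()` implements the half-tetrad readout: both alleles of
a meio-gynogenetic diploid derive from one egg haplotype pair, so an
individual showing a single haplotype pattern is homozygous for a
grandparental haplotype, while two or more distinct patterns (typically one
grandparental, one crossover) mean a meiotic crossover occurred.
`meiotic_hr_frequency()` turns the cohort's heterozygote proportion into the
meiotic HR estimate. An individual whose clones are all of the crossover
pattern is genotyped `HET`: a purely recombinant half-tetrad still evidences
meiotic exchange. `detect_novel_lengths()` flags repeat lengths absent from
both parental alleles, optionally contrasting against a control sample's
spectrum — the signature used to establish repeat instability in the first
place.

## The synthetic-data generator

`simulate_clone()` inverts the classifier's definitions: crossover clones
switch parental haplotype at breakpoints placed uniformly at unit or
inter-marker boundaries within the candidate regions; crossover-I clones
carry the repair template's motif-1 tract; `CO_I_II` clones exchange the
segment between one crossover-I site and one crossover-II site. Artifacts
are layered on top:

* `slippage_prob` (default 0.15) — the amplified tract contracts or expands
  by a geometric number of units (sign-symmetric, never below 1 unit);
* `template_switch_prob` (default 0.10) — a PCR template switch inside the
  homogeneous repeat re-anneals at a shifted register, producing a
  length-variant clone with an unchanged marker pattern, exactly the class
  the exclusion rule is designed to remove;
* `seq_error_rate` (default 0.001) — per-base substitutions, applied last.

The artifact magnitudes are design choices (no rates are published for this
locus); they are plausible for cloned Ex-Taq products and fully
configurable. Simulated crossover-I breaks sit on the paternal (long-tract)
homolog with probability 0.8 by default, reflecting the observed asymmetry
without claiming a measured value. `simulate_embryo_series()` models HR
accumulation over cell divisions — a lineage is recombinant with probability
$1-(1-p)^d$ after $d$ divisions — and `simulate_gynogenote_cohort()`
produces half-tetrad cohorts with known genotypes.

What the generator does *not* emulate: chromatogram noise, read-level error
models, PCR cycle chemistry, gene-conversion tract lengths, or crossovers
outside the two candidate regions. Passing tests therefore demonstrate that
the pipeline recovers truth under the stated clone-generation model, not
that it is robust to every failure mode of real Sanger data (mixed
templates, primer artifacts, low-quality tails).

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: rendered
tracts against a from-scratch reconstruction, alignments against edit
distance, the classifier against brute-force enumeration of all 0/1/2-switch
mosaics on the 8-marker locus, and the whole pipeline against simulation
truth (100% class and DSB-origin recovery at zero artifact rates, across all
classes). Distribution-level properties use: 1000 clones at the default
sequencing error rate for marker-call robustness (≥99% usable calls), 500
clones per time point for the embryo accumulation law (within three binomial
standard errors), 200 replicates of 500 clones for Wilson-interval coverage
at a true HR fraction of 0.30 (≥93% coverage), and 400 individuals per
setting for the gynogenote estimator. These sizes give stable statistics
while keeping the suite fast on a single CPU.

The coverage property is run at zero artifact rates deliberately: template
switching afflicts only parental-pattern clones, so the exclusion rule
removes clones asymmetrically and shifts the retained HR fraction upward.
That bias is inherent to the published exclusion procedure whenever
artifacts are class-dependent — worth remembering when comparing absolute
HR frequencies across studies — and is not a property of the interval
estimator under test.

## Known limitations

* Classification assumes at most two genuine switches; complex multi-switch
  molecules (e.g. nested conversions) are surfaced as `AMBIGUOUS`, never
  guessed.
* Repeat genotyping is length-based; it cannot distinguish a tract whose
  interruptions moved (gene conversion within the tract) from the parental
  tract of equal length.
* The locus model requires exactly three motifs and marker coverage of all
  four flanking segments; other locus architectures would need a
  generalized candidate-region definition.
* The 39-bp/3-bp indel polarities and the exact SNP alleles of the emulated
  locus are configurable stand-ins, not transcriptions of the deposited
  reference sequences; analyses of real data should load a locus spec built
  from those references.
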