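---
title: "Methods: somatic mitochondrial mutation burden, spectra, selection and reversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mitochondrial mutation burden, spectra, selection and reversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosoma)
```

## The problem this package addresses

Duplex sequencing reads both strands of each original DNA molecule and
builds a double-strand consensus, pushing the error rate below 10^-7 and
making somatic mitochondrial mutations at frequencies of 10^-6 to 10^-3
measurable. A typical experiment profiles the ~16.3 kb circular mt-genome
across strains, tissues and ages, producing per-site tables of duplex depth
and alternative-allele depth. `mitosoma` turns such tables into:

* per-site and per-region mutation **burden** with exact Poisson intervals
  and log-link rate tests (age and strain effects);
* **hotspot scans** in sliding windows on the circular genome and pooled
  frequencies over homopolymer tracts;
* strand-collapsed **mutational spectra** (8 classes) and trinucleotide
  contexts of de novo calls;
* a simulation-calibrated **hN/hS selection test** per protein gene;
* **NUMT** (nuclear-embedded mitochondrial segment) contamination
  estimation and correction;
* **reversion-mutation** tests at conplastic haplotype sites - positions
  where a strain's mt-genome differs from the nuclear-matched (B6)
  haplotype, at which somatic selection can favour the re-introduction of
  the ancestral allele.

Because the motivating datasets are hundreds of gigabytes, every stage is
exercised on a synthetic generator that emulates the statistical structure
of per-condition duplex call tables; the generator is itself first-class,
tested code.

## Data model and filters

A **call** is one observed alternative allele at one position
(`position`, `ref`, `alt`, `alt_depth`, `depth`, `sample_id`), VCF-anchored
for indels and left-anchored/parsimony-trimmed on read. A **condition**
aggregates replicate samples of one strain x tissue x age cell by summing
depths and alt depths. Mutation frequency at a position is the summed
alternative depth over all alts divided by the duplex depth there.

Three filters recur, all with *strict* comparisons:

| filter | rule | default | why |
|---|---|---|---|
| high frequency | drop calls with frequency > threshold | 1e-3 | removes inherited/near-fixed heteroplasmies from somatic analyses; a call at exactly the threshold is retained ("greater than") |
| de novo proxy | keep `alt_depth` < 100 AND frequency < 0.01 | 100, 0.01 | operational proxy for newly arisen mutations; each surviving (position, alt) is scored once (weight 1) |
| haplotype sites | drop calls at conplastic haplotype positions | per strain | fixed differences are not somatic; the removed set feeds the reversion module |

The de novo frequency clause is evaluated at the sample level, which is the
level at which the proxy is meaningful.

## Burden statistics

Two frequency summaries are emitted side by side because either averaging
convention is defensible and the source convention is not stated: the mean
of per-position frequencies and the pooled frequency (total alt depth /
total depth). The exact Poisson interval on a count `k` with exposure `E`
is `[qchisq(a/2, 2k)/2, qchisq(1-a/2, 2k+2)/2] / E`.

Age and strain rate contrasts use a Poisson GLM with log link and
log-exposure offset - with two groups this is saturated, so the estimate
equals the closed-form rate ratio `(k2/E2)/(k1/E1)`; fitting is delegated
to `stats::glm` because the contribution here is the design, not the
solver. Bonferroni correction is applied across strain x tissue cells.

The sliding-window scan uses 150-bp windows advanced 1 bp at a time
(the source says "sliding" without a step; 1 bp is the maximal-resolution
choice and is configurable); windows wrap the circular origin. "Percent bp
mutated" is not defined in the source; we take the percentage of genome
positions carrying at least one retained mutation, computed after depth
normalization when conditions are compared.

Depth normalization across conditions is `none` by default (frequencies are
self-normalizing); `thin-to-min` performs hypergeometric thinning to the
per-position minimum depth under a fixed seed, leaving expected frequencies
unchanged. The source's normalization procedure is unstated, so neither
mode is asserted as "the" procedure.

## Strand-collapsed spectra

Double-strand consensus calling cannot assign a mutated strand, so each
substitution is pooled with its reverse complement into six classes plus
INS and DEL. Classes are keyed by the purine-reference representation
(`G>A/C>T`, ...) as printed in the motivating work; `to_pyrimidine_key()`
converts to the COSMIC convention. SNV class frequencies are normalized by
the duplex depth summed over positions whose reference base belongs to the
class's base pair; indel classes by total depth. Multi-base substitutions
(MNVs) are rejected rather than decomposed.

Trinucleotide contexts are read from the reference (circular, positions
-1/0/+1) and purine-reference calls are reverse-complemented into the
pyrimidine-centred facet, so `ACG` represents both `ACG` with C>T and
`CGT` with G>A. Fractions are per de novo mutation, scored once.

Per-class age associations use Fisher's exact test on (class vs rest) x
(young vs aged) with Benjamini-Hochberg correction across the 8 classes.
The condition x class count matrix for external signature extraction is
exported as TSV; signature extraction itself is out of scope.

## The hN/hS selection test

For a protein gene, `hN` is the weighted count of non-synonymous calls per
non-synonymous site and `hS` the synonymous analogue; `hN/hS` plays the
role of dN/dS for a somatic population of genomes. Site counts classify
every possible point substitution in every codon under the vertebrate
mitochondrial code (NCBI table 2: TGA=Trp, ATA=Met, AGA/AGG=stop), each
position contributing fractions that sum to 1, so `N + S` equals the coding
length. Stop-gaining (and stop-losing) changes count as non-synonymous;
nonsense calls are reported distinctly but pooled into hN. Genes are the 13
protein features; tRNA/rRNA are excluded. Uniform substitution weighting is
used for site counting, with the weighting hook left for spectrum-aware
variants.

The null: the observed number of mutations is resampled with a multinomial
draw over the 8 classes (observed proportions) and positions uniformly with
replacement among positions whose reference base is *compatible* with the
drawn class - a G>A/C>T draw must land on G or C to be classifiable, which
is how we read "uniformly" operationally. Simulated indels are single-base
A edits and never enter hN/hS. The per-gene empirical p is the fraction of
valid simulations (those with nonzero simulated hN and hS) at least as
extreme as the observation in the observed direction, doubled and capped at
1; ties count as extreme (conservative). Genes with observed `hN = 0` or
`hS = 0` are excluded. Benjamini-Hochberg correction runs across genes
within a condition; direction (positive if ratio > 1, negative if < 1) is
called at adjusted p < 0.01. For speed the implementation draws, per
simulation, the per-(gene, effect) tallies directly from the induced
multinomial - provably the same law as tallying individual draws, and
verified against the draw-level path in the tests.

Three analysis modes mirror the source: all mutations (frequency <= 1e-3),
all mutations excluding the D-loop, and frequency-binned with the D-loop
excluded and high-frequency calls included; in the binned scan proportions
and counts are recomputed per bin and BH runs within each bin. Default bin
edges are `0, 1e-5, 5e-5, 1e-3, 1`: the two interior bounds 5e-5 and 1e-3
delimit the intermediate-frequency range highlighted by the source; the
others are package defaults. The position target space is configurable
(`genome` default, `coding`) because whether the null should place
mutations in noncoding regions when proportions were estimated without the
D-loop is ambiguous.

### What is calibrated, and what is not

Under a neutral synthetic world the empirical p-values are approximately
Uniform(0,1] **when the analysis mode matches the null's assumptions**:
D-loop calls excluded and unit weighting (each mutation scored once). Two
paper-faithful defaults are *not* exactly calibrated at desk scale and we
keep them anyway, documented:

* counting mutations as summed alternative-allele depths makes one mutant
  lineage contribute several "draws" to the observed statistic while the
  null draws units, overdispersing observed ratios (anti-conservative;
  negligible when counts are large as in the motivating data, visible at
  desk-scale counts);
* retaining D-loop/OriL calls concentrates observed mutations in noncoding
  hotspots while the null spreads them uniformly, leaving simulated
  per-gene counts too large and the null too tight - the same bias that
  motivates the D-loop-excluded mode.

The non-synonymous and synonymous frequency spectra (unit-sum vectors over
bins) and the null spectrum of potential changes (class proportions of all
possible non-synonymous and synonymous substitutions, by brute
enumeration) provide the descriptive complement to the test.

## NUMT contamination and reversion tests

Reads from the nuclear NUMT copy carry the B6 allele at haplotype sites
and therefore mimic reversions. Contamination is estimated per condition as
junction chr1 reads divided by the average mt duplex depth (NUMT span
masked); the adopted fraction is the maximum over junctions (conservative
over-subtraction), optionally validated against the median SNV-cluster
estimate. Correction subtracts the estimated chr1 depth (average depth x
adopted fraction) from depths and reversion counts inside the span,
clamping counts at zero because depths are counts; the source is silent on
negatives.

Reversion enrichment: for strains with at most 10 haplotype sites
(mirroring the 1-3-site strains), each site receives a one-sided empirical
p - the fraction of background (non-haplotype) site frequencies at least as
high - BH-adjusted within the strain; larger strains (the 91-site case) use
a one-sided Wilcoxon rank-sum test of the two distributions. The background
keeps all mutations, including those above 1e-3. Reversion identity uses an
exact binomial test of B6-allele reads against the uniform-alt null
(p0 = 1/3). The age-delta test conditions on the direction of each site's
aged-minus-young frequency change and compares against background deltas
(same tissue), BH within strain, significance at adjusted p < 0.02.

Two deliberate choices deviate from a literal reading of the source. First,
ties count as extreme in the empirical p's (the source wording is "higher
than"/"greater than"): with discrete desk-scale frequencies the strict
comparison is measurably anti-conservative, and ties-as-extreme is the
standard conservative convention (and the one the selection test states).
Second, the flat-slope false-positive calibration of the age-delta test is
run under exchangeability (reversion enrichment fold 1): with a 100-fold
enrichment the haplotype-site deltas have far larger sampling variance than
any background delta, so the background comparison cannot be calibrated in
that regime - which is also why the test is only meaningful alongside the
enrichment analysis.

### Known limitation: leak-affected sites

At haplotype sites *inside* the NUMT span, the B6-allele count includes
binomial leakage with success probability ~5e-3 - two orders of magnitude
above per-site mutation rates - so its sampling variance dominates the
background delta distribution even after correction (an average-based
estimate removes the mean, not the per-site noise). The age-delta empirical
p is therefore anti-conservative at such sites at any depth; the acceptance
suite asserts calibration for leak-free sites and documents the in-span
failure rather than masking it. Interpret in-span reversion deltas with
this in mind; the same caveat applies to the original analysis design.

## The synthetic generator

`sim_config()` states the emulated world; defaults follow the motivating
design where stated and field-realistic choices elsewhere:

* genome: 16,299 bp circular, 13 proteins / 22 tRNAs / 2 rRNAs / D-loop /
  OriL, clean ATG...TAA coding frames, both strands;
* depth: negative binomial per position (default mean 18,000 per sample,
  size 10) - duplex depth varies several-fold across conditions, so Poisson
  would be too tight; four replicates per condition;
* rates: base rate 1e-5 mutations per bp per duplex read in the coding
  background (so a four-replicate condition carries a mutation load of the
  observed order), D-loop fold 6.4, OriL fold 40, aged/young fold 2 on the
  clock-like classes with tissue modifiers (heart lower, liver higher);
* spectrum: replication-error-dominated proportions with G>A/C>T most
  abundant, then G>T/C>A; classes placed only at compatible reference
  bases;
* strains: haplotype-site counts 0/1/3/2/91 (B6/AKR/ALR/FVB/NZB),
  reversion fold 100 with an aged multiplier, NUMT fraction 0.005 as
  binomial leakage of B6 alleles inside the span, junction read summaries
  emitted alongside;
* selection: optional frequency-binned wholesale dropping of
  non-synonymous lineages (a thinned lineage disappears; read-level
  thinning would migrate calls across frequency bins, which is not how
  purifying selection acts on a lineage).

It does **not** emulate read-level artefacts (end-trimming damage, mapping
bias), strand-asymmetric chemistry, clonal expansion within tissues, or
linkage between sites. A green test therefore establishes that the
statistics recover what they claim from data with the assumed sampling
structure - not that the pipeline is robust to artefacts upstream of
variant calls.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive throughout; BED input is converted on
  read. Sequence indexing and windows are modular on the circle.
* Overlapping features resolve by OriL > D-loop > tRNA > rRNA > protein,
  keeping the replication-origin hotspot distinct from whatever it
  overlaps.
* One master seed fans out to per-stage seeds by a stable 31-bit string
  hash (`derive_seed`), so reruns are bit-identical and stages are
  independently reproducible.
* Degenerate inputs fail loudly: empty sample lists, zero-depth regions,
  genes with non-codon-sized spans (unless flagged as
  polyadenylation-completed incomplete stops, which truncate the final
  partial codon), classes with nonzero proportion but no compatible
  positions.
* Empirical p-values of 0 are reported with their resolution floor
  (2 / valid simulations); the pipeline warns when `n_sim` < 1000.
* The pipeline config is JSON (`jsonlite`), holding the same structure a
  YAML file would; no YAML parser is available in the supported
  dependency set.
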