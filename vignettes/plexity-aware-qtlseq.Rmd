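---
title: "Plexity-aware QTL-seq for autotetraploid bulked-segregant analysis"
author: "plexQTLseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plexity-aware QTL-seq for autotetraploid bulked-segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexQTLseq)
```

## The problem

QTL-seq maps trait loci by sequencing two pooled DNA samples ("bulks")
drawn from the phenotypic extremes of a segregating population and
comparing pooled allele frequencies (SNP-indices) between the bulks. The
classical formulation assumes a diploid cross. Autotetraploids such as
cultivated potato inherit four homologous chromosomes, two at random from
each parent, so the expectations change fundamentally:

* A variant carried by one of the donor parent's four homologs (a
  **simplex** variant) segregates 1:1 nulliplex:simplex in F1 progeny of a
  cross with a **nulliplex** (non-carrier) parent. An unselected bulk then
  has an expected SNP-index of $m/(2p) = 1/8 = 0.125$, and complete
  selection at a QTL displaces the between-bulk difference
  ($\Delta$SNP-index) to at most $\pm 0.25$.
* A **duplex** variant (two of four homologs) segregates 1:4:1
  nulliplex:simplex:duplex, the unselected expectation is $0.25$, and the
  maximal displacement is $\pm 0.5$.

A QTL whose causal allele is duplex in the donor is therefore invisible to
an analysis restricted to simplex variants, and vice versa: the parental
SNP-index itself is the instrument that separates the two variant classes.
This package implements that plexity-aware analysis, a full
autotetraploid bulked-segregant simulator, and the companion
allele-dosage (plexity) genotyping used to validate candidate loci.

## Segregation model

`CrossSpec(ploidy, donorPlexity)` fixes the model: a donor parent carrying
$m$ ALT copies crossed to a nulliplex parent, with random chromosomal
segregation and no double reduction. A gamete receives a uniform random
$p/2$-subset of homologs, so its ALT dosage is hypergeometric,

$$P(j) = \frac{\binom{m}{j}\binom{p-m}{p/2-j}}{\binom{p}{p/2}},$$

which yields the 1:1 and 1:4:1 ratios above for $p = 4$, $m = 1, 2$. The
nulliplex parent contributes nothing, so progeny dosage equals gamete
dosage. Double reduction is excluded because the printed expected ratios
for this design (e.g. 29.7:118.7:29.7 for $n = 178$) are exactly the
no-double-reduction ratios; the generalisation to arbitrary even ploidy is
provided but only the tetraploid case is exercised by the shipped tests.

## The plexity filter

`filterDonorVariants()` keeps a variant when

* the donor parent's SNP-index lies in a closed interval — defaults
  0.10–0.36 (`nplex = 1`) or 0.37–0.63 (`nplex = 2`);
* the other parent is effectively devoid of the allele — SNP-index
  $\le$ 0.02 *and* ALT depth $\le$ 1 (the source method requires a
  nulliplex second parent but states no numeric rule; this pair of caps
  tolerates a single stray error read at depth ~60 while excluding any
  genuinely segregating allele);
* all four samples have total depth $\ge$ 40 (`minDepth`; applied
  uniformly to parents and bulks);
* In/Dels longer than 70 bp are dropped; shorter ones are treated exactly
  like SNPs.

`simulateIndexRangeCoverage()` quantifies the ranges: a true simplex
variant read at depth $d$ has ALT count $\sim \mathrm{Binomial}(d, 0.25)$,
and the exact pmf sum shows the 0.10–0.36 interval captures about 94–95%
of simplex variants at depth 40 and $\ge$ 95% from depth 50 upward, which
is what makes 0.10–0.36 / 0.37–0.63 sensible defaults rather than tuned
values.

## Null distribution, P values and bands

Because selection acts only at QTLs, the no-QTL null for a variant is
fully specified by the cross, the bulk sizes and the read depths.
`buildNullThresholds()` simulates it directly: draw each bulk's
individuals from the progeny dosage distribution, pool to an ALT fraction
$f_b = \sum \text{dosage} / (p\,n_b)$, draw ALT reads
$\sim \mathrm{Binomial}(d_b, f_b)$, and form
$\Delta = k_1/d_1 - k_2/d_2$. This genotype-then-binomial-read scheme
follows the QTL-seq lineage this method descends from. Defaults:
$R = 10^4$ replicates per depth pair, with depth pairs binned at width 10
(representative depth = median observed depth in the bin) to bound
compute; two-sided P values use add-one smoothing,
$P = (\#\{|\Delta_0| \ge |\Delta|\} + 1)/(R+1)$.

One numerical subtlety: $\Delta$ is discrete (multiples of $1/d$), so an
empirical "type-1" quantile combined with a boundary-inclusive
significance rule systematically over-rejects by up to the tie mass at the
edge value (~0.3% per side at depth 60) — enough to break 1% calibration.
The band edges are therefore chosen as the observed null value whose
inclusive tail mass is *closest* to $\alpha/2$ (ties resolved toward the
more extreme value). The boundary-inclusive rule is kept — a variant
sitting exactly on the 95% edge is classed P95 — and `nullCalibration()`
verifies that the realised P99/P95 rates sit at their nominal 1%/5%.

## Windows and candidate regions

`slidingWindowStats()` tiles each chromosome with 100-kb windows every
20 kb (a variant contributes to every window containing it) and reports
mean bulk indices, mean $\Delta$, mean $-\log_{10} P$, and the directional
QTL-variant counts: how many variants in the window are classed P95/P99
with positive vs negative $\Delta$. Around a true QTL the displacement is
one-sided, so `callCandidateRegions()` requires the P99 count to *exceed*
100 (strictly) in exactly one direction; windows exceeding it in both
directions are depth-noise artefacts of variant-dense regions, not QTLs.
Qualifying windows that overlap or touch merge into one region per
direction. Coordinates are 1-based inclusive in tables and 0-based
half-open in BED output. The count threshold 100 is a configuration
default chosen relative to genome-wide P99 counts, not a statistical
constant. `runBothOrientations()` repeats everything with the parents
swapped so QTLs from either parent are found and labelled by donor.

## The simulator

`simulateBsaExperiment()` generates the whole experiment from one seed:

* **Variants and parents** — uniform variant placement at a configurable
  density; each variant is assigned a donor and a plexity, and its ALT
  allele is planted on exactly that many donor homologs.
* **Carrier structure** — by default (`carrierStructure = "ibd"`), per
  donor and chromosome, all simplex variants share one carrier homolog
  and all duplex variants one carrier pair. This emulates the
  identity-by-descent origin of the plexity classes: a diverged homolog
  accumulates the private (simplex) variants, an IBD homolog pair the
  shared (duplex) ones. It is what produces the *asymmetric* directional
  window counts a real QTL shows; with fully independent carrier sets
  (`"random"`), variants flanking a QTL split between homolog
  backgrounds and the directional counts cancel, so no candidate can ever
  qualify. Real genomes lie between these extremes (carrier structure
  turns over along a chromosome); the simulator does not model that
  mosaic turnover.
* **Meiosis** — per chromosome, random bivalent pairing of the four
  homologs, Poisson crossovers per bivalent (mean = map length in
  Morgans; Haldane, no interference), one recombinant chromatid per
  bivalent, no double reduction. The constant cM/Mb rate (default 4) is a
  modelling convenience, not an inference about any real map.
* **Phenotypes** — additive (per ALT copy) or dominant (carrier vs not)
  QTL effect plus Gaussian noise, mirroring the dosage-dependent
  ("P-Kα-like", additive duplex) and dominant ("chroma-like", simplex)
  trait architectures; `chroma()` converts CIE $a^*, b^*$ colour readings
  to the $C^* = \sqrt{a^{*2} + b^{*2}}$ saturation phenotype.
* **Bulks and reads** — tails by size or threshold (fractions reported as
  percent of the phenotyped population to one decimal); pooled reads are
  binomial over the bulk's true allele fraction at fixed or Poisson depth,
  with an optional symmetric per-read error rate (default 0).

Desk-scale defaults mirror the study regime: $n = 178$ progeny, tail
bulks of ~18 (~10% of the population), depth 60, 0.8/0.2
simplex/duplex mix. What the simulator deliberately omits: read-level
artefacts (mapping error, allele-specific bias), allopolyploid subgenome
divergence, non-uniform recombination and variant density, and carrier
mosaic turnover. Passing tests therefore demonstrate the statistics are
correct under the stated inheritance and read-sampling model, not that
the pipeline is robust to alignment artefacts in real data.

## Plexity genotyping

Three assay types estimate the allele dosage of individual lines at a
candidate locus:

* qPCR: `dosageFromQpcr()` implements relative quantification,
  $2^{\mathrm{Ct_{calibrator}} - \mathrm{Ct_{sample}}}$ against a
  simplex-mimicking 1:1 parental DNA mix, with optional reference-amplicon
  normalisation for crude extracts.
* Fragment analysis: ALT/REF peak-height ratio.
* Amplicon sequencing: ALT read fraction per target.

`classifyDosage()` bins each measurement with the assay's empirical
intervals (see `defaultDosageBins()`); values in inter-subgroup gaps are
"unclassified" rather than guessed. Where two intervals share an endpoint
(fragment 0.55; qPCR 1.5) the boundary value goes to the higher class —
the border divides the classes, closed on the upper side.
`consensusCall()` takes the most frequent class across assays (ties →
unresolved), `concordanceSummary()` reports population-level agreement,
and `segregationChiSquare()` tests the consensus genotype counts against
an expected ratio such as 1:4:1.

## Numerical and design choices

* All randomness flows from explicit seeds; a dataset, an analysis and
  its written outputs are pure functions of configuration + seed.
* Multi-allelic VCF records are skipped (a single ALT per site is
  assumed); genotype calls in the VCF are ignored in favour of allele
  depths.
* $\Delta = 0$ variants have no direction and enter no directional count.
* P95 window counts include P99 variants (the 95% class is "at least
  95% confidence").
* Empty windows carry zero counts and NA means; terminal windows are
  truncated at the chromosome end.
* The shipped test suite runs the full pipeline at reduced but honest
  problem sizes — e.g. planted-QTL recovery on an 8-Mb chromosome at
  3 × 10⁻³ variants/bp with $n = 178$ and bulks of 18 across 20 seeds per
  plexity, and null calibration on 5 000 independent variants at
  $R = 10^4$ — sizes chosen so the binomial/χ² tolerances stated with
  each test are meaningful.

## Known limitations

* Preferential pairing, double reduction and odd ploidies are out of
  scope; the segregation model is pure random chromosomal segregation.
* The null simulation conditions on binned depths; extremely heterogeneous
  depth distributions would warrant narrower bins.
* Candidate-region extent is linkage-limited: with strong selection on a
  single small chromosome the qualifying region can span most of it. The
  candidate rule guarantees direction-consistent asymmetry, not fine
  mapping.
* Occasional isolated sharp single-window peaks (as real data show) are
  not given any special treatment beyond the window rule itself.
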