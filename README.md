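# plexQTLseq

Plexity-aware QTL-seq for autotetraploid bulked-segregant analysis.

## What it does, and for whom

Bulked-segregant QTL mapping (QTL-seq) compares pooled allele frequencies
(SNP-indices) between two phenotype-tail DNA bulks of a segregating
population. In an autotetraploid F1 cross — potato being the motivating
crop — a donor-parent variant can sit on one (**simplex**) or two
(**duplex**) of the four homologous chromosomes, and the two classes
segregate differently (1:1 vs 1:4:1 against a nulliplex parent), carry
different unselected bulk expectations (0.125 vs 0.25) and different
maximal ΔSNP-index displacements under complete selection (±0.25 vs
±0.5). A QTL whose causal allele is duplex is invisible to an analysis
restricted to simplex variants — so the analysis must *select variants by
plexity*, using the donor parent's own SNP-index (0.10–0.36 for simplex,
0.37–0.63 for duplex at depth ≥ 40).

The package is for geneticists and breeders working with autopolyploid
biparental populations. It provides:

* closed-form tetrasomic segregation distributions and bulk expectations
  (`gameteDosageDistribution`, `expectedBulkSnpIndex`,
  `maxDeltaSnpIndex`);
* the plexity-aware QTL-seq pipeline: donor-variant filtering
  (`filterDonorVariants`), depth-conditional Monte-Carlo F1 null
  thresholds and P values (`buildNullThresholds`,
  `computeVariantStats`), 100-kb/20-kb sliding-window statistics
  (`slidingWindowStats`) and directional candidate-region calling
  (`callCandidateRegions`), wrapped by `runQtlSeq` /
  `runBothOrientations`;
* a full autotetraploid BSA simulator (`simulateBsaExperiment`):
  bivalent meiosis with Haldane crossovers, dosage-dependent phenotypes,
  tail bulks, binomial read sampling, and four-sample VCF output;
* allele-dosage (plexity) genotyping from qPCR, fragment-analysis and
  amplicon-sequencing assays (`dosageFromQpcr`, `classifyDosage`,
  `consensusCall`, `segregationChiSquare`).

The core statistic: for each variant passing the plexity filter,
ΔSNP-index = index(Bulk1) − index(Bulk2) is compared with a simulated
no-QTL F1 null (genotype draw → pooled allele fraction → binomial reads,
conditioned on the observed depths). Variants outside the 99% band count
toward their window's directional "QTL variant count"; a candidate region
is called where that count exceeds 100 in exactly one direction.

## Worked example

Simulate a duplex QTL (additive effect 3x the noise sd) in a 178-line F1
population on an 8-Mb chromosome, bulk the 18 lowest and 18 highest
phenotypes, sequence at depth 60, and analyse with duplex settings:

```r
library(plexQTLseq)

cross <- CrossSpec(ploidy = 4, donorPlexity = 2)
progenyDosageDistribution(cross)
#>         0         1         2
#> 0.1666667 0.6666667 0.1666667
expectedBulkSnpIndex(cross)
#> [1] 0.25

genome <- GenomeSpec(c(chr01 = 8e6), cmPerMb = 4, variantDensity = 3e-3)
sim <- simulateBsaExperiment(genome, n = 178, bulkSize = 18,
  qtl = list(chrom = "chr01", nearPos = 4e6, plexity = 2,
             mode = "additive", effect = 3, noiseSd = 1),
  plexityMix = c(simplex = 0.5, duplex = 0.5), seed = 42)
res <- runQtlSeq(sim$observations, donor = "P2",
                 config = PlexityFilterConfig(nplex = 2),
                 chromLengths = c(chr01 = 8e6), seed = 43)
res
#> QtlSeqResult (donor P2, nplex 2): 11569 variants, 400 windows, 1 candidate region(s)
#> GRanges object with 1 range and 4 metadata columns:
#>       seqnames    ranges strand |   direction   peakP99       donor   plexity
#>          <Rle> <IRanges>  <Rle> | <character> <integer> <character> <integer>
#>   [1]    chr01 1-8000000      * |    negative       179          P2         2
sim$truth$qtl$pos
#> [1] 3999752
```

The planted QTL at 4.0 Mb is recovered as a negative-direction candidate
(the low bulk is depleted of the donor allele, so ΔSNP-index =
low − high < 0 around the locus); its peak window holds 179 P99
QTL-variants, well past the threshold of 100. Running the same data with
`PlexityFilterConfig(nplex = 1)` keeps only variants in the simplex donor
range and finds nothing — the plexity filter, not the test statistic, is
what separates the two QTL classes.

Genotype-validation helpers reproduce the classical dosage workflow:

```r
segregationChiSquare(c(39, 101, 38), c(1, 4, 1))
#> $statistic 7.907  $df 2  $p.value 0.0192  $expected 29.7 118.7 29.7
classifyDosage(c(0.02, 1.0, 1.84), "qpcr")
#> [1] "nulliplex" "simplex"   "duplex"
```

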