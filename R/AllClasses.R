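#' @import methods
#' @importFrom stats rbinom rpois rnorm runif quantile setNames dbinom
#'   chisq.test pchisq median
#' @importFrom utils write.table read.table
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom vcfR read.vcfR getFIX extract.gt
#' @importFrom jsonlite toJSON
NULL

#' Autopolyploid cross specification
#'
#' Describes a biparental cross between a donor parent carrying the
#' alternative allele on \code{donorPlexity} of its \code{ploidy} homologous
#' chromosomes and a second parent that is nulliplex (carries no copy).
#' Random chromosomal (tetrasomic for ploidy 4) segregation is assumed:
#' a gamete receives a uniform random \code{ploidy/2}-subset of homologs,
#' without double reduction.
#'
#' @slot ploidy even integer >= 2: homolog copies per locus (4 for potato).
#' @slot donorPlexity integer in \code{[0, ploidy]}: ALT copies carried by
#'   the donor parent (1 = simplex, 2 = duplex).
#'
#' @examples
#' CrossSpec(ploidy = 4, donorPlexity = 2)
#' @export
setClass("CrossSpec",
  representation(ploidy = "integer", donorPlexity = "integer"),
  prototype(ploidy = 4L, donorPlexity = 1L)
)

setValidity("CrossSpec", function(object) {
  p <- object@ploidy
  m <- object@donorPlexity
  msg <- character()
  if (length(p) != 1L || is.na(p) || p < 2L || p %% 2L != 0L)
    msg <- c(msg, "ploidy must be a single even integer >= 2")
  if (length(m) != 1L || is.na(m) || m < 0L || m > p)
    msg <- c(msg, "donorPlexity must lie in [0, ploidy]")
  if (length(msg)) msg else TRUE
})

#' @rdname CrossSpec-class
#' @param ploidy,donorPlexity see slots.
#' @return A \code{CrossSpec} object.
#' @export
CrossSpec <- function(ploidy = 4L, donorPlexity = 1L) {
  new("CrossSpec", ploidy = as.integer(ploidy),
      donorPlexity = as.integer(donorPlexity))
}

#' @describeIn CrossSpec-class homolog copies per locus.
#' @param object,x a \code{CrossSpec}.
#' @export
setGeneric("ploidy", function(object) standardGeneric("ploidy"))

#' @rdname CrossSpec-class
#' @export
setMethod("ploidy", "CrossSpec", function(object) object@ploidy)

#' @describeIn CrossSpec-class ALT copies in the donor parent.
#' @export
setGeneric("donorPlexity", function(object) standardGeneric("donorPlexity"))

#' @rdname CrossSpec-class
#' @export
setMethod("donorPlexity", "CrossSpec", function(object) object@donorPlexity)

setMethod("show", "CrossSpec", function(object) {
  plex <- c("nulliplex", "simplex", "duplex", "triplex", "quadruplex")
  m <- object@donorPlexity
  lab <- if (m < length(plex)) plex[m + 1L] else paste0(m, "-plex")
  cat("CrossSpec: ploidy ", object@ploidy, ", ", lab,
      " donor x nulliplex\n", sep = "")
})

#' Plexity-selecting variant filter configuration
#'
#' Parameters for selecting donor variants of a target plexity from a
#' four-sample (two parents, two bulks) variant table. A variant is kept
#' when the donor parent's SNP-index falls inside \code{p2IndexRange}
#' (closed interval), the non-donor parent is effectively free of the
#' allele, and all four samples reach \code{minDepth}.
#'
#' Defaults follow the plexity-selecting settings for an autotetraploid:
#' SNP-index range 0.10-0.36 for simplex (\code{nplex = 1}) and 0.37-0.63
#' for duplex (\code{nplex = 2}) donors, with \code{minDepth = 40}; at
#' depths above 40 roughly 95\% of true simplex/duplex variants fall in
#' these ranges (see \code{\link{simulateIndexRangeCoverage}}).
#'
#' @slot nplex target plexity (1 or 2).
#' @slot p2IndexRange closed interval of the donor-parent SNP-index.
#' @slot minDepth minimum total read depth required in all four samples.
#' @slot p1MaxIndex maximum SNP-index tolerated in the non-donor parent.
#' @slot p1MaxAltDepth maximum ALT read count tolerated in the non-donor
#'   parent.
#' @slot maxIndelLength longest In/Del (bp) treated like a SNP.
#'
#' @examples
#' PlexityFilterConfig(nplex = 2)
#' @export
setClass("PlexityFilterConfig",
  representation(nplex = "integer", p2IndexRange = "numeric",
                 minDepth = "integer", p1MaxIndex = "numeric",
                 p1MaxAltDepth = "integer", maxIndelLength = "integer"))

setValidity("PlexityFilterConfig", function(object) {
  r <- object@p2IndexRange
  msg <- character()
  if (!(object@nplex %in% c(1L, 2L)))
    msg <- c(msg, "nplex must be 1 (simplex) or 2 (duplex)")
  if (length(r) != 2L || any(is.na(r)) || r[1] < 0 || r[2] > 1 ||
      r[1] >= r[2])
    msg <- c(msg, "p2IndexRange must satisfy 0 <= low < high <= 1")
  if (object@minDepth < 1L) msg <- c(msg, "minDepth must be >= 1")
  if (object@p1MaxIndex < 0 || object@p1MaxIndex > 1)
    msg <- c(msg, "p1MaxIndex must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname PlexityFilterConfig-class
#' @param nplex,p2IndexRange,minDepth,p1MaxIndex,p1MaxAltDepth,maxIndelLength
#'   see slots; \code{p2IndexRange = NULL} selects the plexity default.
#' @return A \code{PlexityFilterConfig}.
#' @export
PlexityFilterConfig <- function(nplex = 1L, p2IndexRange = NULL,
                                minDepth = 40L, p1MaxIndex = 0.02,
                                p1MaxAltDepth = 1L, maxIndelLength = 70L) {
  nplex <- as.integer(nplex)
  if (is.null(p2IndexRange))
    p2IndexRange <- if (nplex == 2L) c(0.37, 0.63) else c(0.10, 0.36)
  new("PlexityFilterConfig", nplex = nplex,
      p2IndexRange = as.numeric(p2IndexRange), minDepth = as.integer(minDepth),
      p1MaxIndex = as.numeric(p1MaxIndex),
      p1MaxAltDepth = as.integer(p1MaxAltDepth),
      maxIndelLength = as.integer(maxIndelLength))
}

setMethod("show", "PlexityFilterConfig", function(object) {
  cat("PlexityFilterConfig: nplex ", object@nplex,
      ", donor index range [", object@p2IndexRange[1], ", ",
      object@p2IndexRange[2], "], minDepth ", object@minDepth,
      ", non-donor index <= ", object@p1MaxIndex,
      " and ALT depth <= ", object@p1MaxAltDepth, "\n", sep = "")
})

#' Depth-conditional Monte-Carlo null thresholds
#'
#' Empirical two-sided 95\%/99\% confidence bands and the null sample of
#' |Delta(SNP-index)| under the F1 no-QTL hypothesis, simulated per
#' (bulk1 depth, bulk2 depth) bin. Built by
#' \code{\link{buildNullThresholds}}.
#'
#' @slot cross the \code{CrossSpec} of the segregating population.
#' @slot n1,n2 bulk sizes (individuals per bulk).
#' @slot R Monte-Carlo replicates per depth bin.
#' @slot binWidth depth bin width (bp of read depth).
#' @slot bins named list, one element per depth-bin pair, holding the
#'   representative depths, band edges and the sorted |Delta| null sample.
#' @export
setClass("NullThresholds",
  representation(cross = "CrossSpec", n1 = "integer", n2 = "integer",
                 R = "integer", binWidth = "integer", bins = "list"))

setValidity("NullThresholds", function(object) {
  if (object@R < 1000L)
    return("R must be >= 1000 to resolve the 99% band")
  for (b in object@bins) {
    if (!(b$lower95 <= 0 && 0 <= b$upper95))
      return("95% band must contain 0")
    if (b$lower99 > b$lower95 || b$upper99 < b$upper95)
      return("99% band must contain the 95% band")
  }
  TRUE
})

setMethod("show", "NullThresholds", function(object) {
  cat("NullThresholds: ", length(object@bins), " depth bin(s), R = ",
      object@R, ", bulks ", object@n1, "/", object@n2, "\n", sep = "")
  show(object@cross)
  for (nm in names(object@bins)) {
    b <- object@bins[[nm]]
    cat(sprintf("  depth %d/%d: 95%% [%.4f, %.4f]  99%% [%.4f, %.4f]\n",
                b$d1, b$d2, b$lower95, b$upper95, b$lower99, b$upper99))
  }
})

#' Result of one plexity-aware QTL-seq analysis
#'
#' Container returned by \code{\link{runQtlSeq}}: per-variant statistics,
#' sliding-window aggregates and merged candidate regions for one donor
#' orientation.
#'
#' @slot variants data.frame of filtered variants with SNP-indices,
#'   Delta(SNP-index), P values, significance class and direction.
#' @slot windows \code{GRanges} of sliding windows with mean indices, mean
#'   -log10 P and directional P95/P99 variant counts.
#' @slot regions \code{GRanges} of merged candidate regions.
#' @slot donor which parent ("P1" or "P2") was treated as the variant donor.
#' @slot config the \code{PlexityFilterConfig} used.
#' @slot cross the \code{CrossSpec} used.
#' @slot thresholds the \code{NullThresholds} used.
#' @export
setClass("QtlSeqResult",
  representation(variants = "data.frame", windows = "GRanges",
                 regions = "GRanges", donor = "character",
                 config = "PlexityFilterConfig", cross = "CrossSpec",
                 thresholds = "NullThresholds"))

setMethod("show", "QtlSeqResult", function(object) {
  cat("QtlSeqResult (donor ", object@donor, ", nplex ",
      object@config@nplex, "): ", nrow(object@variants),
      " variants, ", length(object@windows), " windows, ",
      length(object@regions), " candidate region(s)\n", sep = "")
  if (length(object@regions)) show(object@regions)
})

#' @describeIn QtlSeqResult-class per-variant statistics table.
#' @param object a \code{QtlSeqResult}.
#' @export
setGeneric("variantStats", function(object) standardGeneric("variantStats"))

#' @rdname QtlSeqResult-class
#' @export
setMethod("variantStats", "QtlSeqResult", function(object) object@variants)

#' @describeIn QtlSeqResult-class sliding-window aggregates.
#' @export
setGeneric("windowStats", function(object) standardGeneric("windowStats"))

#' @rdname QtlSeqResult-class
#' @export
setMethod("windowStats", "QtlSeqResult", function(object) object@windows)

#' @describeIn QtlSeqResult-class merged candidate regions.
#' @export
setGeneric("candidateRegions",
           function(object) standardGeneric("candidateRegions"))

#' @rdname QtlSeqResult-class
#' @export
setMethod("candidateRegions", "QtlSeqResult", function(object) object@regions)
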