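#' Gamete dosage distribution under random chromosomal segregation
#'
#' An autopolyploid gamete receives a uniform random \code{ploidy/2}-subset
#' of the parent's homologs, so the number of ALT copies it carries when the
#' parent is \code{m}-plex is hypergeometric:
#' \deqn{P(j) = \frac{\binom{m}{j}\binom{p-m}{p/2-j}}{\binom{p}{p/2}}.}
#' For a tetraploid this yields the classical 1:1 (simplex) and 1:4:1
#' (duplex) gamete ratios.
#'
#' @param cross a \code{\link{CrossSpec}}.
#' @return Named numeric vector mapping gamete ALT dosage (names "0", "1",
#'   ...) to probability; sums to 1.
#' @examples
#' gameteDosageDistribution(CrossSpec(4, 2))  # 1/6, 4/6, 1/6
#' @export
gameteDosageDistribution <- function(cross) {
  stopifnot(is(cross, "CrossSpec"))
  validObject(cross)
  p <- ploidy(cross)
  m <- donorPlexity(cross)
  k <- p %/% 2L
  j <- 0:min(m, k)
  pr <- choose(m, j) * choose(p - m, k - j) / choose(p, k)
  setNames(pr, as.character(j))
}

#' Progeny dosage distribution for a donor-by-nulliplex cross
#'
#' The nulliplex parent contributes no ALT copies, so progeny dosage equals
#' the donor gamete dosage: 1:1 nulliplex:simplex for a simplex tetraploid
#' donor, 1:4:1 nulliplex:simplex:duplex for a duplex donor.
#'
#' @inheritParams gameteDosageDistribution
#' @return Named numeric vector mapping progeny ALT dosage to probability;
#'   support is within \code{[0, ploidy/2]}.
#' @examples
#' progenyDosageDistribution(CrossSpec(4, 1))  # 0.5, 0.5
#' @export
progenyDosageDistribution <- function(cross) {
  gameteDosageDistribution(cross)
}

#' Expected SNP-index of an unselected progeny bulk
#'
#' With unbiased segregation a bulk of F1 progeny carries on average
#' \code{m/2} ALT copies per individual out of \code{ploidy}, so the pooled
#' ALT read fraction (SNP-index) expected away from any QTL is
#' \code{m / (2 * ploidy)} - 0.125 for a simplex tetraploid donor.
#'
#' @inheritParams gameteDosageDistribution
#' @return Expected bulk SNP-index in \code{[0, 1]}.
#' @examples
#' expectedBulkSnpIndex(CrossSpec(4, 1))  # 0.125
#' @export
expectedBulkSnpIndex <- function(cross) {
  d <- progenyDosageDistribution(cross)
  sum(as.numeric(names(d)) * d) / ploidy(cross)
}

#' Maximal Delta(SNP-index) under complete bulk selection
#'
#' A QTL with complete selection drives one bulk to consist entirely of the
#' highest-dosage progeny class and the other entirely of nulliplex progeny,
#' so |Delta(SNP-index)| cannot exceed (max progeny dosage) / ploidy: 0.25
#' for a simplex tetraploid donor, 0.5 for duplex.
#'
#' @inheritParams gameteDosageDistribution
#' @return Maximal attainable |Delta(SNP-index)|.
#' @examples
#' maxDeltaSnpIndex(CrossSpec(4, 1))  # 0.25
#' @export
maxDeltaSnpIndex <- function(cross) {
  stopifnot(is(cross, "CrossSpec"))
  if (donorPlexity(cross) == 0L)
    stop("donorPlexity = 0: no segregating allele, QTL effect undefined")
  d <- progenyDosageDistribution(cross)
  max(as.numeric(names(d))) / ploidy(cross)
}
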