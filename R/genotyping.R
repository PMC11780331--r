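#' Relative allele dosage from qPCR Ct values
#'
#' Relative quantification against a calibrator that mimics the simplex
#' dosage (an equimolar mix of the two parental DNAs): dosage =
#' 2^(Ct_calibrator - Ct_sample), optionally with reference-amplicon
#' normalisation (delta-delta-Ct) to absorb template-amount differences in
#' crude extracts. A simplex sample therefore scores ~1, a duplex ~2 and a
#' nulliplex ~0.
#'
#' @param ctSample Ct value(s) of the allele-specific amplicon in the
#'   sample(s).
#' @param ctCalibrator Ct of the same amplicon in the simplex-mimicking
#'   calibrator.
#' @param refCtSample,refCtCalibrator optional reference-amplicon Ct values
#'   for normalisation.
#' @return Relative allele dosage (calibrator = 1.0), strictly decreasing
#'   in \code{ctSample}.
#' @examples
#' dosageFromQpcr(25, 25)        # 1
#' dosageFromQpcr(24, 25)        # 2: one cycle earlier = twice the template
#' dosageFromQpcr(30.64, 25)     # ~0.02: nulliplex leakage level
#' @export
dosageFromQpcr <- function(ctSample, ctCalibrator, refCtSample = NULL,
                           refCtCalibrator = NULL) {
  if (is.null(ctCalibrator) || any(is.na(ctCalibrator)))
    stop("calibrator Ct is required")
  stopifnot(all(ctSample > 0), all(ctCalibrator > 0))
  dct <- ctCalibrator - ctSample
  if (!is.null(refCtSample)) {
    if (is.null(refCtCalibrator))
      stop("refCtCalibrator required when refCtSample is given")
    dct <- dct - (refCtCalibrator - refCtSample)
  }
  2^dct
}

#' Default classifier bins for plexity assays
#'
#' The empirically observed measurement intervals separating nulliplex,
#' simplex and duplex F1 subgroups for each assay type: relative allele
#' dosage 0-0.1 / 0.4-1.5 / 1.5-2.2 (qPCR), ALT/REF peak-height ratio
#' 0.05-0.15 / 0.25-0.55 / 0.55-1.15 (fragment analysis), and ALT read
#' fraction 0-0.025 / 0.150-0.375 / 0.375-0.700 (amplicon sequencing).
#' Where adjacent intervals share an endpoint (the simplex/duplex border),
#' the shared value resolves to the higher dosage class.
#'
#' @param assay assay type.
#' @return 3 x 2 numeric matrix (rows nulliplex/simplex/duplex, columns
#'   low/high).
#' @export
defaultDosageBins <- function(assay = c("qpcr", "fragment", "amplicon")) {
  assay <- match.arg(assay)
  b <- switch(assay,
    qpcr = c(0, 0.1, 0.4, 1.5, 1.5, 2.2),
    fragment = c(0.05, 0.15, 0.25, 0.55, 0.55, 1.15),
    amplicon = c(0, 0.025, 0.150, 0.375, 0.375, 0.700))
  matrix(b, nrow = 3, byrow = TRUE,
         dimnames = list(c("nulliplex", "simplex", "duplex"),
                         c("low", "high")))
}

#' Classify a dosage measurement into a plexity class
#'
#' Closed-interval membership in ordered, non-overlapping bins; a value in
#' no bin (an inter-subgroup gap) is "unclassified". When the simplex upper
#' bound equals the duplex lower bound, that boundary value is classified
#' duplex (the border divides the classes, with the upper class closed at
#' it). Classification is monotone: a larger measurement never maps to a
#' lower dosage class.
#'
#' @param values numeric measurement(s).
#' @param assay assay type selecting default bins.
#' @param bins 3 x 2 matrix as from \code{\link{defaultDosageBins}}.
#' @return Character vector: "nulliplex", "simplex", "duplex" or
#'   "unclassified".
#' @examples
#' classifyDosage(c(0.02, 1.0, 1.84), "qpcr")
#' @export
classifyDosage <- function(values, assay = c("qpcr", "fragment", "amplicon"),
                           bins = defaultDosageBins(assay)) {
  assay <- match.arg(assay)
  stopifnot(nrow(bins) == 3, ncol(bins) == 2, all(bins[, 1] <= bins[, 2]),
            all(diff(as.vector(t(bins))) >= 0))
  out <- rep("unclassified", length(values))
  classes <- rownames(bins)
  for (k in 3:1) {   # higher classes claim shared boundaries first
    lo <- bins[k, 1]; hi <- bins[k, 2]
    sharedAbove <- k < 3 && bins[k + 1, 1] == hi
    inBin <- !is.na(values) & values >= lo &
      (if (sharedAbove) values < hi else values <= hi)
    out[inBin & out == "unclassified"] <- classes[k]
  }
  out[is.na(values)] <- NA_character_
  out
}

#' Consensus plexity call across assays for one individual
#'
#' The most frequently suggested genotype wins; an exact tie among the
#' modal classes, or no informative call at all, yields "unresolved".
#' The individual is flagged concordant when all informative (non-missing,
#' classified) calls agree.
#'
#' @param calls character vector of per-assay calls ("nulliplex",
#'   "simplex", "duplex", "unclassified" or NA).
#' @return List: \code{consensus}, \code{concordant}, \code{nInformative}.
#' @examples
#' consensusCall(c("simplex", "simplex", "duplex"))  # simplex, discordant
#' @export
consensusCall <- function(calls) {
  if (length(calls) == 0L) stop("no calls supplied")
  informative <- calls[!is.na(calls) & calls != "unclassified"]
  if (length(informative) == 0L)
    return(list(consensus = "unresolved", concordant = FALSE,
                nInformative = 0L))
  tab <- table(informative)
  top <- names(tab)[tab == max(tab)]
  list(consensus = if (length(top) == 1L) top else "unresolved",
       concordant = length(tab) == 1L,
       nInformative = length(informative))
}

#' Chi-square goodness-of-fit test of a segregation ratio
#'
#' Tests observed genotype-class counts against an expected segregation
#' ratio such as 1:4:1 (duplex x nulliplex tetraploid F1).
#'
#' @param observed integer counts per class, e.g. \code{c(39, 101, 38)} for
#'   nulliplex:simplex:duplex.
#' @param ratio expected ratio weights, e.g. \code{c(1, 4, 1)}.
#' @return List: \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected} counts.
#' @examples
#' segregationChiSquare(c(39, 101, 38), c(1, 4, 1))
#' @export
segregationChiSquare <- function(observed, ratio = c(1, 4, 1)) {
  stopifnot(length(observed) == length(ratio), sum(observed) > 0,
            all(ratio > 0))
  p <- ratio / sum(ratio)
  if (any(sum(observed) * p == 0)) stop("expected count of zero")
  ct <- suppressWarnings(chisq.test(observed, p = p))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = unname(ct$expected))
}

#' Concordance summary over a genotyped population
#'
#' @param concordant logical vector: one flag per individual (from
#'   \code{\link{consensusCall}}).
#' @return List: \code{nConcordant}, \code{nTotal}, \code{percent}
#'   (rounded to the nearest integer).
#' @examples
#' concordanceSummary(rep(c(TRUE, FALSE), c(162, 16)))  # 91%
#' @export
concordanceSummary <- function(concordant) {
  if (length(concordant) == 0L) stop("empty population")
  n <- length(concordant)
  k <- sum(concordant)
  list(nConcordant = k, nTotal = n, percent = round(100 * k / n))
}

#' Genotype a population from one or more assay tables
#'
#' Classifies every measurement column of each assay table with the
#' assay-appropriate bins, then forms per-individual consensus calls.
#'
#' @param assays named list of data.frames; names are assay types
#'   ("qpcr", "fragment", "amplicon"). Each data.frame has a \code{sample}
#'   column plus one or more measurement columns (multi-target assays
#'   contribute one call per target).
#' @param bins optional named list of bin matrices overriding
#'   \code{\link{defaultDosageBins}} per assay type.
#' @return data.frame: sample, per-assay-target calls, \code{consensus},
#'   \code{concordant}.
#' @export
callPopulationDosage <- function(assays, bins = list()) {
  stopifnot(length(assays) >= 1, !is.null(names(assays)))
  samples <- unique(unlist(lapply(assays, function(a) a$sample)))
  callCols <- list()
  for (nm in names(assays)) {
    a <- assays[[nm]]
    b <- if (!is.null(bins[[nm]])) bins[[nm]] else defaultDosageBins(nm)
    for (col in setdiff(names(a), "sample")) {
      calls <- rep(NA_character_, length(samples))
      idx <- match(a$sample, samples)
      calls[idx] <- classifyDosage(a[[col]], nm, b)
      callCols[[paste(nm, col, sep = ".")]] <- calls
    }
  }
  callMat <- do.call(cbind, callCols)
  cons <- apply(callMat, 1L, consensusCall)
  data.frame(sample = samples, callMat,
             consensus = vapply(cons, `[[`, character(1), "consensus"),
             concordant = vapply(cons, `[[`, logical(1), "concordant"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
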