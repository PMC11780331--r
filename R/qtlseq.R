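#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame
NULL

snp_index <- function(ref, alt) {
  tot <- ref + alt
  ifelse(tot > 0, alt / tot, NA_real_)
}

#' Per-sample SNP-index of a variant table
#'
#' SNP-index = ALT depth / total depth for one sample; NA when the sample
#' has no reads at the variant.
#'
#' @param observations variant table with \code{<sample>_ref} and
#'   \code{<sample>_alt} columns.
#' @param sample sample name ("P1", "P2", "Bulk1" or "Bulk2").
#' @return Numeric vector of SNP-indices.
#' @export
snpIndex <- function(observations, sample) {
  snp_index(observations[[paste0(sample, "_ref")]],
            observations[[paste0(sample, "_alt")]])
}

#' Plexity-selecting donor-variant filter
#'
#' Keeps variants whose donor-parent SNP-index lies inside the closed
#' plexity interval (0.10-0.36 simplex, 0.37-0.63 duplex by default), whose
#' non-donor parent is effectively nulliplex (SNP-index and ALT depth below
#' the configured caps), and whose four samples all reach \code{minDepth}
#' total reads.
#'
#' @param observations variant table with per-sample ref/alt depth columns
#'   for P1, P2, Bulk1, Bulk2.
#' @param config a \code{\link{PlexityFilterConfig}}.
#' @param donor which parent donated the variants under analysis.
#' @return The filtered table, with an added \code{plexity} attribute
#'   (\code{config@nplex}) and \code{donor} attribute.
#' @export
filterDonorVariants <- function(observations, config = PlexityFilterConfig(),
                                donor = c("P2", "P1")) {
  donor <- match.arg(donor)
  validObject(config)
  other <- if (donor == "P2") "P1" else "P2"
  need <- as.vector(outer(c("P1", "P2", "Bulk1", "Bulk2"), c("_ref", "_alt"),
                          paste0))
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("missing sample depth columns: ", paste(miss, collapse = ", "))
  depths <- vapply(c("P1", "P2", "Bulk1", "Bulk2"), function(s)
    observations[[paste0(s, "_ref")]] + observations[[paste0(s, "_alt")]],
    numeric(nrow(observations)))
  depths <- matrix(depths, nrow = nrow(observations))
  di <- snpIndex(observations, donor)
  oi <- snpIndex(observations, other)
  keep <- !is.na(di) & !is.na(oi) &
    di >= config@p2IndexRange[1] & di <= config@p2IndexRange[2] &
    oi <= config@p1MaxIndex &
    observations[[paste0(other, "_alt")]] <= config@p1MaxAltDepth &
    rowSums(depths >= config@minDepth) == 4L
  if ("ref" %in% names(observations) && "alt" %in% names(observations)) {
    ilen <- pmax(nchar(observations$ref), nchar(observations$alt)) - 1L
    keep <- keep & ilen <= config@maxIndelLength
  }
  out <- observations[keep, , drop = FALSE]
  attr(out, "plexity") <- config@nplex
  attr(out, "donor") <- donor
  out
}

#' Coverage of a parental SNP-index range at a given depth
#'
#' Probability that the read-sampled SNP-index of a true m-plex parent
#' (ALT read count ~ Binomial(depth, m/ploidy)) falls inside a closed
#' index interval. The exact mode sums the binomial pmf; the Monte-Carlo
#' mode estimates the same fraction from random draws. Used to justify the
#' default filter ranges: at depth 40 the simplex range 0.10-0.36 covers
#' about 94-95\% of true simplex variants, and more at higher depths.
#'
#' @param cross a \code{\link{CrossSpec}} giving ploidy and plexity.
#' @param depth total read depth (>= 1).
#' @param range closed SNP-index interval, low < high.
#' @param method "exact" (binomial pmf sum) or "montecarlo".
#' @param replicates Monte-Carlo draws.
#' @param seed optional integer seed (Monte-Carlo only).
#' @return Coverage fraction in [0, 1].
#' @examples
#' simulateIndexRangeCoverage(CrossSpec(4, 1), depth = 40,
#'                            range = c(0.10, 0.36))
#' @export
simulateIndexRangeCoverage <- function(cross, depth, range = c(0.10, 0.36),
                                       method = c("exact", "montecarlo"),
                                       replicates = 1e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(depth >= 1)
  if (length(range) != 2L || range[1] >= range[2])
    stop("range must be a non-empty interval c(low, high) with low < high")
  p <- donorPlexity(cross) / ploidy(cross)
  depth <- as.integer(depth)
  if (method == "exact") {
    k <- 0:depth
    inside <- k / depth >= range[1] & k / depth <= range[2]
    sum(dbinom(k[inside], depth, p))
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx <- rbinom(replicates, depth, p) / depth
    mean(idx >= range[1] & idx <= range[2])
  }
}

# Band edge for a discrete empirical null: the observed value whose
# inclusive one-sided tail mass is closest to alpha/2 (ties resolved toward
# the more extreme value). Keeps the boundary-inclusive significance rule
# well calibrated despite ties at multiples of 1/depth.
band_edges <- function(delta, alpha) {
  R <- length(delta)
  s <- sort(delta)
  u <- unique(s)
  firstIdx <- match(u, s)                      # ascending first positions
  upMass <- (R - firstIdx + 1) / R             # P(delta >= u), inclusive
  lastIdx <- c(firstIdx[-1] - 1L, R)
  loMass <- lastIdx / R                        # P(delta <= u), inclusive
  a2 <- alpha / 2
  iu <- which.min(abs(upMass - a2) - 1e-15 * seq_along(u))  # prefer larger u
  il <- which.min(abs(loMass - a2) + 1e-15 * seq_along(u))  # prefer smaller u
  c(lower = u[il], upper = u[iu])
}

#' Monte-Carlo F1 null thresholds for Delta(SNP-index)
#'
#' Simulates the no-QTL null: per replicate, each bulk's individuals are
#' independent draws from \code{\link{progenyDosageDistribution}} (no
#' selection), the pooled ALT fraction is dosage sum / (ploidy * bulk
#' size), ALT reads are Binomial(depth, fraction), and Delta = index1 -
#' index2. Replicates are run once per (bulk1, bulk2) depth bin (bin width
#' \code{binWidth}; representative depth = median observed depth in the
#' bin), giving depth-conditional 95\%/99\% two-sided bands and the null
#' sample used for P values.
#'
#' @param cross a \code{\link{CrossSpec}}.
#' @param n1,n2 bulk sizes.
#' @param depthPairs data.frame or matrix with columns \code{d1}, \code{d2}:
#'   the observed bulk total depths of the variants to be tested.
#' @param R replicates per depth bin (>= 1000).
#' @param binWidth depth bin width.
#' @param seed optional integer seed.
#' @return A \code{\link{NullThresholds}} object.
#' @export
buildNullThresholds <- function(cross, n1, n2, depthPairs, R = 1e4,
                                binWidth = 10L, seed = NULL) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (R < 1000) stop("R must be >= 1000 to estimate the 99% band")
  if (!is.null(seed)) set.seed(seed)
  dp <- as.data.frame(depthPairs)
  names(dp)[1:2] <- c("d1", "d2")
  dist <- progenyDosageDistribution(cross)
  support <- as.numeric(names(dist))
  p <- ploidy(cross)
  key <- paste(dp$d1 %/% binWidth, dp$d2 %/% binWidth, sep = ".")
  bins <- list()
  for (k in unique(key)) {
    sel <- key == k
    d1 <- as.integer(round(median(dp$d1[sel])))
    d2 <- as.integer(round(median(dp$d2[sel])))
    f1 <- colSums(matrix(sample(support, n1 * R, TRUE, dist), n1, R)) /
      (p * n1)
    f2 <- colSums(matrix(sample(support, n2 * R, TRUE, dist), n2, R)) /
      (p * n2)
    delta <- rbinom(R, d1, f1) / d1 - rbinom(R, d2, f2) / d2
    b95 <- band_edges(delta, 0.05)
    b99 <- band_edges(delta, 0.01)
    bins[[k]] <- list(d1 = d1, d2 = d2,
                      lower95 = b95[["lower"]], upper95 = b95[["upper"]],
                      lower99 = min(b99[["lower"]], b95[["lower"]]),
                      upper99 = max(b99[["upper"]], b95[["upper"]]),
                      absNull = sort(abs(delta)))
  }
  new("NullThresholds", cross = cross, n1 = as.integer(n1),
      n2 = as.integer(n2), R = as.integer(R),
      binWidth = as.integer(binWidth), bins = bins)
}

#' Per-variant Delta(SNP-index), P value and significance class
#'
#' Delta = SNP-index(Bulk1) - SNP-index(Bulk2). The two-sided P value is
#' the add-one-smoothed null tail fraction (count(|Delta_null| >= |Delta|)
#' + 1) / (R + 1) from the matching depth bin. A variant is classed P99
#' when Delta lies on or outside the 99\% band (boundary counted as
#' significant), else P95 when on or outside the 95\% band, else none.
#' Direction is the sign of Delta (undefined at 0).
#'
#' @param observations filtered variant table with Bulk1/Bulk2 depth
#'   columns.
#' @param thresholds a \code{\link{NullThresholds}} covering the observed
#'   depth bins.
#' @return The table with added columns \code{index_P1}, \code{index_P2},
#'   \code{index_Bulk1}, \code{index_Bulk2}, \code{delta}, \code{pvalue},
#'   \code{class} ("none"/"P95"/"P99") and \code{direction}
#'   ("positive"/"negative"/NA).
#' @export
computeVariantStats <- function(observations, thresholds) {
  o <- observations
  d1 <- o$Bulk1_ref + o$Bulk1_alt
  d2 <- o$Bulk2_ref + o$Bulk2_alt
  if (any(d1 == 0 | d2 == 0)) stop("zero bulk depth: filter on minDepth first")
  for (s in c("P1", "P2", "Bulk1", "Bulk2"))
    o[[paste0("index_", s)]] <- snpIndex(o, s)
  o$delta <- o$index_Bulk1 - o$index_Bulk2
  key <- paste(d1 %/% thresholds@binWidth, d2 %/% thresholds@binWidth,
               sep = ".")
  miss <- setdiff(unique(key), names(thresholds@bins))
  if (length(miss))
    stop("no null thresholds for depth bin(s): ", paste(miss, collapse = ", "))
  R <- thresholds@R
  n <- nrow(o)
  o$pvalue <- rep(NA_real_, n)
  o$class <- rep("none", n)
  for (k in unique(key)) {
    b <- thresholds@bins[[k]]
    sel <- which(key == k)
    absd <- abs(o$delta[sel])
    cnt <- R - findInterval(absd - 1e-9, b$absNull)
    o$pvalue[sel] <- (cnt + 1) / (R + 1)
    cls <- ifelse(o$delta[sel] >= b$upper99 | o$delta[sel] <= b$lower99,
                  "P99",
           ifelse(o$delta[sel] >= b$upper95 | o$delta[sel] <= b$lower95,
                  "P95", "none"))
    o$class[sel] <- cls
  }
  o$direction <- ifelse(o$delta > 0, "positive",
                 ifelse(o$delta < 0, "negative", NA_character_))
  o
}

#' Sliding-window aggregation of variant statistics
#'
#' Tiles each chromosome with windows of \code{windowSize} bp every
#' \code{step} bp (default 100 kb / 20 kb); a variant contributes to every
#' window containing its position. Reports per window the variant count,
#' mean bulk SNP-indices, mean Delta, mean -log10 P, and the directional
#' P95/P99 QTL-variant counts (P95 counts include P99 variants; Delta = 0
#' variants enter no directional count).
#'
#' @param variants output of \code{\link{computeVariantStats}}.
#' @param windowSize,step window size and increment in bp; \code{step}
#'   must not exceed \code{windowSize}.
#' @param chromLengths optional named chromosome lengths; defaults to the
#'   maximum observed variant position per chromosome.
#' @return \code{GRanges} of windows with aggregate metadata columns.
#' @export
slidingWindowStats <- function(variants, windowSize = 1e5, step = 2e4,
                               chromLengths = NULL) {
  if (step > windowSize) stop("step must not exceed windowSize")
  if (is.null(chromLengths)) {
    if (nrow(variants) == 0L) return(GRanges())
    chromLengths <- tapply(variants$pos, variants$chrom, max)
    chromLengths <- setNames(as.numeric(chromLengths), names(chromLengths))
  }
  winChrom <- character(0); winStart0 <- numeric(0); winEnd <- numeric(0)
  for (nm in names(chromLengths)) {
    s0 <- seq(0, max(0, chromLengths[[nm]] - 1), by = step)
    winChrom <- c(winChrom, rep(nm, length(s0)))
    winStart0 <- c(winStart0, s0)
    winEnd <- c(winEnd, pmin(s0 + windowSize, chromLengths[[nm]]))
  }
  win <- GRanges(winChrom, IRanges(start = winStart0 + 1, end = winEnd))
  nw <- length(win)
  agg <- data.frame(nVariants = integer(nw), meanIndexBulk1 = NA_real_,
                    meanIndexBulk2 = NA_real_, meanDelta = NA_real_,
                    meanNegLog10P = NA_real_, nP95pos = 0L, nP95neg = 0L,
                    nP99pos = 0L, nP99neg = 0L)
  if (nrow(variants)) {
    vgr <- GRanges(variants$chrom, IRanges(variants$pos, width = 1))
    ov <- findOverlaps(vgr, win)
    vi <- queryHits(ov); wi <- subjectHits(ov)
    addMean <- function(x) {
      s <- rowsum(x[vi], wi)
      out <- rep(NA_real_, nw)
      out[as.integer(rownames(s))] <- s[, 1]
      out
    }
    cnt <- addMean(rep(1, nrow(variants)))
    cnt[is.na(cnt)] <- 0
    agg$nVariants <- as.integer(cnt)
    nz <- agg$nVariants > 0
    agg$meanIndexBulk1[nz] <- addMean(variants$index_Bulk1)[nz] /
      agg$nVariants[nz]
    agg$meanIndexBulk2[nz] <- addMean(variants$index_Bulk2)[nz] /
      agg$nVariants[nz]
    agg$meanDelta[nz] <- addMean(variants$delta)[nz] / agg$nVariants[nz]
    agg$meanNegLog10P[nz] <- addMean(-log10(variants$pvalue))[nz] /
      agg$nVariants[nz]
    sig95 <- variants$class %in% c("P95", "P99")
    sig99 <- variants$class == "P99"
    pos <- !is.na(variants$direction) & variants$direction == "positive"
    neg <- !is.na(variants$direction) & variants$direction == "negative"
    cnt0 <- function(x) {
      v <- addMean(as.numeric(x)); v[is.na(v)] <- 0; as.integer(v)
    }
    agg$nP95pos <- cnt0(sig95 & pos)
    agg$nP95neg <- cnt0(sig95 & neg)
    agg$nP99pos <- cnt0(sig99 & pos)
    agg$nP99neg <- cnt0(sig99 & neg)
  }
  mcols(win) <- DataFrame(agg)
  win
}

#' Call candidate QTL regions from window statistics
#'
#' A window qualifies when its P99 QTL-variant count strictly exceeds
#' \code{countThreshold} in exactly one direction (asymmetric displacement;
#' windows exceeding the threshold in both directions reflect depth noise,
#' not a QTL). Overlapping or bookended qualifying windows of the same
#' direction merge into one candidate region.
#'
#' @param windows output of \code{\link{slidingWindowStats}}.
#' @param countThreshold directional P99 count that must be exceeded
#'   (default 100).
#' @param donor,plexity labels stored on the output regions.
#' @return \code{GRanges} of merged regions with metadata \code{direction},
#'   \code{peakP99}, \code{donor}, \code{plexity}.
#' @export
callCandidateRegions <- function(windows, countThreshold = 100,
                                 donor = NA_character_,
                                 plexity = NA_integer_) {
  m <- mcols(windows)
  qpos <- m$nP99pos > countThreshold & m$nP99neg <= countThreshold
  qneg <- m$nP99neg > countThreshold & m$nP99pos <= countThreshold
  out <- GRanges()
  for (dir in c("positive", "negative")) {
    q <- if (dir == "positive") qpos else qneg
    if (!any(q)) next
    merged <- reduce(windows[q], min.gapwidth = 1L)
    peak <- vapply(seq_along(merged), function(i) {
      ov <- findOverlaps(windows[q], merged[i])
      cnt <- if (dir == "positive") m$nP99pos[q] else m$nP99neg[q]
      max(cnt[queryHits(ov)])
    }, integer(1))
    mcols(merged) <- DataFrame(direction = dir, peakP99 = peak,
                               donor = donor, plexity = plexity)
    out <- c(out, merged)
  }
  sort(out)
}

#' Run one plexity-aware QTL-seq analysis
#'
#' Full pipeline for one donor orientation: plexity filter, depth-binned
#' Monte-Carlo F1 null thresholds, per-variant Delta(SNP-index) statistics,
#' sliding-window aggregation and candidate-region calling.
#'
#' @param observations four-sample variant table (see
#'   \code{\link{readVariantTable}} / \code{\link{simulateBsaExperiment}}).
#' @param donor parent treated as variant donor ("P2" or "P1").
#' @param config a \code{\link{PlexityFilterConfig}}.
#' @param cross a \code{\link{CrossSpec}}; defaults to a tetraploid with
#'   donor plexity \code{config@nplex}.
#' @param n1,n2 bulk sizes (individuals in Bulk1 / Bulk2).
#' @param R null replicates per depth bin.
#' @param windowSize,step,countThreshold window and candidate parameters.
#' @param chromLengths optional named chromosome lengths for window tiling.
#' @param seed optional integer seed for the null simulation.
#' @return A \code{\link{QtlSeqResult}}.
#' @export
runQtlSeq <- function(observations, donor = "P2",
                      config = PlexityFilterConfig(), cross = NULL,
                      n1 = 18, n2 = 18, R = 1e4, windowSize = 1e5,
                      step = 2e4, countThreshold = 100, chromLengths = NULL,
                      seed = NULL) {
  if (is.null(cross)) cross <- CrossSpec(4L, config@nplex)
  filt <- filterDonorVariants(observations, config, donor)
  if (nrow(filt) == 0L) {
    thr <- new("NullThresholds", cross = cross, n1 = as.integer(n1),
               n2 = as.integer(n2), R = as.integer(R), binWidth = 10L,
               bins = list())
    win <- slidingWindowStats(filt[, c("chrom", "pos"), drop = FALSE],
                              windowSize, step, chromLengths)
    empty <- GRanges()
    mcols(empty) <- DataFrame(direction = character(0),
                              peakP99 = integer(0), donor = character(0),
                              plexity = integer(0))
    return(new("QtlSeqResult", variants = filt, windows = win,
               regions = empty, donor = donor, config = config,
               cross = cross, thresholds = thr))
  }
  dp <- data.frame(d1 = filt$Bulk1_ref + filt$Bulk1_alt,
                   d2 = filt$Bulk2_ref + filt$Bulk2_alt)
  thr <- buildNullThresholds(cross, n1, n2, dp, R = R, seed = seed)
  stats <- computeVariantStats(filt, thr)
  win <- slidingWindowStats(stats, windowSize, step, chromLengths)
  reg <- callCandidateRegions(win, countThreshold, donor = donor,
                              plexity = config@nplex)
  new("QtlSeqResult", variants = stats, windows = win, regions = reg,
      donor = donor, config = config, cross = cross, thresholds = thr)
}

#' Run the analysis in both donor orientations
#'
#' Repeats the full analysis with the parents swapped so QTLs originating
#' from either parent are explored; candidate regions carry the donor
#' label.
#'
#' @inheritParams runQtlSeq
#' @param ... passed to \code{\link{runQtlSeq}}.
#' @return Named list with elements \code{P2} and \code{P1}, each a
#'   \code{\link{QtlSeqResult}}.
#' @export
runBothOrientations <- function(observations, config = PlexityFilterConfig(),
                                ...) {
  list(P2 = runQtlSeq(observations, donor = "P2", config = config, ...),
       P1 = runQtlSeq(observations, donor = "P1", config = config, ...))
}

#' Type-I-error calibration of the F1 null thresholds
#'
#' Simulates independent no-QTL variants: per variant, \code{n} F1 dosages
#' are drawn from the cross's progeny distribution, two disjoint random
#' bulks of \code{bulkSize} are pooled and read-sampled at \code{depth},
#' and the variants are classified against freshly built null thresholds.
#' The fractions classed P95-or-beyond and P99 estimate the realised
#' significance levels (nominal 5\% and 1\%).
#'
#' @param cross a \code{\link{CrossSpec}}.
#' @param n F1 population size.
#' @param bulkSize individuals per bulk.
#' @param depth fixed read depth per bulk.
#' @param nVariants independent null variants to classify.
#' @param R null replicates for the thresholds.
#' @param seed optional integer seed.
#' @return List: \code{fracP95}, \code{fracP99}, \code{stats} (variant
#'   table), \code{thresholds}.
#' @export
nullCalibration <- function(cross = CrossSpec(4, 1), n = 178, bulkSize = 18,
                            depth = 60, nVariants = 5000, R = 1e4,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dist <- progenyDosageDistribution(cross)
  support <- as.numeric(names(dist))
  p <- ploidy(cross)
  dos <- matrix(sample(support, nVariants * n, TRUE, dist), nVariants, n)
  f1 <- rowSums(dos[, seq_len(bulkSize), drop = FALSE]) / (p * bulkSize)
  f2 <- rowSums(dos[, seq.int(n - bulkSize + 1L, n), drop = FALSE]) /
    (p * bulkSize)
  obs <- data.frame(chrom = "chrSim",
                    pos = seq_len(nVariants),
                    Bulk1_alt = rbinom(nVariants, depth, f1),
                    Bulk2_alt = rbinom(nVariants, depth, f2))
  obs$Bulk1_ref <- depth - obs$Bulk1_alt
  obs$Bulk2_ref <- depth - obs$Bulk2_alt
  obs$P1_ref <- depth; obs$P1_alt <- 0L
  obs$P2_ref <- depth; obs$P2_alt <- 0L
  thr <- buildNullThresholds(cross, bulkSize, bulkSize,
                             data.frame(d1 = depth, d2 = depth), R = R)
  stats <- computeVariantStats(obs, thr)
  list(fracP95 = mean(stats$class %in% c("P95", "P99")),
       fracP99 = mean(stats$class == "P99"),
       stats = stats, thresholds = thr)
}
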