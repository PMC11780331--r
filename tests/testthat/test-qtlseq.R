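test_that("the plexity filter applies index ranges, parent purity and minDepth", {
  cfg1 <- PlexityFilterConfig(nplex = 1)
  cfg2 <- PlexityFilterConfig(nplex = 2)
  keep <- obs_row(P1 = c(60, 0), P2 = c(45, 15))          # donor index 0.25
  expect_identical(nrow(filterDonorVariants(keep, cfg1, "P2")), 1L)
  dup <- obs_row(P1 = c(60, 0), P2 = c(30, 30))           # donor index 0.50
  expect_identical(nrow(filterDonorVariants(dup, cfg1, "P2")), 0L)
  expect_identical(nrow(filterDonorVariants(dup, cfg2, "P2")), 1L)
  shallow <- obs_row(P1 = c(39, 0), P2 = c(45, 15))       # one sample at 39
  expect_identical(nrow(filterDonorVariants(shallow, cfg1, "P2")), 0L)
  leaky <- obs_row(P1 = c(58, 2), P2 = c(45, 15))         # non-donor ALT = 2
  expect_identical(nrow(filterDonorVariants(leaky, cfg1, "P2")), 0L)
  # donor swap: same depths judged from the P1 side
  swapped <- obs_row(P1 = c(45, 15), P2 = c(60, 0))
  expect_identical(nrow(filterDonorVariants(swapped, cfg1, "P1")), 1L)
  expect_identical(nrow(filterDonorVariants(swapped, cfg1, "P2")), 0L)
  # long In/Del dropped, short kept
  long <- obs_row(P1 = c(60, 0), P2 = c(45, 15), ref = "A",
                  alt = paste(rep("T", 101), collapse = ""))
  expect_identical(nrow(filterDonorVariants(long, cfg1, "P2")), 0L)
  expect_error(filterDonorVariants(keep[, 1:6], cfg1, "P2"), "missing sample")
})

test_that("index-range coverage matches the exact binomial oracle", {
  cross <- CrossSpec(4, 1)
  # oracle: direct pmf sum over read counts landing inside the range
  oracle <- function(depth, p, lo, hi) {
    k <- 0:depth
    sum(dbinom(k[k / depth >= lo & k / depth <= hi], depth, p))
  }
  for (depth in c(40, 55, 83)) {
    expect_equal(
      simulateIndexRangeCoverage(cross, depth, c(0.10, 0.36)),
      oracle(depth, 0.25, 0.10, 0.36), tolerance = 1e-12)
  }
  # the defaults cover ~94-95% of simplex variants at depth 40
  c40 <- simulateIndexRangeCoverage(cross, 40, c(0.10, 0.36))
  expect_gt(c40, 0.93)
  expect_lt(c40, 0.96)
  # Monte-Carlo mode agrees within 3 SE
  mc <- simulateIndexRangeCoverage(cross, 40, c(0.10, 0.36),
                                   method = "montecarlo",
                                   replicates = 4e4, seed = 1)
  expect_lt(abs(mc - c40), 3 * sqrt(c40 * (1 - c40) / 4e4))
  # concentration and degenerate cases
  expect_gt(simulateIndexRangeCoverage(cross, 1e4, c(0.10, 0.36)), 0.9999)
  expect_equal(simulateIndexRangeCoverage(cross, 40, c(0, 1)), 1,
               tolerance = 1e-9)
  expect_error(simulateIndexRangeCoverage(cross, 40, c(0.4, 0.4)), "interval")
})

test_that("null thresholds behave like a no-QTL Delta(SNP-index) distribution", {
  cross1 <- CrossSpec(4, 1)
  cross2 <- CrossSpec(4, 2)
  dp <- data.frame(d1 = c(40, 400), d2 = c(40, 400))
  thr1 <- buildNullThresholds(cross1, 18, 18, dp, R = 2e4, seed = 5)
  expect_identical(length(thr1@bins), 2L)
  b40 <- thr1@bins[["4.4"]]
  b400 <- thr1@bins[["40.40"]]
  # symmetric bulks: bands roughly symmetric about 0
  expect_lt(abs(b40$upper95 + b40$lower95), 0.03)
  # deeper sequencing narrows the bands
  expect_lt(b400$upper99 - b400$lower99, b40$upper99 - b40$lower99)
  # duplex null is wider than simplex at equal n and depth
  thr2 <- buildNullThresholds(cross2, 18, 18,
                              data.frame(d1 = 40, d2 = 40), R = 2e4,
                              seed = 6)
  expect_gt(thr2@bins[["4.4"]]$upper99, b40$upper99)
  expect_error(buildNullThresholds(cross1, 18, 18, dp, R = 500), ">= 1000")
})

test_that("variant P values agree with exact enumeration of a small null", {
  # exact null of Delta for bulks of 2 at depth 5 (simplex cross)
  cross <- CrossSpec(4, 1)
  dist <- progenyDosageDistribution(cross)
  dosSupport <- as.numeric(names(dist))
  # pooled dosage sum distribution for a bulk of 2
  sum2 <- tapply(as.vector(outer(dist, dist)),
                 outer(dosSupport, dosSupport, "+"), sum)
  fvals <- as.numeric(names(sum2)) / (4 * 2)
  d <- 5L
  idxP <- vapply(0:d, function(k)
    sum(vapply(seq_along(fvals), function(j)
      sum2[[j]] * dbinom(k, d, fvals[j]), numeric(1))), numeric(1))
  deltaP <- outer(idxP, idxP)                      # P(k1, k2)
  deltaV <- outer(0:d, 0:d, "-") / d               # delta values
  exactTail <- function(x)
    sum(deltaP[abs(deltaV) >= x - 1e-12])
  set.seed(7)
  thr <- buildNullThresholds(cross, 2, 2, data.frame(d1 = d, d2 = d),
                             R = 5e4)
  obs <- obs_row(P1 = c(5, 0), P2 = c(4, 1), Bulk1 = c(3, 2),
                 Bulk2 = c(5, 0))
  st <- computeVariantStats(obs, thr)
  pEx <- exactTail(abs(st$delta))
  seP <- sqrt(pEx * (1 - pEx) / 5e4)
  expect_lt(abs(st$pvalue - pEx), 3 * seP + 1 / 5e4)
})

test_that("classification is boundary-inclusive and direction follows the sign", {
  # synthetic null on the depth-60 grid so band edges are exactly attainable
  delta <- rep((-30:30) / 60, each = 33)
  thr <- manual_thresholds(delta)
  b <- thr@bins[[1]]
  expect_identical(b$upper95, 29 / 60)
  expect_identical(b$upper99, 30 / 60)
  at_edge <- obs_row(Bulk1 = c(31, 29), Bulk2 = c(60, 0))  # delta = 29/60
  st <- computeVariantStats(at_edge, thr)
  expect_identical(st$delta, b$upper95)
  expect_identical(st$class, "P95")   # on the 95% edge, inside the 99% band
  mid <- obs_row(Bulk1 = c(50, 10), Bulk2 = c(50, 10))
  stMid <- computeVariantStats(mid, thr)
  expect_identical(stMid$delta, 0)
  expect_identical(stMid$class, "none")
  expect_true(is.na(stMid$direction))
  neg <- computeVariantStats(obs_row(Bulk1 = c(60, 0), Bulk2 = c(30, 30)),
                             thr)
  expect_identical(neg$direction, "negative")
  expect_error(computeVariantStats(obs_row(Bulk1 = c(0, 0)), thr),
               "zero bulk depth")
})

test_that("sliding windows tile correctly and match brute-force recomputation", {
  # single variant at 150 kb touches exactly the windows starting 60-140 kb
  v <- data.frame(chrom = "chrA", pos = 150000L, index_Bulk1 = 0.2,
                  index_Bulk2 = 0.1, delta = 0.1, pvalue = 0.5,
                  class = "none", direction = "positive")
  w <- slidingWindowStats(v, 1e5, 2e4, chromLengths = c(chrA = 1e6))
  hit <- which(S4Vectors::mcols(w)$nVariants == 1)
  expect_identical(length(hit), 5L)
  expect_identical(GenomicRanges::start(w)[hit],
                   as.integer(seq(60000, 140000, 20000)) + 1L)
  # no variants: all windows empty, count = ceiling(len/step)
  w0 <- slidingWindowStats(v[0, ], 1e5, 2e4, chromLengths = c(chrA = 1e6))
  expect_identical(length(w0), as.integer(ceiling(1e6 / 2e4)))
  expect_true(all(S4Vectors::mcols(w0)$nVariants == 0))
  expect_error(slidingWindowStats(v, 1e4, 2e4), "step")

  # brute force on random instances
  set.seed(11)
  for (rep in 1:3) {
    n <- 60
    vv <- data.frame(
      chrom = sample(c("c1", "c2"), n, TRUE),
      pos = sample.int(3e5, n),
      index_Bulk1 = runif(n), index_Bulk2 = runif(n),
      delta = runif(n, -0.3, 0.3), pvalue = runif(n),
      class = sample(c("none", "P95", "P99"), n, TRUE),
      direction = NA_character_)
    vv$direction <- ifelse(vv$delta > 0, "positive",
                    ifelse(vv$delta < 0, "negative", NA))
    lens <- c(c1 = 3e5, c2 = 3e5)
    ws <- slidingWindowStats(vv, 5e4, 1e4, chromLengths = lens)
    m <- S4Vectors::mcols(ws)
    for (i in sample(length(ws), 20)) {
      chr <- as.character(GenomicRanges::seqnames(ws))[i]
      s <- GenomicRanges::start(ws)[i]; e <- GenomicRanges::end(ws)[i]
      inw <- vv$chrom == chr & vv$pos >= s & vv$pos <= e
      expect_identical(m$nVariants[i], sum(inw))
      if (any(inw)) {
        expect_equal(m$meanDelta[i], mean(vv$delta[inw]))
        expect_equal(m$meanNegLog10P[i], mean(-log10(vv$pvalue[inw])))
        expect_identical(m$nP99pos[i],
                         sum(inw & vv$class == "P99" & vv$delta > 0))
        expect_identical(m$nP95neg[i],
                         sum(inw & vv$class %in% c("P95", "P99") &
                               vv$delta < 0))
      }
    }
  }
})

test_that("candidate calling requires asymmetric directional P99 counts", {
  mkwin <- function(p99pos, p99neg, startKb) {
    w <- GenomicRanges::GRanges("chrA",
      IRanges::IRanges(startKb * 1000 + 1, startKb * 1000 + 1e5))
    S4Vectors::mcols(w) <- S4Vectors::DataFrame(
      nVariants = 200L, meanIndexBulk1 = 0.1, meanIndexBulk2 = 0.1,
      meanDelta = 0, meanNegLog10P = 1, nP95pos = p99pos, nP95neg = p99neg,
      nP99pos = p99pos, nP99neg = p99neg)
    w
  }
  expect_identical(length(callCandidateRegions(mkwin(120L, 5L, 0))), 1L)
  expect_identical(
    as.character(S4Vectors::mcols(
      callCandidateRegions(mkwin(120L, 5L, 0)))$direction), "positive")
  expect_identical(length(callCandidateRegions(mkwin(120L, 110L, 0))), 0L)
  expect_identical(length(callCandidateRegions(mkwin(100L, 0L, 0))), 0L)
  # overlapping qualifying windows of one direction merge into one region
  w <- c(mkwin(150L, 2L, 0), mkwin(130L, 1L, 20), mkwin(120L, 0L, 40))
  reg <- callCandidateRegions(w)
  expect_identical(length(reg), 1L)
  expect_identical(GenomicRanges::start(reg), 1L)
  expect_identical(GenomicRanges::end(reg), 140000L)
  expect_identical(S4Vectors::mcols(reg)$peakP99, 150L)
})

test_that("donor-orientation swapping is an involution and no-QTL runs stay quiet", {
  g <- GenomeSpec(c(chrA = 2e6, chrB = 2e6), cmPerMb = 4,
                  variantDensity = 5e-4)
  sim <- simulateBsaExperiment(g, n = 60, bulkSize = 8, qtl = NULL,
                               plexityMix = c(simplex = 1),
                               seed = 81)
  both <- runBothOrientations(sim$observations,
                              config = PlexityFilterConfig(nplex = 1),
                              n1 = 8, n2 = 8, R = 2000,
                              chromLengths = c(chrA = 2e6, chrB = 2e6),
                              seed = 82)
  # all variants were donated by P2: the P1 orientation keeps none
  expect_identical(nrow(variantStats(both$P1)), 0L)
  expect_gt(nrow(variantStats(both$P2)), 0)
  # no QTL was planted: no candidate regions in either orientation
  expect_identical(length(candidateRegions(both$P2)), 0L)
  expect_identical(length(candidateRegions(both$P1)), 0L)
  # relabelling the parents and analysing from the other side is the same
  # analysis: delta, P values and classes are unchanged
  swapped <- sim$observations
  names(swapped) <- sub("^P1_", "tmp_", names(swapped))
  names(swapped) <- sub("^P2_", "P1_", names(swapped))
  names(swapped) <- sub("^tmp_", "P2_", names(swapped))
  res1 <- runQtlSeq(sim$observations, donor = "P2",
                    config = PlexityFilterConfig(nplex = 1), n1 = 8, n2 = 8,
                    R = 2000, chromLengths = c(chrA = 2e6, chrB = 2e6),
                    seed = 99)
  res2 <- runQtlSeq(swapped, donor = "P1",
                    config = PlexityFilterConfig(nplex = 1), n1 = 8, n2 = 8,
                    R = 2000, chromLengths = c(chrA = 2e6, chrB = 2e6),
                    seed = 99)
  for (col in c("pos", "delta", "pvalue", "class", "direction"))
    expect_identical(variantStats(res1)[[col]], variantStats(res2)[[col]])
})

test_that("a no-QTL genome keeps the genome-wide mean Delta(SNP-index) near 0", {
  lens <- setNames(rep(8e5, 8), paste0("chr", 1:8))
  sim <- simulateBsaExperiment(GenomeSpec(lens, 4, 5e-4), n = 178,
                               bulkSize = 18, qtl = NULL,
                               plexityMix = c(simplex = 1), seed = 91)
  res <- runQtlSeq(sim$observations, donor = "P2",
                   config = PlexityFilterConfig(nplex = 1), R = 2000,
                   chromLengths = lens, seed = 92)
  v <- variantStats(res)
  chromMeans <- tapply(v$delta, v$chrom, mean)
  se <- sd(chromMeans) / sqrt(length(chromMeans))
  expect_lt(abs(mean(chromMeans)), 3 * se)
})
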