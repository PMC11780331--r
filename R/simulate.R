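#' Genome specification for the bulked-segregant simulator
#'
#' A deliberately small stand-in for real chromosome coordinates: chromosome
#' lengths, a constant recombination rate and an expected variant density.
#'
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot cmPerMb constant recombination rate (centimorgan per megabase).
#' @slot variantDensity expected segregating variants per bp.
#' @export
setClass("GenomeSpec",
  representation(chromLengths = "numeric", cmPerMb = "numeric",
                 variantDensity = "numeric"))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@chromLengths) < 1L || any(object@chromLengths <= 0) ||
      is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be a named vector of positive lengths")
  if (object@cmPerMb < 0) msg <- c(msg, "cmPerMb must be >= 0")
  if (object@variantDensity <= 0) msg <- c(msg, "variantDensity must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeSpec-class
#' @param chromLengths,cmPerMb,variantDensity see slots.
#' @return A \code{GenomeSpec}.
#' @examples
#' GenomeSpec(c(chr01 = 1e7), cmPerMb = 4, variantDensity = 1e-3)
#' @export
GenomeSpec <- function(chromLengths = c(chr01 = 1e7), cmPerMb = 4,
                       variantDensity = 1e-3) {
  new("GenomeSpec", chromLengths = chromLengths, cmPerMb = cmPerMb,
      variantDensity = variantDensity)
}

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec: ", length(object@chromLengths), " chromosome(s), ",
      sum(object@chromLengths) / 1e6, " Mb total, ", object@cmPerMb,
      " cM/Mb, density ", object@variantDensity, " variants/bp\n", sep = "")
})

#' Read-depth model for pooled sequencing
#'
#' @param meanDepth mean total depth per sample per variant.
#' @param law "fixed" (every variant at \code{meanDepth}) or "poisson"
#'   (depth ~ Poisson(meanDepth)).
#' @param errorRate per-read probability of reading the opposite allele.
#' @return A list of class \code{ReadDepthModel}.
#' @examples
#' ReadDepthModel(60)
#' @export
ReadDepthModel <- function(meanDepth = 60, law = c("fixed", "poisson"),
                           errorRate = 0) {
  law <- match.arg(law)
  stopifnot(meanDepth >= 1, errorRate >= 0, errorRate < 0.5)
  structure(list(meanDepth = meanDepth, law = law, errorRate = errorRate),
            class = "ReadDepthModel")
}

#' QTL model for phenotype simulation
#'
#' @param chrom,pos coordinates of the causal variant (must exist in the
#'   simulated variant list when phenotypes are assigned).
#' @param mode "additive" (effect per ALT copy) or "dominant" (effect per
#'   presence of at least one copy).
#' @param effect phenotype shift per copy / per presence.
#' @param noiseSd standard deviation of Gaussian environmental noise.
#' @param baseline phenotype value of a noise-free nulliplex individual.
#' @return A list of class \code{QtlModel}.
#' @export
QtlModel <- function(chrom, pos, mode = c("additive", "dominant"),
                     effect = 1, noiseSd = 0, baseline = 0) {
  mode <- match.arg(mode)
  stopifnot(noiseSd >= 0)
  structure(list(chrom = chrom, pos = pos, mode = mode, effect = effect,
                 noiseSd = noiseSd, baseline = baseline),
            class = "QtlModel")
}

rand_bases <- function(n) {
  b <- c("A", "C", "G", "T")
  ref <- sample(b, n, replace = TRUE)
  alt <- sample(b, n, replace = TRUE)
  clash <- alt == ref
  while (any(clash)) {
    alt[clash] <- sample(b, sum(clash), replace = TRUE)
    clash <- alt == ref
  }
  list(ref = ref, alt = alt)
}

#' Simulate two autotetraploid parental genomes and their variant list
#'
#' Variants are placed uniformly along each chromosome at the requested
#' density. Each variant is assigned a donor parent and a plexity (1 =
#' simplex, 2 = duplex) and its ALT allele is planted on exactly that many
#' of the donor's \code{ploidy} homologs; the other parent is nulliplex for
#' every variant, mirroring the filtered variant sets used for QTL-seq.
#'
#' @param genome a \code{\link{GenomeSpec}}.
#' @param plexityMix named fractions \code{c(simplex = , duplex = )} of
#'   variants at each plexity (normalised to sum to 1).
#' @param donorWeights named probabilities \code{c(P1 = , P2 = )} that a
#'   variant's donor is P1 vs P2.
#' @param ploidy homolog copies (even, default 4).
#' @param carrierStructure "ibd" (default): per donor and chromosome, all
#'   simplex variants share one carrier homolog and all duplex variants
#'   share one carrier pair, emulating the identity-by-descent origin of
#'   plexity classes (a diverged homolog carries the private simplex
#'   variants; an IBD homolog pair carries the duplex ones). "random":
#'   every variant draws its carrier set independently, which breaks
#'   haplotype structure between neighbouring variants.
#' @param seed optional integer seed.
#' @return A list with \code{variants} (data.frame: chrom, pos, ref, alt,
#'   donor, plexity), \code{hapP1} and \code{hapP2} (logical variant x
#'   homolog carrier matrices), and \code{ploidy}.
#' @examples
#' p <- simulateParents(GenomeSpec(c(chr01 = 1e6)), seed = 1)
#' head(p$variants)
#' @export
simulateParents <- function(genome,
                            plexityMix = c(simplex = 0.8, duplex = 0.2),
                            donorWeights = c(P1 = 0, P2 = 1),
                            ploidy = 4L,
                            carrierStructure = c("ibd", "random"),
                            seed = NULL) {
  carrierStructure <- match.arg(carrierStructure)
  validObject(genome)
  stopifnot(all(plexityMix >= 0), sum(plexityMix) > 0, sum(plexityMix) <= 1,
            ploidy %% 2 == 0)
  if (!is.null(seed)) set.seed(seed)
  chrom <- character(0); pos <- integer(0)
  for (nm in names(genome@chromLengths)) {
    len <- genome@chromLengths[[nm]]
    nv <- rbinom(1L, as.integer(len), genome@variantDensity)
    if (nv > 0) {
      p <- sort(sample.int(as.integer(len), nv))
      chrom <- c(chrom, rep(nm, nv))
      pos <- c(pos, p)
    }
  }
  nvar <- length(pos)
  if (nvar == 0L)
    stop("no variants generated: increase variantDensity or genome size")
  bases <- rand_bases(nvar)
  psim <- if ("simplex" %in% names(plexityMix))
    plexityMix[["simplex"]] / sum(plexityMix) else 0
  plexity <- ifelse(runif(nvar) < psim, 1L, 2L)
  donor <- ifelse(runif(nvar) < donorWeights[["P1"]] / sum(donorWeights),
                  "P1", "P2")
  hapP1 <- matrix(FALSE, nvar, ploidy)
  hapP2 <- matrix(FALSE, nvar, ploidy)
  if (carrierStructure == "ibd") {
    for (d in c("P1", "P2")) {
      for (nm in unique(chrom)) {
        simplexCarrier <- sample.int(ploidy, 1L)
        duplexPair <- sample.int(ploidy, 2L)
        for (m in 1:2) {
          i <- which(donor == d & chrom == nm & plexity == m)
          if (!length(i)) next
          carriers <- if (m == 1L) simplexCarrier else duplexPair
          if (d == "P1") hapP1[i, carriers] <- TRUE
          else hapP2[i, carriers] <- TRUE
        }
      }
    }
  } else {
    for (i in seq_len(nvar)) {
      carriers <- sample.int(ploidy, plexity[i])
      if (donor[i] == "P1") hapP1[i, carriers] <- TRUE
      else hapP2[i, carriers] <- TRUE
    }
  }
  list(variants = data.frame(chrom = chrom, pos = pos, ref = bases$ref,
                             alt = bases$alt, donor = donor,
                             plexity = plexity, stringsAsFactors = FALSE),
       hapP1 = hapP1, hapP2 = hapP2, ploidy = as.integer(ploidy))
}

# Source-homolog indices for the two chromatids of one gamete on one
# chromosome: random bivalent pairing of the 4 homologs, Poisson(Haldane)
# crossovers per bivalent at uniform positions, one chromatid per bivalent.
gamete_sources <- function(pos, lenBp, cmPerMb) {
  perm <- sample.int(4L)
  morgans <- lenBp / 1e6 * cmPerMb / 100
  src <- matrix(0L, length(pos), 2L)
  for (b in 1:2) {
    pair <- perm[c(2L * b - 1L, 2L * b)]
    nco <- rpois(1L, morgans)
    first <- sample.int(2L, 1L)
    if (nco == 0L) {
      src[, b] <- pair[first]
    } else {
      breaks <- sort(runif(nco, 0, lenBp))
      seg <- findInterval(pos, breaks)
      src[, b] <- ifelse(seg %% 2L == 0L, pair[first], pair[3L - first])
    }
  }
  src
}

#' Draw one gamete from a tetraploid parent
#'
#' Per chromosome the four homologs form two random bivalents; each bivalent
#' receives a Poisson number of crossovers (mean = genetic length in
#' Morgans, Haldane model, no interference) at uniform positions, and one
#' recombinant chromatid per bivalent enters the gamete. Double reduction is
#' absent, giving the 1:1 / 1:4:1 gamete ratios of random chromosomal
#' segregation.
#'
#' @param hap logical variant x homolog carrier matrix for the parent.
#' @param variants variant data.frame (chrom, pos) matching \code{hap} rows.
#' @param genome a \code{\link{GenomeSpec}}.
#' @param seed optional integer seed.
#' @return Logical variant x 2 matrix: ALT presence on each gamete
#'   haplotype.
#' @export
makeGamete <- function(hap, variants, genome, seed = NULL) {
  stopifnot(ncol(hap) == 4L, nrow(hap) == nrow(variants))
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(FALSE, nrow(hap), 2L)
  for (nm in unique(variants$chrom)) {
    i <- which(variants$chrom == nm)
    src <- gamete_sources(variants$pos[i], genome@chromLengths[[nm]],
                          genome@cmPerMb)
    out[i, 1L] <- hap[cbind(i, src[, 1L])]
    out[i, 2L] <- hap[cbind(i, src[, 2L])]
  }
  out
}

#' Simulate an F1 population of an autotetraploid biparental cross
#'
#' Each progeny unites one \code{\link{makeGamete}} draw from each parent,
#' so per-variant dosages marginally follow
#' \code{\link{progenyDosageDistribution}} while linked variants stay
#' correlated through shared homolog segments.
#'
#' @param parents output of \code{\link{simulateParents}}.
#' @param genome the \code{\link{GenomeSpec}} used to simulate the parents.
#' @param n population size (>= 1).
#' @param seed optional integer seed.
#' @return Integer variant x individual dosage matrix (ALT copies, 0 to
#'   ploidy/2 per parent side).
#' @export
simulatePopulation <- function(parents, genome, n, seed = NULL) {
  if (n < 1) stop("population size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nvar <- nrow(parents$variants)
  dosage <- matrix(0L, nvar, n)
  for (k in seq_len(n)) {
    g1 <- makeGamete(parents$hapP1, parents$variants, genome)
    g2 <- makeGamete(parents$hapP2, parents$variants, genome)
    dosage[, k] <- as.integer(g1[, 1L]) + as.integer(g1[, 2L]) +
      as.integer(g2[, 1L]) + as.integer(g2[, 2L])
  }
  dosage
}

#' Chroma (C*) from CIE 1976 a* and b*
#'
#' C* = sqrt(a*^2 + b*^2), the colour-saturation index used as the
#' yellow-flesh phenotype.
#'
#' @param aStar,bStar CIE 1976 a* (red-green) and b* (yellow-blue) values.
#' @return Non-negative chroma value(s).
#' @examples
#' chroma(3, 4)  # 5
#' @export
chroma <- function(aStar, bStar) sqrt(aStar^2 + bStar^2)

#' Assign phenotypes from a QTL model
#'
#' Additive mode: baseline + effect * dosage + N(0, sd). Dominant mode:
#' baseline + effect * 1\{dosage >= 1\} + N(0, sd).
#'
#' @param dosage variant x individual dosage matrix.
#' @param variants variant data.frame matching \code{dosage} rows.
#' @param qtl a \code{\link{QtlModel}}.
#' @param seed optional integer seed.
#' @return Numeric phenotype vector, one value per individual.
#' @export
assignPhenotypes <- function(dosage, variants, qtl, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  i <- which(variants$chrom == qtl$chrom & variants$pos == qtl$pos)
  if (length(i) != 1L)
    stop("causal variant ", qtl$chrom, ":", qtl$pos,
         " not found in the variant list")
  d <- dosage[i, ]
  g <- if (qtl$mode == "additive") qtl$effect * d
       else qtl$effect * as.numeric(d >= 1L)
  qtl$baseline + g + rnorm(length(d), 0, qtl$noiseSd)
}

#' Select phenotype-tail bulks
#'
#' Either fixed-size tails (lowest/highest \code{bulkSize} phenotyped
#' individuals) or threshold-based tails (phenotype strictly below
#' \code{thresholds[1]} / strictly above \code{thresholds[2]}). Individuals
#' with missing phenotypes are excluded from both bulks and from the
#' population size used for the reported fractions.
#'
#' @param phenotypes numeric vector, NA = not phenotyped.
#' @param bulkSize individuals per tail (ignored when \code{thresholds}
#'   given).
#' @param thresholds length-2 numeric: low cutoff, high cutoff.
#' @return List: \code{low} and \code{high} index vectors,
#'   \code{percentLow}/\code{percentHigh} (percent of phenotyped
#'   individuals, one decimal), \code{nPhenotyped}.
#' @examples
#' ph <- c(rnorm(150), rep(NA, 19))  # 150 phenotyped of 169 planted
#' selectBulks(ph, bulkSize = 15)
#' @export
selectBulks <- function(phenotypes, bulkSize = NULL, thresholds = NULL) {
  ok <- which(!is.na(phenotypes))
  nPh <- length(ok)
  if (nPh == 0L) stop("no phenotyped individuals")
  if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2L)
    low <- ok[phenotypes[ok] < thresholds[1]]
    high <- ok[phenotypes[ok] > thresholds[2]]
  } else {
    stopifnot(!is.null(bulkSize), bulkSize >= 1, 2 * bulkSize <= nPh)
    ord <- ok[order(phenotypes[ok])]
    low <- sort(ord[seq_len(bulkSize)])
    high <- sort(ord[seq.int(nPh - bulkSize + 1L, nPh)])
  }
  if (length(low) == 0L || length(high) == 0L)
    stop("empty bulk: selection thresholds exclude every individual")
  if (length(intersect(low, high)))
    stop("bulk selection overlaps: thresholds assign individuals to both tails")
  list(low = low, high = high,
       percentLow = round(100 * length(low) / nPh, 1),
       percentHigh = round(100 * length(high) / nPh, 1),
       nPhenotyped = nPh)
}

#' Sample pooled sequencing reads for a bulk or a parent
#'
#' The pooled true ALT fraction of the sampled set is
#' f = (total ALT copies) / (ploidy * set size); with per-read error rate e
#' the ALT read count at depth d is Binomial(d, f(1-e) + (1-f)e),
#' reflecting stochastic reading of homologous chromosomes.
#'
#' @param altCopies variant x individual matrix of ALT copy numbers (for a
#'   parent, a one-column matrix of its plexities).
#' @param depthModel a \code{\link{ReadDepthModel}}.
#' @param ploidy copies per individual per locus.
#' @param seed optional integer seed.
#' @return data.frame with \code{ref} and \code{alt} read counts per
#'   variant.
#' @export
sampleReads <- function(altCopies, depthModel = ReadDepthModel(),
                        ploidy = 4L, seed = NULL) {
  altCopies <- as.matrix(altCopies)
  if (ncol(altCopies) == 0L) stop("empty individual set")
  if (!is.null(seed)) set.seed(seed)
  nvar <- nrow(altCopies)
  f <- rowSums(altCopies) / (ploidy * ncol(altCopies))
  d <- switch(depthModel$law,
              fixed = rep.int(as.integer(round(depthModel$meanDepth)), nvar),
              poisson = rpois(nvar, depthModel$meanDepth))
  e <- depthModel$errorRate
  alt <- rbinom(nvar, d, f * (1 - e) + (1 - f) * e)
  data.frame(ref = d - alt, alt = alt)
}

#' Simulate a complete bulked-segregant experiment
#'
#' End-to-end driver: parents, F1 population, phenotypes, tail bulks and
#' pooled read depths for the four samples (P1, P2, low bulk = Bulk1, high
#' bulk = Bulk2). Defaults emulate the desk-scale study regime: n = 178
#' progeny, tails of 18, fixed depth 60. With \code{qtl = NULL} phenotypes
#' are pure noise (no-QTL dataset).
#'
#' @param genome a \code{\link{GenomeSpec}}.
#' @param n F1 population size.
#' @param bulkSize individuals per tail bulk.
#' @param qtl a \code{\link{QtlModel}}, or a list with elements
#'   \code{nearPos} (approximate position), \code{chrom}, \code{plexity},
#'   \code{mode}, \code{effect}, \code{noiseSd}, \code{baseline} to anchor
#'   the QTL at the nearest simulated variant of that plexity; or NULL.
#' @param plexityMix,donorWeights,ploidy passed to
#'   \code{\link{simulateParents}}.
#' @param depthModel a \code{\link{ReadDepthModel}}.
#' @param seed integer seed governing the whole experiment.
#' @return List: \code{observations} (variant table with per-sample
#'   ref/alt depths), \code{truth} (parents, dosage matrix, phenotypes,
#'   bulks, causal variant row or NULL), \code{genome}, \code{ploidy}.
#' @export
simulateBsaExperiment <- function(genome = GenomeSpec(), n = 178,
                                  bulkSize = 18, qtl = NULL,
                                  plexityMix = c(simplex = 0.8, duplex = 0.2),
                                  donorWeights = c(P1 = 0, P2 = 1),
                                  ploidy = 4L,
                                  depthModel = ReadDepthModel(60),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parents <- simulateParents(genome, plexityMix, donorWeights, ploidy)
  dosage <- simulatePopulation(parents, genome, n)
  v <- parents$variants
  causal <- NULL
  if (!is.null(qtl)) {
    if (!inherits(qtl, "QtlModel")) {
      cand <- which(v$chrom == qtl$chrom & v$plexity == qtl$plexity)
      if (length(cand) == 0L)
        stop("no variant of plexity ", qtl$plexity, " on ", qtl$chrom)
      i <- cand[which.min(abs(v$pos[cand] - qtl$nearPos))]
      qtl <- QtlModel(v$chrom[i], v$pos[i], mode = qtl$mode,
                      effect = qtl$effect, noiseSd = qtl$noiseSd,
                      baseline = if (is.null(qtl$baseline)) 0 else qtl$baseline)
    }
    causal <- which(v$chrom == qtl$chrom & v$pos == qtl$pos)
    phenotypes <- assignPhenotypes(dosage, v, qtl)
  } else {
    phenotypes <- rnorm(n)
  }
  bulks <- selectBulks(phenotypes, bulkSize = bulkSize)
  reads <- list(
    P1 = sampleReads(matrix(rowSums(parents$hapP1), ncol = 1), depthModel,
                     ploidy),
    P2 = sampleReads(matrix(rowSums(parents$hapP2), ncol = 1), depthModel,
                     ploidy),
    Bulk1 = sampleReads(dosage[, bulks$low, drop = FALSE], depthModel,
                        ploidy),
    Bulk2 = sampleReads(dosage[, bulks$high, drop = FALSE], depthModel,
                        ploidy))
  obs <- v
  for (s in names(reads)) {
    obs[[paste0(s, "_ref")]] <- reads[[s]]$ref
    obs[[paste0(s, "_alt")]] <- reads[[s]]$alt
  }
  list(observations = obs,
       truth = list(parents = parents, dosage = dosage,
                    phenotypes = phenotypes, bulks = bulks,
                    qtl = qtl, causal = causal),
       genome = genome, ploidy = as.integer(ploidy))
}

#' Write a simulated experiment as a four-sample VCF
#'
#' Emits a minimal VCF 4.2 file with samples P1, P2, Bulk1, Bulk2 carrying
#' per-sample allele depths in the AD FORMAT field (ref,alt), sorted by
#' chromosome and position. Round-trips losslessly through
#' \code{\link{readVariantTable}}.
#'
#' @param observations variant table as produced by
#'   \code{\link{simulateBsaExperiment}} (columns chrom, pos, ref, alt and
#'   \code{<sample>_ref}/\code{<sample>_alt} depths).
#' @param path output file path.
#' @param contigLengths optional named vector for ##contig header lines.
#' @return Invisibly, \code{path}.
#' @export
writeSimulatedVcf <- function(observations, path, contigLengths = NULL) {
  samples <- c("P1", "P2", "Bulk1", "Bulk2")
  hdr <- c("##fileformat=VCFv4.2", "##source=plexQTLseq-simulator")
  if (!is.null(contigLengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                          as.integer(contigLengths)))
  hdr <- c(hdr,
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  o <- observations[order(observations$chrom, observations$pos), ,
                    drop = FALSE]
  lines <- hdr
  if (nrow(o)) {
    ad <- vapply(samples, function(s)
      paste0(o[[paste0(s, "_ref")]], ",", o[[paste0(s, "_alt")]]),
      character(nrow(o)))
    ad <- matrix(ad, nrow = nrow(o))
    body <- paste(o$chrom, o$pos, ".", o$ref, o$alt, ".", "PASS", ".", "AD",
                  ad[, 1], ad[, 2], ad[, 3], ad[, 4], sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
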