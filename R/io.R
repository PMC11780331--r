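#' Read a four-sample variant table from a VCF
#'
#' Parses a multi-sample VCF with a per-sample allele-depth (AD) FORMAT
#' field into the observation table used by the pipeline. Genotype calls in
#' the VCF are ignored: SNP-indices are always recomputed from depths.
#' Multi-allelic records are skipped (the method needs a single ALT allele
#' per site) and In/Dels longer than \code{maxIndelLength} bp are dropped;
#' SNPs and short In/Dels are treated identically.
#'
#' @param path VCF file (plain or bgzipped).
#' @param roles named character vector mapping the four roles to VCF sample
#'   names, e.g. \code{c(P1 = "BM", P2 = "TY", Bulk1 = "low", Bulk2 =
#'   "high")}. Defaults to samples already named by role.
#' @param maxIndelLength longest In/Del kept (bp).
#' @return data.frame: chrom, pos, ref, alt and \code{<role>_ref} /
#'   \code{<role>_alt} depth columns.
#' @export
readVariantTable <- function(path,
                             roles = c(P1 = "P1", P2 = "P2",
                                       Bulk1 = "Bulk1", Bulk2 = "Bulk2"),
                             maxIndelLength = 70L) {
  need <- c("P1", "P2", "Bulk1", "Bulk2")
  if (!all(need %in% names(roles)))
    stop("roles must name all of: ", paste(need, collapse = ", "))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  vcfSamples <- colnames(vcf@gt)[-1]
  miss <- setdiff(unname(roles[need]), vcfSamples)
  if (length(miss))
    stop("role-mapped sample(s) absent from VCF header: ",
         paste(miss, collapse = ", "))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop("VCF has no AD (allele depth) FORMAT field")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    pmax(nchar(ref), nchar(alt)) - 1L <= maxIndelLength
  out <- data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                    alt = alt[keep], stringsAsFactors = FALSE)
  for (role in need) {
    col <- ad[keep, roles[[role]]]
    parts <- strsplit(col, ",", fixed = TRUE)
    out[[paste0(role, "_ref")]] <-
      vapply(parts, function(x) as.integer(x[1]), integer(1))
    out[[paste0(role, "_alt")]] <-
      vapply(parts, function(x) as.integer(x[2]), integer(1))
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

granges_to_bed <- function(gr, extraCols = character(0)) {
  if (length(gr) == 0L)
    return(character(0))
  m <- mcols(gr)
  cols <- cbind(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  for (cc in extraCols) cols <- cbind(cols, as.character(m[[cc]]))
  apply(cols, 1L, paste, collapse = "\t")
}

#' Write analysis outputs to disk
#'
#' Writes, with deterministic column order: the per-variant statistics TSV,
#' the sliding-window TSV (including the four directional P95/P99 counts),
#' the candidate regions as BED (0-based half-open) and TSV, and a JSON run
#' manifest recording the configuration and seed.
#'
#' @param result a \code{\link{QtlSeqResult}}.
#' @param outdir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param seed seed recorded in the manifest.
#' @return Invisibly, named vector of the written file paths.
#' @export
writeOutputs <- function(result, outdir, prefix = "qtlseq", seed = NA) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  paths <- c(
    variants = file.path(outdir, paste0(prefix, ".variants.tsv")),
    windows = file.path(outdir, paste0(prefix, ".windows.tsv")),
    regionsBed = file.path(outdir, paste0(prefix, ".regions.bed")),
    regionsTsv = file.path(outdir, paste0(prefix, ".regions.tsv")),
    manifest = file.path(outdir, paste0(prefix, ".manifest.json")))
  v <- variantStats(result)
  vcols <- intersect(c("chrom", "pos", "ref", "alt", "index_P1", "index_P2",
                       "index_Bulk1", "index_Bulk2", "delta", "pvalue",
                       "class", "direction"), names(v))
  write.table(v[, vcols, drop = FALSE], paths[["variants"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  w <- windowStats(result)
  wdf <- data.frame(chrom = as.character(seqnames(w)), start = start(w),
                    end = end(w), as.data.frame(mcols(w)))
  write.table(wdf, paths[["windows"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  r <- candidateRegions(result)
  bed <- c("# candidate QTL regions: chrom start0 end direction peakP99",
           granges_to_bed(r, c("direction", "peakP99")))
  writeLines(bed, paths[["regionsBed"]])
  rdf <- data.frame(chrom = as.character(seqnames(r)), start = start(r),
                    end = end(r), as.data.frame(mcols(r)))
  write.table(rdf, paths[["regionsTsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- result@config
  manifest <- list(
    package = "plexQTLseq",
    version = as.character(utils::packageVersion("plexQTLseq")),
    donor = result@donor,
    ploidy = ploidy(result@cross),
    donorPlexity = donorPlexity(result@cross),
    nplex = cfg@nplex,
    p2IndexRange = cfg@p2IndexRange,
    minDepth = cfg@minDepth,
    p1MaxIndex = cfg@p1MaxIndex,
    p1MaxAltDepth = cfg@p1MaxAltDepth,
    maxIndelLength = cfg@maxIndelLength,
    nullReplicates = result@thresholds@R,
    bulkSizes = c(result@thresholds@n1, result@thresholds@n2),
    seed = seed,
    nVariants = nrow(v),
    nWindows = length(w),
    nRegions = length(r))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths[["manifest"]])
  invisible(paths)
}

#' Read a per-assay measurement table
#'
#' Plain TSV with a \code{sample} column and one or more numeric
#' measurement columns (one per assay target).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readAssayTable <- function(path) {
  a <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample" %in% names(a)) stop("assay table needs a 'sample' column")
  a
}
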