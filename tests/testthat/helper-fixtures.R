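# Small in-code fixtures shared across test files.

# One-row observation table with the given per-sample (ref, alt) depths.
obs_row <- function(P1 = c(60, 0), P2 = c(45, 15), Bulk1 = c(50, 10),
                    Bulk2 = c(50, 10), chrom = "chr01", pos = 1000L,
                    ref = "A", alt = "T") {
  d <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  for (s in c("P1", "P2", "Bulk1", "Bulk2")) {
    v <- get(s)
    d[[paste0(s, "_ref")]] <- v[1]
    d[[paste0(s, "_alt")]] <- v[2]
  }
  d
}

# Hand-built NullThresholds with one depth bin and a prescribed null
# sample, for testing classification conventions in isolation.
manual_thresholds <- function(delta, d1 = 60L, d2 = 60L, cross = CrossSpec(4, 1)) {
  R <- length(delta)
  q <- function(p) as.numeric(quantile(delta, p, type = 1))
  new("NullThresholds", cross = cross, n1 = 18L, n2 = 18L, R = as.integer(R),
      binWidth = 10L,
      bins = setNames(list(list(
        d1 = d1, d2 = d2,
        lower95 = q(0.025), upper95 = q(0.975),
        lower99 = q(0.005), upper99 = q(0.995),
        absNull = sort(abs(delta)))),
        paste(d1 %/% 10L, d2 %/% 10L, sep = ".")))
}

# Tiny genome used throughout the simulator tests.
tiny_genome <- function(lengths = c(chrA = 1e6), cmPerMb = 4,
                        density = 2e-4) {
  GenomeSpec(lengths, cmPerMb = cmPerMb, variantDensity = density)
}
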