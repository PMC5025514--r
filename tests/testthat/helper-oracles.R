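# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the code paths they check.

# --- site-call oracle: direct transcription of the calling rules as
# nested conditionals, independent of the vectorised implementation
siteCallOracle <- function(hasVariant, depth, altFrac, covered, platform) {
  minDepth <- if (platform == "LONG_454") 3 else 8
  if (!covered) return("MISSING")
  if (!hasVariant) return("REFERENCE")
  if (depth < minDepth) return("MISSING")
  if (altFrac > 0.8) return("HOM_VARIANT")
  if (altFrac >= 0.2) return("HET")
  "REFERENCE"
}

# --- brute-force probe-match oracle: enumerate every minRun-length
# window of genome and probe as plain strings, intersect, merge intervals
# by hand, count merged loci
.oracleWindows <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character())
  starts <- seq_len(n - w + 1L)
  substring(s, starts, starts + w - 1L)
}

.oracleMerge <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  cnt <- 0L; curEnd <- -Inf
  for (i in seq_along(starts)) {
    if (starts[i] > curEnd + 1) {
      cnt <- cnt + 1L
      curEnd <- ends[i]
    } else curEnd <- max(curEnd, ends[i])
  }
  cnt
}

revcompStr <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

probeMatchOracle <- function(probe, genomes, minRun = 35) {
  pw <- .oracleWindows(probe, minRun)
  total <- 0L
  for (ch in names(genomes)) {
    g <- genomes[[ch]]
    L <- nchar(g)
    gw <- .oracleWindows(g, minRun)
    hitF <- which(gw %in% pw)
    gwR <- .oracleWindows(revcompStr(g), minRun)
    hitRraw <- which(gwR %in% pw)
    # map reverse-strand window start i to forward coordinates
    hitRstart <- L - (hitRraw + minRun - 1L) + 1L
    starts <- c(hitF, hitRstart)
    if (!length(starts)) next
    total <- total + .oracleMerge(starts, starts + minRun - 1L)
  }
  total
}

# --- fixture builders --------------------------------------------------

randomGenomeString <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# one-genotype variant set over a single toy chromosome
toyVariantSet <- function(genotype, platform, chrom, df,
                          covered = NULL, chromLen = NULL) {
  v <- data.frame(chrom = chrom, pos = df$pos, ref = df$ref, alt = df$alt,
                  depth = df$depth, altFrac = df$altFrac)
  cov <- covered %||% GenomicRanges::GRanges(
    chrom, IRanges::IRanges(1, chromLen))
  GenotypeVariantSet(genotype, platform, v, cov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic theta/R cloud sampler for direct cluster-model tests
cloudTheta <- function(means, weights, n, sd, seed) {
  set.seed(seed)
  comp <- sample(seq_along(means), n, replace = TRUE, prob = weights)
  list(theta = pmin(pmax(rnorm(n, means[comp], sd), 0), 1),
       comp = comp,
       R = pmax(rnorm(n, 1, 0.05), 0.1))
}
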