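# Synthetic-data generators. Every generator records ground truth so that
# each downstream stage can be tested for exact recovery without external
# data. All generators are fully deterministic under a fixed seed.

.OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))
.TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSION_OF <- c(A = "T", T = "A", C = "G", G = "C")  # two-bead pairs

#' Simulation configuration
#'
#' Central parameter object consumed by all simulators. Defaults describe
#' a desk-scale allotetraploid design study: two homoeologous subgenomes
#' at 3 % divergence, a 20-genotype resequencing panel, 200-sample
#' intensity panels dominated by genome-specific assays (roughly the 60 %
#' seen on real allotetraploid arrays), and a 124-line doubled-haploid
#' mapping population.
#'
#' @param seed mandatory integer seed; all generators derive their RNG
#'   state from it
#' @param subgenomeChroms chromosomes per subgenome (default 2)
#' @param chromLength chromosome length in bp (default 1e5)
#' @param divergence per-bp substitution rate between homoeologous
#'   subgenomes (default 0.03)
#' @param nGenotypes resequenced genotypes in the variant panel
#' @param nSNP total candidate sites emitted by the variant-panel
#'   simulator (including planted failure modes)
#' @param hetRate within-genotype heterozygous-call rate at clean sites
#' @param missingRate missing-data rate at clean sites
#' @param failFractions named fractions of sites planted to fail each
#'   filter step (`flank`, `multiallele`, `missing`, `het`, `freq`,
#'   `score`, `transversion`)
#' @param platform454Frac fraction of genotypes on the long-read platform
#' @param nIntensitySNPs,nSamples size of the simulated intensity panel
#' @param noiseSd Gaussian theta noise of the intensity clouds
#' @param classMixture named mixing proportions over the six cluster
#'   pattern classes (must sum to 1)
#' @param dhLines doubled-haploid lines (default 124)
#' @param lgLengths named numeric vector of linkage-group lengths in cM
#' @param markersPerLg markers simulated per linkage group
#' @param dhMissingRate missing-call rate in the DH matrix
#' @param kbPerCm physical-to-genetic scale used for anchor positions
#'   (default 400 Kb/cM)
#' @param swapFrac fraction of markers planted at the homoeologous
#'   physical position
#' @param translocation optional list `list(lg=, start=, len=,
#'   destChrom=)` planting a translocated marker block
#' @param plantedRepeats optional list of exact repeats to plant in the
#'   reference, each `list(chrom=, start=, len=, destChrom=, destStart=,
#'   revcomp=FALSE)`
#' @return classed list
#' @export
simConfig <- function(seed,
                      subgenomeChroms = 2, chromLength = 1e5,
                      divergence = 0.03,
                      nGenotypes = 20, nSNP = 1000,
                      hetRate = 0.10, missingRate = 0.05,
                      failFractions = c(flank = 0.06, multiallele = 0.05,
                                        missing = 0.05, het = 0.05,
                                        freq = 0.05, score = 0.05,
                                        transversion = 0.05),
                      platform454Frac = 0.25,
                      nIntensitySNPs = 300, nSamples = 200,
                      noiseSd = 0.03,
                      classMixture = c(GENOME_SPECIFIC = 0.60,
                                       MULTI_CLUSTER_UNRESOLVABLE = 0.10,
                                       SHIFTED = 0.15,
                                       PRESENCE_ABSENCE = 0.05,
                                       MONOMORPHIC = 0.05,
                                       FAILED_LOW_INTENSITY = 0.05),
                      dhLines = 124,
                      lgLengths = c(LG1 = 90, LG2 = 90, LG3 = 90, LG4 = 90),
                      markersPerLg = 50, dhMissingRate = 0.02,
                      kbPerCm = 400, swapFrac = 0.05,
                      translocation = NULL, plantedRepeats = NULL) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(chromLength >= 1000, divergence >= 0, divergence <= 1,
            .isProb(c(hetRate, missingRate, failFractions, noiseSd,
                      swapFrac)),
            abs(sum(classMixture) - 1) < 1e-9,
            noiseSd > 0, all(lgLengths >= 0), markersPerLg >= 2)
  structure(as.list(environment()), class = "SimConfig")
}

.randSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate an allotetraploid reference genome
#'
#' Subgenome A chromosomes are drawn uniformly at random; each subgenome C
#' chromosome is derived from its A homoeolog by independent per-bp
#' substitution at the configured divergence, so homoeologous coordinates
#' are identical and recorded in the truth. Optional exact repeats can be
#' planted to exercise probe-match counting.
#'
#' @param config a [simConfig()]
#' @return list with `reference` ([ReferenceGenome-class]) and `truth`
#'   (homoeolog pairs, per-chromosome substitution positions)
#' @export
simulateAllotetraploid <- function(config) {
  set.seed(config$seed)
  d <- config$divergence
  nC <- config$subgenomeChroms
  len <- config$chromLength
  seqs <- character(0)
  subs <- list()
  for (i in seq_len(nC)) {
    a <- strsplit(.randSeq(len), "")[[1]]
    idx <- which(runif(len) < d)
    c2 <- a
    if (length(idx))
      c2[idx] <- vapply(a[idx], function(b)
        sample(.OTHER_BASES[[b]], 1), character(1))
    nmA <- sprintf("A%02d", i); nmC <- sprintf("C%02d", i)
    seqs[nmA] <- paste(a, collapse = "")
    seqs[nmC] <- paste(c2, collapse = "")
    subs[[nmC]] <- idx
  }
  if (!is.null(config$plantedRepeats)) {
    for (rp in config$plantedRepeats) {
      frag <- substr(seqs[[rp$chrom]], rp$start, rp$start + rp$len - 1)
      if (isTRUE(rp$revcomp))
        frag <- as.character(reverseComplement(DNAString(frag)))
      substr(seqs[[rp$destChrom]], rp$destStart,
             rp$destStart + rp$len - 1) <- frag
    }
  }
  ref <- ReferenceGenome(DNAStringSet(seqs),
                         setNames(substr(names(seqs), 1, 1), names(seqs)))
  homoeologPairs <- data.frame(chromA = sprintf("A%02d", seq_len(nC)),
                               chromC = sprintf("C%02d", seq_len(nC)))
  list(reference = ref,
       truth = list(homoeologPairs = homoeologPairs,
                    substitutions = subs, divergence = d))
}

# deterministic per-class genotype call counts; returns a data.frame of
# per-genotype calls plus the implied panel statistics
.planSiteCalls <- function(class, n, hetRate, missingRate, highFreq) {
  nMiss <- switch(class,
                  missing = ceiling(0.75 * n),
                  round(missingRate * n))
  nObs <- n - nMiss
  nHet <- switch(class,
                 het = ceiling(0.5 * nObs),
                 missing = 0L, freq = 0L, multiallele = 0L,
                 round(hetRate * nObs))
  nHom <- switch(class,
                 freq = if (highFreq) nObs - 1L else 1L,
                 het = max(round(0.5 * nObs - 0.5 * nHet), 0L),
                 multiallele = 0L, # handled by caller (two alt alleles)
                 missing = max(round(0.5 * nObs), 1L),
                 { f <- runif(1, 0.3, 0.7)
                   min(max(round(f * nObs - 0.5 * nHet), 1L), nObs - nHet) })
  list(nMiss = nMiss, nHet = nHet, nHom = nHom, nObs = nObs)
}

#' Simulate a resequencing variant panel with planted filter failures
#'
#' Plants candidate sites across the reference with deterministic
#' per-class genotype-call compositions so that each planted failure mode
#' fails exactly its intended filter step: flank contamination (a victim
#' site with secondary variants planted in both 60-bp flanks; the
#' contaminating sites themselves retain one clean side and are expected
#' survivors), multi-allelic sites, confidence failures (missing data,
#' heterozygote excess, out-of-band allele frequency), low design scores,
#' and two-bead transversion pairs. All remaining sites are clean. The
#' truth table records every emitted site with its expected first-failing
#' step.
#'
#' @param reference a [ReferenceGenome-class]
#' @param config a [simConfig()]
#' @return list with `variantSets` (list of [GenotypeVariantSet-class]),
#'   `designScores` (data.frame `snpId, score`), and `truth` (data.frame
#'   with planted class, expected step and planted panel statistics)
#' @export
simulateVariantPanel <- function(reference, config) {
  set.seed(config$seed + 1L)
  n <- config$nGenotypes
  nSNP <- config$nSNP
  ff <- config$failFractions
  lens <- chromLengths(reference)

  nFlank <- round(ff[["flank"]] * nSNP / 3)  # victims; each unit emits 3
  nMulti <- round(ff[["multiallele"]] * nSNP)
  nMissC <- round(ff[["missing"]] * nSNP)
  nHetC <- round(ff[["het"]] * nSNP)
  nFreq <- round(ff[["freq"]] * nSNP)
  nScore <- round(ff[["score"]] * nSNP)
  nTv <- round(ff[["transversion"]] * nSNP)
  nUnits <- nSNP - 2 * nFlank  # one slot per isolated site or flank unit

  slots <- do.call(rbind, lapply(names(lens), function(ch) {
    p <- seq(151L, lens[[ch]] - 151L, by = 220L)
    if (!length(p)) NULL else data.frame(chrom = ch, pos = p)
  }))
  if (is.null(slots) || nrow(slots) < nUnits)
    stop("requested SNP count exceeds genome capacity")
  slots <- slots[sample(nrow(slots), nUnits), , drop = FALSE]

  classes <- c(rep("flank", nFlank), rep("multiallele", nMulti),
               rep("missing", nMissC), rep("het", nHetC),
               rep("freq", nFreq), rep("score", nScore),
               rep("transversion", nTv))
  if (length(classes) > nUnits)
    stop("failure fractions exceed available sites")
  classes <- c(classes, rep("clean", nUnits - length(classes)))
  classes <- sample(classes)

  platforms <- ifelse(seq_len(n) <= round(config$platform454Frac * n),
                      "LONG_454", "SHORT_ILLUMINA")
  gids <- sprintf("G%02d", seq_len(n))

  baseAt <- function(ch, pos)
    as.character(Biostrings::extractAt(refSequences(reference)[[ch]],
                                       IRanges(pos, width = 1)))

  sites <- NULL     # one row per emitted site
  highFreqToggle <- TRUE
  for (i in seq_len(nUnits)) {
    cls <- classes[i]
    ch <- slots$chrom[i]; p <- slots$pos[i]
    if (cls == "flank") {
      unit <- data.frame(chrom = ch, pos = c(p - 40L, p, p + 45L),
                         class = c("flank_neighbour", "flank",
                                   "flank_neighbour"))
    } else {
      unit <- data.frame(chrom = ch, pos = p, class = cls)
    }
    sites <- rbind(sites, unit)
  }
  sites$ref <- vapply(seq_len(nrow(sites)), function(i)
    baseAt(sites$chrom[i], sites$pos[i]), character(1))
  sites$snpId <- paste(sites$chrom, sites$pos, sep = ":")

  # per-site call plan
  nS <- nrow(sites)
  callM <- matrix("REFERENCE", nS, n, dimnames = list(sites$snpId, gids))
  altM <- matrix(NA_character_, nS, n)
  alt1 <- character(nS); alt2 <- rep(NA_character_, nS)
  plannedFreq <- numeric(nS)
  plannedMiss <- numeric(nS); plannedHet <- numeric(nS)
  for (i in seq_len(nS)) {
    cls <- sites$class[i]
    ref <- sites$ref[i]
    alt1[i] <- if (cls == "transversion") .TRANSVERSION_OF[[ref]]
               else .TRANSITION_OF[[ref]]
    effClass <- switch(cls, flank_neighbour = "clean", flank = "clean", cls)
    plan <- .planSiteCalls(effClass, n, config$hetRate, config$missingRate,
                           highFreqToggle)
    if (effClass == "freq") highFreqToggle <- !highFreqToggle
    perm <- sample(n)
    k <- 0
    if (plan$nMiss) {
      callM[i, perm[k + seq_len(plan$nMiss)]] <- "MISSING"; k <- k + plan$nMiss
    }
    if (effClass == "multiallele") {
      alt2[i] <- setdiff(c("A", "C", "G", "T"), c(ref, alt1[i]))[1]
      n1 <- max(round(0.3 * plan$nObs), 1L)
      n2 <- max(round(0.3 * plan$nObs), 1L)
      callM[i, perm[k + seq_len(n1)]] <- "HOM_VARIANT"
      altM[i, perm[k + seq_len(n1)]] <- alt1[i]; k <- k + n1
      callM[i, perm[k + seq_len(n2)]] <- "HOM_VARIANT"
      altM[i, perm[k + seq_len(n2)]] <- alt2[i]; k <- k + n2
      plannedFreq[i] <- (n1 + n2) / plan$nObs
    } else {
      if (plan$nHet) {
        callM[i, perm[k + seq_len(plan$nHet)]] <- "HET"
        altM[i, perm[k + seq_len(plan$nHet)]] <- alt1[i]; k <- k + plan$nHet
      }
      if (plan$nHom) {
        callM[i, perm[k + seq_len(plan$nHom)]] <- "HOM_VARIANT"
        altM[i, perm[k + seq_len(plan$nHom)]] <- alt1[i]; k <- k + plan$nHom
      }
      plannedFreq[i] <- (plan$nHom + 0.5 * plan$nHet) / plan$nObs
    }
    plannedMiss[i] <- plan$nMiss / n
    plannedHet[i] <- plan$nHet / plan$nObs
  }

  # materialise per-genotype variant sets: missing cells are uncovered
  variantSets <- lapply(seq_len(n), function(j) {
    minDepth <- if (platforms[j] == "LONG_454") 3 else 8
    isVar <- callM[, j] %in% c("HOM_VARIANT", "HET")
    v <- data.frame(chrom = sites$chrom[isVar], pos = sites$pos[isVar],
                    ref = sites$ref[isVar], alt = altM[isVar, j],
                    depth = minDepth + rpois(sum(isVar), 7),
                    altFrac = ifelse(callM[isVar, j] == "HET",
                                     runif(sum(isVar), 0.30, 0.70),
                                     runif(sum(isVar), 0.82, 0.99)))
    missIdx <- which(callM[, j] == "MISSING")
    holes <- GRanges(sites$chrom[missIdx],
                     IRanges(sites$pos[missIdx], width = 1))
    full <- GRanges(names(lens), IRanges(1, unname(lens)))
    cov <- GenomicRanges::setdiff(full, holes)
    GenotypeVariantSet(gids[j], platforms[j], v, cov)
  })

  scores <- data.frame(
    snpId = sites$snpId,
    score = ifelse(sites$class == "score", runif(nS, 0.20, 0.55),
                   runif(nS, 0.70, 0.98)))

  expectedStep <- c(flank = "flanking", flank_neighbour = "pass",
                    multiallele = "multiallelic", missing = "confidence",
                    het = "confidence", freq = "confidence",
                    score = "design_score", transversion = "transversion",
                    clean = "pass")[sites$class]
  truth <- data.frame(snpId = sites$snpId, chrom = sites$chrom,
                      pos = sites$pos, ref = sites$ref, alt1 = alt1,
                      alt2 = alt2, class = sites$class,
                      expectedStep = unname(expectedStep),
                      plannedFreq = plannedFreq,
                      plannedMissingFrac = plannedMiss,
                      plannedHetFrac = plannedHet)
  list(variantSets = variantSets, designScores = scores, truth = truth)
}

# per-class theta/R cloud geometries, one SNP at a time
# cloud weights model a diversity panel of largely homozygous inbred
# lines (small heterozygote cloud), the material cluster files are built
# from; the unresolvable class keeps its diagnostic heterozygote excess
.classGeometry <- list(
  GENOME_SPECIFIC = list(means = c(0.04, 0.50, 0.96),
                         weights = c(0.40, 0.20, 0.40),
                         labels = c("AA", "AB", "BB")),
  MULTI_CLUSTER_UNRESOLVABLE = list(
    means = c(0.04, 0.27, 0.50, 0.73, 0.96),
    weights = c(0.10, 0.20, 0.40, 0.20, 0.10),
    labels = rep(NA_character_, 5)),
  SHIFTED_LOW = list(means = c(0.06, 0.22, 0.38),
                     weights = c(0.40, 0.20, 0.40),
                     labels = c("AA", "AB", "BB")),
  SHIFTED_HIGH = list(means = c(0.62, 0.78, 0.94),
                      weights = c(0.40, 0.20, 0.40),
                      labels = c("AA", "AB", "BB")))

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate two-colour intensity panels for the six cluster patterns
#'
#' For each SNP a pattern class is drawn from the configured mixture and
#' sample points are generated from class-specific theta/R layouts:
#' genome-specific assays span theta with extremes near 0 and 1; shifted
#' assays compress three genotype clouds into one half of theta space
#' (a monomorphic homoeolog co-hybridising); unresolvable assays show
#' four-to-five clusters with inflated heterozygote weight; presence/
#' absence assays separate in R at a single theta position; monomorphic
#' assays form one cloud; failed assays have near-zero intensity
#' throughout. Gaussian theta noise of `config$noiseSd` is applied and
#' values clamped to \[0,1\].
#'
#' @param config a [simConfig()]
#' @param noiseSd optional override of `config$noiseSd`
#' @return list with `intensities` ([IntensityMatrix-class]) and `truth`
#'   (per-SNP class, owner subgenome, per-sample genotype labels)
#' @export
simulateIntensities <- function(config, noiseSd = config$noiseSd) {
  set.seed(config$seed + 2L)
  nSNP <- config$nIntensitySNPs
  nSam <- config$nSamples
  mix <- config$classMixture
  counts <- round(mix * nSNP)
  while (sum(counts) > nSNP) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  while (sum(counts) < nSNP) counts[which.max(mix)] <-
    counts[which.max(mix)] + 1L
  classes <- sample(rep(names(counts), counts))
  snps <- sprintf("SNP%04d", seq_len(nSNP))
  samples <- sprintf("S%03d", seq_len(nSam))

  theta <- matrix(NA_real_, nSNP, nSam, dimnames = list(snps, samples))
  R <- matrix(NA_real_, nSNP, nSam, dimnames = list(snps, samples))
  genos <- matrix(NA_character_, nSNP, nSam, dimnames = list(snps, samples))
  owner <- sample(c("A", "C"), nSNP, replace = TRUE)

  highR <- function(m) pmax(rnorm(m, 1, 0.08), 0.01)
  lowR <- function(m) pmax(rnorm(m, 0.06, 0.02), 0)

  for (i in seq_len(nSNP)) {
    cls <- classes[i]
    if (cls == "FAILED_LOW_INTENSITY") {
      theta[i, ] <- runif(nSam)
      R[i, ] <- lowR(nSam)
    } else if (cls == "MONOMORPHIC") {
      mu <- sample(c(0.04, 0.96), 1)
      theta[i, ] <- .clamp01(rnorm(nSam, mu, noiseSd))
      R[i, ] <- highR(nSam)
      genos[i, ] <- if (mu < 0.5) "AA" else "BB"
    } else if (cls == "PRESENCE_ABSENCE") {
      mu <- sample(c(0.04, 0.96), 1)
      present <- runif(nSam) < 0.6
      theta[i, present] <- .clamp01(rnorm(sum(present), mu, noiseSd))
      theta[i, !present] <- .clamp01(rnorm(sum(!present), 0.5, 0.15))
      R[i, present] <- highR(sum(present))
      R[i, !present] <- lowR(sum(!present))
      pl <- if (mu < 0.5) "AA" else "BB"
      genos[i, ] <- ifelse(present, pl, if (pl == "AA") "BB" else "AA")
    } else {
      geo <- switch(cls,
                    GENOME_SPECIFIC = .classGeometry$GENOME_SPECIFIC,
                    MULTI_CLUSTER_UNRESOLVABLE =
                      .classGeometry$MULTI_CLUSTER_UNRESOLVABLE,
                    SHIFTED = if (runif(1) < 0.5)
                      .classGeometry$SHIFTED_LOW else
                        .classGeometry$SHIFTED_HIGH)
      comp <- sample(seq_along(geo$means), nSam, replace = TRUE,
                     prob = geo$weights)
      theta[i, ] <- .clamp01(rnorm(nSam, geo$means[comp], noiseSd))
      R[i, ] <- highR(nSam)
      genos[i, ] <- geo$labels[comp]
    }
  }
  list(intensities = IntensityMatrix(theta = theta, R = R,
                                     species = rep("NAPUS", nSam)),
       truth = list(classes = setNames(classes, snps),
                    owner = setNames(owner, snps),
                    genotypes = genos))
}

#' Simulate a diploid intensity panel from tetraploid assay truth
#'
#' Re-expresses each simulated tetraploid assay on a diploid ancestral
#' panel: genome-specific assays owned by the other subgenome lose all
#' signal (the probe has no target); shifted and multi-cluster assays
#' resolve to clean full-span clusters in the diploid carrying their
#' polymorphic locus (the co-hybridising homoeolog is absent) and to a
#' monomorphic cloud in the other; presence/absence, monomorphic and
#' failed classes keep their pattern. Truth records the expected
#' per-species scorable and polymorphic status of every SNP.
#'
#' @param truth the `truth` element returned by [simulateIntensities()]
#' @param config a [simConfig()]
#' @param species `"RAPA"` (A subgenome) or `"OLERACEA"` (C subgenome)
#' @param nSamples samples in the diploid panel (default 60)
#' @param noiseSd theta noise (default `config$noiseSd`)
#' @return list with `intensities` and `truth` (`expectedScorable`,
#'   `expectedPolymorphic` per SNP)
#' @export
simulateDiploidIntensities <- function(truth, config, species,
                                       nSamples = 60,
                                       noiseSd = config$noiseSd) {
  set.seed(config$seed + 3L + (species == "OLERACEA"))
  genome <- if (species == "RAPA") "A" else "C"
  snps <- names(truth$classes)
  nSNP <- length(snps)
  samples <- sprintf("D%03d", seq_len(nSamples))
  theta <- matrix(NA_real_, nSNP, nSamples,
                  dimnames = list(snps, samples))
  R <- matrix(NA_real_, nSNP, nSamples, dimnames = list(snps, samples))
  expScor <- logical(nSNP); expPoly <- logical(nSNP)
  highR <- function(m) pmax(rnorm(m, 1, 0.08), 0.01)
  lowR <- function(m) pmax(rnorm(m, 0.06, 0.02), 0)
  gs <- .classGeometry$GENOME_SPECIFIC
  for (i in seq_len(nSNP)) {
    cls <- truth$classes[i]
    own <- truth$owner[i]
    kind <- if (cls == "FAILED_LOW_INTENSITY") "failed"
      else if (cls == "MONOMORPHIC") "mono"
      else if (cls == "PRESENCE_ABSENCE") "pa"
      else if (cls == "GENOME_SPECIFIC" && own != genome) "failed"
      else if (cls == "GENOME_SPECIFIC") "full"
      else if (cls == "MULTI_CLUSTER_UNRESOLVABLE") "full"
      else if (cls == "SHIFTED" && own == genome) "full"
      else "mono"  # shifted assay whose polymorphic locus is elsewhere
    if (kind == "failed") {
      theta[i, ] <- runif(nSamples); R[i, ] <- lowR(nSamples)
      expScor[i] <- FALSE; expPoly[i] <- FALSE
    } else if (kind == "mono") {
      mu <- sample(c(0.04, 0.96), 1)
      theta[i, ] <- .clamp01(rnorm(nSamples, mu, noiseSd))
      R[i, ] <- highR(nSamples)
      expScor[i] <- TRUE; expPoly[i] <- FALSE
    } else if (kind == "pa") {
      mu <- sample(c(0.04, 0.96), 1)
      present <- runif(nSamples) < 0.6
      theta[i, present] <- .clamp01(rnorm(sum(present), mu, noiseSd))
      theta[i, !present] <- .clamp01(rnorm(sum(!present), 0.5, 0.15))
      R[i, present] <- highR(sum(present))
      R[i, !present] <- lowR(sum(!present))
      expScor[i] <- TRUE; expPoly[i] <- TRUE
    } else { # full-span diploid clusters
      comp <- sample(1:3, nSamples, replace = TRUE, prob = gs$weights)
      theta[i, ] <- .clamp01(rnorm(nSamples, gs$means[comp], noiseSd))
      R[i, ] <- highR(nSamples)
      expScor[i] <- TRUE; expPoly[i] <- TRUE
    }
  }
  list(intensities = IntensityMatrix(theta = theta, R = R,
                                     species = rep(species, nSamples)),
       truth = list(expectedScorable = setNames(expScor, snps),
                    expectedPolymorphic = setNames(expPoly, snps)))
}

#' Simulate a doubled-haploid mapping population with anchor truth
#'
#' Crossovers are placed per line independently in each marker interval
#' (no interference) with recombination fractions obtained by inverting
#' the Kosambi distance of the true map. Missing calls are masked at the
#' configured rate. Physical anchors follow the genetic order at the
#' configured Kb/cM scale; a configured fraction of markers is planted at
#' the homoeologous chromosome, and an optional translocated block is
#' anchored to a foreign chromosome.
#'
#' @param config a [simConfig()]
#' @return list with `geno` (lines x markers matrix), `map` (true marker
#'   order and cM positions), `anchors` (data.frame `marker, chrom, bp,
#'   identity`), `lgChrom`, `homoeology`, and `truth` (crossover matrix
#'   per LG, swapped markers, translocated block)
#' @export
simulateDH <- function(config) {
  set.seed(config$seed + 7L)
  nL <- config$dhLines
  lgs <- names(config$lgLengths)
  m <- config$markersPerLg
  nLg <- length(lgs)
  half <- ceiling(nLg / 2)
  lgChrom <- data.frame(
    lg = lgs,
    chrom = c(sprintf("A%02d", seq_len(half)),
              sprintf("C%02d", seq_len(nLg - half))))
  homoeology <- data.frame(chromA = sprintf("A%02d", seq_len(half)),
                           chromC = sprintf("C%02d", seq_len(half)))

  geno <- NULL; map <- NULL; anchors <- NULL
  crossovers <- list()
  for (li in seq_along(lgs)) {
    lg <- lgs[li]
    cm <- sort(runif(m, 0, config$lgLengths[[lg]]))
    cm[1] <- 0
    markers <- sprintf("%s_M%03d", lg, seq_len(m))
    r <- kosambiInverse(diff(cm))
    g <- matrix(NA_character_, nL, m, dimnames = list(NULL, markers))
    g[, 1] <- sample(c("A", "B"), nL, replace = TRUE)
    xo <- matrix(FALSE, nL, m - 1)
    for (j in 2:m) {
      flip <- runif(nL) < r[j - 1]
      xo[, j - 1] <- flip
      g[, j] <- ifelse(flip, ifelse(g[, j - 1] == "A", "B", "A"),
                       g[, j - 1])
    }
    if (config$dhMissingRate > 0) {
      mask <- matrix(runif(nL * m) < config$dhMissingRate, nL, m)
      g[mask] <- NA_character_
    }
    crossovers[[lg]] <- xo
    geno <- cbind(geno, g)
    map <- rbind(map, data.frame(marker = markers, lg = lg, cM = cm))
    bp <- round(cm * config$kbPerCm * 1000) +
      round(runif(m, 0, config$kbPerCm * 100))
    anchors <- rbind(anchors, data.frame(
      marker = markers, chrom = lgChrom$chrom[li], bp = bp,
      identity = runif(m, 90, 100)))
  }

  truth <- list(crossovers = crossovers, swapped = character(),
                block = NULL)
  total <- nrow(map)
  blockMarkers <- character()
  if (!is.null(config$translocation)) {
    tl <- config$translocation
    idx <- which(map$lg == tl$lg)[tl$start:(tl$start + tl$len - 1)]
    blockMarkers <- map$marker[idx]
    anchors$chrom[anchors$marker %in% blockMarkers] <- tl$destChrom
    anchors$bp[anchors$marker %in% blockMarkers] <-
      5e5 + seq(0, 5e5, length.out = length(blockMarkers))
    truth$block <- data.frame(lg = tl$lg, destChrom = tl$destChrom,
                              startMarker = blockMarkers[1],
                              endMarker = blockMarkers[length(blockMarkers)])
  }
  nSwap <- round(config$swapFrac * total)
  if (nSwap > 0) {
    eligible <- setdiff(map$marker, blockMarkers)
    sw <- sample(eligible, nSwap)
    i <- match(sw, anchors$marker)
    anchors$chrom[i] <- homoeologOf(anchors$chrom[i], homoeology)
    truth$swapped <- sw
  }
  list(geno = geno, map = map, anchors = anchors, lgChrom = lgChrom,
       homoeology = homoeology, truth = truth)
}
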