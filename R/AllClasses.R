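#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement DNAString alphabetFrequency matchPDict PDict
#' @importFrom IRanges IRanges reduce start end width findOverlaps
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   "rowData<-" colData rowRanges assayNames
#' @importFrom stats dnorm rpois runif rnorm sd median quantile setNames
#' @importFrom utils read.table write.table head modifyList
NULL

# ---------------------------------------------------------------------------
# ReferenceGenome: chromosome sequences plus a subgenome tag per chromosome.
# In an allotetraploid the tag distinguishes the two ancestral subgenomes
# (e.g. "A"/"C"); probes and anchors are interpreted against it.

#' Reference genome with subgenome tags
#'
#' Holds chromosome sequences of a (possibly allopolyploid) reference as a
#' [Biostrings::DNAStringSet] together with a subgenome tag per chromosome.
#' The alphabet is restricted to A/C/G/T/N and chromosome names must be
#' unique.
#'
#' @slot sequences [Biostrings::DNAStringSet] of chromosome sequences
#' @slot subgenome named character vector, one tag per chromosome
#' @export
setClass("ReferenceGenome",
  representation(sequences = "DNAStringSet", subgenome = "character"))

setValidity("ReferenceGenome", function(object) {
  msg <- NULL
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "chromosome names must be present and unique")
  if (!identical(sort(names(object@subgenome)), sort(nm %||% character())))
    msg <- c(msg, "subgenome tags must be named by chromosome")
  af <- Biostrings::alphabetFrequency(object@sequences)
  allowed <- c("A", "C", "G", "T", "N")
  if (length(object@sequences) &&
      any(rowSums(af[, !colnames(af) %in% allowed, drop = FALSE]) > 0))
    msg <- c(msg, "sequence alphabet restricted to A/C/G/T/N")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ReferenceGenome
#'
#' @param sequences [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences
#' @param subgenome named character vector of subgenome tags; defaults to
#'   the first character of each chromosome name
#' @return a [ReferenceGenome-class] object
#' @export
#' @examples
#' ReferenceGenome(c(A01 = "ACGTACGTNN", C01 = "TTGCAACGGT"))
ReferenceGenome <- function(sequences, subgenome = NULL) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (is.null(subgenome))
    subgenome <- setNames(substr(names(sequences), 1L, 1L), names(sequences))
  new("ReferenceGenome", sequences = sequences,
      subgenome = subgenome[names(sequences)])
}

#' @describeIn ReferenceGenome chromosome sequences
#' @param x a ReferenceGenome
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname ReferenceGenome
#' @export
setMethod("refSequences", "ReferenceGenome", function(x) x@sequences)

#' @describeIn ReferenceGenome subgenome tag per chromosome
#' @export
setGeneric("subgenomeTags", function(x) standardGeneric("subgenomeTags"))

#' @rdname ReferenceGenome
#' @export
setMethod("subgenomeTags", "ReferenceGenome", function(x) x@subgenome)

#' @describeIn ReferenceGenome chromosome lengths in bp
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname ReferenceGenome
#' @export
setMethod("chromLengths", "ReferenceGenome",
          function(x) setNames(width(x@sequences), names(x@sequences)))

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome with", length(object@sequences), "chromosomes,",
      sum(width(object@sequences)), "bp total\n")
  cat("  subgenomes:", paste(unique(object@subgenome), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# GenotypeVariantSet: one genotype's variant calls plus covered intervals.

#' Per-genotype variant calls with coverage
#'
#' Variant records (1-based positions, single-nucleotide) and the covered
#' intervals for one sequenced genotype, tagged with the sequencing platform
#' that determines the minimum calling depth.
#'
#' @slot genotype genotype identifier
#' @slot platform one of `"LONG_454"`, `"SHORT_ILLUMINA"`
#' @slot variants data.frame with columns chrom, pos, ref, alt, depth,
#'   altFrac
#' @slot coverage [GenomicRanges::GRanges] of covered intervals (1-based,
#'   closed; normalised to non-overlapping)
#' @export
setClass("GenotypeVariantSet",
  representation(genotype = "character", platform = "character",
                 variants = "data.frame", coverage = "GRanges"))

setValidity("GenotypeVariantSet", function(object) {
  msg <- NULL
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "depth", "altFrac")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variants need columns:", paste(need, collapse = ", ")))
  else {
    if (any(v$depth < 0, na.rm = TRUE)) msg <- c(msg, "depths must be >= 0")
    if (nrow(v) && !.isProb(v$altFrac))
      msg <- c(msg, "altFrac must lie in [0,1]")
  }
  if (!object@platform %in% c("LONG_454", "SHORT_ILLUMINA"))
    msg <- c(msg, "unknown platform tag")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeVariantSet
#'
#' @param genotype genotype id
#' @param platform `"LONG_454"` or `"SHORT_ILLUMINA"`
#' @param variants data.frame (chrom, pos, ref, alt, depth, altFrac)
#' @param coverage GRanges of covered intervals; overlapping intervals are
#'   merged
#' @return a [GenotypeVariantSet-class]
#' @export
GenotypeVariantSet <- function(genotype, platform, variants, coverage) {
  new("GenotypeVariantSet", genotype = genotype, platform = platform,
      variants = variants, coverage = GenomicRanges::reduce(coverage))
}

setMethod("show", "GenotypeVariantSet", function(object) {
  cat("GenotypeVariantSet", object@genotype, "(", object@platform, "):",
      nrow(object@variants), "variants,",
      length(object@coverage), "covered intervals\n")
})

# ---------------------------------------------------------------------------
# SNPSummaryMatrix: sites x genotypes cross-panel call matrix.

#' Cross-panel SNP summary matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one row per
#' candidate site and one column per genotype. Assays: `call` (character:
#' MISSING/REFERENCE/HOM_VARIANT/HET), `alt` (the alternate allele behind a
#' variant cell), `depth` and `altFrac`. Row metadata carries the reference
#' allele, the set of observed alternate alleles, a reference-mismatch flag
#' and the panel statistics (`missingFrac`, `hetFrac`, `altFreq`) used by
#' the confidence filter.
#'
#' @export
setClass("SNPSummaryMatrix", contains = "RangedSummarizedExperiment")

setValidity("SNPSummaryMatrix", function(object) {
  msg <- NULL
  if (!all(c("call", "alt", "depth", "altFrac") %in% assayNames(object)))
    msg <- c(msg, "assays call/alt/depth/altFrac required")
  rd <- rowData(object)
  need <- c("ref", "alts", "refMismatch", "missingFrac", "hetFrac", "altFreq")
  if (!all(need %in% names(rd)))
    msg <- c(msg, paste("rowData needs:", paste(need, collapse = ", ")))
  else if (nrow(object)) {
    if (!.isProb(rd$missingFrac) || !.isProb(rd$hetFrac))
      msg <- c(msg, "panel fractions must lie in [0,1]")
    f <- rd$altFreq[!is.na(rd$altFreq)]
    if (length(f) && (any(f < 0) || any(f > 1)))
      msg <- c(msg, "altFreq must lie in [0,1] or be NA")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SNPSummaryMatrix the character call matrix
#' @param x a SNPSummaryMatrix
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))

#' @rdname SNPSummaryMatrix
#' @export
setMethod("callMatrix", "SNPSummaryMatrix", function(x) assay(x, "call"))

#' @describeIn SNPSummaryMatrix per-site panel statistics as a data.frame
#' @export
setGeneric("siteStats", function(x) standardGeneric("siteStats"))

#' @rdname SNPSummaryMatrix
#' @export
setMethod("siteStats", "SNPSummaryMatrix", function(x) {
  rd <- rowData(x)
  data.frame(snpId = rownames(x),
             chrom = as.character(seqnames(rowRanges(x))),
             pos = start(rowRanges(x)),
             ref = rd$ref, alts = rd$alts, refMismatch = rd$refMismatch,
             missingFrac = rd$missingFrac, hetFrac = rd$hetFrac,
             altFreq = rd$altFreq, row.names = NULL)
})

setMethod("show", "SNPSummaryMatrix", function(object) {
  cat("SNPSummaryMatrix:", nrow(object), "candidate sites x",
      ncol(object), "genotypes\n")
  if (nrow(object))
    cat("  median missingFrac",
        roundHalfUp(median(rowData(object)$missingFrac), 3),
        "| median altFreq",
        roundHalfUp(median(rowData(object)$altFreq, na.rm = TRUE), 3), "\n")
})

# ---------------------------------------------------------------------------
# IntensityMatrix: two-colour signal per SNP per sample in theta/R space.

#' Two-colour intensity matrix in theta/R space
#'
#' Per-SNP, per-sample polar-normalised signal: `theta` in \[0,1\] (0 = pure
#' allele-A signal) and total intensity `R >= 0`. Cells where both raw
#' channels were zero are NA ("no signal"). Each sample carries a species
#' tag used when deriving diploid cluster files.
#'
#' @slot theta numeric matrix (SNPs x samples)
#' @slot totalR numeric matrix (SNPs x samples)
#' @slot species named character vector per sample
#'   (`"NAPUS"`, `"OLERACEA"`, `"RAPA"`)
#' @export
setClass("IntensityMatrix",
  representation(theta = "matrix", totalR = "matrix", species = "character"))

setValidity("IntensityMatrix", function(object) {
  msg <- NULL
  if (!identical(dim(object@theta), dim(object@totalR)))
    msg <- c(msg, "theta and R dimensions differ")
  th <- object@theta[!is.na(object@theta)]
  if (length(th) && (any(th < 0) || any(th > 1)))
    msg <- c(msg, "theta must lie in [0,1]")
  rr <- object@totalR[!is.na(object@totalR)]
  if (length(rr) && any(rr < 0)) msg <- c(msg, "R must be >= 0")
  if (length(object@species) != ncol(object@theta))
    msg <- c(msg, "one species tag per sample required")
  if (is.null(msg)) TRUE else msg
})

#' Construct an IntensityMatrix
#'
#' Either supply `theta`/`R` directly, or raw channels `X`/`Y` which are
#' polar-normalised via [normalizeIntensity()].
#'
#' @param theta,R numeric SNP x sample matrices (normalised space)
#' @param X,Y numeric SNP x sample matrices (raw channels)
#' @param species character vector of per-sample species tags; defaults to
#'   `"NAPUS"`
#' @return an [IntensityMatrix-class]
#' @export
IntensityMatrix <- function(theta = NULL, R = NULL, X = NULL, Y = NULL,
                            species = NULL) {
  if (is.null(theta)) {
    stopifnot(!is.null(X), !is.null(Y))
    nz <- normalizeIntensity(X, Y)
    theta <- matrix(nz$theta, nrow(X), ncol(X), dimnames = dimnames(X))
    R <- matrix(nz$R, nrow(X), ncol(X), dimnames = dimnames(X))
  }
  if (is.null(species)) species <- rep("NAPUS", ncol(theta))
  if (is.null(names(species)) && !is.null(colnames(theta)))
    names(species) <- colnames(theta)
  new("IntensityMatrix", theta = theta, totalR = R, species = species)
}

#' @describeIn IntensityMatrix theta matrix
#' @param x an IntensityMatrix
#' @export
setGeneric("thetaValues", function(x) standardGeneric("thetaValues"))

#' @rdname IntensityMatrix
#' @export
setMethod("thetaValues", "IntensityMatrix", function(x) x@theta)

#' @describeIn IntensityMatrix total-intensity matrix
#' @export
setGeneric("signalR", function(x) standardGeneric("signalR"))

#' @rdname IntensityMatrix
#' @export
setMethod("signalR", "IntensityMatrix", function(x) x@totalR)

#' @describeIn IntensityMatrix per-sample species tags
#' @export
setGeneric("sampleSpecies", function(x) standardGeneric("sampleSpecies"))

#' @rdname IntensityMatrix
#' @export
setMethod("sampleSpecies", "IntensityMatrix", function(x) x@species)

setMethod("show", "IntensityMatrix", function(object) {
  cat("IntensityMatrix:", nrow(object@theta), "SNPs x",
      ncol(object@theta), "samples;", "species:",
      paste(names(table(object@species)), table(object@species),
            collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# ClusterModel: fitted per-SNP mixture in theta space with pattern label.

#' Per-SNP genotype cluster model
#'
#' A one-dimensional Gaussian mixture over theta describing the genotype
#' clouds of one SNP assay, with empirical R statistics per component, a
#' component-to-genotype label map, the cluster-pattern classification and
#' the per-sample component assignments.
#'
#' Patterns: `GENOME_SPECIFIC` (three clean clusters spanning theta),
#' `SHIFTED` / `SHIFTED_RESCUED` (homoeolog-compressed clusters in one half
#' of theta space, before/after relabelling), `MULTI_CLUSTER_UNRESOLVABLE`
#' (both homoeologous loci segregating), `PRESENCE_ABSENCE` (one allele
#' yields no fluorescence; clusters separate in R), `MONOMORPHIC`,
#' `FAILED_LOW_INTENSITY`.
#'
#' @slot snpId SNP identifier
#' @slot K number of mixture components
#' @slot thetaMeans,thetaSds,rMeans,rSds,weights per-component parameters
#' @slot labels per-component genotype label (`AA`/`AB`/`BB`/`none`)
#' @slot pattern pattern label (see Details)
#' @slot scorable whether genotypes can be called from this model
#' @slot polymorphic whether more than one genotype class is expected
#' @slot assignments integer component index per sample (0 = no signal)
#' @export
setClass("ClusterModel",
  representation(snpId = "character", K = "integer",
                 thetaMeans = "numeric", thetaSds = "numeric",
                 rMeans = "numeric", rSds = "numeric", weights = "numeric",
                 labels = "character", pattern = "character",
                 scorable = "logical", polymorphic = "logical",
                 assignments = "integer"))

.PATTERNS <- c("GENOME_SPECIFIC", "SHIFTED", "SHIFTED_RESCUED",
               "MULTI_CLUSTER_UNRESOLVABLE", "PRESENCE_ABSENCE",
               "MONOMORPHIC", "FAILED_LOW_INTENSITY")

setValidity("ClusterModel", function(object) {
  msg <- NULL
  K <- object@K
  if (K > 0 && abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "component weights must sum to 1")
  lab <- object@labels[object@labels != "none"]
  if (anyDuplicated(lab))
    msg <- c(msg, "labelled components must carry distinct labels")
  if (!object@pattern %in% .PATTERNS)
    msg <- c(msg, "unknown pattern label")
  if (object@scorable &&
      object@pattern %in% c("MULTI_CLUSTER_UNRESOLVABLE",
                            "FAILED_LOW_INTENSITY"))
    msg <- c(msg, "unresolvable/failed SNPs cannot be scorable")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ClusterModel pattern label
#' @param x a ClusterModel
#' @export
setGeneric("clusterPattern", function(x) standardGeneric("clusterPattern"))

#' @rdname ClusterModel
#' @export
setMethod("clusterPattern", "ClusterModel", function(x) x@pattern)

#' @describeIn ClusterModel can genotypes be called from this model?
#' @export
setGeneric("isScorable", function(x) standardGeneric("isScorable"))

#' @rdname ClusterModel
#' @export
setMethod("isScorable", "ClusterModel", function(x) x@scorable)

#' @describeIn ClusterModel is more than one genotype class expected?
#' @export
setGeneric("isPolymorphic", function(x) standardGeneric("isPolymorphic"))

#' @rdname ClusterModel
#' @export
setMethod("isPolymorphic", "ClusterModel", function(x) x@polymorphic)

#' @describeIn ClusterModel per-component parameter table
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname ClusterModel
#' @export
setMethod("componentTable", "ClusterModel", function(x) {
  data.frame(thetaMean = x@thetaMeans, thetaSd = x@thetaSds,
             rMean = x@rMeans, rSd = x@rSds,
             weight = x@weights, label = x@labels)
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel", object@snpId, "-", object@pattern,
      sprintf("(K=%d, scorable=%s)\n", object@K, object@scorable))
  if (object@K > 0)
    cat("  theta means:",
        paste(sprintf("%.3f[%s]", object@thetaMeans, object@labels),
              collapse = " "), "\n")
})
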