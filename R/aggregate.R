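# Aggregation of per-genotype variant calls into a cross-panel summary
# matrix. The site-call logic is deliberately total: every (coverage,
# depth, fraction, platform) combination maps to exactly one call.

#' Depth thresholds for site calling
#'
#' Platform-specific minimum read depths and the within-genotype
#' heterozygote band applied to the alternate-read fraction. Defaults: 3x
#' for long-read 454 data, 8x for short-read Illumina data, het band
#' \[0.2, 0.8\].
#'
#' @param minDepth454 minimum depth for `LONG_454` data
#' @param minDepthIllumina minimum depth for `SHORT_ILLUMINA` data
#' @param hetBand length-2 numeric; alternate-read-fraction band within
#'   which a covered variant is called heterozygous (inclusive); above the
#'   band the call is HOM_VARIANT, below it REFERENCE
#' @return a classed list of thresholds
#' @export
depthThresholds <- function(minDepth454 = 3, minDepthIllumina = 8,
                            hetBand = c(0.2, 0.8)) {
  stopifnot(minDepth454 >= 1, minDepthIllumina >= 1,
            length(hetBand) == 2, hetBand[1] < hetBand[2],
            hetBand[1] >= 0, hetBand[2] <= 1)
  structure(list(minDepth454 = minDepth454,
                 minDepthIllumina = minDepthIllumina,
                 hetBand = hetBand),
            class = "DepthThresholds")
}

.minDepthFor <- function(platform, thresholds) {
  switch(platform,
         LONG_454 = thresholds$minDepth454,
         SHORT_ILLUMINA = thresholds$minDepthIllumina,
         stop("unknown platform tag: ", platform, call. = FALSE))
}

#' Call one genotype at one site
#'
#' Determines a missing, reference, heterozygous or homozygous-variant call
#' for a genotype at a covered position. Uncovered positions and variant
#' records below the platform depth minimum are MISSING; covered positions
#' without a variant record are REFERENCE; otherwise the alternate-read
#' fraction decides (within the het band: HET; above: HOM_VARIANT; below:
#' REFERENCE).
#'
#' @param variant NULL (no variant record) or a list/row with `alt`,
#'   `depth`, `altFrac`
#' @param covered logical, is the position inside this genotype's covered
#'   intervals?
#' @param platform `"LONG_454"` or `"SHORT_ILLUMINA"`
#' @param thresholds a [depthThresholds()] object
#' @return list with `call`, `alt`, `depth`, `altFrac`
#' @export
#' @examples
#' buildSiteCall(list(alt = "G", depth = 10, altFrac = 0.5), TRUE,
#'               "SHORT_ILLUMINA", depthThresholds())$call
buildSiteCall <- function(variant, covered, platform,
                          thresholds = depthThresholds()) {
  minDepth <- .minDepthFor(platform, thresholds)
  if (!isTRUE(covered))
    return(list(call = "MISSING", alt = NA_character_,
                depth = NA_real_, altFrac = NA_real_))
  if (is.null(variant))
    return(list(call = "REFERENCE", alt = NA_character_,
                depth = NA_real_, altFrac = NA_real_))
  if (variant$depth < minDepth)
    return(list(call = "MISSING", alt = NA_character_,
                depth = variant$depth, altFrac = variant$altFrac))
  band <- thresholds$hetBand
  call <- if (variant$altFrac > band[2]) "HOM_VARIANT"
          else if (variant$altFrac >= band[1]) "HET"
          else "REFERENCE"
  alt <- if (call %in% c("HOM_VARIANT", "HET")) variant$alt else NA_character_
  list(call = call, alt = alt, depth = variant$depth,
       altFrac = variant$altFrac)
}

# vectorised site calling; NA alt marks "no variant record"
.siteCallVec <- function(alt, depth, altFrac, covered, platform, thresholds) {
  minDepth <- .minDepthFor(platform, thresholds)
  band <- thresholds$hetBand
  n <- length(covered)
  call <- rep("REFERENCE", n)
  call[!covered] <- "MISSING"
  hasVar <- covered & !is.na(alt)
  lowDepth <- hasVar & depth < minDepth
  call[lowDepth] <- "MISSING"
  ok <- hasVar & !lowDepth
  call[ok & altFrac > band[2]] <- "HOM_VARIANT"
  call[ok & altFrac >= band[1] & altFrac <= band[2]] <- "HET"
  outAlt <- ifelse(call %in% c("HOM_VARIANT", "HET"), alt, NA_character_)
  list(call = call, alt = outAlt,
       depth = ifelse(hasVar, depth, NA_real_),
       altFrac = ifelse(hasVar, altFrac, NA_real_))
}

#' Panel statistics for a vector of site calls
#'
#' Missing fraction over all genotypes, heterozygote fraction among
#' non-missing calls, and the alternate-allele frequency among non-missing
#' calls with each HET contributing half an alternate allele. When every
#' call is MISSING, the frequency is NA (undefined sentinel), never an
#' error.
#'
#' @param calls character vector of
#'   MISSING/REFERENCE/HOM_VARIANT/HET calls
#' @return named numeric vector `missingFrac`, `hetFrac`, `altFreq`
#' @export
#' @examples
#' panelStats(c("HET", "HET"))
panelStats <- function(calls) {
  stopifnot(length(calls) >= 1)
  n <- length(calls)
  nMiss <- sum(calls == "MISSING")
  nObs <- n - nMiss
  if (nObs == 0)
    return(c(missingFrac = 1, hetFrac = NA_real_, altFreq = NA_real_))
  nHet <- sum(calls == "HET")
  nHom <- sum(calls == "HOM_VARIANT")
  c(missingFrac = nMiss / n,
    hetFrac = nHet / nObs,
    altFreq = (nHom + 0.5 * nHet) / nObs)
}

#' Aggregate per-genotype variant sets into a summary matrix
#'
#' Builds one row per reference position carrying at least one variant call
#' (HET or HOM_VARIANT) in at least one genotype, filling every genotype
#' cell via the site-calling rules and computing per-row panel statistics.
#' Rows are sorted by (chromosome, position). A variant record whose
#' reference allele disagrees with the reference sequence raises a warning
#' and flags the row (`refMismatch`), but the row is retained: merged
#' panels from mixed pipelines commonly contain such rows. Sites with more
#' than one alternate allele are retained here so the multi-allele filter
#' downstream is observable as its own attrition step.
#'
#' @param variantSets list of [GenotypeVariantSet-class] objects with
#'   unique genotype ids
#' @param reference a [ReferenceGenome-class]
#' @param thresholds a [depthThresholds()] object
#' @return a [SNPSummaryMatrix-class]
#' @export
aggregatePanel <- function(variantSets, reference,
                           thresholds = depthThresholds()) {
  gids <- vapply(variantSets, function(v) v@genotype, character(1))
  if (anyDuplicated(gids)) stop("genotype ids must be unique")
  allVar <- do.call(rbind, lapply(variantSets, function(v) {
    if (nrow(v@variants) == 0) return(NULL)
    cbind(v@variants, genotype = v@genotype)
  }))
  emptyOut <- function() {
    rr <- GRanges()
    se <- SummarizedExperiment(
      assays = list(call = matrix(character(), 0, length(gids),
                                  dimnames = list(NULL, gids)),
                    alt = matrix(character(), 0, length(gids)),
                    depth = matrix(numeric(), 0, length(gids)),
                    altFrac = matrix(numeric(), 0, length(gids))),
      rowRanges = rr,
      colData = DataFrame(genotype = gids,
                          platform = vapply(variantSets,
                                            function(v) v@platform,
                                            character(1)),
                          row.names = gids))
    rowData(se) <- DataFrame(ref = character(), alts = character(),
                             refMismatch = logical(),
                             missingFrac = numeric(), hetFrac = numeric(),
                             altFreq = numeric())
    new("SNPSummaryMatrix", se)
  }
  if (is.null(allVar) || nrow(allVar) == 0) return(emptyOut())

  chromNames <- names(refSequences(reference))
  bad <- setdiff(unique(allVar$chrom), chromNames)
  if (length(bad))
    stop("variant chromosomes absent from reference: ",
         paste(bad, collapse = ", "))

  sites <- unique(allVar[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  key <- paste(sites$chrom, sites$pos, sep = ":")
  nS <- nrow(sites); nG <- length(gids)

  # reference allele straight from the sequence set
  refAllele <- character(nS)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    seqCh <- refSequences(reference)[[ch]]
    refAllele[idx] <- as.character(
      Biostrings::extractAt(seqCh, IRanges(sites$pos[idx], width = 1)))
  }

  refMismatch <- logical(nS)
  callM <- matrix("MISSING", nS, nG, dimnames = list(key, gids))
  altM <- matrix(NA_character_, nS, nG, dimnames = list(key, gids))
  depthM <- matrix(NA_real_, nS, nG, dimnames = list(key, gids))
  fracM <- matrix(NA_real_, nS, nG, dimnames = list(key, gids))

  siteGR <- GRanges(sites$chrom, IRanges(sites$pos, width = 1))
  for (j in seq_along(variantSets)) {
    vs <- variantSets[[j]]
    covered <- rep(FALSE, nS)
    ov <- findOverlaps(siteGR, vs@coverage)
    covered[unique(S4Vectors::queryHits(ov))] <- TRUE
    v <- vs@variants
    alt <- rep(NA_character_, nS); depth <- rep(NA_real_, nS)
    frac <- rep(NA_real_, nS)
    if (nrow(v)) {
      vkey <- paste(v$chrom, v$pos, sep = ":")
      m <- match(vkey, key)
      alt[m] <- v$alt; depth[m] <- v$depth; frac[m] <- v$altFrac
      mm <- which(v$ref != refAllele[m])
      if (length(mm)) refMismatch[m[mm]] <- TRUE
    }
    sc <- .siteCallVec(alt, depth, frac, covered, vs@platform, thresholds)
    callM[, j] <- sc$call; altM[, j] <- sc$alt
    depthM[, j] <- sc$depth; fracM[, j] <- sc$altFrac
  }
  if (any(refMismatch))
    warning(sum(refMismatch),
            " site(s) with variant reference allele disagreeing with the",
            " reference sequence; rows flagged and retained")

  keep <- rowSums(callM == "HOM_VARIANT" | callM == "HET") >= 1
  callM <- callM[keep, , drop = FALSE]; altM <- altM[keep, , drop = FALSE]
  depthM <- depthM[keep, , drop = FALSE]
  fracM <- fracM[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]; refAllele <- refAllele[keep]
  refMismatch <- refMismatch[keep]
  if (nrow(sites) == 0) return(emptyOut())

  stats <- t(apply(callM, 1, panelStats))
  alts <- vapply(seq_len(nrow(altM)), function(i) {
    a <- altM[i, ]
    a <- sort(unique(a[callM[i, ] %in% c("HOM_VARIANT", "HET") & !is.na(a)]))
    paste(a, collapse = ",")
  }, character(1))

  rr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1))
  names(rr) <- paste(sites$chrom, sites$pos, sep = ":")
  se <- SummarizedExperiment(
    assays = list(call = callM, alt = altM, depth = depthM, altFrac = fracM),
    rowRanges = rr,
    colData = DataFrame(genotype = gids,
                        platform = vapply(variantSets,
                                          function(v) v@platform,
                                          character(1)),
                        row.names = gids))
  rowData(se) <- DataFrame(ref = refAllele, alts = alts,
                           refMismatch = refMismatch,
                           missingFrac = stats[, "missingFrac"],
                           hetFrac = stats[, "hetFrac"],
                           altFreq = stats[, "altFreq"])
  new("SNPSummaryMatrix", se)
}
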