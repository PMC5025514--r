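# The five-step single-locus filter cascade. All inequalities are strict
# ("greater than 70 %", "less than 0.6"), so exact-boundary candidates
# pass; this is encoded exactly and asserted in the tests.

#' Thresholds for the candidate-SNP filter cascade
#'
#' @param flankLength bp of variant-free flanking sequence required on at
#'   least one side (default 60)
#' @param maxAlleles maximum total distinct alleles at a site (reference +
#'   alternates; default 2, i.e. biallelic)
#' @param maxMissing sites with missing-data fraction strictly greater than
#'   this are excluded (default 0.70)
#' @param maxHet sites with heterozygote fraction strictly greater than
#'   this are excluded (default 0.40)
#' @param freqBand sites with panel alternate-allele frequency strictly
#'   outside this band are excluded (default \[0.2, 0.8\]; boundary values
#'   retained)
#' @param minDesignScore sites with external design score strictly below
#'   this are excluded (default 0.6)
#' @param transversionMode `"AT_CG_ONLY"` excludes only A/T and C/G allele
#'   pairs (the pairs requiring two beads per assay); `"ALL_TRANSVERSIONS"`
#'   excludes every non-transition pair
#' @param failMissingScore should candidates lacking a design score fail
#'   the score step? (default TRUE)
#' @return classed list of thresholds
#' @export
filterThresholds <- function(flankLength = 60, maxAlleles = 2,
                             maxMissing = 0.70, maxHet = 0.40,
                             freqBand = c(0.2, 0.8), minDesignScore = 0.6,
                             transversionMode = c("AT_CG_ONLY",
                                                  "ALL_TRANSVERSIONS"),
                             failMissingScore = TRUE) {
  transversionMode <- match.arg(transversionMode)
  stopifnot(flankLength >= 1, maxAlleles >= 2,
            .isProb(c(maxMissing, maxHet, freqBand)),
            freqBand[1] < freqBand[2], .isProb(minDesignScore))
  structure(list(flankLength = flankLength, maxAlleles = maxAlleles,
                 maxMissing = maxMissing, maxHet = maxHet,
                 freqBand = freqBand, minDesignScore = minDesignScore,
                 transversionMode = transversionMode,
                 failMissingScore = failMissingScore),
            class = "FilterThresholds")
}

#' Annotate candidate SNPs with flank cleanliness
#'
#' For each site of the summary matrix, each flank window (default 60 bp)
#' is marked clean iff it contains no N, no other site of the full
#' pre-filter variant position set, and does not run off the chromosome
#' end. Truncated flanks are simply unclean, never an error. The flanking
#' sequences themselves are recorded for downstream probe extraction.
#'
#' @param x a [SNPSummaryMatrix-class]
#' @param reference a [ReferenceGenome-class]
#' @param flankLength flank window size in bp
#' @return data.frame of candidates (one row per site) with columns
#'   `snpId, chrom, pos, ref, alts, nAlleles, upClean, downClean, upFlank,
#'   downFlank, missingFrac, hetFrac, altFreq, refMismatch, designScore`
#' @export
annotateFlanks <- function(x, reference, flankLength = 60) {
  st <- siteStats(x)
  if (nrow(st) == 0) {
    st$nAlleles <- integer(); st$upClean <- logical()
    st$downClean <- logical(); st$upFlank <- character()
    st$downFlank <- character(); st$designScore <- numeric()
    return(st)
  }
  lens <- chromLengths(reference)
  if (any(st$pos < 1 | st$pos > lens[st$chrom]))
    stop("site positions outside chromosome bounds")
  nAlt <- ifelse(st$alts == "", 0L,
                 lengths(strsplit(st$alts, ",", fixed = TRUE)))
  st$nAlleles <- 1L + nAlt

  # all pre-filter variant positions, per chromosome, for neighbour checks
  posByChrom <- split(st$pos, st$chrom)

  up <- character(nrow(st)); down <- character(nrow(st))
  upClean <- logical(nrow(st)); downClean <- logical(nrow(st))
  for (ch in unique(st$chrom)) {
    idx <- which(st$chrom == ch)
    seqCh <- refSequences(reference)[[ch]]
    chLen <- lens[[ch]]
    pos <- st$pos[idx]
    others <- sort(posByChrom[[ch]])
    upOk <- pos - flankLength >= 1
    downOk <- pos + flankLength <= chLen
    upStart <- pmax(pos - flankLength, 1)
    downEnd <- pmin(pos + flankLength, chLen)
    upSeq <- as.character(Biostrings::extractAt(
      seqCh, IRanges(upStart, pmax(pos - 1, upStart - 1))))
    downSeq <- as.character(Biostrings::extractAt(
      seqCh, IRanges(pmin(pos + 1, downEnd + 1), downEnd)))
    hasNeighbour <- function(lo, hi) {
      # any other panel variant position within [lo, hi]?
      n <- findInterval(hi, others) - findInterval(lo - 1L, others)
      n > 0
    }
    upNb <- hasNeighbour(pos - flankLength, pos - 1L)
    downNb <- hasNeighbour(pos + 1L, pos + flankLength)
    upClean[idx] <- upOk & !upNb & !grepl("N", upSeq, fixed = TRUE)
    downClean[idx] <- downOk & !downNb & !grepl("N", downSeq, fixed = TRUE)
    up[idx] <- upSeq; down[idx] <- downSeq
  }
  st$upClean <- upClean; st$downClean <- downClean
  st$upFlank <- up; st$downFlank <- down
  st$designScore <- NA_real_
  st
}

#' Attach external design scores to candidates
#'
#' The assay design score (e.g. from a vendor design tool) is consumed as
#' an opaque input column in \[0,1\]; no attempt is made to re-create the
#' proprietary scorer.
#'
#' @param candidates candidate data.frame from [annotateFlanks()]
#' @param scores data.frame with columns `snpId`, `score`
#' @return candidates with `designScore` filled where available
#' @export
addDesignScores <- function(candidates, scores) {
  m <- match(candidates$snpId, scores$snpId)
  candidates$designScore <- scores$score[m]
  candidates
}

# --- individual filter predicates (TRUE = pass) ----------------------------

.passFlanking <- function(c, th) c$upClean | c$downClean

.passMultiallelic <- function(c, th) c$nAlleles <= th$maxAlleles

.passConfidence <- function(c, th) {
  !is.na(c$altFreq) &
    c$missingFrac <= th$maxMissing &
    c$hetFrac <= th$maxHet &
    c$altFreq >= th$freqBand[1] & c$altFreq <= th$freqBand[2]
}

.passDesignScore <- function(c, th) {
  s <- c$designScore
  ifelse(is.na(s), !th$failMissingScore, s >= th$minDesignScore)
}

.pairExcluded <- function(pairs, mode) {
  if (mode == "AT_CG_ONLY") pairs %in% .AT_CG
  else !pairs %in% .TRANSITIONS
}

.passTransversion <- function(c, th) {
  excl <- vapply(seq_len(nrow(c)), function(i) {
    alts <- strsplit(c$alts[i], ",", fixed = TRUE)[[1]]
    if (!length(alts)) return(FALSE)
    any(.pairExcluded(.allelePair(c$ref[i], alts), th$transversionMode))
  }, logical(1))
  !excl
}

.FILTER_STEPS <- c(flanking = ".passFlanking",
                   multiallelic = ".passMultiallelic",
                   confidence = ".passConfidence",
                   design_score = ".passDesignScore",
                   transversion = ".passTransversion")

.applyStep <- function(candidates, step, thresholds) {
  fn <- get(.FILTER_STEPS[[step]], mode = "function")
  pass <- fn(candidates, thresholds)
  list(pass = candidates[pass, , drop = FALSE],
       fail = candidates[!pass, , drop = FALSE])
}

#' Individual filter steps
#'
#' Each step splits a candidate table into passing and failing subsets.
#' `filterFlanking` requires at least one clean flank; `filterMultiallelic`
#' excludes sites with more than `maxAlleles` distinct alleles;
#' `filterConfidence` excludes sites with too much missing data, too many
#' heterozygous calls, an allele frequency strictly outside the retention
#' band, or an undefined frequency; `filterDesignScore` excludes scores
#' strictly below the minimum; `filterTransversion` excludes allele pairs
#' per the configured mode.
#'
#' @param candidates candidate data.frame from [annotateFlanks()]
#' @param thresholds a [filterThresholds()] object
#' @return list with elements `pass` and `fail`
#' @export
filterFlanking <- function(candidates, thresholds = filterThresholds())
  .applyStep(candidates, "flanking", thresholds)

#' @rdname filterFlanking
#' @export
filterMultiallelic <- function(candidates, thresholds = filterThresholds())
  .applyStep(candidates, "multiallelic", thresholds)

#' @rdname filterFlanking
#' @export
filterConfidence <- function(candidates, thresholds = filterThresholds())
  .applyStep(candidates, "confidence", thresholds)

#' @rdname filterFlanking
#' @export
filterDesignScore <- function(candidates, thresholds = filterThresholds())
  .applyStep(candidates, "design_score", thresholds)

#' @rdname filterFlanking
#' @export
filterTransversion <- function(candidates, thresholds = filterThresholds())
  .applyStep(candidates, "transversion", thresholds)

#' Run the full filter cascade
#'
#' Applies the five filter steps in order and produces an attrition report
#' in the style of an array-design filtering table: one row per step with
#' the count excluded at that step and the count remaining after it. Each
#' failed candidate is attributed to exactly the first step it fails; the
#' survivor set is invariant under permutation of the step order because
#' the filters are independent predicates.
#'
#' @param candidates candidate data.frame from [annotateFlanks()] (with
#'   design scores attached if the score step is to be informative)
#' @param thresholds a [filterThresholds()] object
#' @param stepOrder permutation of
#'   `c("flanking","multiallelic","confidence","design_score","transversion")`
#' @return list with `report` (data.frame `step, excluded, remaining`,
#'   first row `none` giving the initial count), `survivors` (candidate
#'   rows passing all steps) and `failures` (failed rows with a
#'   `failedStep` column)
#' @export
runCascade <- function(candidates, thresholds = filterThresholds(),
                       stepOrder = names(.FILTER_STEPS)) {
  if (!setequal(stepOrder, names(.FILTER_STEPS)) ||
      length(stepOrder) != length(.FILTER_STEPS))
    stop("stepOrder must be a permutation of the five filter steps")
  remaining <- candidates
  report <- data.frame(step = "none", excluded = 0L,
                       remaining = nrow(candidates))
  failures <- NULL
  for (s in stepOrder) {
    res <- .applyStep(remaining, s, thresholds)
    if (nrow(res$fail)) {
      f <- res$fail; f$failedStep <- s
      failures <- rbind(failures, f)
    }
    report <- rbind(report,
                    data.frame(step = s, excluded = nrow(res$fail),
                               remaining = nrow(res$pass)))
    remaining <- res$pass
  }
  list(report = report, survivors = remaining,
       failures = failures %||% cbind(candidates[0, , drop = FALSE],
                                      failedStep = character()))
}
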