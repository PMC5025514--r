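# Genetic-map construction helpers for doubled-haploid populations and the
# genetic-vs-physical concordance analysis. Marker ordering is an input:
# this module validates and measures an order, it does not search order
# space.

#' Kosambi mapping function and its inverse
#'
#' `kosambi(r) = 25 * log((1 + 2r) / (1 - 2r))` centimorgans, converting a
#' recombinant fraction to a map distance allowing partial interference;
#' `kosambiInverse(d) = tanh(d / 50) / 2` recovers the fraction. The
#' functions round-trip to better than 1e-12 over the domain.
#'
#' @param r recombinant fraction(s) in \[0, 0.5)
#' @param d map distance(s) in cM, >= 0
#' @return numeric vector (cM for `kosambi`, fraction for `kosambiInverse`)
#' @export
#' @examples
#' kosambi(0.25)        # 25 * log(3)
#' kosambiInverse(kosambi(0.1))
kosambi <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombinant fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambiInverse <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("map distance must be >= 0")
  tanh(d / 50) / 2
}

#' Estimate the recombinant fraction between two DH marker vectors
#'
#' For a doubled-haploid population every non-missing line is informative:
#' `r` is the fraction of discordant lines among jointly non-missing
#' lines. Returns the NA sentinel when no line is jointly informative.
#' Values above 0.5 indicate unlinked markers.
#'
#' @param v1,v2 character vectors of `"A"`/`"B"`/NA calls, same length
#' @return recombinant fraction in \[0, 1\], or NA
#' @export
estimateR <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  joint <- !is.na(v1) & !is.na(v2)
  if (!any(joint)) return(NA_real_)
  mean(v1[joint] != v2[joint])
}

#' Place ordered markers into recombination bins
#'
#' Consecutive markers are merged into one bin iff their genotype vectors
#' agree on every line where both are non-missing and at least one line is
#' jointly informative (missing data act as wildcards, but a merge is
#' never made on zero shared information). Bins partition the markers;
#' within a bin all pairwise recombinant-fraction estimates between
#' adjacent markers are zero.
#'
#' @param geno lines x markers matrix of `"A"`/`"B"`/NA (doubled haploid:
#'   no heterozygote codes)
#' @param markerOrder character vector giving the marker order (default:
#'   column order)
#' @return named integer vector of bin ids (1-based, increasing along the
#'   order)
#' @export
findBins <- function(geno, markerOrder = colnames(geno)) {
  stopifnot(!is.null(markerOrder), all(markerOrder %in% colnames(geno)))
  g <- geno[, markerOrder, drop = FALSE]
  m <- ncol(g)
  bins <- integer(m)
  bins[1] <- 1L
  if (m > 1) for (j in 2:m) {
    v1 <- g[, j - 1]; v2 <- g[, j]
    joint <- !is.na(v1) & !is.na(v2)
    same <- any(joint) && all(v1[joint] == v2[joint])
    bins[j] <- if (same) bins[j - 1] else bins[j - 1] + 1L
  }
  setNames(bins, markerOrder)
}

#' Build a genetic map from an ordered DH matrix
#'
#' Cumulative Kosambi distances along the given order, with co-segregating
#' markers collapsed into bins at the same position.
#'
#' @param geno lines x markers matrix of `"A"`/`"B"`/NA
#' @param lg linkage-group name stored in the output
#' @param markerOrder marker order (default: column order)
#' @return data.frame `marker, lg, cM, bin`
#' @export
buildGeneticMap <- function(geno, lg = "LG1", markerOrder = colnames(geno)) {
  bins <- findBins(geno, markerOrder)
  m <- length(markerOrder)
  cm <- numeric(m)
  if (m > 1) for (j in 2:m) {
    r <- estimateR(geno[, markerOrder[j - 1]], geno[, markerOrder[j]])
    step <- if (is.na(r) || r >= 0.5) 0 else kosambi(r)
    cm[j] <- cm[j - 1] + step
  }
  data.frame(marker = markerOrder, lg = lg, cM = cm, bin = unname(bins))
}

#' Anchor markers to physical positions from alignment hits
#'
#' Retains the best hit per marker by percent identity. Markers whose best
#' identity falls below the threshold are unanchored; markers with
#' co-optimal best hits on different chromosomes are flagged ambiguous
#' (placed on either homoeolog with equal probability). Malformed hit rows
#' (missing fields) are skipped with a message.
#'
#' @param hits data.frame with columns `marker, chrom, bp, identity`
#'   (percent identity, 0-100)
#' @param minIdentity minimum percent identity (default 85)
#' @return data.frame `marker, chrom, bp, identity, ambiguous, unanchored`
#' @export
assignPhysical <- function(hits, minIdentity = 85) {
  need <- c("marker", "chrom", "bp", "identity")
  stopifnot(all(need %in% names(hits)))
  bad <- !complete.cases(hits[, need])
  if (any(bad)) {
    message("skipping ", sum(bad), " malformed hit row(s)")
    hits <- hits[!bad, , drop = FALSE]
  }
  out <- lapply(split(hits, hits$marker), function(h) {
    bestId <- max(h$identity)
    if (bestId < minIdentity)
      return(data.frame(marker = h$marker[1], chrom = NA_character_,
                        bp = NA_real_, identity = bestId,
                        ambiguous = FALSE, unanchored = TRUE))
    best <- h[h$identity == bestId, , drop = FALSE]
    amb <- length(unique(best$chrom)) > 1
    best <- best[order(best$chrom, best$bp), , drop = FALSE][1, ]
    data.frame(marker = best$marker, chrom = best$chrom, bp = best$bp,
               identity = bestId, ambiguous = amb, unanchored = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @importFrom stats complete.cases
NULL

# density statistics shared by computeMapStats and mapDensityStats
.densities <- function(bins, physLoci, physKb, mappedLoci, mapCm) {
  data.frame(
    bins = bins, physLoci = physLoci, physKb = physKb,
    mappedLoci = mappedLoci, mapCm = mapCm,
    markersPerCm = ifelse(mapCm > 0,
                          roundHalfUp(mappedLoci / mapCm, 2), NA_real_),
    cmPerMarker = ifelse(mappedLoci > 0 & mapCm > 0,
                         roundHalfUp(mapCm / mappedLoci, 2), NA_real_),
    kbPerMarker = ifelse(physLoci > 0,
                         roundHalfUp(physKb / physLoci, 2), NA_real_))
}

#' Recompute map-density statistics from per-linkage-group counts
#'
#' Given the per-LG bin counts, physically positioned locus counts,
#' physical lengths (Kb), mapped locus counts and map lengths (cM) — for
#' example the printed rows of a published map summary table — computes
#' markers/cM, cM/marker and Kb/marker per row plus a `Total` row, rounded
#' half-up to two decimals as conventionally printed.
#'
#' @param counts data.frame with columns `lg, bins, physLoci, physKb,
#'   mappedLoci, mapCm`
#' @return data.frame with the input counts plus the three density columns
#'   and a final `Total` row
#' @export
mapDensityStats <- function(counts) {
  need <- c("lg", "bins", "physLoci", "physKb", "mappedLoci", "mapCm")
  stopifnot(all(need %in% names(counts)))
  per <- cbind(lg = counts$lg,
               .densities(counts$bins, counts$physLoci, counts$physKb,
                          counts$mappedLoci, counts$mapCm))
  if ("Total" %in% counts$lg) return(per)  # table already carries totals
  tot <- cbind(lg = "Total",
               .densities(sum(counts$bins), sum(counts$physLoci),
                          sum(counts$physKb), sum(counts$mappedLoci),
                          sum(counts$mapCm)))
  rbind(per, tot)
}

#' Map and anchor summary statistics with gap lists
#'
#' Per linkage group: bin count, physically positioned loci, physical
#' length (Kb, span of anchored positions), mapped loci, map length (cM),
#' and the three density statistics; plus a `Total` row. Gap lists report
#' genetic gaps of at least `geneticGapMin` cM between consecutive mapped
#' positions and physical intervals strictly greater than `physicalGapKb`
#' between consecutive anchored loci. Linkage groups of zero genetic
#' length get NA density sentinels.
#'
#' @param map data.frame `marker, lg, cM` (optionally `bin`)
#' @param anchors data.frame from [assignPhysical()]
#' @param geneticGapMin genetic gap threshold in cM (default 9)
#' @param physicalGapKb physical gap threshold in Kb (default 500)
#' @return list with `stats`, `geneticGaps`, `physicalGaps`
#' @export
computeMapStats <- function(map, anchors, geneticGapMin = 9,
                            physicalGapKb = 500) {
  a <- anchors[!anchors$unanchored, , drop = FALSE]
  m <- merge(map, a[, c("marker", "chrom", "bp")], by = "marker",
             all.x = TRUE)
  lgs <- unique(map$lg)
  rows <- lapply(lgs, function(l) {
    ml <- m[m$lg == l, , drop = FALSE]
    bins <- if ("bin" %in% names(ml)) length(unique(ml$bin))
            else length(unique(ml$cM))
    anch <- ml[!is.na(ml$bp), , drop = FALSE]
    physKb <- if (nrow(anch) > 1) (max(anch$bp) - min(anch$bp)) / 1000 else 0
    data.frame(lg = l, bins = bins, physLoci = nrow(anch),
               physKb = physKb, mappedLoci = nrow(ml),
               mapCm = max(ml$cM) - min(ml$cM))
  })
  counts <- do.call(rbind, rows)
  stats <- mapDensityStats(counts)

  gGaps <- do.call(rbind, lapply(lgs, function(l) {
    cm <- sort(unique(m$cM[m$lg == l]))
    if (length(cm) < 2) return(NULL)
    d <- diff(cm)
    i <- which(d >= geneticGapMin)
    if (!length(i)) return(NULL)
    data.frame(lg = l, fromCm = cm[i], toCm = cm[i + 1], gapCm = d[i])
  }))
  pGaps <- do.call(rbind, lapply(lgs, function(l) {
    al <- m[m$lg == l & !is.na(m$bp), , drop = FALSE]
    if (nrow(al) < 2) return(NULL)
    bp <- sort(al$bp)
    d <- diff(bp)
    i <- which(d / 1000 > physicalGapKb)
    if (!length(i)) return(NULL)
    data.frame(lg = l, fromBp = bp[i], toBp = bp[i + 1],
               gapKb = d[i] / 1000)
  }))
  list(stats = stats,
       geneticGaps = gGaps %||% data.frame(lg = character(),
                                           fromCm = numeric(),
                                           toCm = numeric(),
                                           gapCm = numeric()),
       physicalGaps = pGaps %||% data.frame(lg = character(),
                                            fromBp = numeric(),
                                            toBp = numeric(),
                                            gapKb = numeric()))
}

#' Look up the homoeologous chromosome
#'
#' @param chrom chromosome name(s)
#' @param homoeology data.frame with columns `chromA`, `chromC` giving the
#'   homoeologous pairing (symmetric lookup)
#' @return homoeologous partner(s), NA where unknown
#' @export
homoeologOf <- function(chrom, homoeology) {
  m1 <- match(chrom, homoeology$chromA)
  m2 <- match(chrom, homoeology$chromC)
  ifelse(!is.na(m1), homoeology$chromC[m1],
         ifelse(!is.na(m2), homoeology$chromA[m2], NA_character_))
}

#' Classify genetic-vs-physical concordance per marker
#'
#' Each genetically mapped marker is labelled `CONCORDANT` when its
#' physical anchor chromosome matches the chromosome expected for its
#' linkage group, `HOMOEOLOGOUS` when the anchor sits on the homoeologous
#' partner of the expected chromosome, `DISCORDANT` otherwise, and
#' `UNANCHORED` when it has no qualifying physical anchor or its linkage
#' group has no chromosome correspondence (with a warning). Summary
#' fractions are computed over the classified (non-UNANCHORED) markers
#' and sum to 1.
#'
#' @param map data.frame `marker, lg, cM`
#' @param anchors data.frame from [assignPhysical()]
#' @param homoeology data.frame `chromA, chromC`
#' @param lgChrom data.frame `lg, chrom` mapping linkage groups to their
#'   expected chromosome
#' @return list with `records` (per-marker table) and `summary` (named
#'   fractions `CONCORDANT`, `HOMOEOLOGOUS`, `DISCORDANT`)
#' @export
classifyConcordance <- function(map, anchors, homoeology, lgChrom) {
  rec <- merge(map, anchors, by = "marker", all.x = TRUE, sort = FALSE)
  rec$expected <- lgChrom$chrom[match(rec$lg, lgChrom$lg)]
  noCorr <- is.na(rec$expected)
  if (any(noCorr))
    warning(sum(noCorr), " marker(s) on linkage groups without a ",
            "chromosome correspondence: treated as UNANCHORED")
  homoeo <- homoeologOf(rec$expected, homoeology)
  status <- rep("UNANCHORED", nrow(rec))
  anchored <- !is.na(rec$chrom) & !noCorr
  status[anchored & rec$chrom == rec$expected] <- "CONCORDANT"
  status[anchored & !is.na(homoeo) & rec$chrom == homoeo] <- "HOMOEOLOGOUS"
  status[anchored & rec$chrom != rec$expected &
           (is.na(homoeo) | rec$chrom != homoeo)] <- "DISCORDANT"
  rec$status <- status
  classified <- status != "UNANCHORED"
  tab <- table(factor(status[classified],
                      levels = c("CONCORDANT", "HOMOEOLOGOUS",
                                 "DISCORDANT")))
  list(records = rec[order(rec$lg, rec$cM), , drop = FALSE],
       summary = tab / max(sum(tab), 1))
}

#' Detect rearranged segments from ordered concordance records
#'
#' Scans each linkage group in map order for maximal runs of at least
#' `minRun` consecutive non-concordant markers anchored to one and the
#' same alternate chromosome — the signature of a translocated or
#' mis-anchored genomic segment — and reports their genetic and physical
#' extents.
#'
#' @param records per-marker table from [classifyConcordance()]
#' @param minRun minimum run length (default 3)
#' @return data.frame `lg, chrom, nMarkers, startMarker, endMarker,
#'   cmStart, cmEnd, bpStart, bpEnd`
#' @export
detectSegments <- function(records, minRun = 3) {
  segs <- NULL
  for (l in unique(records$lg)) {
    r <- records[records$lg == l, , drop = FALSE]
    r <- r[order(r$cM), , drop = FALSE]
    bad <- r$status %in% c("HOMOEOLOGOUS", "DISCORDANT")
    key <- ifelse(bad, r$chrom, NA_character_)
    i <- 1
    n <- nrow(r)
    while (i <= n) {
      if (is.na(key[i])) { i <- i + 1; next }
      j <- i
      while (j < n && !is.na(key[j + 1]) && key[j + 1] == key[i]) j <- j + 1
      if (j - i + 1 >= minRun)
        segs <- rbind(segs, data.frame(
          lg = l, chrom = key[i], nMarkers = j - i + 1,
          startMarker = r$marker[i], endMarker = r$marker[j],
          cmStart = r$cM[i], cmEnd = r$cM[j],
          bpStart = min(r$bp[i:j], na.rm = TRUE),
          bpEnd = max(r$bp[i:j], na.rm = TRUE)))
      i <- j + 1
    }
  }
  segs %||% data.frame(lg = character(), chrom = character(),
                       nMarkers = integer(), startMarker = character(),
                       endMarker = character(), cmStart = numeric(),
                       cmEnd = numeric(), bpStart = numeric(),
                       bpEnd = numeric())
}
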