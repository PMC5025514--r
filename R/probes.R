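# Probe extraction and genome-wide match counting. A probe "matches" a
# genomic locus when 35 consecutive base pairs are identical on either
# strand; hits whose genomic intervals overlap are one locus. The scan is
# implemented as constant-width k-mer dictionary matching (Biostrings
# PDict) over every minRun-length window of each probe, with the interval
# merging and locus counting done here.

#' Extract candidate assay probes for a SNP
#'
#' One 50-bp probe per clean flank side, excluding the SNP base itself
#' (single-base extension chemistry). Downstream-side probes are returned
#' as the reverse complement so the 3' end abuts the SNP. The assay class
#' is `INFINIUM_I` iff the allele pair is A/T or C/G (two beads per assay),
#' otherwise `INFINIUM_II`.
#'
#' @param candidates candidate data.frame from [annotateFlanks()] (needs
#'   `snpId, chrom, pos, ref, alts, upClean, downClean`)
#' @param reference a [ReferenceGenome-class]
#' @param probeLength probe length in bp (default 50)
#' @return data.frame `snpId, side, strand, probeSeq, assayClass`; zero
#'   rows for candidates without a clean flank of sufficient length
#' @export
extractProbes <- function(candidates, reference, probeLength = 50) {
  lens <- chromLengths(reference)
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    seqCh <- refSequences(reference)[[cd$chrom]]
    alts <- strsplit(cd$alts, ",", fixed = TRUE)[[1]]
    pair <- if (length(alts)) .allelePair(cd$ref, alts[1]) else ""
    cls <- if (pair %in% .AT_CG) "INFINIUM_I" else "INFINIUM_II"
    rows <- NULL
    if (isTRUE(cd$upClean) && cd$pos - probeLength >= 1) {
      p <- as.character(Biostrings::extractAt(
        seqCh, IRanges(cd$pos - probeLength, cd$pos - 1)))
      rows <- rbind(rows, data.frame(snpId = cd$snpId, side = "UPSTREAM",
                                     strand = "+", probeSeq = p,
                                     assayClass = cls))
    }
    if (isTRUE(cd$downClean) && cd$pos + probeLength <= lens[[cd$chrom]]) {
      p <- as.character(reverseComplement(DNAString(
        as.character(Biostrings::extractAt(
          seqCh, IRanges(cd$pos + 1, cd$pos + probeLength))))))
      rows <- rbind(rows, data.frame(snpId = cd$snpId, side = "DOWNSTREAM",
                                     strand = "-", probeSeq = p,
                                     assayClass = cls))
    }
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snpId = character(), side = character(),
                      strand = character(), probeSeq = character(),
                      assayClass = character())
  res
}

#' Count genome-wide probe matches under the consecutive-bp rule
#'
#' Returns, for each probe, the number of distinct genomic loci (on either
#' strand) sharing an exact common substring of length >= `minRun` with the
#' probe. Hits whose genomic intervals overlap or abut are merged into a
#' single locus, and a hit present on both strands over the same interval
#' counts once. The count includes the probe's source locus, so a designed
#' probe always has a count >= 1.
#'
#' @param probeSeqs character vector of probe sequences (A/C/G/T only; a
#'   probe containing N is undesignable and raises an error)
#' @param reference a [ReferenceGenome-class]
#' @param minRun minimum run of identical consecutive base pairs (default
#'   35); must not exceed the shortest probe
#' @return integer vector of match counts, one per probe
#' @export
countProbeMatches <- function(probeSeqs, reference, minRun = 35) {
  if (length(probeSeqs) == 0) return(integer())
  if (any(grepl("[^ACGT]", probeSeqs)))
    stop("probe contains non-ACGT characters (undesignable)")
  if (minRun > min(nchar(probeSeqs)))
    stop("minRun exceeds probe length")
  if (minRun < 1) stop("minRun must be >= 1")

  # every minRun-window of every probe, tagged with its probe index
  win <- lapply(seq_along(probeSeqs), function(i) {
    p <- probeSeqs[i]
    s <- seq_len(nchar(p) - minRun + 1L)
    data.frame(probe = i, seq = substring(p, s, s + minRun - 1L))
  })
  win <- do.call(rbind, win)
  dict <- DNAStringSet(win$seq)
  pd <- Biostrings::PDict(dict)

  hits <- vector("list", length(probeSeqs))
  seqs <- refSequences(reference)
  for (ch in names(seqs)) {
    subj <- seqs[[ch]]
    chLen <- length(subj)
    fwd <- Biostrings::matchPDict(pd, subj)
    rev <- Biostrings::matchPDict(pd, reverseComplement(subj))
    for (dir in 1:2) {
      m <- if (dir == 1) fwd else rev
      cnt <- S4Vectors::elementNROWS(m)
      nz <- which(cnt > 0)
      if (!length(nz)) next
      for (k in nz) {
        ir <- m[[k]]
        if (dir == 2) # project reverse-strand hits to forward coordinates
          ir <- IRanges(chLen - end(ir) + 1L, chLen - start(ir) + 1L)
        pi <- win$probe[k]
        hits[[pi]] <- c(hits[[pi]],
                        list(data.frame(chrom = ch, start = start(ir),
                                        end = end(ir))))
      }
    }
  }
  vapply(seq_along(probeSeqs), function(i) {
    h <- hits[[i]]
    if (is.null(h)) return(0L)
    h <- do.call(rbind, h)
    total <- 0L
    for (ch in unique(h$chrom)) {
      ir <- IRanges(h$start[h$chrom == ch], h$end[h$chrom == ch])
      total <- total + length(reduce(ir))
    }
    total
  }, integer(1))
}

#' Build the per-SNP probe table with match counts
#'
#' Convenience wrapper: extracts probes for all candidates and annotates
#' each with its genome-wide match count.
#'
#' @inheritParams extractProbes
#' @inheritParams countProbeMatches
#' @return data.frame `snpId, side, strand, probeSeq, assayClass,
#'   matchCount`
#' @export
probeTable <- function(candidates, reference, probeLength = 50,
                       minRun = 35) {
  pt <- extractProbes(candidates, reference, probeLength)
  pt$matchCount <- if (nrow(pt))
    countProbeMatches(pt$probeSeq, reference, minRun) else integer()
  pt
}

#' Per-SNP match count across its candidate probes
#'
#' The design picks the best side, so the per-SNP count defaults to the
#' minimum over that SNP's probes; `combine = max` gives the conservative
#' alternative.
#'
#' @param probes probe table from [probeTable()]
#' @param combine `min` (default) or `max`
#' @return data.frame `snpId, matchCount`
#' @export
snpMatchCounts <- function(probes, combine = min) {
  if (nrow(probes) == 0)
    return(data.frame(snpId = character(), matchCount = integer()))
  agg <- tapply(probes$matchCount, probes$snpId, combine)
  data.frame(snpId = names(agg), matchCount = as.integer(agg),
             row.names = NULL)
}

#' Selection policy for ranked SNPs
#'
#' @param maxMatches maximum admitted probe match count (default 2: unique
#'   and twice-matching loci)
#' @param quotas optional named numeric vector capping the number of SNPs
#'   admitted per match-count class, e.g. `c("2" = 1000)`; classes without
#'   an entry are unlimited
#' @param minSpacing optional minimum genomic spacing in bp between
#'   selected SNPs on the same chromosome (0 = off)
#' @return classed list
#' @export
selectionPolicy <- function(maxMatches = 2, quotas = NULL, minSpacing = 0) {
  stopifnot(maxMatches >= 1, minSpacing >= 0,
            is.null(quotas) || all(quotas >= 0))
  structure(list(maxMatches = maxMatches, quotas = quotas,
                 minSpacing = minSpacing), class = "SelectionPolicy")
}

#' Rank SNPs by probe match count and select
#'
#' SNPs are sorted ascending by match count — fewer matches preferred —
#' with ties broken by higher design score and then deterministic id
#' order. The match-count cap and any per-class quotas are enforced; with
#' a minimum spacing, a SNP too close to an already-selected SNP on the
#' same chromosome is skipped. Output order is deterministic given the
#' inputs.
#'
#' @param snps data.frame with `snpId`, `matchCount` and optionally
#'   `designScore`, `chrom`, `pos`
#' @param policy a [selectionPolicy()]
#' @return the selected rows, in selection order
#' @export
rankAndSelect <- function(snps, policy = selectionPolicy()) {
  if (nrow(snps) == 0) return(snps)
  score <- if ("designScore" %in% names(snps))
    ifelse(is.na(snps$designScore), -Inf, snps$designScore) else
      rep(0, nrow(snps))
  ord <- order(snps$matchCount, -score, snps$snpId)
  snps <- snps[ord, , drop = FALSE]
  snps <- snps[snps$matchCount <= policy$maxMatches, , drop = FALSE]
  taken <- rep(TRUE, nrow(snps))
  if (!is.null(policy$quotas)) {
    for (cls in names(policy$quotas)) {
      idx <- which(snps$matchCount == as.integer(cls))
      if (length(idx) > policy$quotas[[cls]])
        taken[idx[-seq_len(policy$quotas[[cls]])]] <- FALSE
    }
  }
  snps <- snps[taken, , drop = FALSE]
  if (policy$minSpacing > 0 && all(c("chrom", "pos") %in% names(snps))) {
    keep <- logical(nrow(snps))
    chosen <- list()
    for (i in seq_len(nrow(snps))) {
      ch <- snps$chrom[i]
      near <- FALSE
      if (!is.null(chosen[[ch]]))
        near <- any(abs(chosen[[ch]] - snps$pos[i]) < policy$minSpacing)
      if (!near) {
        keep[i] <- TRUE
        chosen[[ch]] <- c(chosen[[ch]], snps$pos[i])
      }
    }
    snps <- snps[keep, , drop = FALSE]
  }
  rownames(snps) <- NULL
  snps
}
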