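#' @importFrom mclust Mclust mclustBIC
NULL

# Two-colour intensity clustering. The mixture is fitted in theta only
# (one dimension keeps the model identifiable on small panels); total
# intensity R drives the low-intensity and presence/absence decisions.
# Component count is selected by BIC with K capped at 5, matching the
# four-to-five clusters seen when both homoeologous loci segregate.

#' Parameters for cluster fitting and classification
#'
#' @param kRange candidate component counts (default 1:5)
#' @param thetaSep genome-specific separation: minimum difference between
#'   the extreme component theta means (default 0.6)
#' @param noCallThreshold confidence below which a sample is NO_CALL
#'   (default 0.05)
#' @param rLowThreshold total intensity below which a cell is treated as
#'   no-signal (default 0.2, on a scale where a full-signal assay has
#'   R near 1)
#' @param excessHetWeight middle-component weight above which a
#'   three-cluster SNP is deemed an unresolvable homoeolog mixture
#'   (default 0.6)
#' @param shiftedBoundary theta value splitting the space into halves for
#'   the shifted-pattern rule (default 0.5)
#' @param lowIntensityFrac fraction of no-signal samples above which the
#'   SNP fails outright (default 0.5)
#' @param paLowRange no-signal fraction range indicating a
#'   presence/absence marker (default (0.1, 0.5\])
#' @param paThetaSpan maximum theta span of the with-signal clusters for
#'   the presence/absence call (default 0.3)
#' @param mergeTol components whose theta means differ by less than this
#'   are coalesced after the fit (default 0.12). Theta is truncated to
#'   \[0,1\], so extreme clouds develop boundary point masses that BIC
#'   otherwise fits as spurious near-zero-variance sub-components;
#'   coalescing restores one component per genotype cloud. Even
#'   homoeolog-compressed patterns place three genotype clouds within
#'   half the theta space (cloud spacing around 0.16), so sub-components
#'   closer than 0.12 cannot be distinct genotype clouds.
#' @param minSamples minimum number of with-signal samples required to fit
#'   (default 10)
#' @param seed optional RNG seed recorded for provenance (the fit itself
#'   is deterministic)
#' @return classed list
#' @export
clusterParams <- function(kRange = 1:5, thetaSep = 0.6,
                          noCallThreshold = 0.05, rLowThreshold = 0.2,
                          excessHetWeight = 0.6, shiftedBoundary = 0.5,
                          lowIntensityFrac = 0.5, paLowRange = c(0.1, 0.5),
                          paThetaSpan = 0.3, mergeTol = 0.12,
                          minSamples = 10, seed = NULL) {
  stopifnot(thetaSep > 0, thetaSep < 1,
            .isProb(c(noCallThreshold, excessHetWeight, shiftedBoundary,
                      lowIntensityFrac, paLowRange, paThetaSpan)))
  structure(list(kRange = kRange, thetaSep = thetaSep,
                 noCallThreshold = noCallThreshold,
                 rLowThreshold = rLowThreshold,
                 excessHetWeight = excessHetWeight,
                 shiftedBoundary = shiftedBoundary,
                 lowIntensityFrac = lowIntensityFrac,
                 paLowRange = paLowRange, paThetaSpan = paThetaSpan,
                 mergeTol = mergeTol, minSamples = minSamples, seed = seed),
            class = "ClusterParams")
}

#' Polar normalisation of two-colour intensities
#'
#' `theta = (2/pi) * atan2(Y, X)` in \[0,1\] (0 = pure allele-A signal,
#' 1 = pure allele-B signal) and `R = X + Y`. Cells with X = Y = 0 carry
#' no signal and are returned as NA sentinels.
#'
#' @param X,Y non-negative numeric vectors of allele-A and allele-B signal
#' @return list with `theta` and `R`
#' @export
#' @examples
#' normalizeIntensity(3, 1)$theta  # (2/pi) * atan(1/3)
normalizeIntensity <- function(X, Y) {
  stopifnot(all(X >= 0, na.rm = TRUE), all(Y >= 0, na.rm = TRUE))
  theta <- (2 / pi) * atan2(Y, X)
  R <- X + Y
  none <- !is.na(X) & !is.na(Y) & X == 0 & Y == 0
  theta[none] <- NA_real_
  R[none] <- NA_real_
  list(theta = theta, R = R)
}

# iteratively merge adjacent (theta-sorted) components whose means are
# closer than tol; moment-matched mean/sd, summed weight
.mergeComponents <- function(means, sds, weights, cls, tol) {
  repeat {
    K <- length(means)
    if (K < 2) break
    gaps <- diff(means)
    if (all(gaps >= tol)) break
    i <- which.min(gaps)  # merge the closest pair first
    w <- weights[i] + weights[i + 1]
    m <- (weights[i] * means[i] + weights[i + 1] * means[i + 1]) / w
    v <- (weights[i] * (sds[i]^2 + (means[i] - m)^2) +
            weights[i + 1] * (sds[i + 1]^2 + (means[i + 1] - m)^2)) / w
    means <- c(means[seq_len(i - 1)], m, means[-seq_len(i + 1)])
    sds <- c(sds[seq_len(i - 1)], sqrt(v), sds[-seq_len(i + 1)])
    weights <- c(weights[seq_len(i - 1)], w, weights[-seq_len(i + 1)])
    cls[cls == i + 1] <- i
    cls[cls > i + 1] <- cls[cls > i + 1] - 1L
  }
  list(means = means, sds = sds, weights = weights, cls = as.integer(cls))
}

.failedModel <- function(snpId, assignments) {
  new("ClusterModel", snpId = snpId, K = 0L,
      thetaMeans = numeric(), thetaSds = numeric(),
      rMeans = numeric(), rSds = numeric(), weights = numeric(),
      labels = character(), pattern = "FAILED_LOW_INTENSITY",
      scorable = FALSE, polymorphic = FALSE, assignments = assignments)
}

#' Fit a per-SNP cluster model in theta space
#'
#' Fits one-dimensional Gaussian mixtures (equal- and unequal-variance) to
#' the theta values of all with-signal samples for each K in
#' `params$kRange`, selects K by BIC, classifies the cluster pattern and
#' assigns genotype labels where the pattern permits. Samples with total
#' intensity below `rLowThreshold` (or no signal at all) are excluded from
#' the fit and carry assignment 0. The fit is deterministic.
#'
#' @param theta numeric vector of theta values (named by sample)
#' @param R numeric vector of total intensities
#' @param params a [clusterParams()]
#' @param snpId identifier stored in the model
#' @return a [ClusterModel-class]
#' @export
fitClusterModel <- function(theta, R, params = clusterParams(),
                            snpId = "SNP") {
  stopifnot(length(theta) == length(R))
  low <- is.na(theta) | is.na(R) | R < params$rLowThreshold
  assignments <- setNames(rep(0L, length(theta)), names(theta))
  if (sum(!low) < params$minSamples)
    return(.failedModel(snpId, assignments))

  th <- theta[!low]
  fit <- mclust::Mclust(th, G = params$kRange, modelNames = c("E", "V"),
                        verbose = FALSE)
  if (is.null(fit)) return(.failedModel(snpId, assignments))
  K <- fit$G
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(rep(as.numeric(fit$parameters$variance$sigmasq),
                  length.out = K))
  weights <- as.numeric(fit$parameters$pro)
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  cls <- match(fit$classification, ord)

  # coalesce boundary-truncation sub-components (see clusterParams)
  merged <- .mergeComponents(means, sds, weights, cls, params$mergeTol)
  means <- merged$means; sds <- merged$sds; weights <- merged$weights
  cls <- merged$cls; K <- length(means)
  assignments[!low] <- cls

  rMeans <- vapply(seq_len(K), function(k) {
    v <- R[!low][cls == k]; if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  rSds <- vapply(seq_len(K), function(k) {
    v <- R[!low][cls == k]; if (length(v) > 1) sd(v) else 0
  }, numeric(1))

  model <- new("ClusterModel", snpId = snpId, K = as.integer(K),
               thetaMeans = means, thetaSds = sds,
               rMeans = rMeans, rSds = rSds, weights = weights,
               labels = rep("none", K), pattern = "MONOMORPHIC",
               scorable = FALSE, polymorphic = FALSE,
               assignments = assignments)
  model@pattern <- classifyPattern(model, params)
  .labelModel(model, theta, R, params)
}

#' Classify the cluster pattern of a fitted model
#'
#' Applies the fixed precedence order: low-intensity, presence/absence,
#' multi-cluster, genome-specific, shifted, monomorphic. The taxonomy is
#' total: two-to-three-cluster models that neither span theta space nor
#' sit in one half fall back to `MULTI_CLUSTER_UNRESOLVABLE`.
#'
#' @param model a [ClusterModel-class] with assignments (0 = no signal)
#' @param params a [clusterParams()]
#' @return pattern label (character)
#' @export
classifyPattern <- function(model, params = clusterParams()) {
  lowFrac <- mean(model@assignments == 0L)
  if (lowFrac > params$lowIntensityFrac || model@K == 0L)
    return("FAILED_LOW_INTENSITY")
  means <- model@thetaMeans
  span <- max(means) - min(means)
  if (lowFrac > params$paLowRange[1] && lowFrac <= params$paLowRange[2] &&
      span <= params$paThetaSpan)
    return("PRESENCE_ABSENCE")
  K <- model@K
  if (K >= 4 || (K == 3 && model@weights[2] > params$excessHetWeight))
    return("MULTI_CLUSTER_UNRESOLVABLE")
  if (K >= 2 && span > params$thetaSep)
    return("GENOME_SPECIFIC")
  b <- params$shiftedBoundary
  if (K >= 2 && (all(means <= b) || all(means >= b)))
    return("SHIFTED")
  if (K == 1) return("MONOMORPHIC")
  "MULTI_CLUSTER_UNRESOLVABLE"
}

# assign genotype labels and flags according to the pattern
.labelModel <- function(model, theta, R, params) {
  p <- model@pattern
  K <- model@K
  if (p == "GENOME_SPECIFIC") {
    model@labels <- if (K == 2) c("AA", "BB")
                    else c("AA", rep("AB", K - 2), "BB")
    model@scorable <- TRUE
    model@polymorphic <- TRUE
  } else if (p == "MONOMORPHIC") {
    model@labels <- if (model@thetaMeans[1] < 0.5) "AA" else "BB"
    model@scorable <- TRUE
    model@polymorphic <- FALSE
  } else if (p == "PRESENCE_ABSENCE") {
    # collapse to two R-separated components: with-signal vs no-signal
    sig <- model@assignments > 0L
    presentLabel <- if (mean(theta[sig]) < 0.5) "AA" else "BB"
    absentLabel <- if (presentLabel == "AA") "BB" else "AA"
    lowTheta <- theta[!sig]
    lowR <- R[!sig]
    model@K <- 2L
    model@thetaMeans <- c(mean(theta[sig]),
                          mean(lowTheta, na.rm = TRUE))
    model@thetaSds <- c(max(sd(theta[sig]), 1e-6),
                        max(sd(lowTheta, na.rm = TRUE), 1e-6, na.rm = TRUE))
    model@rMeans <- c(mean(R[sig]), mean(lowR, na.rm = TRUE))
    model@rSds <- c(max(sd(R[sig]), 1e-6),
                    max(sd(lowR, na.rm = TRUE), 1e-6, na.rm = TRUE))
    model@weights <- c(mean(sig), 1 - mean(sig))
    model@labels <- c(presentLabel, absentLabel)
    a <- ifelse(sig, 1L, 2L)
    names(a) <- names(model@assignments)
    model@assignments <- a
    model@scorable <- TRUE
    model@polymorphic <- TRUE
  } else if (p == "SHIFTED") {
    model@labels <- rep("none", K)
    model@scorable <- FALSE
    model@polymorphic <- TRUE
  } else if (p == "MULTI_CLUSTER_UNRESOLVABLE") {
    model@labels <- rep("none", K)
    model@scorable <- FALSE
    model@polymorphic <- K >= 2
  } else { # FAILED_LOW_INTENSITY
    model@labels <- rep("none", K)
    model@scorable <- FALSE
    model@polymorphic <- FALSE
  }
  validObject(model)
  model
}

#' Rescue a shifted (homoeolog-compressed) cluster model
#'
#' When a monomorphic homoeolog co-hybridises, the true genotype clusters
#' are compressed into one half of theta space and mislabelled by routine
#' analysis; the cluster definition can nevertheless be adjusted to the
#' correct genotype positions, rendering the SNP perfectly scorable. This
#' automates that adjustment: the extreme components are relabelled AA and
#' BB (in theta order) and the middle component, if present, AB.
#' Sample-to-component assignments are unchanged.
#'
#' @param model a [ClusterModel-class] with pattern `SHIFTED` and 2-3
#'   components
#' @return the adjusted model with pattern `SHIFTED_RESCUED`
#' @export
rescueShifted <- function(model) {
  if (clusterPattern(model) != "SHIFTED")
    stop("rescue applies only to SHIFTED models")
  if (model@K > 3L)
    stop("more than 3 components: refusing rescue (stays unresolvable)")
  model@labels <- if (model@K == 2L) c("AA", "BB") else c("AA", "AB", "BB")
  model@pattern <- "SHIFTED_RESCUED"
  model@scorable <- TRUE
  model@polymorphic <- TRUE
  validObject(model)
  model
}

#' Call genotypes from a cluster model
#'
#' Each sample is assigned the labelled component with the highest
#' responsibility under the fitted theta mixture; the confidence score is
#' the margin between the best and second-best labelled responsibility
#' (so a sample equidistant between two clouds scores 0). Samples are
#' NO_CALL when the SNP is unscorable, the signal is below the
#' low-intensity threshold (except for presence/absence markers, which are
#' scored by signal versus no-signal), or the confidence falls below the
#' no-call threshold.
#'
#' @param model a [ClusterModel-class]
#' @param theta,R numeric vectors for the samples to call (named)
#' @param params a [clusterParams()]
#' @return data.frame `snpId, sampleId, call, confidence`
#' @export
callGenotypes <- function(model, theta, R, params = clusterParams()) {
  n <- length(theta)
  ids <- names(theta) %||% as.character(seq_len(n))
  out <- data.frame(snpId = rep(model@snpId, n), sampleId = ids,
                    call = rep("NO_CALL", n), confidence = rep(0, n))
  if (!isScorable(model)) return(out)
  low <- is.na(theta) | is.na(R) | R < params$rLowThreshold

  if (clusterPattern(model) == "PRESENCE_ABSENCE") {
    present <- which(model@labels != "none")
    lab <- model@labels
    out$call <- ifelse(low, lab[2], lab[1])
    out$confidence <- 1
    return(out)
  }

  labelled <- which(model@labels != "none")
  if (!length(labelled)) return(out)
  dens <- vapply(labelled, function(k)
    model@weights[k] * dnorm(theta, model@thetaMeans[k],
                             max(model@thetaSds[k], 1e-9)),
    numeric(n))
  dens <- matrix(dens, nrow = n)
  tot <- rowSums(dens)
  resp <- dens / ifelse(tot > 0, tot, 1)
  best <- max.col(resp, ties.method = "first")
  conf <- if (length(labelled) == 1) resp[, 1] else {
    sorted <- t(apply(resp, 1, sort, decreasing = TRUE))
    sorted[, 1] - sorted[, 2]
  }
  conf[tot == 0] <- 0
  call <- model@labels[labelled][best]
  noCall <- low | conf < params$noCallThreshold
  out$call <- ifelse(noCall, "NO_CALL", call)
  out$confidence <- ifelse(is.na(conf), 0, conf)
  out
}

#' Fit cluster models for every SNP of an intensity matrix
#'
#' @param intensities an [IntensityMatrix-class]
#' @param params a [clusterParams()]
#' @return named list of [ClusterModel-class] objects
#' @export
fitClusterModels <- function(intensities, params = clusterParams()) {
  th <- thetaValues(intensities); rr <- signalR(intensities)
  snps <- rownames(th) %||% as.character(seq_len(nrow(th)))
  models <- lapply(seq_len(nrow(th)), function(i)
    fitClusterModel(setNames(th[i, ], colnames(th)), rr[i, ], params,
                    snpId = snps[i]))
  names(models) <- snps
  models
}

#' Call genotypes for a whole panel
#'
#' @param models named list of [ClusterModel-class] objects
#' @param intensities an [IntensityMatrix-class] with matching SNP rows
#' @param params a [clusterParams()]
#' @return data.frame of calls for all SNPs and samples
#' @export
callGenotypesPanel <- function(models, intensities,
                               params = clusterParams()) {
  th <- thetaValues(intensities); rr <- signalR(intensities)
  do.call(rbind, lapply(names(models), function(s) {
    callGenotypes(models[[s]], setNames(th[s, ], colnames(th)), rr[s, ],
                  params)
  }))
}

.modelToList <- function(m) {
  list(snpId = m@snpId, K = m@K, pattern = m@pattern,
       scorable = m@scorable, polymorphic = m@polymorphic,
       thetaMeans = m@thetaMeans, thetaSds = m@thetaSds,
       rMeans = m@rMeans, rSds = m@rSds, weights = m@weights,
       labels = m@labels,
       samples = names(m@assignments), assignments = unname(m@assignments))
}

.modelFromList <- function(l) {
  new("ClusterModel", snpId = l$snpId, K = as.integer(l$K),
      thetaMeans = as.numeric(l$thetaMeans),
      thetaSds = as.numeric(l$thetaSds),
      rMeans = as.numeric(l$rMeans), rSds = as.numeric(l$rSds),
      weights = as.numeric(l$weights),
      labels = as.character(l$labels), pattern = l$pattern,
      scorable = l$scorable, polymorphic = l$polymorphic,
      assignments = setNames(as.integer(l$assignments),
                             as.character(l$samples)))
}

#' Build, write and read cluster files
#'
#' A cluster file records, per scorable SNP, the fitted component
#' positions, genotype labels and pattern so that genotypes can be called
#' automatically on new samples and compared across laboratories. The file
#' format is JSON; vendor binary formats are explicitly not produced.
#'
#' @param models named list of [ClusterModel-class] objects
#' @param path optional path to write JSON to
#' @param scorableOnly keep only scorable SNPs (default TRUE)
#' @return invisibly, the list representation of the cluster file
#' @export
buildClusterFile <- function(models, path = NULL, scorableOnly = TRUE) {
  keep <- if (scorableOnly) Filter(isScorable, models) else models
  cf <- list(version = 1L,
             nSNPs = length(keep),
             snps = lapply(unname(keep), .modelToList))
  if (!is.null(path))
    jsonlite::write_json(cf, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(cf)
}

#' @rdname buildClusterFile
#' @export
readClusterFile <- function(path) {
  cf <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  models <- lapply(cf$snps, .modelFromList)
  names(models) <- vapply(models, function(m) m@snpId, character(1))
  models
}

#' Derive a species-specific (diploid) cluster file
#'
#' Refits every SNP of a tetraploid cluster-model set on the samples of
#' one ancestral diploid species. SNPs whose probe is specific to the
#' other subgenome collapse to no-signal in the diploid and are marked
#' failed; the remainder are refitted so that cluster positions follow
#' the diploid clouds (markers that were homoeolog-compressed in the
#' tetraploid typically resolve to well-separated diploid clusters).
#'
#' @param models tetraploid models (named list)
#' @param intensities an [IntensityMatrix-class] carrying the diploid
#'   samples (species tags required)
#' @param species `"OLERACEA"` or `"RAPA"`; must be present among the
#'   sample species tags
#' @param params a [clusterParams()]
#' @return list with `models` (the refitted per-SNP models), and `summary`
#'   (named counts: `scorable`, `polymorphic`, `failed`)
#' @export
deriveDiploidClusterFile <- function(models, intensities, species,
                                     params = clusterParams()) {
  sel <- sampleSpecies(intensities) == species
  if (!any(sel))
    stop("no samples with species tag ", species)
  th <- thetaValues(intensities)[, sel, drop = FALSE]
  rr <- signalR(intensities)[, sel, drop = FALSE]
  snps <- intersect(names(models), rownames(th))
  out <- lapply(snps, function(s)
    fitClusterModel(setNames(th[s, ], colnames(th)), rr[s, ], params,
                    snpId = s))
  names(out) <- snps
  # shifted patterns resolve in the diploid: rescue is not needed, but a
  # residual shifted call is still scorable after relabelling
  out <- lapply(out, function(m)
    if (clusterPattern(m) == "SHIFTED" && m@K <= 3L) rescueShifted(m) else m)
  scorable <- vapply(out, isScorable, logical(1))
  poly <- vapply(out, function(m) isScorable(m) && isPolymorphic(m),
                 logical(1))
  failed <- vapply(out, function(m)
    clusterPattern(m) == "FAILED_LOW_INTENSITY", logical(1))
  list(models = out,
       summary = c(scorable = sum(scorable), polymorphic = sum(poly),
                   failed = sum(failed)))
}
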