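# Kosambi distances, bins, anchoring, concordance and segments.

test_that("kosambi closed form, round trip and lower bound", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3), tolerance = 1e-12)
  r <- seq(0, 0.499, by = 0.001)
  expect_equal(kosambiInverse(kosambi(r)), r, tolerance = 1e-12)
  expect_true(all(diff(kosambi(r)) > 0))
  # d >= 100 r with equality only at 0
  expect_true(all(kosambi(r[-1]) > 100 * r[-1]))
  expect_error(kosambi(0.5), "0.5")
  expect_error(kosambi(-0.1), "0.5")
  expect_error(kosambiInverse(-1), ">= 0")
})

test_that("estimateR counts discordant lines over joint information", {
  v <- rep(c("A", "B"), 50)
  expect_equal(estimateR(v, v), 0)
  v2 <- v; v2[c(3, 10)] <- ifelse(v[c(3, 10)] == "A", "B", "A")
  expect_equal(estimateR(v, v2), 0.02)
  # missing cells drop out of the denominator
  v3 <- v; v3[1:20] <- NA
  expect_equal(estimateR(v, v3), 0)
  expect_true(is.na(estimateR(v, rep(NA_character_, 100))))
})

test_that("recombination estimates are unbiased at the Kosambi scale", {
  set.seed(61)
  trueD <- kosambi(0.25)  # 27.465 cM
  r <- kosambiInverse(trueD)
  est <- replicate(400, mean(rbinom(124, 1, r)))
  # mean estimate within the binomial standard error of truth
  expect_lt(abs(mean(est) - r), 3 * sqrt(r * (1 - r) / 124) / sqrt(400))
})

test_that("findBins merges identical vectors and respects wildcards", {
  g <- matrix(c("A", "A", "A",
                "A", "A", "A",
                "B", "B", "A"), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  # m1 and m2 identical -> one bin; m3 differs in line 3 -> new bin
  expect_equal(unname(findBins(g)), c(1L, 1L, 2L))
  # a single discordant line splits neighbours
  g2 <- g; g2[1, 2] <- "B"
  expect_equal(unname(findBins(g2)), c(1L, 2L, 3L))
  # missing acts as wildcard but a merge needs joint information
  g3 <- matrix(c("A", NA, "A",
                 "B", NA, "B"), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("m1", "m2", "m3")))
  expect_equal(unname(findBins(g3)), c(1L, 2L, 3L))
})

test_that("bin boundaries equal simulated crossover intervals", {
  cfg <- simConfig(seed = 62, dhMissingRate = 0, markersPerLg = 40,
                   lgLengths = c(LG1 = 80, LG2 = 60))
  dh <- simulateDH(cfg)
  for (lg in c("LG1", "LG2")) {
    mk <- dh$map$marker[dh$map$lg == lg]
    bins <- findBins(dh$geno[, mk])
    truthBreaks <- which(colSums(dh$truth$crossovers[[lg]]) > 0)
    expect_equal(which(diff(bins) > 0), truthBreaks,
                 ignore_attr = TRUE, info = lg)
    # within-bin adjacent markers have r = 0
    for (j in which(diff(bins) == 0))
      expect_equal(estimateR(dh$geno[, mk[j]], dh$geno[, mk[j + 1]]), 0)
  }
})

test_that("physical anchoring applies the identity threshold and
           ambiguity rules", {
  hits <- data.frame(
    marker = c("m1", "m2", "m2", "m3", "m4", "m4"),
    chrom = c("A01", "A01", "C01", "A01", "A01", "A01"),
    bp = c(100, 200, 250, 300, 400, 900),
    identity = c(99, 95, 95, 84.9, 97, 92))
  a <- assignPhysical(hits, minIdentity = 85)
  expect_false(a$ambiguous[a$marker == "m1"])
  # co-optimal hits on different chromosomes -> ambiguous
  expect_true(a$ambiguous[a$marker == "m2"])
  # best hit below 85 % -> unanchored
  expect_true(a$unanchored[a$marker == "m3"])
  expect_true(is.na(a$chrom[a$marker == "m3"]))
  # best hit wins among same-chromosome hits
  expect_equal(a$bp[a$marker == "m4"], 400)
  expect_message(assignPhysical(rbind(hits,
    data.frame(marker = "m5", chrom = NA, bp = NA, identity = NA))),
    "malformed")
})

test_that("density statistics reproduce printed-table conventions", {
  counts <- data.frame(lg = c("L1", "L2"),
                       bins = c(10, 20), physLoci = c(100, 300),
                       physKb = c(1000, 6000), mappedLoci = c(50, 150),
                       mapCm = c(25, 75))
  st <- mapDensityStats(counts)
  expect_equal(st$markersPerCm, c(2, 2, 2))
  expect_equal(st$cmPerMarker, c(0.5, 0.5, 0.5))
  expect_equal(st$kbPerMarker, c(10, 20, 17.5))
  expect_equal(st$lg[3], "Total")
  # half-up rounding at two decimals
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(11.985, 2), 11.99)
})

test_that("computeMapStats reports totals, sentinels and gap lists", {
  map <- data.frame(marker = sprintf("m%d", 1:6),
                    lg = c(rep("L1", 5), "L2"),
                    cM = c(0, 1, 2, 12, 13, 0))
  anchors <- data.frame(marker = map$marker,
                        chrom = "A01",
                        bp = c(0, 1e5, 2e5, 9e5, 9.5e5, 1e5),
                        identity = 99, ambiguous = FALSE,
                        unanchored = FALSE)
  ms <- computeMapStats(map, anchors, geneticGapMin = 9,
                        physicalGapKb = 500)
  # single-marker LG: zero length, undefined densities, no gaps
  l2 <- ms$stats[ms$stats$lg == "L2", ]
  expect_true(is.na(l2$markersPerCm) && is.na(l2$cmPerMarker))
  expect_equal(ms$geneticGaps$gapCm, 10)
  expect_equal(ms$physicalGaps$gapKb, 700)
  tot <- ms$stats[ms$stats$lg == "Total", ]
  expect_equal(tot$mappedLoci, 6)
  expect_equal(tot$bins, sum(ms$stats$bins[ms$stats$lg != "Total"]))
})

test_that("concordance classification recovers planted homoeologous
           swaps exactly and sums to one", {
  cfg <- simConfig(seed = 63, dhMissingRate = 0, swapFrac = 0.05,
                   markersPerLg = 50,
                   lgLengths = c(LG1 = 90, LG2 = 90, LG3 = 90, LG4 = 90))
  dh <- simulateDH(cfg)
  anch <- assignPhysical(dh$anchors)
  conc <- classifyConcordance(dh$map, anch, dh$homoeology, dh$lgChrom)
  expect_equal(sum(conc$summary), 1)
  expect_equal(unname(conc$summary["HOMOEOLOGOUS"]), 0.05)
  hom <- conc$records$marker[conc$records$status == "HOMOEOLOGOUS"]
  expect_setequal(hom, dh$truth$swapped)
  # LG without correspondence -> UNANCHORED with warning
  expect_warning(
    c2 <- classifyConcordance(dh$map, anch, dh$homoeology,
                              dh$lgChrom[-1, ]), "correspondence")
  expect_true(all(c2$records$status[c2$records$lg == "LG1"] ==
                    "UNANCHORED"))
})

test_that("translocated blocks are detected within one marker of truth", {
  cfg <- simConfig(seed = 64, dhMissingRate = 0, swapFrac = 0.05,
                   translocation = list(lg = "LG3", start = 15, len = 8,
                                        destChrom = "A01"))
  dh <- simulateDH(cfg)
  anch <- assignPhysical(dh$anchors)
  conc <- classifyConcordance(dh$map, anch, dh$homoeology, dh$lgChrom)
  segs <- detectSegments(conc$records, minRun = 3)
  blk <- segs[segs$lg == "LG3" & segs$chrom == "A01", ]
  expect_equal(nrow(blk), 1)
  truthIdx <- match(c(dh$truth$block$startMarker, dh$truth$block$endMarker),
                    dh$map$marker)
  gotIdx <- match(c(blk$startMarker, blk$endMarker), dh$map$marker)
  expect_lte(abs(gotIdx[1] - truthIdx[1]), 1)
  expect_lte(abs(gotIdx[2] - truthIdx[2]), 1)
  # isolated discordant markers do not form segments
  iso <- data.frame(marker = c("x1", "x2", "x3"), lg = "L9",
                    cM = 1:3, chrom = c("A01", "C05", "A01"),
                    status = c("CONCORDANT", "DISCORDANT", "CONCORDANT"),
                    bp = 1:3 * 1e5)
  expect_equal(nrow(detectSegments(iso, minRun = 3)), 0)
})

test_that("buildGeneticMap accumulates Kosambi distances along bins", {
  cfg <- simConfig(seed = 65, dhMissingRate = 0, markersPerLg = 30,
                   lgLengths = c(LG1 = 60))
  dh <- simulateDH(cfg)
  gm <- buildGeneticMap(dh$geno, lg = "LG1")
  expect_true(all(diff(gm$cM) >= 0))
  # estimated total length within 35 % of simulated truth at n = 124
  expect_lt(abs(max(gm$cM) - max(dh$map$cM)) / max(dh$map$cM), 0.35)
  # co-segregating markers sit at identical positions
  sameBin <- which(diff(gm$bin) == 0)
  expect_true(all(diff(gm$cM)[sameBin] == 0))
})
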