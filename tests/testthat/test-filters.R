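# The five-step filter cascade and its attrition report.

# small candidate table builder with sensible defaults
mkCand <- function(n = 1, ...) {
  base <- data.frame(snpId = sprintf("s%02d", seq_len(n)),
                     chrom = "chr1", pos = 1000 + seq_len(n) * 200,
                     ref = "A", alts = "G", nAlleles = 2L,
                     upClean = TRUE, downClean = TRUE,
                     upFlank = "", downFlank = "",
                     missingFrac = 0.1, hetFrac = 0.1, altFreq = 0.5,
                     refMismatch = FALSE, designScore = 0.9)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

test_that("flank annotation marks sides clean per window content", {
  set.seed(31)
  g <- randomGenomeString(500, 31)
  ref <- ReferenceGenome(c(chr1 = g))
  mkvs <- function(pos) {
    refs <- vapply(pos, function(p) substr(g, p, p), character(1))
    alts <- vapply(refs, function(r)
      setdiff(c("A", "C", "G", "T"), r)[1], character(1))
    toyVariantSet("g1", "SHORT_ILLUMINA", "chr1",
                  data.frame(pos = pos, ref = refs, alt = alts,
                             depth = 20, altFrac = 0.9), chromLen = 500)
  }
  # isolated SNP mid-chromosome: both sides clean
  m <- aggregatePanel(list(mkvs(250)), ref)
  cand <- annotateFlanks(m, ref)
  expect_true(cand$upClean && cand$downClean)

  # second variant 59 bp upstream: upstream unclean, downstream clean
  m2 <- aggregatePanel(list(mkvs(c(250, 250 - 59))), ref)
  cand2 <- annotateFlanks(m2, ref)
  row <- cand2[cand2$pos == 250, ]
  expect_false(row$upClean)
  expect_true(row$downClean)
  expect_true(.subset2(filterFlanking(row)$pass, "snpId") == row$snpId)

  # variant at position 30 (upstream runs off) with a neighbour 10 bp
  # downstream: both sides unclean, fails step 1
  m3 <- aggregatePanel(list(mkvs(c(30, 40))), ref)
  cand3 <- annotateFlanks(m3, ref)
  row3 <- cand3[cand3$pos == 30, ]
  expect_false(row3$upClean || row3$downClean)
  expect_equal(nrow(filterFlanking(row3)$pass), 0)

  # N in the flank window makes the side unclean
  gN <- paste0(substr(g, 1, 219), "N", substr(g, 221, 500))
  refN <- ReferenceGenome(c(chr1 = gN))
  mN <- aggregatePanel(list(mkvs(250)), refN)
  candN <- annotateFlanks(mN, refN)
  expect_false(candN$upClean)
  expect_true(candN$downClean)
})

test_that("boundary values are retained (strict inequalities)", {
  th <- filterThresholds()
  cand <- mkCand(4,
                 missingFrac = c(0.70, 0.75, 0.1, 0.1),
                 hetFrac = c(0.1, 0.1, 0.40, 0.1),
                 altFreq = c(0.5, 0.5, 0.5, 0.8))
  res <- filterConfidence(cand, th)
  # exact 0.70 missing, exact 0.40 het and exact 0.8 frequency all pass
  expect_setequal(res$pass$snpId, c("s01", "s03", "s04"))
  expect_equal(res$fail$snpId, "s02")

  # undefined frequency (all-missing) fails the confidence step
  expect_equal(
    nrow(filterConfidence(mkCand(1, altFreq = NA_real_), th)$pass), 0)

  # score exactly 0.6 passes; 0.59 fails; missing score fails by default
  sc <- mkCand(3, designScore = c(0.6, 0.59, NA))
  expect_equal(filterDesignScore(sc, th)$pass$snpId, "s01")
  thKeep <- filterThresholds(failMissingScore = FALSE)
  expect_setequal(filterDesignScore(sc, thKeep)$pass$snpId, c("s01", "s03"))
})

test_that("transversion step follows the configured mode", {
  atcg <- filterThresholds(transversionMode = "AT_CG_ONLY")
  alltv <- filterThresholds(transversionMode = "ALL_TRANSVERSIONS")
  cand <- mkCand(4, ref = c("A", "A", "C", "A"),
                 alts = c("G", "T", "G", "C"))
  # A/G transition retained under either mode
  expect_true("s01" %in% filterTransversion(cand, atcg)$pass$snpId)
  expect_true("s01" %in% filterTransversion(cand, alltv)$pass$snpId)
  # A/T and C/G excluded under AT_CG_ONLY; A/C only under ALL_TRANSVERSIONS
  expect_setequal(filterTransversion(cand, atcg)$fail$snpId, c("s02", "s03"))
  expect_setequal(filterTransversion(cand, alltv)$fail$snpId,
                  c("s02", "s03", "s04"))
})

test_that("multi-allele step counts total distinct alleles", {
  cand <- mkCand(2, alts = c("G", "G,T"), nAlleles = c(2L, 3L))
  res <- filterMultiallelic(cand)
  expect_equal(res$pass$snpId, "s01")
  expect_equal(res$fail$snpId, "s02")
})

test_that("cascade report telescopes and attributes first failures", {
  cfg <- simConfig(seed = 33, nSNP = 400, nGenotypes = 20)
  sim <- simulateAllotetraploid(cfg)
  panel <- simulateVariantPanel(sim$reference, cfg)
  m <- aggregatePanel(panel$variantSets, sim$reference)
  cands <- addDesignScores(annotateFlanks(m, sim$reference),
                           panel$designScores)
  casc <- runCascade(cands)
  rep <- casc$report
  # telescoping: remaining(k) = remaining(k-1) - excluded(k)
  expect_equal(rep$remaining[-1], head(rep$remaining, -1) - rep$excluded[-1])
  expect_equal(rep$remaining[1], nrow(cands))
  expect_true(all(diff(rep$remaining) <= 0))
  # per-step counts equal simulator truth exactly
  tr <- panel$truth
  for (s in c("flanking", "multiallelic", "confidence", "design_score",
              "transversion")) {
    expect_equal(rep$excluded[rep$step == s], sum(tr$expectedStep == s),
                 info = s)
  }
  expect_setequal(casc$survivors$snpId,
                  tr$snpId[tr$expectedStep == "pass"])
  # each failure attributed to its first failing step
  expect_equal(sort(table(casc$failures$failedStep)),
               sort(table(tr$expectedStep[tr$expectedStep != "pass"])),
               ignore_attr = TRUE)

  # empty candidate list: all-zero report
  emptyRep <- runCascade(cands[0, , drop = FALSE])$report
  expect_true(all(emptyRep$excluded == 0) && all(emptyRep$remaining == 0))
})

test_that("survivor set is invariant under step permutation", {
  cfg <- simConfig(seed = 34, nSNP = 250, nGenotypes = 16)
  sim <- simulateAllotetraploid(cfg)
  panel <- simulateVariantPanel(sim$reference, cfg)
  m <- aggregatePanel(panel$variantSets, sim$reference)
  cands <- addDesignScores(annotateFlanks(m, sim$reference),
                           panel$designScores)
  baseline <- sort(runCascade(cands)$survivors$snpId)
  steps <- c("flanking", "multiallelic", "confidence", "design_score",
             "transversion")
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(steps)
    expect_equal(sort(runCascade(cands, stepOrder = perm)$survivors$snpId),
                 baseline, info = paste(perm, collapse = ">"))
  }
  expect_error(runCascade(cands, stepOrder = steps[-1]), "permutation")
})

test_that("relaxing any single threshold never shrinks the survivor set", {
  cfg <- simConfig(seed = 35, nSNP = 250, nGenotypes = 16)
  sim <- simulateAllotetraploid(cfg)
  panel <- simulateVariantPanel(sim$reference, cfg)
  m <- aggregatePanel(panel$variantSets, sim$reference)
  cands <- addDesignScores(annotateFlanks(m, sim$reference),
                           panel$designScores)
  base <- runCascade(cands)$survivors$snpId
  relaxed <- list(
    filterThresholds(maxMissing = 0.9),
    filterThresholds(maxHet = 0.7),
    filterThresholds(freqBand = c(0.01, 0.99)),
    filterThresholds(minDesignScore = 0.1),
    filterThresholds(maxAlleles = 4))
  for (th in relaxed)
    expect_true(all(base %in% runCascade(cands, th)$survivors$snpId))
})
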