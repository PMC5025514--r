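# Probe extraction and genome-wide match counting.

test_that("extractProbes returns clean-side probes with correct geometry", {
  set.seed(51)
  g <- randomGenomeString(200, 51)
  ref <- ReferenceGenome(c(chr1 = g))
  cand <- data.frame(snpId = "s1", chrom = "chr1", pos = 100,
                     ref = substr(g, 100, 100),
                     alts = "X", upClean = TRUE, downClean = TRUE)
  cand$alts <- setdiff(c("A", "C", "G", "T"), cand$ref)[1]
  pr <- extractProbes(cand, ref)
  expect_equal(nrow(pr), 2)
  expect_setequal(pr$side, c("UPSTREAM", "DOWNSTREAM"))
  # upstream probe is the 50 bp immediately left of the SNP base
  expect_identical(pr$probeSeq[pr$side == "UPSTREAM"], substr(g, 50, 99))
  # downstream probe is the hand-computed reverse complement
  expect_identical(pr$probeSeq[pr$side == "DOWNSTREAM"],
                   revcompStr(substr(g, 101, 150)))
  expect_true(all(nchar(pr$probeSeq) == 50))

  # only the clean side yields a probe; no clean side yields none
  prUp <- extractProbes(transform(cand, downClean = FALSE), ref)
  expect_equal(prUp$side, "UPSTREAM")
  expect_equal(nrow(extractProbes(
    transform(cand, upClean = FALSE, downClean = FALSE), ref)), 0)
})

test_that("assay class is INFINIUM_I exactly for A/T and C/G pairs", {
  set.seed(52)
  g <- randomGenomeString(200, 52)
  ref <- ReferenceGenome(c(chr1 = g))
  mk <- function(refA, altA) data.frame(
    snpId = "s1", chrom = "chr1", pos = 100, ref = refA, alts = altA,
    upClean = TRUE, downClean = FALSE)
  expect_equal(unique(extractProbes(mk("C", "G"), ref)$assayClass),
               "INFINIUM_I")
  expect_equal(unique(extractProbes(mk("T", "A"), ref)$assayClass),
               "INFINIUM_I")
  expect_equal(unique(extractProbes(mk("A", "G"), ref)$assayClass),
               "INFINIUM_II")
})

test_that("match counting agrees with the brute-force oracle on planted
           repeats including the 34/35 boundary", {
  set.seed(53)
  plant <- function(g, frag, at) {
    paste0(substr(g, 1, at - 1), frag,
           substr(g, at + nchar(frag), nchar(g)))
  }
  for (rep in 1:12) {
    g <- randomGenomeString(8000, 530 + rep)
    probe <- substr(g, 3001, 3050)
    kind <- rep %% 4
    if (kind == 1) {        # forward 35-bp copy
      g <- plant(g, substr(probe, 1, 35), 6000)
    } else if (kind == 2) { # reverse-complement 35-bp copy
      g <- plant(g, revcompStr(substr(probe, 1, 35)), 6000)
    } else if (kind == 3) { # 34-bp copy: below the run threshold
      # guard the trailing base so the run cannot extend to 35 by chance
      blocker <- setdiff(c("A", "C", "G", "T"), substr(probe, 35, 35))[1]
      g <- plant(g, paste0(substr(probe, 1, 34), blocker), 6000)
    }                       # kind 0: no extra copy
    ref <- ReferenceGenome(c(chr1 = g))
    got <- countProbeMatches(probe, ref, minRun = 35)
    want <- probeMatchOracle(probe, c(chr1 = g), minRun = 35)
    expect_identical(got, want, info = paste("kind", kind))
    expect_identical(want, if (kind %in% 1:2) 2L else 1L)
  }
  # multi-chromosome case
  g1 <- randomGenomeString(4000, 61)
  probe <- substr(g1, 1001, 1050)
  g2 <- plant(randomGenomeString(4000, 62), substr(probe, 10, 46), 2000)
  ref <- ReferenceGenome(c(chr1 = g1, chr2 = g2))
  expect_identical(countProbeMatches(probe, ref),
                   probeMatchOracle(probe, c(chr1 = g1, chr2 = g2)))
})

test_that("match counting rejects undesignable probes and bad minRun", {
  ref <- ReferenceGenome(c(chr1 = randomGenomeString(1000, 54)))
  expect_error(countProbeMatches("ACGTN", ref, minRun = 4), "ACGT")
  expect_error(countProbeMatches("ACGTACGT", ref, minRun = 9), "length")
})

test_that("strand symmetry: reverse-complementing the reference leaves
           counts unchanged", {
  set.seed(55)
  g <- randomGenomeString(6000, 55)
  probes <- substring(g, c(501, 2001, 4001), c(550, 2050, 4050))
  ref <- ReferenceGenome(c(chr1 = g))
  refRC <- ReferenceGenome(c(chr1 = revcompStr(g)))
  expect_identical(countProbeMatches(probes, ref),
                   countProbeMatches(probes, refRC))
})

test_that("increasing minRun never increases a match count", {
  set.seed(56)
  for (i in 1:3) {
    g <- randomGenomeString(5000, 560 + i)
    # plant a partial copy to create non-trivial counts
    probe <- substr(g, 2001, 2050)
    g <- paste0(substr(g, 1, 3999), substr(probe, 1, 40),
                substr(g, 4040, 5000))
    ref <- ReferenceGenome(c(chr1 = g))
    counts <- vapply(c(35, 38, 41, 45, 50), function(w)
      countProbeMatches(probe, ref, minRun = w), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("probe uniqueness rises with subgenome divergence", {
  frac1 <- vapply(c(0, 0.05, 0.3), function(d) {
    cfg <- simConfig(seed = 57, nSNP = 60, chromLength = 3e4,
                     divergence = d)
    sim <- simulateAllotetraploid(cfg)
    panel <- simulateVariantPanel(sim$reference, cfg)
    m <- aggregatePanel(panel$variantSets, sim$reference)
    cands <- addDesignScores(annotateFlanks(m, sim$reference),
                             panel$designScores)
    surv <- runCascade(cands)$survivors
    pt <- probeTable(surv, sim$reference)
    mean(snpMatchCounts(pt)$matchCount == 1)
  }, numeric(1))
  # identical subgenomes: every probe matches both homoeologs
  expect_equal(frac1[1], 0)
  expect_true(all(diff(frac1) >= 0))
  # at 30 % divergence essentially every probe is unique
  expect_gte(frac1[3], 0.99)
})

test_that("rankAndSelect enforces cap, quotas and deterministic ties", {
  snps <- data.frame(snpId = c("a", "b", "c", "d"),
                     matchCount = c(1, 1, 2, 3),
                     designScore = c(0.9, 0.95, 0.8, 0.99))
  sel <- rankAndSelect(snps, selectionPolicy(maxMatches = 2))
  # the count-3 SNP is excluded; fewest matches first, score breaks ties
  expect_equal(sel$snpId, c("b", "a", "c"))

  # all counts equal: selection reduces to tie-breaker order
  eq <- data.frame(snpId = c("z", "y", "x"), matchCount = 1,
                   designScore = c(0.5, 0.5, 0.9))
  expect_equal(rankAndSelect(eq)$snpId, c("x", "y", "z"))

  # quota on the count-2 class
  many <- data.frame(snpId = sprintf("s%03d", 1:100),
                     matchCount = rep(c(1, 2), each = 50),
                     designScore = runif(100))
  sel2 <- rankAndSelect(many, selectionPolicy(maxMatches = 2,
                                              quotas = c("2" = 10)))
  expect_equal(sum(sel2$matchCount == 1), 50)
  expect_equal(sum(sel2$matchCount == 2), 10)

  expect_equal(nrow(rankAndSelect(many[0, ])), 0)
})
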