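# Theta-space cluster fitting, pattern taxonomy, rescue and calling.

test_that("polar normalisation has the closed-form and invariance
           properties", {
  expect_equal(normalizeIntensity(1, 1)$theta, 0.5)
  expect_equal(normalizeIntensity(5, 0)$theta, 0)
  expect_equal(normalizeIntensity(0, 5)$theta, 1)
  expect_equal(normalizeIntensity(3, 1)$theta, (2 / pi) * atan(1 / 3),
               tolerance = 1e-12)
  expect_equal(round(normalizeIntensity(3, 1)$theta, 4), 0.2048)
  # no-signal sentinel
  nz <- normalizeIntensity(0, 0)
  expect_true(is.na(nz$theta) && is.na(nz$R))
  # theta invariant under common scaling, R linear
  x <- runif(20, 0.1, 2); y <- runif(20, 0.1, 2)
  expect_equal(normalizeIntensity(3 * x, 3 * y)$theta,
               normalizeIntensity(x, y)$theta)
  expect_equal(normalizeIntensity(3 * x, 3 * y)$R,
               3 * normalizeIntensity(x, y)$R)
  # monotone in Y/X
  th <- normalizeIntensity(c(4, 2, 1), c(1, 2, 4))$theta
  expect_true(all(diff(th) > 0))
})

test_that("component count is recovered for planted 1/3/5-cloud SNPs", {
  p <- clusterParams()
  c3 <- cloudTheta(c(0.05, 0.50, 0.95), c(0.4, 0.2, 0.4), 200, 0.03, 71)
  m3 <- fitClusterModel(c3$theta, c3$R, p)
  expect_equal(m3@K, 3L)
  expect_equal(m3@thetaMeans, c(0.05, 0.50, 0.95), tolerance = 0.02)
  expect_equal(clusterPattern(m3), "GENOME_SPECIFIC")

  c1 <- cloudTheta(0.5, 1, 200, 0.03, 72)
  m1 <- fitClusterModel(c1$theta, c1$R, p)
  expect_equal(m1@K, 1L)
  expect_equal(clusterPattern(m1), "MONOMORPHIC")

  c5 <- cloudTheta(c(0.04, 0.27, 0.5, 0.73, 0.96),
                   c(0.1, 0.2, 0.4, 0.2, 0.1), 250, 0.03, 73)
  m5 <- fitClusterModel(c5$theta, c5$R, p)
  expect_equal(m5@K, 5L)
  expect_equal(clusterPattern(m5), "MULTI_CLUSTER_UNRESOLVABLE")
})

test_that("pattern classification follows the worked taxonomy examples", {
  p <- clusterParams()
  mk <- function(means, weights, n = 200, sd = 0.02, seed = 80) {
    cl <- cloudTheta(means, weights, n, sd, seed)
    fitClusterModel(cl$theta, cl$R, p)
  }
  # extreme means 0.05/0.95: difference 0.9 > 0.6 -> genome specific
  expect_equal(clusterPattern(mk(c(0.05, 0.95), c(0.5, 0.5))),
               "GENOME_SPECIFIC")
  # means compressed into the lower half -> shifted
  expect_equal(clusterPattern(mk(c(0.04, 0.16, 0.33), c(0.4, 0.2, 0.4),
                                 seed = 81)), "SHIFTED")
  # three clusters with an inflated middle weight -> unresolvable
  expect_equal(clusterPattern(mk(c(0.1, 0.5, 0.9), c(0.15, 0.7, 0.15),
                                 seed = 82)), "MULTI_CLUSTER_UNRESOLVABLE")
  # all samples no-signal -> failed immediately
  n <- 50
  mF <- fitClusterModel(rep(NA_real_, n), rep(NA_real_, n), p)
  expect_equal(clusterPattern(mF), "FAILED_LOW_INTENSITY")
  expect_false(isScorable(mF))
  # presence/absence: R-separated at a single theta position
  set.seed(83)
  pres <- c(rep(TRUE, 120), rep(FALSE, 80))
  thetaPA <- ifelse(pres, pmax(rnorm(200, 0.05, 0.02), 0), runif(200))
  rPA <- ifelse(pres, rnorm(200, 1, 0.05), abs(rnorm(200, 0.05, 0.02)))
  mPA <- fitClusterModel(thetaPA, rPA, p)
  expect_equal(clusterPattern(mPA), "PRESENCE_ABSENCE")
  expect_true(isScorable(mPA))
})

test_that("shifted rescue relabels without touching assignments", {
  cl <- cloudTheta(c(0.04, 0.16, 0.33), c(0.4, 0.2, 0.4), 200, 0.015, 84)
  m <- fitClusterModel(cl$theta, cl$R, clusterParams())
  expect_equal(clusterPattern(m), "SHIFTED")
  expect_false(isScorable(m))
  r <- rescueShifted(m)
  expect_equal(clusterPattern(r), "SHIFTED_RESCUED")
  expect_true(isScorable(r))
  expect_equal(componentTable(r)$label, c("AA", "AB", "BB"))
  expect_identical(r@assignments, m@assignments)
  # two shifted components: AA/BB, no AB
  cl2 <- cloudTheta(c(0.08, 0.35), c(0.5, 0.5), 150, 0.02, 85)
  m2 <- fitClusterModel(cl2$theta, cl2$R, clusterParams())
  r2 <- rescueShifted(m2)
  expect_equal(componentTable(r2)$label, c("AA", "BB"))
  # refuse on non-shifted input
  c3 <- cloudTheta(c(0.05, 0.5, 0.95), c(0.4, 0.2, 0.4), 150, 0.02, 86)
  expect_error(rescueShifted(fitClusterModel(c3$theta, c3$R,
                                             clusterParams())), "SHIFTED")
})

test_that("genotype calling scores by responsibility margin", {
  p <- clusterParams()
  cl <- cloudTheta(c(0.05, 0.5, 0.95), c(0.4, 0.2, 0.4), 200, 0.03, 87)
  m <- fitClusterModel(cl$theta, cl$R, p)
  # a sample exactly at a component mean gets that label, confidence ~ 1
  at <- setNames(m@thetaMeans, c("sAA", "sAB", "sBB"))
  calls <- callGenotypes(m, at, rep(1, 3), p)
  expect_equal(calls$call, c("AA", "AB", "BB"))
  expect_true(all(calls$confidence > 0.99))
  # the responsibility midpoint between two clouds is NO_CALL
  mid <- uniroot(function(t) {
    d <- dnorm(t, m@thetaMeans, m@thetaSds) * m@weights
    d[1] - d[2]
  }, c(m@thetaMeans[1], m@thetaMeans[2]))$root
  midCall <- callGenotypes(m, c(s = mid), 1, p)
  expect_equal(midCall$call, "NO_CALL")
  # no-signal samples are NO_CALL; unscorable SNPs are all NO_CALL
  expect_equal(callGenotypes(m, c(s = 0.5), 0.01, p)$call, "NO_CALL")
  cl5 <- cloudTheta(c(0.04, 0.27, 0.5, 0.73, 0.96),
                    c(0.1, 0.2, 0.4, 0.2, 0.1), 250, 0.03, 88)
  m5 <- fitClusterModel(cl5$theta, cl5$R, p)
  calls5 <- callGenotypes(m5, cl5$theta, cl5$R, p)
  expect_true(all(calls5$call == "NO_CALL"))
})

test_that("call concordance with simulation truth is near-perfect at
           moderate noise", {
  cfg <- simConfig(seed = 89, nIntensitySNPs = 40, nSamples = 150,
                   noiseSd = 0.04,
                   classMixture = c(GENOME_SPECIFIC = 1,
                                    MULTI_CLUSTER_UNRESOLVABLE = 0,
                                    SHIFTED = 0, PRESENCE_ABSENCE = 0,
                                    MONOMORPHIC = 0,
                                    FAILED_LOW_INTENSITY = 0))
  si <- simulateIntensities(cfg)
  models <- fitClusterModels(si$intensities)
  calls <- callGenotypesPanel(models, si$intensities)
  called <- calls$call != "NO_CALL"
  truth <- si$truth$genotypes[cbind(calls$snpId, calls$sampleId)]
  expect_gte(mean(calls$call[called] == truth[called]), 0.99)
  expect_gte(mean(called), 0.95)
})

test_that("lowering the no-call threshold never decreases calls", {
  cl <- cloudTheta(c(0.05, 0.5, 0.95), c(0.4, 0.2, 0.4), 200, 0.06, 90)
  m <- fitClusterModel(cl$theta, cl$R, clusterParams())
  nCalled <- vapply(c(0.3, 0.2, 0.1, 0.05, 0.01, 0), function(t) {
    p <- clusterParams(noCallThreshold = t)
    sum(callGenotypes(m, cl$theta, cl$R, p)$call != "NO_CALL")
  }, numeric(1))
  expect_true(all(diff(nCalled) >= 0))
})

test_that("cluster files round-trip through JSON unchanged", {
  cfg <- simConfig(seed = 91, nIntensitySNPs = 25, nSamples = 60,
                   noiseSd = 0.03)
  si <- simulateIntensities(cfg)
  models <- fitClusterModels(si$intensities)
  path <- withr::local_tempfile(fileext = ".json")
  buildClusterFile(models, path, scorableOnly = FALSE)
  back <- readClusterFile(path)
  expect_identical(names(back), names(models))
  for (s in names(models)) {
    expect_equal(componentTable(back[[s]]), componentTable(models[[s]]),
                 tolerance = 1e-12)
    expect_identical(clusterPattern(back[[s]]), clusterPattern(models[[s]]))
    expect_identical(back[[s]]@assignments, models[[s]]@assignments)
  }
  # scorable-only filtering drops unscorable SNPs
  cf <- buildClusterFile(models)
  expect_equal(cf$nSNPs, sum(vapply(models, isScorable, logical(1))))
})

test_that("diploid cluster files mark other-subgenome assays failed and
           match simulated per-species truth", {
  cfg <- simConfig(seed = 92, nIntensitySNPs = 60, nSamples = 100,
                   noiseSd = 0.02)
  si <- simulateIntensities(cfg)
  models <- fitClusterModels(si$intensities)
  for (sp in c("RAPA", "OLERACEA")) {
    dip <- simulateDiploidIntensities(si$truth, cfg, sp, nSamples = 60)
    dc <- deriveDiploidClusterFile(models, dip$intensities, sp)
    expect_equal(unname(dc$summary["scorable"]),
                 sum(dip$truth$expectedScorable), info = sp)
    expect_equal(unname(dc$summary["polymorphic"]),
                 sum(dip$truth$expectedPolymorphic), info = sp)
    # genome-specific assays of the other subgenome collapse to failure
    genome <- if (sp == "RAPA") "A" else "C"
    other <- names(which(si$truth$classes == "GENOME_SPECIFIC" &
                           si$truth$owner != genome))
    pats <- vapply(dc$models[other], clusterPattern, character(1))
    expect_true(all(pats == "FAILED_LOW_INTENSITY"))
  }
  expect_error(deriveDiploidClusterFile(models, si$intensities, "RAPA"),
               "species")
})
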