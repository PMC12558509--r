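test_that("the support threshold is inclusive at exactly five reads", {
  counts <- makeCounts("chr1", c(1L, 1L, 2L, 2L), c("A", "G", "A", "G"),
                       c(100L, 5L, 100L, 4L))
  calls <- callCfdnaAlleles(counts, 5L)
  expect_setequal(paste(calls$pos, calls$allele),
                  c("1 A", "1 G", "2 A"))
  expect_equal(nrow(callCfdnaAlleles(counts[0, ], 5L)), 0)
  expect_error(callCfdnaAlleles(makeCounts("c", 1L, "A", -1L)), "negative")
  expect_error(callCfdnaAlleles(counts, 0L), "minSupport")
})

test_that("raising the support threshold never increases called alleles", {
  cfg <- smallConfig(seed = 59L, meanDepth = 30)
  pair <- simulatePairGenotypes(simulateSites(cfg), cfg)
  cf <- simulateCfdnaCounts(pair$donor, pair$recipient, cfg)
  idx <- buildIndex(pair$donor, pair$recipient)
  prev <- Inf
  for (ms in c(5L, 10L, 20L)) {
    est <- estimateFractionSitecount(idx, callCfdnaAlleles(cf$counts, ms))
    expect_lte(est@pooledNumerator, prev)
    prev <- est@pooledNumerator
  }
})

test_that("site-count estimator is positive-site arithmetic", {
  # both-unique sites: donor discriminates with G, recipient with A
  donor <- makeGt("chr1", 1:4, "A", "G", 1L, 1L)
  recip <- makeGt("chr1", 1:4, "A", "G", 0L, 0L)
  idx <- buildIndex(donor, recip)
  calls <- rbind(makeCounts("chr1", 1L, "G", 10L),
                 makeCounts("chr1", 1:4, "A", 10L))
  est <- estimateFractionSitecount(idx, calls)
  expect_equal(pooledPercent(est), 100 * 1 / 5)
  # cfDNA identical to the recipient genotype: zero percent
  callsR <- makeCounts("chr1", 1:4, "A", 10L)
  estR <- estimateFractionSitecount(idx, callsR)
  expect_equal(pooledPercent(estR), 0)
  expect_equal(estR@pooledDenominator, 0 + 4)  # 4 recipient-positive sites
})

test_that("thirty donor-positive of a thousand positive sites is 3 percent", {
  n <- 1000L
  # 30 donor-unique-positive and 970 recipient-unique-positive sites
  donor <- makeGt("chr1", 1:n, "A", "G",
                  c(rep(1L, 30), rep(0L, n - 30)),
                  c(rep(1L, 30), rep(0L, n - 30)))
  recip <- makeGt("chr1", 1:n, "A", "G",
                  c(rep(0L, 30), rep(1L, n - 30)),
                  c(rep(0L, 30), rep(1L, n - 30)))
  idx <- buildIndex(donor, recip)
  calls <- makeCounts("chr1", 1:n, "G", 10L)
  est <- estimateFractionSitecount(idx, calls)
  expect_equal(pooledPercent(est), 3.0)
})

test_that("read-fraction estimator reproduces the analytic value", {
  # donor homozygous for the discriminating allele at every used site,
  # 7 of 100 reads carry it: f-hat = 7 percent exactly (w = 1)
  n <- 50L
  donor <- makeGt("chr1", 1:n, "A", "G", 1L, 1L)
  recip <- makeGt("chr1", 1:n, "A", "G", 0L, 0L)
  idx <- buildIndex(donor, recip)
  counts <- rbind(makeCounts("chr1", 1:n, "G", 7L),
                  makeCounts("chr1", 1:n, "A", 93L))
  est <- estimateFractionReadfraction(idx, counts)
  expect_equal(pooledPercent(est), 7.0)
  expect_equal(est@details$nSitesUsed, n)
  # heterozygous donor gets weight 2
  donorHet <- makeGt("chr1", 1:n, "A", "G", 0L, 1L)
  idxHet <- buildIndex(donorHet, recip)
  estHet <- estimateFractionReadfraction(idxHet, counts)
  expect_equal(pooledPercent(estHet), 14.0)
})

test_that("zero mixture with error-free reads estimates exactly zero", {
  cfg <- smallConfig(seed = 61L, donorFraction = 0, errorRate = 0,
                     meanDepth = 100)
  pair <- simulatePairGenotypes(simulateSites(cfg), cfg)
  cf <- simulateCfdnaCounts(pair$donor, pair$recipient, cfg)
  idx <- buildIndex(pair$donor, pair$recipient)
  est <- estimateFractionReadfraction(idx, cf$counts)
  expect_identical(pooledPercent(est), 0)
})

test_that("read-fraction recovers the true donor fraction within 3 SE", {
  cfg <- simulationConfig(chromLengths = c(a = 1500000, ctrl = 1000),
                          donorFraction = 0.05, meanDepth = 500,
                          errorRate = 0.001, seed = 67L)
  pair <- simulatePairGenotypes(simulateSites(cfg), cfg)
  cf <- simulateCfdnaCounts(pair$donor, pair$recipient, cfg)
  idx <- buildIndex(pair$donor, pair$recipient)
  est <- estimateFractionReadfraction(idx, cf$counts)
  se <- readFractionSE(idx, cf$counts, 0.05, 0.001)
  expect_lt(abs(pooledPercent(est) / 100 - 0.05), 3 * se)
  # the uncorrected value carries the predicted positive error bias
  expect_gt(est@details$rawPercent, pooledPercent(est))
})

test_that("site-count estimate increases with the true donor fraction", {
  pooled <- vapply(c(0.01, 0.02, 0.05, 0.10), function(f) {
    vals <- vapply(1:5, function(s) {
      cfg <- smallConfig(seed = 100L + s, donorFraction = f,
                         meanDepth = 60, errorRate = 0)
      pair <- simulatePairGenotypes(simulateSites(cfg), cfg)
      cf <- simulateCfdnaCounts(pair$donor, pair$recipient, cfg)
      idx <- buildIndex(pair$donor, pair$recipient)
      pooledPercent(estimateFractionSitecount(
        idx, callCfdnaAlleles(cf$counts, 5L)))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(pooled) > 0))
})

test_that("pooled estimates equal the weighted combination of chromosomes", {
  cfg <- smallConfig(seed = 71L, meanDepth = 100)
  pair <- simulatePairGenotypes(simulateSites(cfg), cfg)
  cf <- simulateCfdnaCounts(pair$donor, pair$recipient, cfg)
  idx <- buildIndex(pair$donor, pair$recipient)
  for (est in list(estimateFractionSitecount(idx,
                                             callCfdnaAlleles(cf$counts)),
                   estimateFractionReadfraction(idx, cf$counts))) {
    pc <- perChromosome(est)
    expect_equal(pooledPercent(est),
                 100 * sum(pc$numerator) / sum(pc$denominator))
    expect_equal(est@pooledNumerator, sum(pc$numerator))
  }
})

test_that("the control chromosome reports its covered-position fraction", {
  cfg <- smallConfig(seed = 73L)
  ds <- simulateDataset(cfg, nFragments = 10)
  contigs <- chromLengths(cfg)
  ctrl <- contaminationControl(ds$counts, "ctrl", contigs)
  expect_identical(ctrl$percentCovered, 0)
  spiked <- rbind(ds$counts, makeCounts("ctrl", 123L, "A", 1L))
  ctrl2 <- contaminationControl(spiked, "ctrl",
                                c(contigs[names(contigs) != "ctrl"],
                                  ctrl = 10000))
  expect_equal(ctrl2$percentCovered, 0.01)
  expect_error(contaminationControl(ds$counts, "chrY", contigs),
               "missing from the genome declaration")
})
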