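# Set-difference oracle for site classification, written independently of
# the implementation.
oracleClassify <- function(d, r) {
  dd <- setdiff(d, r)
  rd <- setdiff(r, d)
  cls <- if (identical(sort(d), sort(r))) "shared"
    else if (length(dd) && length(rd)) "both-unique"
    else if (length(dd)) "donor-unique"
    else if (length(rd)) "recipient-unique"
    else "uninformative"
  list(class = cls, donorDisc = sort(dd), recipDisc = sort(rd))
}

test_that("classifySite matches the set-difference oracle exhaustively", {
  gts2 <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))  # biallelic
  for (d in gts2) for (r in gts2) {
    got <- classifySite(d, r)
    want <- oracleClassify(d, r)
    expect_equal(got$class, want$class)
    expect_equal(got$donorDisc, want$donorDisc)
    expect_equal(got$recipDisc, want$recipDisc)
  }
  # all unordered genotypes over three alleles
  gts3 <- list(c(0L, 0L), c(0L, 1L), c(0L, 2L), c(1L, 1L), c(1L, 2L),
               c(2L, 2L))
  for (d in gts3) for (r in gts3) {
    got <- classifySite(d, r)
    want <- oracleClassify(d, r)
    expect_equal(got$class, want$class)
    expect_equal(got$donorDisc, want$donorDisc)
  }
})

test_that("specific genotype pairs classify as expected", {
  v <- classifySite(c(1, 1), c(0, 0))
  expect_equal(v$class, "both-unique")
  expect_equal(v$donorDisc, 1L)
  expect_equal(v$recipDisc, 0L)
  v <- classifySite(c(0, 1), c(0, 1))
  expect_equal(v$class, "shared")
  expect_length(v$donorDisc, 0)
  v <- classifySite(c(0, 1), c(0, 0))
  expect_equal(v$class, "donor-unique")
  expect_equal(v$donorDisc, 1L)
  expect_length(v$recipDisc, 0)
  # donor 0/1 vs recipient 1/1: donor side contributes, recipient does not
  v <- classifySite(c(0, 1), c(1, 1))
  expect_equal(v$class, "donor-unique")
  expect_equal(v$donorDisc, 0L)
})

test_that("donor-recipient swap maps classes and sets symmetrically", {
  set.seed(101)
  swapClass <- c(`donor-unique` = "recipient-unique",
                 `recipient-unique` = "donor-unique",
                 shared = "shared", `both-unique` = "both-unique",
                 uninformative = "uninformative")
  for (i in 1:200) {
    d <- sample(0:3, 2, replace = TRUE)
    r <- sample(0:3, 2, replace = TRUE)
    a <- classifySite(d, r)
    b <- classifySite(r, d)
    expect_equal(b$class, unname(swapClass[a$class]))
    expect_equal(b$donorDisc, a$recipDisc)
    expect_equal(b$recipDisc, a$donorDisc)
  }
})

test_that("buildIndex classifies a simulated pair consistently with a recount", {
  cfg <- smallConfig(seed = 17L)
  sites <- simulateSites(cfg)
  pair <- simulatePairGenotypes(sites, cfg)
  idx <- buildIndex(pair$donor, pair$recipient)
  tab <- indexSites(idx)
  expect_equal(nrow(tab), nrow(sites))
  # independent second pass over every site
  for (i in sample(nrow(tab), 200)) {
    want <- oracleClassify(c(pair$donor$a1[i], pair$donor$a2[i]),
                           c(pair$recipient$a1[i], pair$recipient$a2[i]))
    expect_equal(tab$class[i], want$class)
  }
  nonShared <- sum(tab$class != "shared")
  oracleNonShared <- sum(vapply(seq_len(nrow(tab)), function(i)
    oracleClassify(c(pair$donor$a1[i], pair$donor$a2[i]),
                   c(pair$recipient$a1[i],
                     pair$recipient$a2[i]))$class != "shared",
    logical(1)))
  expect_equal(nonShared, oracleNonShared)
  # class counts sum to jointly-called sites
  expect_equal(sum(classCounts(idx)$count), nrow(tab))
})

test_that("identical streams give 100 percent shared sites", {
  cfg <- smallConfig(seed = 23L)
  pair <- simulatePairGenotypes(simulateSites(cfg), cfg)
  idx <- buildIndex(pair$donor, pair$donor)
  expect_true(all(indexSites(idx)$class == "shared"))
  expect_true(all(indexSites(idx)$donorDisc == ""))
})

test_that("unsorted input errors name the first offending position", {
  gt <- makeGt("chr1", c(10L, 5L), c("A", "C"), c("G", "T"),
               c(0L, 0L), c(1L, 1L))
  expect_error(buildIndex(gt, gt), "chr1:5")
  split <- makeGt(c("chr1", "chr2", "chr1"), c(1L, 1L, 2L),
                  "A", "G", 0L, 1L)
  expect_error(buildIndex(split, split), "more than one block")
})

test_that("half-called sites are counted, not classified", {
  donor <- makeGt("chr1", c(1L, 2L, 3L), "A", "G", c(0L, 0L, 1L),
                  c(1L, 0L, 1L))
  recip <- makeGt("chr1", c(2L, 3L), "A", "G", c(0L, 0L), c(0L, 0L))
  idx <- buildIndex(donor, recip)
  expect_equal(halfCalledCount(idx), 1L)
  expect_equal(nrow(indexSites(idx)), 2L)
})

test_that("index serialization round-trips losslessly", {
  cfg <- smallConfig(seed = 29L)
  pair <- simulatePairGenotypes(simulateSites(cfg), cfg)
  idx <- buildIndex(pair$donor, pair$recipient)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeIndex(idx, path)
  back <- readIndex(path)
  expect_equal(indexSites(back), indexSites(idx))
  expect_equal(halfCalledCount(back), halfCalledCount(idx))
})

test_that("snpDensity is site count over kilobases, length-weighted overall", {
  sites <- data.frame(chrom = rep("chrA", 342), pos = seq_len(342))
  d <- snpDensity(sites, c(chrA = 100000))
  expect_equal(d$overall, 3.42)
  expect_equal(d$perChrom$densityPerKb, 3.42)
  dEmpty <- snpDensity(sites[0, ], c(chrA = 100000))
  expect_equal(dEmpty$overall, 0)
  expect_error(snpDensity(sites, c(chrB = 1000)), "chrA")
  # simulator recovery at the default density
  cfg <- simulationConfig(chromLengths = c(a = 400000, ctrl = 1000),
                          seed = 37L)
  sim <- simulateSites(cfg)
  est <- snpDensity(sim, c(a = 400000))
  se <- sqrt(3.42 / 400)  # Poisson SE of the per-kb rate over 400 kb
  expect_lt(abs(est$overall - 3.42), 3 * se)
})
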