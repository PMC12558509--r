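# Brute-force re-evaluation of each printed predicate, used as the oracle
# throughout this file.
oracleSnp <- function(a) {
  fails <- c(
    QD = !is.na(a$QD) && a$QD < 2.0,
    QUAL = !is.na(a$QUAL) && a$QUAL < 30.0,
    SOR = !is.na(a$SOR) && a$SOR > 3.0,
    FS = !is.na(a$FS) && a$FS > 60.0,
    MQ = !is.na(a$MQ) && a$MQ < 40.0,
    MQRankSum = !is.na(a$MQRankSum) && a$MQRankSum < -12.5,
    ReadPosRankSum = !is.na(a$ReadPosRankSum) && a$ReadPosRankSum < -8.0)
  names(fails)[fails]
}
oracleIndel <- function(a) {
  fails <- c(
    QD = !is.na(a$QD) && a$QD < 2.0,
    QUAL = !is.na(a$QUAL) && a$QUAL < 30.0,
    FS = !is.na(a$FS) && a$FS > 200.0,
    ReadPosRankSum = !is.na(a$ReadPosRankSum) && a$ReadPosRankSum < -20.0)
  names(fails)[fails]
}

randomAnnotations <- function(n, seed) {
  set.seed(seed)
  # values straddling every threshold, with missingness
  draw <- function(lo, hi) {
    v <- runif(n, lo, hi)
    v[runif(n) < 0.1] <- NA
    v
  }
  data.frame(
    class = sample(c("SNP", "INDEL"), n, replace = TRUE),
    QD = draw(0, 5), QUAL = draw(0, 60), SOR = draw(0, 6),
    FS = draw(0, 300), MQ = draw(20, 60), MQRankSum = draw(-20, 5),
    ReadPosRankSum = draw(-25, 5), stringsAsFactors = FALSE)
}

test_that("variant classification distinguishes SNP, INDEL and other", {
  expect_equal(classifyVariant("A", "G"), "SNP")
  expect_equal(classifyVariant("A", "AT"), "INDEL")
  expect_equal(classifyVariant("AC", "GT"), "other")
  expect_equal(classifyVariant(c("A", "GT"), c("C", "G")),
               c("SNP", "INDEL"))
  expect_error(classifyVariant("A", ""), "non-empty")
  expect_error(classifyVariant("A", "N"), "A/C/G/T")
})

test_that("every strict boundary value passes its predicate", {
  boundary <- nominalAnn(QD = 2.0, QUAL = 30.0, SOR = 3.0, FS = 60.0,
                         MQ = 40.0, MQRankSum = -12.5,
                         ReadPosRankSum = -8.0)
  v <- hardFilterSnp(boundary)
  expect_true(v$pass)
  expect_length(v$failed, 0)
  vi <- hardFilterIndel(nominalAnn(class = "INDEL", QD = 2.0, QUAL = 30.0,
                                   FS = 200.0, ReadPosRankSum = -20.0))
  expect_true(vi$pass)
})

test_that("single violations fail with exactly the offending predicate", {
  v <- hardFilterSnp(nominalAnn(QD = 1.9))
  expect_false(v$pass)
  expect_equal(v$failed, "QD")
  v <- hardFilterSnp(nominalAnn(MQRankSum = -13.0))
  expect_equal(v$failed, "MQRankSum")
  expect_true(hardFilterIndel(nominalAnn(class = "INDEL", FS = 150))$pass)
  v <- hardFilterIndel(nominalAnn(class = "INDEL", FS = 201))
  expect_equal(v$failed, "FS")
  # class-mismatch usage errors
  expect_error(hardFilterSnp(nominalAnn(class = "INDEL")), "INDEL record")
  expect_error(hardFilterIndel(nominalAnn(class = "SNP")), "SNP record")
})

test_that("missing statistics never trigger their predicate and are logged", {
  v <- hardFilterSnp(nominalAnn(MQRankSum = NA, ReadPosRankSum = NA))
  expect_true(v$pass)
  expect_setequal(v$missing, c("MQRankSum", "ReadPosRankSum"))
  res <- filterStream(data.frame(class = "SNP", QD = 20, QUAL = NA,
                                 SOR = 1, FS = 1, MQ = 50, MQRankSum = 0,
                                 ReadPosRankSum = 0))
  expect_equal(res$summary$passed, 1)
  expect_equal(res$summary$missingEvaluations, 1)
})

test_that("filterStream matches the predicate oracle on randomized records", {
  ann <- randomAnnotations(2000, seed = 77L)
  res <- filterStream(ann)
  for (i in seq_len(nrow(ann))) {
    reasons <- if (ann$class[i] == "SNP") oracleSnp(ann[i, ]) else
      oracleIndel(ann[i, ])
    if (length(reasons)) {
      expect_true(paste(ann$class[i], i) %in%
                    paste(res$failed$class, rownames(res$failed)))
    }
  }
  # exact partition and per-record reasons
  oracleFailed <- vapply(seq_len(nrow(ann)), function(i) {
    r <- if (ann$class[i] == "SNP") oracleSnp(ann[i, ]) else
      oracleIndel(ann[i, ])
    paste(r, collapse = ";")
  }, character(1))
  expect_equal(sum(oracleFailed != ""), res$summary$failedCount)
  expect_equal(unname(oracleFailed[oracleFailed != ""]),
               res$failed$filterReasons)
  expect_equal(res$summary$passed + res$summary$failedCount +
                 res$summary$malformedCount, nrow(ann))
})

test_that("filtering preserves order, is idempotent, and flags malformed", {
  ann <- randomAnnotations(500, seed = 12L)
  ann$class[c(3, 50)] <- c("other", NA)
  res <- filterStream(ann)
  expect_equal(res$summary$malformedCount, 2)
  expect_true(all(diff(as.integer(rownames(res$passing))) > 0))
  again <- filterStream(res$passing)
  expect_equal(nrow(again$passing), nrow(res$passing))
  expect_equal(again$summary$failedCount, 0)
  empty <- filterStream(ann[0, ])
  expect_equal(nrow(empty$passing), 0)
  expect_equal(empty$summary$total, 0)
})

test_that("lowering a passing SNP statistic past its threshold flips it", {
  base <- nominalAnn()
  for (f in c("QD", "MQ", "QUAL")) {
    mod <- base
    mod[[f]] <- 1.0  # below all three lower thresholds
    v <- hardFilterSnp(mod)
    expect_false(v$pass)
    expect_equal(v$failed, f)
  }
})

test_that("injected violations are recovered exactly from simulator truth", {
  cfg <- smallConfig(seed = 31L)
  sites <- simulateSites(cfg)
  ann <- simulateAnnotations(sites, cfg, violationFraction = 0.1,
                             indelFraction = 0.2)
  res <- filterStream(ann$annotations)
  expect_equal(res$summary$failedCount, nrow(ann$truth))
  expect_setequal(paste(res$failed$chrom, res$failed$pos),
                  paste(ann$truth$chrom, ann$truth$pos))
  expect_equal(sort(res$failed$filterReasons),
               sort(ann$truth$field))
  # zero injection: everything passes
  clean <- simulateAnnotations(sites, cfg, violationFraction = 0)
  resClean <- filterStream(clean$annotations)
  expect_equal(resClean$summary$failedCount, 0)
  expect_equal(nrow(resClean$passing), nrow(sites))
  # an INDEL injected with FS = 100 is logged as non-violating
  annI <- simulateAnnotations(sites, cfg, indelFraction = 1,
                              injections = data.frame(row = 1L,
                                                      field = "FS",
                                                      value = 100))
  expect_false(annI$truth$violates[1])
})
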