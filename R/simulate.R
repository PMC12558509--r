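# Synthetic transplant-pair genomes and cfDNA mixtures with known truth.
# Biallelic SNPs only; reads are single-site observations; sequencing error
# flips a read to the other allele of its site.

BASES <- c("A", "C", "G", "T")

#' Simulate SNP site positions per chromosome
#'
#' Draws a Poisson number of sites per chromosome with expectation
#' `length_kb * snpDensity` and places them uniformly without replacement.
#' The control chromosome receives no sites.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer seed; defaults to the config seed.
#' @return data.frame with `chrom` and 1-based `pos`, strictly increasing
#'   within each chromosome.
#' @examples
#' sites <- simulateSites(simulationConfig(seed = 7L))
#' head(sites)
#' @export
simulateSites <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(seed)
  lens <- config@chromLengths
  lens <- lens[names(lens) != config@controlChrom]
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    len <- lens[[i]]
    n <- stats::rpois(1L, len / 1000 * config@snpDensity)
    n <- min(n, len)
    out[[i]] <- data.frame(chrom = names(lens)[i],
                           pos = sort(sample.int(len, n)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate phased diploid genotypes for a donor-recipient pair
#'
#' Each site gets a random ref/alt base pair and an alternate allele
#' frequency drawn from the configured Beta distribution; the two
#' individuals are independent draws from the same frequency model (an
#' unrelated, deliberately mismatched pair). Both haplotypes are recorded,
#' so phase is known.
#'
#' @param sites output of [simulateSites()].
#' @inheritParams simulateSites
#' @param altFreq optional fixed alternate allele frequency overriding the
#'   Beta draw (useful for closed-form checks).
#' @return list with `donor` and `recipient` genotype data.frames (`chrom`,
#'   `pos`, `ref`, `alt`, allele indices `a1`/`a2`, `phased = TRUE`) and the
#'   per-site `altFreq` used.
#' @export
simulatePairGenotypes <- function(sites, config, seed = config@seed + 1L,
                                  altFreq = NULL) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  set.seed(seed)
  n <- nrow(sites)
  refIdx <- sample.int(4L, n, replace = TRUE)
  altIdx <- ((refIdx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  p <- if (is.null(altFreq)) {
    stats::rbeta(n, config@altFreqShape1, config@altFreqShape2)
  } else rep(altFreq, length.out = n)
  gt <- function() {
    data.frame(chrom = sites$chrom, pos = sites$pos,
               ref = BASES[refIdx], alt = BASES[altIdx],
               a1 = stats::rbinom(n, 1L, p), a2 = stats::rbinom(n, 1L, p),
               phased = TRUE, stringsAsFactors = FALSE)
  }
  list(donor = gt(), recipient = gt(), altFreq = p)
}

# Nominal (comfortably passing) annotation values and one violating value
# per predicate, per variant class.
.nominalAnnotations <- function(n) {
  data.frame(
    QD = stats::runif(n, 10, 35), QUAL = stats::runif(n, 100, 2000),
    SOR = stats::runif(n, 0.3, 2.0), FS = stats::runif(n, 0, 30),
    MQ = stats::runif(n, 50, 60), MQRankSum = stats::runif(n, -3, 3),
    ReadPosRankSum = stats::runif(n, -3, 3)
  )
}

.violatingValue <- function(field, class) {
  switch(field,
         QD = 1.0, QUAL = 10.0, SOR = 3.5,
         FS = if (class == "INDEL") 250.0 else 75.0,
         MQ = 30.0, MQRankSum = -13.0,
         ReadPosRankSum = if (class == "INDEL") -21.0 else -9.0)
}

#' Simulate per-site variant annotations with optional injected violations
#'
#' Every site receives the seven filter statistics (QD, QUAL, SOR, FS, MQ,
#' MQRankSum, ReadPosRankSum) at values that comfortably pass the hard
#' filters, plus a variant class. A fraction of sites can be injected with
#' a value violating exactly one named predicate, and explicit injections
#' can be supplied; the injection log is returned as truth, with each entry
#' marked by whether it actually violates the class-appropriate predicate.
#'
#' @inheritParams simulatePairGenotypes
#' @param violationFraction fraction of sites to inject with one randomly
#'   chosen violated predicate; must lie in \[0, 1\].
#' @param indelFraction fraction of sites labelled INDEL instead of SNP.
#' @param injections optional data.frame (`row`, `field`, `value`) applied
#'   verbatim to site rows after random injection.
#' @return list with `annotations` (data.frame: `chrom`, `pos`, `class`,
#'   seven statistics) and `truth` (data.frame: `chrom`, `pos`, `field`,
#'   `value`, `violates`).
#' @export
simulateAnnotations <- function(sites, config, seed = config@seed + 2L,
                                violationFraction = 0,
                                indelFraction = 0,
                                injections = NULL) {
  if (violationFraction < 0 || violationFraction > 1)
    stop("violationFraction must lie in [0, 1]")
  set.seed(seed)
  n <- nrow(sites)
  ann <- cbind(
    data.frame(chrom = sites$chrom, pos = sites$pos,
               class = ifelse(stats::runif(n) < indelFraction,
                              "INDEL", "SNP"),
               stringsAsFactors = FALSE),
    .nominalAnnotations(n))
  truth <- data.frame(chrom = character(), pos = integer(),
                      field = character(), value = numeric(),
                      violates = logical(), stringsAsFactors = FALSE)
  nInject <- floor(violationFraction * n)
  if (nInject > 0) {
    rows <- sample.int(n, nInject)
    for (i in rows) {
      fields <- if (ann$class[i] == "INDEL") {
        c("QD", "QUAL", "FS", "ReadPosRankSum")
      } else names(.nominalAnnotations(1L))
      f <- sample(fields, 1L)
      v <- .violatingValue(f, ann$class[i])
      ann[i, f] <- v
      truth <- rbind(truth, data.frame(
        chrom = ann$chrom[i], pos = ann$pos[i], field = f, value = v,
        violates = TRUE, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(injections)) {
    for (k in seq_len(nrow(injections))) {
      i <- injections$row[k]
      f <- injections$field[k]
      v <- injections$value[k]
      ann[i, f] <- v
      verdict <- if (ann$class[i] == "SNP") {
        hardFilterSnp(ann[i, , drop = FALSE])
      } else hardFilterIndel(ann[i, , drop = FALSE])
      truth <- rbind(truth, data.frame(
        chrom = ann$chrom[i], pos = ann$pos[i], field = f, value = v,
        violates = f %in% verdict$failed, stringsAsFactors = FALSE))
    }
  }
  list(annotations = ann, truth = truth)
}

#' Simulate cfDNA allele counts from a donor/recipient mixture
#'
#' Per site, depth is Poisson(meanDepth); each read comes from the donor
#' with probability `donorFraction`, otherwise from the recipient; the read
#' allele is drawn uniformly from the source's two haplotype alleles; with
#' probability `errorRate` it is flipped to the site's other allele. Counts
#' at each site sum to its depth, and the per-site source of every read is
#' recorded as ground truth.
#'
#' @param donor,recipient genotype data.frames from
#'   [simulatePairGenotypes()], aligned on the same site list.
#' @inheritParams simulateSites
#' @return list with `counts` (data.frame: `chrom`, `pos`, `allele`,
#'   `count`; zero-count alleles omitted) and `truth` (list: `donorFraction`,
#'   and `sources`, a per-site data.frame of `depth`, `donorReads`,
#'   `recipientReads`).
#' @export
simulateCfdnaCounts <- function(donor, recipient, config,
                                seed = config@seed + 3L) {
  if (nrow(donor) != nrow(recipient) ||
      !all(donor$chrom == recipient$chrom & donor$pos == recipient$pos))
    stop("donor and recipient genotypes must be aligned on the same sites")
  set.seed(seed)
  n <- nrow(donor)
  f <- config@donorFraction
  eps <- config@errorRate
  depth <- stats::rpois(n, config@meanDepth)
  nD <- stats::rbinom(n, depth, f)
  nR <- depth - nD
  flipProb <- function(pAlt) pAlt * (1 - eps) + (1 - pAlt) * eps
  altD <- stats::rbinom(n, nD, flipProb((donor$a1 + donor$a2) / 2))
  altR <- stats::rbinom(n, nR, flipProb((recipient$a1 + recipient$a2) / 2))
  altCount <- altD + altR
  refCount <- depth - altCount
  counts <- rbind(
    data.frame(chrom = donor$chrom, pos = donor$pos, allele = donor$ref,
               count = refCount, stringsAsFactors = FALSE),
    data.frame(chrom = donor$chrom, pos = donor$pos, allele = donor$alt,
               count = altCount, stringsAsFactors = FALSE))
  counts <- counts[counts$count > 0L, ]
  counts <- counts[order(counts$chrom, counts$pos, counts$allele), ]
  rownames(counts) <- NULL
  list(counts = counts,
       truth = list(donorFraction = f,
                    sources = data.frame(
                      chrom = donor$chrom, pos = donor$pos, depth = depth,
                      donorReads = nD, recipientReads = nR,
                      stringsAsFactors = FALSE)))
}

#' Simulate cfDNA fragment sizes
#'
#' Log-normal draws with condition-specific location/scale; the endpoint
#' location exceeds the baseline location by construction (config
#' validity), emulating the fragment-size increase seen at rejection.
#'
#' @param condition "baseline" or "endpoint".
#' @param n number of fragments (> 0).
#' @inheritParams simulateSites
#' @return numeric vector of fragment sizes in bp.
#' @export
simulateFragmentSizes <- function(condition, n, config,
                                  seed = config@seed + 4L) {
  if (!condition %in% c("baseline", "endpoint"))
    stop("condition must be 'baseline' or 'endpoint'")
  if (n <= 0) stop("n must be > 0")
  set.seed(seed)
  stats::rlnorm(n, config@fragmentMeanlog[[condition]],
                config@fragmentSdlog[[condition]])
}

#' Run the full generator
#'
#' Convenience wrapper running [simulateSites()],
#' [simulatePairGenotypes()], [simulateAnnotations()],
#' [simulateCfdnaCounts()] and [simulateFragmentSizes()] with seeds derived
#' deterministically from the config seed.
#'
#' @inheritParams simulateSites
#' @param nFragments fragments per condition.
#' @param violationFraction,indelFraction passed to [simulateAnnotations()].
#' @return list bundling `config`, `sites`, `donor`, `recipient`,
#'   `annotations`, `annotationTruth`, `counts`, `countsTruth`, and
#'   `fragments` (list of baseline/endpoint vectors).
#' @export
simulateDataset <- function(config, nFragments = 5000,
                            violationFraction = 0, indelFraction = 0) {
  sites <- simulateSites(config)
  pair <- simulatePairGenotypes(sites, config)
  ann <- simulateAnnotations(sites, config,
                             violationFraction = violationFraction,
                             indelFraction = indelFraction)
  cf <- simulateCfdnaCounts(pair$donor, pair$recipient, config)
  list(config = config, sites = sites,
       donor = pair$donor, recipient = pair$recipient,
       annotations = ann$annotations, annotationTruth = ann$truth,
       counts = cf$counts, countsTruth = cf$truth,
       fragments = list(
         baseline = simulateFragmentSizes("baseline", nFragments, config),
         endpoint = simulateFragmentSizes("endpoint", nFragments, config,
                                          seed = config@seed + 5L)))
}

#' Write a simulated dataset to disk
#'
#' Emits phased donor and recipient VCFs (with the seven INFO/QUAL
#' annotations and contig headers that include the read-free control
#' chromosome), the cfDNA allele-count TSV, plain-text fragment-size lists
#' and a JSON truth file. All files round-trip through the package readers.
#'
#' @param dataset output of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of file paths.
#' @export
emitDataset <- function(dataset, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  cfg <- dataset$config
  paths <- c(donorVcf = file.path(dir, "donor.vcf"),
             recipientVcf = file.path(dir, "recipient.vcf"),
             counts = file.path(dir, "cfdna_counts.tsv"),
             baseline = file.path(dir, "fragments_baseline.txt"),
             endpoint = file.path(dir, "fragments_endpoint.txt"),
             truth = file.path(dir, "truth.json"))
  writeGenotypeVcf(dataset$donor, dataset$annotations, cfg,
                   paths[["donorVcf"]], sample = "donor")
  writeGenotypeVcf(dataset$recipient, dataset$annotations, cfg,
                   paths[["recipientVcf"]], sample = "recipient")
  writeTsv(dataset$counts, paths[["counts"]])
  writeLines(format(dataset$fragments$baseline, trim = TRUE),
             paths[["baseline"]])
  writeLines(format(dataset$fragments$endpoint, trim = TRUE),
             paths[["endpoint"]])
  jsonlite::write_json(
    list(donorFraction = cfg@donorFraction,
         errorRate = cfg@errorRate,
         meanDepth = cfg@meanDepth,
         seed = cfg@seed,
         sources = dataset$countsTruth$sources),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
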