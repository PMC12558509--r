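#' @import methods
NULL

#' Simulation configuration for a transplant-pair cfDNA experiment
#'
#' Holds every parameter of the synthetic-data generator: the genome
#' declaration (chromosome lengths plus a designated control chromosome that
#' receives no reads, standing in for a Y-chromosome negative control in an
#' all-female cohort), the SNP density, the per-site alternate allele
#' frequency model (Beta), the donor fraction of the cfDNA mixture, mean read
#' depth, per-read sequencing error rate, the fragment-size analysis window,
#' condition-specific log-normal fragment-size parameters, and the seed.
#'
#' @slot chromLengths named numeric vector of chromosome lengths in bp
#'   (includes the control chromosome).
#' @slot controlChrom name of the control chromosome; it is declared in
#'   output headers but receives zero simulated sites and zero reads.
#' @slot snpDensity expected SNPs per kilobase (default 3.42).
#' @slot altFreqShape1,altFreqShape2 shape parameters of the Beta
#'   distribution from which per-site alternate allele frequencies are drawn.
#' @slot donorFraction true fraction of cfDNA reads of donor origin, in
#'   \[0, 1\].
#' @slot meanDepth mean sequencing depth per site (Poisson).
#' @slot errorRate per-read probability that the observed allele is flipped
#'   to the other allele of the biallelic site; in \[0, 0.5).
#' @slot fragmentWindow closed \[min, max\] window in bp used when averaging
#'   fragment sizes (default 40 and 10000).
#' @slot fragmentMeanlog,fragmentSdlog named numeric vectors (names
#'   "baseline", "endpoint") giving log-normal location and scale of the
#'   fragment-size distribution per condition; the endpoint location must
#'   exceed the baseline location.
#' @slot seed integer seed driving all randomness.
#'
#' @seealso [simulationConfig()] for the user-facing constructor.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    chromLengths = "numeric",
    controlChrom = "character",
    snpDensity = "numeric",
    altFreqShape1 = "numeric",
    altFreqShape2 = "numeric",
    donorFraction = "numeric",
    meanDepth = "numeric",
    errorRate = "numeric",
    fragmentWindow = "numeric",
    fragmentMeanlog = "numeric",
    fragmentSdlog = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@chromLengths) < 1L || is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be a named vector")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "all chromosome lengths must be > 0")
  if (anyDuplicated(names(object@chromLengths)))
    msg <- c(msg, "chromosome names must be unique")
  if (!(object@controlChrom %in% names(object@chromLengths)))
    msg <- c(msg, "controlChrom must be one of the declared chromosomes")
  if (object@snpDensity <= 0)
    msg <- c(msg, "snpDensity must be > 0")
  if (object@altFreqShape1 <= 0 || object@altFreqShape2 <= 0)
    msg <- c(msg, "Beta shape parameters must be > 0")
  if (object@donorFraction < 0 || object@donorFraction > 1)
    msg <- c(msg, "donorFraction must lie in [0, 1]")
  if (object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be > 0")
  if (object@errorRate < 0 || object@errorRate >= 0.5)
    msg <- c(msg, "errorRate must lie in [0, 0.5)")
  if (length(object@fragmentWindow) != 2L ||
      object@fragmentWindow[1] >= object@fragmentWindow[2])
    msg <- c(msg, "fragmentWindow must be c(min, max) with min < max")
  for (s in c("fragmentMeanlog", "fragmentSdlog")) {
    v <- slot(object, s)
    if (!all(c("baseline", "endpoint") %in% names(v)))
      msg <- c(msg, paste(s, "needs 'baseline' and 'endpoint' entries"))
  }
  if (all(c("baseline", "endpoint") %in% names(object@fragmentMeanlog)) &&
      object@fragmentMeanlog["endpoint"] <= object@fragmentMeanlog["baseline"])
    msg <- c(msg, "endpoint fragment location must exceed baseline")
  if (any(object@fragmentSdlog <= 0))
    msg <- c(msg, "fragmentSdlog values must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults describe the study conditions the package emulates: 18
#' autosome-like chromosomes plus one read-free control chromosome, 3.42
#' SNPs/kb, uniform (Beta(1,1)) alternate allele frequencies for an outbred
#' unrelated donor-recipient pair, 1000x mean depth at informative SNPs, a
#' 0.1% per-read flip error, a 40-10000 bp fragment window, and log-normal
#' fragment sizes centred near 2.5 kb at baseline and 4.3 kb at the
#' rejection endpoint.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param controlChrom name of the control chromosome (zero sites, zero
#'   reads); must appear in `chromLengths`.
#' @param snpDensity expected SNPs per kb.
#' @param altFreqShape1,altFreqShape2 Beta shape parameters for per-site
#'   alternate allele frequency.
#' @param donorFraction true donor fraction f of the cfDNA mixture.
#' @param meanDepth mean per-site read depth.
#' @param errorRate per-read allele flip probability.
#' @param fragmentWindow closed window (bp) for fragment-size averaging.
#' @param fragmentMeanlog,fragmentSdlog named ("baseline", "endpoint")
#'   log-normal parameters of fragment size.
#' @param seed integer seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(donorFraction = 0.05, seed = 1L)
#' donorFraction(cfg)
#' @export
simulationConfig <- function(chromLengths = NULL,
                             controlChrom = "ctrl",
                             snpDensity = 3.42,
                             altFreqShape1 = 1, altFreqShape2 = 1,
                             donorFraction = 0.05,
                             meanDepth = 1000,
                             errorRate = 0.001,
                             fragmentWindow = c(40, 10000),
                             fragmentMeanlog = c(baseline = log(2500),
                                                 endpoint = log(4300)),
                             fragmentSdlog = c(baseline = 0.35,
                                               endpoint = 0.35),
                             seed = 1L) {
  if (is.null(chromLengths)) {
    chromLengths <- stats::setNames(rep(120000, 18), paste0("chr", 1:18))
    chromLengths[controlChrom] <- 10000
  }
  new("SimulationConfig",
      chromLengths = chromLengths, controlChrom = controlChrom,
      snpDensity = snpDensity,
      altFreqShape1 = altFreqShape1, altFreqShape2 = altFreqShape2,
      donorFraction = donorFraction, meanDepth = meanDepth,
      errorRate = errorRate, fragmentWindow = as.numeric(fragmentWindow),
      fragmentMeanlog = fragmentMeanlog, fragmentSdlog = fragmentSdlog,
      seed = as.integer(seed))
}

#' @describeIn simulationConfig chromosome lengths (bp), named.
#' @param x,object a `SimulationConfig`.
#' @export
chromLengths <- function(x) x@chromLengths

#' @describeIn simulationConfig name of the read-free control chromosome.
#' @export
controlChrom <- function(x) x@controlChrom

#' @describeIn simulationConfig the true donor fraction f.
#' @export
donorFraction <- function(x) x@donorFraction

#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d chromosomes (%.2f Mb total), control: %s\n",
              length(object@chromLengths),
              sum(object@chromLengths) / 1e6, object@controlChrom))
  cat(sprintf("  snpDensity: %.2f /kb | donorFraction: %.4f | depth: %.0f | error: %.4g\n",
              object@snpDensity, object@donorFraction,
              object@meanDepth, object@errorRate))
  cat(sprintf("  fragment window: [%g, %g] bp | seed: %d\n",
              object@fragmentWindow[1], object@fragmentWindow[2],
              object@seed))
})

#' Informative-site index of a donor-recipient pair
#'
#' Per-site classification of jointly-called genotypes into shared,
#' donor-unique, recipient-unique, both-unique or uninformative, together
#' with the allele-level discriminating sets (alleles carried by one
#' individual and absent from the other) that the cfDNA comparison consumes.
#'
#' @slot sites data.frame with one row per jointly-called site: `chrom`,
#'   `pos`, `ref`, `alt`, donor and recipient allele indices (`donorA1`,
#'   `donorA2`, `recipA1`, `recipA2`), `class`, and comma-joined
#'   discriminating allele bases `donorDisc` / `recipDisc` ("" when empty).
#' @slot classCounts data.frame of per-chromosome counts per class.
#' @slot halfCalled number of sites present in only one individual (counted,
#'   never classified).
#'
#' @seealso [buildIndex()], [classifySite()], [snpDensity()]
#' @exportClass InformativeSiteIndex
setClass("InformativeSiteIndex",
  representation(
    sites = "data.frame",
    classCounts = "data.frame",
    halfCalled = "integer"
  )
)

setValidity("InformativeSiteIndex", function(object) {
  msg <- character()
  need <- c("chrom", "pos", "ref", "alt", "donorA1", "donorA2",
            "recipA1", "recipA2", "class", "donorDisc", "recipDisc")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("sites must have columns:",
                        paste(need, collapse = ", ")))
  else {
    ok <- object@sites$class %in% c("shared", "donor-unique",
                                    "recipient-unique", "both-unique",
                                    "uninformative")
    if (!all(ok)) msg <- c(msg, "unknown site class")
    bad <- object@sites$class %in% c("shared", "recipient-unique") &
      object@sites$donorDisc != ""
    if (any(bad))
      msg <- c(msg, "donor discriminating set must be empty for shared/recipient-unique sites")
    if (sum(object@classCounts$count) != nrow(object@sites))
      msg <- c(msg, "class counts must sum to the number of jointly-called sites")
  }
  if (object@halfCalled < 0L) msg <- c(msg, "halfCalled must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn InformativeSiteIndex-class per-site classification table.
#' @param x an `InformativeSiteIndex`.
#' @export
indexSites <- function(x) x@sites

#' @describeIn InformativeSiteIndex-class per-chromosome class counts.
#' @export
classCounts <- function(x) x@classCounts

#' @describeIn InformativeSiteIndex-class number of half-called sites
#'   (present in only one individual).
#' @export
halfCalledCount <- function(x) x@halfCalled

#' @export
setMethod("show", "InformativeSiteIndex", function(object) {
  tab <- tapply(object@classCounts$count, object@classCounts$class, sum)
  cat("InformativeSiteIndex\n")
  cat(sprintf("  %d jointly-called sites on %d chromosomes; %d half-called (excluded)\n",
              nrow(object@sites),
              length(unique(object@sites$chrom)), object@halfCalled))
  for (cl in names(tab))
    cat(sprintf("    %-17s %d\n", cl, tab[[cl]]))
})

#' Donor-fraction estimate
#'
#' The result of one ddcfDNA quantification method: per-chromosome and
#' pooled percent donor-derived cfDNA, the counts behind them, and flags for
#' chromosomes without informative coverage. The pooled value is always
#' recomputed from pooled counts, never averaged over chromosomes.
#'
#' @slot method one of "unphased-sitecount", "unphased-readfraction",
#'   "phased".
#' @slot perChrom data.frame with per-chromosome `numerator`, `denominator`
#'   and `percent` (plus method-specific columns such as per-origin matched
#'   and total counts used by [concordanceReport()]).
#' @slot pooledPercent aggregate percent ddcfDNA (NA when flagged).
#' @slot pooledNumerator,pooledDenominator pooled counts.
#' @slot flags names of chromosomes with no informative coverage.
#' @slot details method-specific extras (e.g. the background error-rate
#'   estimate and the uncorrected percent for the read-fraction method).
#'
#' @exportClass DonorFractionEstimate
setClass("DonorFractionEstimate",
  representation(
    method = "character",
    perChrom = "data.frame",
    pooledPercent = "numeric",
    pooledNumerator = "numeric",
    pooledDenominator = "numeric",
    flags = "character",
    details = "list"
  )
)

setValidity("DonorFractionEstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("unphased-sitecount", "unphased-readfraction",
                            "phased"))
    msg <- c(msg, "unknown method tag")
  p <- object@perChrom$percent
  if (any(!is.na(p) & (p < 0 | p > 100)))
    msg <- c(msg, "per-chromosome percent must lie in [0, 100]")
  if (!is.na(object@pooledPercent) &&
      (object@pooledPercent < 0 || object@pooledPercent > 100))
    msg <- c(msg, "pooled percent must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' @describeIn DonorFractionEstimate-class the method tag.
#' @param x a `DonorFractionEstimate`.
#' @export
estimateMethod <- function(x) x@method

#' @describeIn DonorFractionEstimate-class per-chromosome estimate table.
#' @export
perChromosome <- function(x) x@perChrom

#' @describeIn DonorFractionEstimate-class pooled percent ddcfDNA (NA when
#'   no informative coverage exists anywhere).
#' @export
pooledPercent <- function(x) x@pooledPercent

#' @export
setMethod("show", "DonorFractionEstimate", function(object) {
  cat(sprintf("DonorFractionEstimate [%s]\n", object@method))
  if (is.na(object@pooledPercent)) {
    cat("  pooled: no informative coverage\n")
  } else {
    cat(sprintf("  pooled: %.3f%% ddcfDNA (%.0f / %.0f)\n",
                object@pooledPercent, object@pooledNumerator,
                object@pooledDenominator))
  }
  cat(sprintf("  %d chromosomes", nrow(object@perChrom)))
  if (length(object@flags))
    cat(sprintf("; flagged no-coverage: %s",
                paste(object@flags, collapse = ", ")))
  cat("\n")
})

#' Pearson correlation result
#'
#' Pearson's r with its t statistic and two-tailed p on n - 2 degrees of
#' freedom, as produced by [pearsonTest()].
#'
#' @slot r correlation coefficient in \[-1, 1\].
#' @slot n number of paired observations.
#' @slot statistic t statistic.
#' @slot df degrees of freedom (n - 2).
#' @slot p two-tailed p-value.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(r = "numeric", n = "integer", statistic = "numeric",
                 df = "numeric", p = "numeric")
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must be <= 1")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  if (!is.na(object@p) && object@p == 0 && abs(object@r) < 1 - 1e-12)
    msg <- c(msg, "p can only be exactly 0 at |r| = 1")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson r = %.3f (n = %d, t = %.3f, df = %g, p = %.4g) %s\n",
              object@r, object@n, object@statistic, object@df, object@p,
              significanceBand(object@p)))
})
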