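# End-to-end orchestration: simulate -> emit -> read back -> hard-filter ->
# index -> call -> quantify (site-count, read-fraction, phased) ->
# fragment stats -> concordance, with a content-addressed run manifest.

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes every stage in order against files on disk, so each stage
#' consumes exactly what its reader parses: the simulator's VCFs and
#' count/fragment files are written, read back, hard-filtered, indexed and
#' quantified by all three estimators. A manifest records the seed, input
#' file digests and per-stage summaries; a rerun with an identical config
#' reproduces it byte for byte.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory for the dataset, result tables and
#'   `manifest.json`.
#' @param minSupport minimum cfDNA read support per allele (default 5).
#' @param violationFraction fraction of sites given an injected
#'   hard-filter violation (exercises the filter stage; default 0.02).
#' @return invisibly, a list with `manifest`, `index`, `estimates` (list
#'   of the three [DonorFractionEstimate-class]s), `concordance`,
#'   `fragments` (windowed means and the paired test inputs), and
#'   `control` (negative-control coverage).
#' @export
runPipeline <- function(config, outDir, minSupport = 5L,
                        violationFraction = 0.02) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dataset <- stage("simulate",
                   simulateDataset(config,
                                   violationFraction = violationFraction))
  paths <- stage("emit", emitDataset(dataset, outDir))
  donor <- stage("read-donor", readGenotypeVcf(paths[["donorVcf"]]))
  recip <- stage("read-recipient",
                 readGenotypeVcf(paths[["recipientVcf"]]))
  contigs <- attr(donor, "contigs")
  counts <- stage("read-counts", readTsv(paths[["counts"]]))

  donor$class <- classifyVariant(donor$ref, donor$alt)
  filt <- stage("filter", filterStream(donor))
  passKey <- paste(filt$passing$chrom, filt$passing$pos)
  dPass <- donor[paste(donor$chrom, donor$pos) %in% passKey, ]
  rPass <- recip[paste(recip$chrom, recip$pos) %in% passKey, ]

  index <- stage("index", buildIndex(dPass, rPass))
  writeIndex(index, file.path(outDir, "index.tsv"))
  calls <- stage("call", callCfdnaAlleles(counts, minSupport))

  estSite <- stage("quantify-sitecount",
                   estimateFractionSitecount(index, calls))
  estRead <- stage("quantify-readfraction",
                   estimateFractionReadfraction(index, counts))
  sets <- stage("phased-sets", buildPhasedSets(dPass, rPass))
  matched <- stage("phased-match",
                   matchCfdnaToSets(sets, calls, contigs))
  estPhased <- stage("quantify-phased", estimateFractionPhased(matched))
  # degenerate when every chromosome estimates identically (e.g. all 0)
  conc <- tryCatch(concordanceReport(estPhased, estSite),
                   error = function(e) NULL)
  ctrl <- stage("control",
                contaminationControl(counts, config@controlChrom, contigs))

  frag <- lapply(dataset$fragments, meanFragmentSize,
                 window = config@fragmentWindow)
  for (m in list(estSite, estRead, estPhased)) {
    writeTsv(perChromosome(m),
             file.path(outDir, paste0("estimate_", estimateMethod(m),
                                      ".tsv")))
  }
  manifest <- list(
    seed = config@seed,
    donorFraction = config@donorFraction,
    inputDigests = as.list(stats::setNames(
      unname(tools::md5sum(unname(paths))), names(paths))),
    stages = list(
      simulate = list(nSites = nrow(dataset$sites)),
      filter = filt$summary,
      index = list(jointlyCalled = nrow(indexSites(index)),
                   halfCalled = halfCalledCount(index)),
      quantify = list(
        sitecount = pooledPercent(estSite),
        readfraction = pooledPercent(estRead),
        phased = pooledPercent(estPhased)),
      concordance = if (is.null(conc)) {
        list(donorR = NA, recipientR = NA,
             note = "degenerate: zero variance across chromosomes")
      } else list(donorR = conc$donor@r, recipientR = conc$recipient@r),
      control = ctrl,
      fragments = list(baselineMean = frag$baseline$mean,
                       endpointMean = frag$endpoint$mean)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, index = index,
                 estimates = list(sitecount = estSite,
                                  readfraction = estRead,
                                  phased = estPhased),
                 concordance = conc,
                 fragments = frag, control = ctrl))
}
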