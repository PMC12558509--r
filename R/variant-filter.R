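# GATK-style hard filtering. Every inequality is strict, exactly as the
# recommended hard-filter thresholds are stated; boundary values pass.
# Missing statistics cannot be evaluated and never trigger their predicate,
# but each such non-evaluation is counted.

# name, direction, threshold per variant class
SNP_FILTERS <- list(
  QD = c(dir = -1, thr = 2.0), QUAL = c(dir = -1, thr = 30.0),
  SOR = c(dir = 1, thr = 3.0), FS = c(dir = 1, thr = 60.0),
  MQ = c(dir = -1, thr = 40.0), MQRankSum = c(dir = -1, thr = -12.5),
  ReadPosRankSum = c(dir = -1, thr = -8.0)
)
INDEL_FILTERS <- list(
  QD = c(dir = -1, thr = 2.0), QUAL = c(dir = -1, thr = 30.0),
  FS = c(dir = 1, thr = 200.0), ReadPosRankSum = c(dir = -1, thr = -20.0)
)

#' Classify a variant by its ref/alt alleles
#'
#' SNP: both alleles single, differing nucleotides. INDEL: alleles of
#' different length. Anything else (e.g. a same-length multi-nucleotide
#' substitution) is "other" and is excluded by [filterStream()] with a
#' logged reason, since neither hard-filter predicate set applies to it.
#'
#' @param ref,alt non-empty allele strings over A/C/G/T (vectorised).
#' @return character vector: "SNP", "INDEL" or "other".
#' @examples
#' classifyVariant("A", "G")   # SNP
#' classifyVariant("A", "AT")  # INDEL
#' @export
classifyVariant <- function(ref, alt) {
  ok <- nzchar(ref) & nzchar(alt) &
    grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  if (any(!ok))
    stop("alleles must be non-empty strings over A/C/G/T; offending: ",
         paste(utils::head(paste(ref[!ok], alt[!ok], sep = "/"), 5L),
               collapse = ", "))
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L & ref != alt, "SNP",
         ifelse(nchar(ref) != nchar(alt), "INDEL", "other"))
}

.evalFilters <- function(ann, filters) {
  failed <- character()
  missing <- character()
  for (nm in names(filters)) {
    v <- ann[[nm]]
    if (is.null(v) || is.na(v)) {
      missing <- c(missing, nm)
    } else {
      d <- filters[[nm]][["dir"]]
      thr <- filters[[nm]][["thr"]]
      if ((d < 0 && v < thr) || (d > 0 && v > thr)) failed <- c(failed, nm)
    }
  }
  list(pass = length(failed) == 0L, failed = failed, missing = missing)
}

#' Hard-filter verdict for one SNP record
#'
#' Fails iff QD < 2.0, QUAL < 30.0, SOR > 3.0, FS > 60.0, MQ < 40.0,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.0 (all strict). Missing
#' statistics do not trigger their predicate and are reported.
#'
#' @param ann named list / one-row data.frame of annotation statistics;
#'   if a `class` entry is present it must be "SNP".
#' @return list with `pass` (logical), `failed` (names of violated
#'   predicates) and `missing` (non-evaluable predicates).
#' @export
hardFilterSnp <- function(ann) {
  if (!is.null(ann[["class"]]) && ann[["class"]] != "SNP")
    stop("hardFilterSnp applied to a ", ann[["class"]], " record")
  .evalFilters(ann, SNP_FILTERS)
}

#' Hard-filter verdict for one INDEL record
#'
#' Fails iff QD < 2.0, QUAL < 30.0, FS > 200.0 or
#' ReadPosRankSum < -20.0 (all strict).
#'
#' @inheritParams hardFilterSnp
#' @return as [hardFilterSnp()].
#' @export
hardFilterIndel <- function(ann) {
  if (!is.null(ann[["class"]]) && ann[["class"]] != "INDEL")
    stop("hardFilterIndel applied to a ", ann[["class"]], " record")
  .evalFilters(ann, INDEL_FILTERS)
}

#' Apply the hard filters to an annotated variant stream
#'
#' Splits records by variant class, evaluates the class-appropriate strict
#' thresholds on each, and partitions the stream while preserving input
#' order. Records whose class is neither SNP nor INDEL, or whose class is
#' missing, are counted as malformed and excluded (never silently dropped:
#' they are returned under `malformed`). Failed records carry a
#' semicolon-joined `filterReasons` column.
#'
#' @param variants data.frame with a `class` column ("SNP"/"INDEL") and any
#'   of the annotation statistics QD, QUAL, SOR, FS, MQ, MQRankSum,
#'   ReadPosRankSum (missing columns = missing values).
#' @return list with `passing` (data.frame), `failed` (data.frame plus
#'   `filterReasons`), `malformed` (data.frame), and `summary` (list:
#'   `total`, `passed`, `failedCount`, `malformedCount`, per-reason counts
#'   `byReason`, per-class counts `byClass`, and `missingEvaluations`, the
#'   number of predicate evaluations skipped for missing values).
#' @export
filterStream <- function(variants) {
  n <- nrow(variants)
  cls <- variants[["class"]]
  if (is.null(cls)) cls <- rep(NA_character_, n)
  malformedMask <- is.na(cls) | !(cls %in% c("SNP", "INDEL"))
  val <- function(nm) {
    v <- variants[[nm]]
    if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
  }
  failMat <- matrix(FALSE, n, length(SNP_FILTERS),
                    dimnames = list(NULL, names(SNP_FILTERS)))
  missingEvals <- 0L
  for (nm in names(SNP_FILTERS)) {
    v <- val(nm)
    applies <- !malformedMask &
      (cls == "SNP" | (cls == "INDEL" & nm %in% names(INDEL_FILTERS)))
    missingEvals <- missingEvals + sum(applies & is.na(v))
    thrS <- SNP_FILTERS[[nm]]
    hit <- rep(FALSE, n)
    isS <- applies & cls == "SNP" & !is.na(v)
    hit[isS] <- if (thrS[["dir"]] < 0) v[isS] < thrS[["thr"]] else
      v[isS] > thrS[["thr"]]
    if (nm %in% names(INDEL_FILTERS)) {
      thrI <- INDEL_FILTERS[[nm]]
      isI <- applies & cls == "INDEL" & !is.na(v)
      hit[isI] <- if (thrI[["dir"]] < 0) v[isI] < thrI[["thr"]] else
        v[isI] > thrI[["thr"]]
    }
    failMat[, nm] <- hit
  }
  anyFail <- rowSums(failMat) > 0L
  passMask <- !malformedMask & !anyFail
  failMask <- !malformedMask & anyFail
  failed <- variants[failMask, , drop = FALSE]
  if (nrow(failed)) {
    failed$filterReasons <- apply(
      failMat[failMask, , drop = FALSE], 1L,
      function(r) paste(colnames(failMat)[r], collapse = ";"))
  } else failed$filterReasons <- character()
  byReason <- colSums(failMat)
  byClass <- c(SNP = sum(failMask & cls == "SNP"),
               INDEL = sum(failMask & cls == "INDEL"))
  list(
    passing = variants[passMask, , drop = FALSE],
    failed = failed,
    malformed = variants[malformedMask, , drop = FALSE],
    summary = list(total = n, passed = sum(passMask),
                   failedCount = sum(failMask),
                   malformedCount = sum(malformedMask),
                   byReason = as.list(byReason),
                   byClass = as.list(byClass),
                   missingEvaluations = missingEvals))
}
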