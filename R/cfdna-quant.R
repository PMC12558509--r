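# Unphased quantification from the informative-site index: allele calling
# under the minimum read-support rule, then a site-count estimator (the
# genotype-matching formulation) and a zygosity-weighted read-fraction
# estimator with background error correction (the parameter-recovery
# surface). Both are reported with distinct method tags.

#' Call cfDNA alleles under a minimum read-support rule
#'
#' An allele is present at a site iff its read count reaches `minSupport`
#' (inclusive: the default 5 means "at least five reads of support").
#' Sites where no allele reaches support yield no call and are thereby
#' excluded from downstream denominators.
#'
#' @param counts data.frame of site-level allele counts (`chrom`, `pos`,
#'   `allele`, `count`).
#' @param minSupport minimum reads for an allele to be called (>= 1).
#' @return data.frame (`chrom`, `pos`, `allele`, `count`) of called
#'   alleles.
#' @export
callCfdnaAlleles <- function(counts, minSupport = 5L) {
  if (minSupport < 1L) stop("minSupport must be >= 1")
  if (any(counts$count < 0L)) stop("negative allele counts")
  out <- counts[counts$count >= minSupport, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# donor-positive / recipient-positive masks: does the cfDNA call at a site
# contain any of the site's (comma-joined) discriminating alleles?
.discPresent <- function(sites, disc, calls) {
  callKey <- paste(calls$chrom, calls$pos, calls$allele)
  hit <- logical(nrow(sites))
  has <- disc != ""
  if (!any(has)) return(hit)
  reps <- strsplit(disc[has], ",", fixed = TRUE)
  idx <- rep(which(has), lengths(reps))
  key <- paste(sites$chrom[idx], sites$pos[idx], unlist(reps))
  found <- key %in% callKey
  hit[unique(idx[found])] <- TRUE
  hit
}

#' Site-count ddcfDNA estimator (unphased)
#'
#' Counts informative sites whose donor-discriminating allele appears in
#' the cfDNA call (numerator) against those plus sites whose
#' recipient-discriminating allele appears (denominator), per chromosome
#' and pooled. This mirrors comparing called cfDNA genotypes against the
#' donor/recipient sets; it is monotone in the true donor fraction but not
#' an unbiased estimate of it (the support threshold intervenes), so it is
#' tagged distinctly from the read-fraction estimator.
#'
#' @param index an [InformativeSiteIndex-class].
#' @param calls cfDNA allele calls from [callCfdnaAlleles()].
#' @return A [DonorFractionEstimate-class] with method
#'   "unphased-sitecount"; `details$noCallInformativeSites` counts
#'   informative sites with no called allele at all.
#' @export
estimateFractionSitecount <- function(index, calls) {
  sites <- index@sites
  donorPos <- .discPresent(sites, sites$donorDisc, calls)
  recipPos <- .discPresent(sites, sites$recipDisc, calls)
  informative <- sites$class %in% c("donor-unique", "recipient-unique",
                                    "both-unique")
  calledKey <- unique(paste(calls$chrom, calls$pos))
  noCall <- informative & !(paste(sites$chrom, sites$pos) %in% calledKey)
  chroms <- sort(unique(sites$chrom))
  tab <- function(w) as.integer(table(factor(sites$chrom[w],
                                             levels = chroms)))
  dTotalMask <- informative & sites$donorDisc != ""
  rTotalMask <- informative & sites$recipDisc != ""
  perChrom <- data.frame(
    chrom = chroms,
    numerator = tab(donorPos),
    denominator = tab(donorPos) + tab(recipPos),
    donorMatched = tab(donorPos), donorTotal = tab(dTotalMask),
    recipMatched = tab(recipPos), recipTotal = tab(rTotalMask),
    stringsAsFactors = FALSE)
  .makeEstimate("unphased-sitecount", perChrom,
                details = list(noCallInformativeSites = sum(noCall)))
}

#' Read-fraction ddcfDNA estimator (unphased, zygosity-weighted)
#'
#' Over sites where the donor carries a discriminating allele and the
#' recipient is homozygous for a non-discriminating allele, estimates
#' f = sum(w x discriminating-allele reads) / sum(depth), with w = 2 when
#' the donor is heterozygous for the discriminating allele (only half of
#' donor reads can carry it) and w = 1 when homozygous. This makes the
#' estimator's expectation equal the donor fraction under the mixture
#' model with error-free reads.
#'
#' With sequencing errors, reads flipped at recipient-homozygous sites
#' mimic donor signal; the estimator therefore measures the background
#' flip rate from shared-homozygous sites (donor and recipient homozygous
#' for the same allele, where every discordant read is an error) and
#' reports the first-order-exact corrected value
#' (raw - eps * wBar) / (1 - 2 eps) alongside the raw one. With
#' `errorCorrect = FALSE`, or when no shared-homozygous site is covered,
#' the raw value is reported.
#'
#' @param index an [InformativeSiteIndex-class] (carries both genotypes).
#' @param counts site-level allele counts (`chrom`, `pos`, `allele`,
#'   `count`) - raw counts, not threshold-filtered calls.
#' @param errorCorrect apply the background error correction (default
#'   TRUE).
#' @return A [DonorFractionEstimate-class] with method
#'   "unphased-readfraction". `details` holds `rawPercent`,
#'   `errorRateEstimate`, `meanWeight` and `nSitesUsed`.
#' @export
estimateFractionReadfraction <- function(index, counts,
                                         errorCorrect = TRUE) {
  if (any(counts$count < 0L)) stop("negative allele counts")
  sites <- index@sites
  recipHom <- sites$recipA1 == sites$recipA2
  used <- recipHom & sites$donorDisc != ""
  # donor copies of the discriminating allele(s): how many of the donor's
  # two alleles are absent from the recipient genotype
  dAll1 <- sites$donorA1
  dAll2 <- sites$donorA2
  rHomAllele <- sites$recipA1
  copies <- (dAll1 != rHomAllele) + (dAll2 != rHomAllele)
  w <- ifelse(copies > 0L, 2 / copies, NA_real_)
  siteKey <- paste(sites$chrom, sites$pos)
  cntSiteKey <- paste(counts$chrom, counts$pos)
  depthBySite <- tapply(counts$count, cntSiteKey, sum)
  depth <- as.numeric(depthBySite[siteKey])
  depth[is.na(depth)] <- 0
  # reads carrying any discriminating allele, per site
  discReads <- numeric(nrow(sites))
  has <- sites$donorDisc != ""
  if (any(has)) {
    reps <- strsplit(sites$donorDisc[has], ",", fixed = TRUE)
    idx <- rep(which(has), lengths(reps))
    key <- paste(sites$chrom[idx], sites$pos[idx], unlist(reps))
    cntKey <- paste(cntSiteKey, counts$allele)
    m <- match(key, cntKey)
    got <- !is.na(m)
    if (any(got)) {
      agg <- tapply(counts$count[m[got]], idx[got], sum)
      discReads[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  # background flip-rate estimate from shared-homozygous covered sites
  sharedHom <- sites$class == "shared" & recipHom
  epsHat <- NA_real_
  if (any(sharedHom)) {
    shKey <- siteKey[sharedHom]
    shDepth <- sum(depth[sharedHom])
    if (shDepth > 0) {
      homBase <- .alleleBaseVec(sites$recipA1[sharedHom],
                                sites$ref[sharedHom], sites$alt[sharedHom])
      matchKey <- paste(shKey, homBase)
      cntKey <- paste(cntSiteKey, counts$allele)
      m <- match(matchKey, cntKey)
      concordant <- sum(counts$count[m[!is.na(m)]])
      epsHat <- (shDepth - concordant) / shDepth
    }
  }
  chroms <- sort(unique(sites$chrom))
  chF <- factor(sites$chrom, levels = chroms)
  num <- tapply(ifelse(used, w * discReads, 0), chF, sum)
  den <- tapply(ifelse(used, depth, 0), chF, sum)
  wBarNum <- tapply(ifelse(used, w * depth, 0), chF, sum)
  correct <- function(raw, wBar) {
    if (!errorCorrect || is.na(epsHat) || epsHat == 0) return(raw)
    max(0, (raw - epsHat * wBar) / (1 - 2 * epsHat))
  }
  perChrom <- data.frame(chrom = chroms,
                         numerator = as.numeric(num),
                         denominator = as.numeric(den),
                         stringsAsFactors = FALSE)
  rawPerChrom <- ifelse(perChrom$denominator > 0,
                        perChrom$numerator / perChrom$denominator, NA_real_)
  wBarPerChrom <- ifelse(perChrom$denominator > 0,
                         as.numeric(wBarNum) / perChrom$denominator,
                         NA_real_)
  corrected <- vapply(seq_along(rawPerChrom), function(i) {
    if (is.na(rawPerChrom[i])) NA_real_
    else correct(rawPerChrom[i], wBarPerChrom[i])
  }, numeric(1L))
  # rebuild numerators so percent = 100 * numerator / denominator holds
  # after correction (keeps the pooled = pooled-counts invariant)
  perChrom$numerator <- ifelse(is.na(corrected), 0,
                               corrected * perChrom$denominator)
  est <- .makeEstimate("unphased-readfraction", perChrom)
  pooledDen <- sum(den)
  rawPooled <- if (pooledDen > 0) sum(num) / pooledDen else NA_real_
  wBar <- if (pooledDen > 0) sum(wBarNum) / pooledDen else NA_real_
  est@details <- list(
    rawPercent = 100 * rawPooled,
    errorRateEstimate = epsHat,
    meanWeight = wBar,
    nSitesUsed = sum(used & depth > 0))
  validObject(est)
  est
}

# vectorised allele index -> base (biallelic fast path, list fallback)
.alleleBaseVec <- function(idx, ref, alt) {
  simple <- !grepl(",", alt, fixed = TRUE)
  out <- character(length(idx))
  out[simple] <- ifelse(idx[simple] == 0L, ref[simple], alt[simple])
  for (i in which(!simple)) out[i] <- .alleleBase(idx[i], ref[i], alt[i])
  out
}

#' Negative-control coverage check
#'
#' Fraction of positions on the declared control chromosome carrying any
#' read, in percent. On simulator output (no control-chromosome reads)
#' this is exactly 0; on real data it plays the role of mapping reads to
#' a chromosome the cohort does not carry.
#'
#' @param counts site-level allele counts.
#' @param controlChrom control chromosome name.
#' @param contigs named vector of declared chromosome lengths; must
#'   declare `controlChrom`.
#' @return list with `coveredPositions`, `length` and `percentCovered`.
#' @export
contaminationControl <- function(counts, controlChrom, contigs) {
  if (!(controlChrom %in% names(contigs)))
    stop("control chromosome '", controlChrom,
         "' missing from the genome declaration")
  len <- contigs[[controlChrom]]
  on <- counts$chrom == controlChrom & counts$count > 0
  covered <- length(unique(counts$pos[on]))
  list(coveredPositions = covered, length = len,
       percentCovered = 100 * covered / len)
}
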