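# Haplotype-aware quantification: build disjoint donor-derived and
# recipient-derived variant sets from phased genotypes and intersect them
# with the cfDNA allele calls. Restricted to SNPs, allele matching after
# left-normalisation reduces to direct base comparison at a coordinate.

.makeEstimate <- function(method, perChrom, details = list()) {
  num <- sum(perChrom$numerator)
  den <- sum(perChrom$denominator)
  flags <- perChrom$chrom[perChrom$denominator == 0]
  perChrom$percent <- ifelse(perChrom$denominator > 0,
                             100 * perChrom$numerator / perChrom$denominator,
                             NA_real_)
  new("DonorFractionEstimate", method = method, perChrom = perChrom,
      pooledPercent = if (den > 0) 100 * num / den else NA_real_,
      pooledNumerator = num, pooledDenominator = den,
      flags = as.character(flags), details = details)
}

#' Build donor-derived and recipient-derived variant sets from phased
#' genotypes
#'
#' An allele at a site is donor-derived iff it occurs on at least one donor
#' haplotype and on neither recipient haplotype; symmetrically for
#' recipient-derived. The two sets are disjoint by construction. Inputs
#' must be phased; unphased genotypes raise an error directing to the
#' unphased informative-index method.
#'
#' @param donor,recipient phased genotype data.frames (`chrom`, `pos`,
#'   `ref`, `alt`, `a1`, `a2`, `phased = TRUE`) on shared coordinates.
#' @return list with `donorDerived` and `recipientDerived` data.frames
#'   (`chrom`, `pos`, `allele`, `donorCopies`/`recipCopies`: copies of the
#'   allele in the carrying individual) and `perChrom` set-size counts.
#' @export
buildPhasedSets <- function(donor, recipient) {
  for (nm in c("donor", "recipient")) {
    gt <- get(nm)
    if (!all(gt$phased))
      stop(nm, " genotypes are unphased; haplotype-aware set construction ",
           "requires phased input - use buildIndex() and the unphased ",
           "method instead")
  }
  if (nrow(donor) != nrow(recipient) ||
      !all(donor$chrom == recipient$chrom & donor$pos == recipient$pos))
    stop("donor and recipient must be phased on shared coordinates")
  oneOrigin <- function(a, b) {
    # alleles on >=1 'a' haplotype and neither 'b' haplotype
    out <- vector("list", nrow(a))
    for (i in seq_len(nrow(a))) {
      aAll <- unique(c(a$a1[i], a$a2[i]))
      bAll <- unique(c(b$a1[i], b$a2[i]))
      der <- setdiff(aAll, bAll)
      if (length(der)) {
        out[[i]] <- data.frame(
          chrom = a$chrom[i], pos = a$pos[i],
          allele = .alleleBase(der, a$ref[i], a$alt[i]),
          copies = vapply(der, function(al)
            sum(c(a$a1[i], a$a2[i]) == al), integer(1L)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  }
  emptySet <- data.frame(chrom = character(), pos = integer(),
                         allele = character(), copies = integer(),
                         stringsAsFactors = FALSE)
  dSet <- oneOrigin(donor, recipient)
  rSet <- oneOrigin(recipient, donor)
  if (is.null(dSet)) dSet <- emptySet
  if (is.null(rSet)) rSet <- emptySet
  names(dSet)[4L] <- "donorCopies"
  names(rSet)[4L] <- "recipCopies"
  chroms <- sort(unique(donor$chrom))
  perChrom <- data.frame(
    chrom = chroms,
    donorSetSize = as.integer(table(factor(dSet$chrom, levels = chroms))),
    recipSetSize = as.integer(table(factor(rSet$chrom, levels = chroms))),
    stringsAsFactors = FALSE)
  list(donorDerived = dSet, recipientDerived = rSet, perChrom = perChrom)
}

#' Match cfDNA allele calls against the derived variant sets
#'
#' A set member is matched iff its allele is present in the cfDNA call at
#' its site. Calls at coordinates outside the declared genome are logged
#' and skipped.
#'
#' @param sets output of [buildPhasedSets()].
#' @param calls cfDNA allele calls from [callCfdnaAlleles()] (`chrom`,
#'   `pos`, `allele`).
#' @param contigs optional named vector of declared chromosome lengths;
#'   when given, calls on undeclared chromosomes are dropped with a
#'   message.
#' @return data.frame per chromosome: `donorMatched`, `donorTotal`,
#'   `recipMatched`, `recipTotal`.
#' @export
matchCfdnaToSets <- function(sets, calls, contigs = NULL) {
  if (!is.null(contigs)) {
    off <- !(calls$chrom %in% names(contigs))
    if (any(off)) {
      message(sum(off), " cfDNA call(s) on undeclared chromosome(s) skipped")
      calls <- calls[!off, , drop = FALSE]
    }
  }
  key <- function(df) paste(df$chrom, df$pos, df$allele)
  callKey <- key(calls)
  dHit <- key(sets$donorDerived) %in% callKey
  rHit <- key(sets$recipientDerived) %in% callKey
  chroms <- sets$perChrom$chrom
  tab <- function(ch, w) as.integer(table(factor(ch[w], levels = chroms)))
  data.frame(
    chrom = chroms,
    donorMatched = tab(sets$donorDerived$chrom, dHit),
    donorTotal = sets$perChrom$donorSetSize,
    recipMatched = tab(sets$recipientDerived$chrom, rHit),
    recipTotal = sets$perChrom$recipSetSize,
    stringsAsFactors = FALSE)
}

#' Percent ddcfDNA from phased matched counts
#'
#' Per chromosome and pooled: 100 x donor-matched / (donor-matched +
#' recipient-matched). Chromosomes with a zero denominator are flagged as
#' having no informative coverage rather than reported as 0.
#'
#' @param matched output of [matchCfdnaToSets()].
#' @return A [DonorFractionEstimate-class] with method "phased". The
#'   per-chromosome table keeps the per-origin matched/total counts for
#'   [concordanceReport()].
#' @export
estimateFractionPhased <- function(matched) {
  perChrom <- data.frame(
    chrom = matched$chrom,
    numerator = matched$donorMatched,
    denominator = matched$donorMatched + matched$recipMatched,
    donorMatched = matched$donorMatched, donorTotal = matched$donorTotal,
    recipMatched = matched$recipMatched, recipTotal = matched$recipTotal,
    stringsAsFactors = FALSE)
  .makeEstimate("phased", perChrom)
}
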