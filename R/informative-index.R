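# The unphased donor/recipient informative-SNP index: classify each
# jointly-called site as shared or unique to one individual, and record the
# allele-level discriminating sets the cfDNA comparison looks for.

#' Classify one site's donor/recipient genotype pair
#'
#' Genotypes are unordered pairs of allele indices. A site is `shared` when
#' the two genotypes are identical as unordered pairs; otherwise the
#' discriminating sets decide: an allele carried by the donor but absent
#' from the recipient is donor-discriminating (and symmetrically). A
#' non-empty donor set with an empty recipient set gives `donor-unique`,
#' the converse `recipient-unique`, both non-empty `both-unique`. The
#' residual `uninformative` class (differing genotypes, both sets empty) is
#' unreachable for diploid genotypes under allele-set semantics but kept so
#' the classification is total.
#'
#' @param donorGt,recipGt integer vectors of length 2 (allele indices; 0 =
#'   ref). Order and phase are ignored.
#' @return list with `class`, `donorDisc` and `recipDisc` (sorted integer
#'   vectors of discriminating allele indices).
#' @examples
#' classifySite(c(0, 1), c(0, 0))  # donor-unique, donorDisc = 1
#' classifySite(c(1, 1), c(0, 0))  # both-unique
#' @export
classifySite <- function(donorGt, recipGt) {
  stopifnot(length(donorGt) == 2L, length(recipGt) == 2L)
  d <- sort(as.integer(donorGt))
  r <- sort(as.integer(recipGt))
  dDisc <- sort(setdiff(d, r))
  rDisc <- sort(setdiff(r, d))
  cls <- if (identical(d, r)) "shared"
    else if (length(dDisc) && length(rDisc)) "both-unique"
    else if (length(dDisc)) "donor-unique"
    else if (length(rDisc)) "recipient-unique"
    else "uninformative"
  list(class = cls, donorDisc = dDisc, recipDisc = rDisc)
}

# VCF-style sortedness: each chromosome forms one contiguous block and
# positions increase strictly within it (chromosome block order is free).
.checkSorted <- function(gt, who) {
  if (nrow(gt) < 2L) return(invisible(TRUE))
  r <- rle(gt$chrom)
  if (anyDuplicated(r$values)) {
    ch <- r$values[duplicated(r$values)][1L]
    stop(who, " genotypes not sorted: chromosome ", ch,
         " appears in more than one block")
  }
  newChrom <- c(TRUE, gt$chrom[-1L] != gt$chrom[-nrow(gt)])
  increasing <- c(TRUE, diff(gt$pos) > 0)
  bad <- !newChrom & !increasing
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(who, " genotypes not sorted by position; first offending record ",
         "at ", gt$chrom[i], ":", gt$pos[i])
  }
  invisible(TRUE)
}

# allele index -> base, given per-site ref and comma-separated alt
.alleleBase <- function(idx, ref, alt) {
  all <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1L]])
  all[idx + 1L]
}

#' Build the informative-site index for a donor-recipient pair
#'
#' One coordinated pass over two position-sorted genotype streams. Sites
#' called in only one individual are counted as half-called and excluded
#' from classification; jointly-called sites are classified with
#' [classifySite()] and their discriminating allele bases recorded.
#'
#' @param donor,recipient genotype data.frames (`chrom`, `pos`, `ref`,
#'   `alt`, `a1`, `a2`), sorted by chromosome then position.
#' @return An [InformativeSiteIndex-class].
#' @export
buildIndex <- function(donor, recipient) {
  .checkSorted(donor, "donor")
  .checkSorted(recipient, "recipient")
  dKey <- paste(donor$chrom, donor$pos)
  rKey <- paste(recipient$chrom, recipient$pos)
  common <- intersect(dKey, rKey)
  halfCalled <- (nrow(donor) - length(common)) +
    (nrow(recipient) - length(common))
  d <- donor[match(common, dKey), , drop = FALSE]
  r <- recipient[match(common, rKey), , drop = FALSE]
  if (!all(d$ref == r$ref & d$alt == r$alt)) {
    i <- which(d$ref != r$ref | d$alt != r$alt)[1L]
    stop("conflicting ref/alt declarations at ", d$chrom[i], ":", d$pos[i])
  }
  n <- nrow(d)
  biallelic <- !grepl(",", d$alt, fixed = TRUE)
  cls <- character(n)
  dDisc <- character(n)
  rDisc <- character(n)
  if (any(biallelic)) {
    # vectorised allele-presence masks over indices {0, 1}
    idx <- which(biallelic)
    dh0 <- d$a1[idx] == 0L | d$a2[idx] == 0L
    dh1 <- d$a1[idx] == 1L | d$a2[idx] == 1L
    rh0 <- r$a1[idx] == 0L | r$a2[idx] == 0L
    rh1 <- r$a1[idx] == 1L | r$a2[idx] == 1L
    dOnly0 <- dh0 & !rh0; dOnly1 <- dh1 & !rh1
    rOnly0 <- rh0 & !dh0; rOnly1 <- rh1 & !dh1
    dAny <- dOnly0 | dOnly1
    rAny <- rOnly0 | rOnly1
    same <- pmin(d$a1[idx], d$a2[idx]) == pmin(r$a1[idx], r$a2[idx]) &
      pmax(d$a1[idx], d$a2[idx]) == pmax(r$a1[idx], r$a2[idx])
    cls[idx] <- ifelse(same, "shared",
                ifelse(dAny & rAny, "both-unique",
                ifelse(dAny, "donor-unique",
                ifelse(rAny, "recipient-unique", "uninformative"))))
    join2 <- function(m0, m1, b0, b1)
      ifelse(m0 & m1, paste(b0, b1, sep = ","),
             ifelse(m0, b0, ifelse(m1, b1, "")))
    dDisc[idx] <- join2(dOnly0, dOnly1, d$ref[idx], d$alt[idx])
    rDisc[idx] <- join2(rOnly0, rOnly1, r$ref[idx], r$alt[idx])
    dDisc[idx][same] <- ""
    rDisc[idx][same] <- ""
  }
  for (i in which(!biallelic)) {
    cs <- classifySite(c(d$a1[i], d$a2[i]), c(r$a1[i], r$a2[i]))
    cls[i] <- cs$class
    dDisc[i] <- paste(.alleleBase(cs$donorDisc, d$ref[i], d$alt[i]),
                      collapse = ",")
    rDisc[i] <- paste(.alleleBase(cs$recipDisc, r$ref[i], r$alt[i]),
                      collapse = ",")
  }
  sites <- data.frame(chrom = d$chrom, pos = d$pos, ref = d$ref,
                      alt = d$alt, donorA1 = d$a1, donorA2 = d$a2,
                      recipA1 = r$a1, recipA2 = r$a2, class = cls,
                      donorDisc = dDisc, recipDisc = rDisc,
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL  # keeps the donor stream's chromosome order
  cc <- as.data.frame(table(chrom = sites$chrom, class = sites$class),
                      stringsAsFactors = FALSE)
  names(cc)[3L] <- "count"
  new("InformativeSiteIndex", sites = sites, classCounts = cc,
      halfCalled = as.integer(halfCalled))
}

#' SNP density per kilobase
#'
#' Per-chromosome density is the site count divided by the length in kb;
#' the aggregate is length-weighted, i.e. total sites over total length.
#'
#' @param index an [InformativeSiteIndex-class] (or a data.frame with a
#'   `chrom` column, e.g. a site list).
#' @param chromLengths named numeric vector of chromosome lengths (bp)
#'   covering every chromosome in the index.
#' @return list with `overall` (SNPs/kb) and `perChrom` (data.frame:
#'   `chrom`, `n`, `densityPerKb`).
#' @export
snpDensity <- function(index, chromLengths) {
  sites <- if (is(index, "InformativeSiteIndex")) index@sites else index
  chroms <- unique(sites$chrom)
  missing <- setdiff(chroms, names(chromLengths))
  if (length(missing))
    stop("no length declared for chromosome(s): ",
         paste(missing, collapse = ", "))
  counts <- table(factor(sites$chrom, levels = names(chromLengths)))
  perChrom <- data.frame(
    chrom = names(chromLengths),
    n = as.integer(counts),
    densityPerKb = as.numeric(counts) / (chromLengths / 1000),
    stringsAsFactors = FALSE)
  list(overall = nrow(sites) / (sum(chromLengths) / 1000),
       perChrom = perChrom)
}

#' Serialize / reload an informative-site index
#'
#' The TSV holds the per-site table; class counts and the half-called
#' count travel in '#' header comments so the round trip is lossless.
#'
#' @param index an [InformativeSiteIndex-class].
#' @param path TSV path.
#' @return `writeIndex`: invisibly, the path. `readIndex`: the index.
#' @export
writeIndex <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#halfCalled=%d", index@halfCalled), con)
  utils::write.table(index@sites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeIndex
#' @export
readIndex <- function(path) {
  header <- readLines(path, n = 1L)
  hc <- as.integer(sub("#halfCalled=", "", header, fixed = TRUE))
  sites <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  sites$donorDisc[is.na(sites$donorDisc)] <- ""
  sites$recipDisc[is.na(sites$recipDisc)] <- ""
  cc <- as.data.frame(table(chrom = sites$chrom, class = sites$class),
                      stringsAsFactors = FALSE)
  names(cc)[3L] <- "count"
  new("InformativeSiteIndex", sites = sites, classCounts = cc,
      halfCalled = hc)
}
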