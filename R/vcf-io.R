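# VCF and TSV I/O. Reading goes through vcfR; writing is a minimal VCF 4.2
# emitter for the simulator's biallelic SNP records (contig headers, QUAL
# column, the six INFO statistics, phased single-sample GT).

INFO_KEYS <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Write a genotype table as a phased single-sample VCF
#'
#' @param gt genotype data.frame (`chrom`, `pos`, `ref`, `alt`, `a1`, `a2`,
#'   `phased`).
#' @param annotations per-site annotation data.frame aligned with `gt`
#'   (columns QUAL plus the INFO statistics), or NULL for missing values.
#' @param config a [SimulationConfig-class]; supplies the contig
#'   declarations (including the control chromosome).
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @return invisibly, `path`.
#' @export
writeGenotypeVcf <- function(gt, annotations, config, path,
                             sample = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (i in seq_along(config@chromLengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(config@chromLengths)[i],
                       as.integer(config@chromLengths[i])), con)
  for (k in INFO_KEYS)
    writeLines(sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k), con)
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             con)
  writeLines(paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample), con)
  n <- nrow(gt)
  if (n > 0L) {
    if (is.null(annotations)) {
      qual <- rep(".", n)
      info <- rep(".", n)
    } else {
      stopifnot(nrow(annotations) == n)
      qual <- sprintf("%.2f", annotations$QUAL)
      info <- do.call(paste, c(lapply(INFO_KEYS, function(k) {
        sprintf("%s=%.3f", k, annotations[[k]])
      }), sep = ";"))
    }
    sep <- ifelse(gt$phased, "|", "/")
    writeLines(paste(gt$chrom, gt$pos, ".", gt$ref, gt$alt, qual, ".",
                     info, "GT", paste0(gt$a1, sep, gt$a2), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a VCF into a genotype stream
#'
#' Parses a VCF 4.x file via `vcfR` and returns the fields the pipeline
#' consumes: coordinates, ref/alt alleles, the first sample's allele
#' indices and phase flag, QUAL and the six INFO filter statistics
#' (NA, with a warning, when an INFO key is absent). Contig lengths from
#' the header are attached as the `contigs` attribute.
#'
#' @param path VCF path.
#' @param requirePhased error (with guidance towards the unphased method)
#'   if any genotype uses the unphased "/" separator.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `a1`, `a2`,
#'   `phased`, `QUAL`, and the INFO statistics; attribute `contigs` is a
#'   named numeric vector of header contig lengths.
#' @export
readGenotypeVcf <- function(path, requirePhased = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record files drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  contigs <- .parseContigs(vcf@meta)
  if (nrow(vcf@fix) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      a1 = integer(), a2 = integer(), phased = logical())
    attr(out, "contigs") <- contigs
    return(out)
  }
  gtStr <- as.character(vcfR::extract.gt(vcf)[, 1L])
  phased <- grepl("|", gtStr, fixed = TRUE)
  if (requirePhased && any(!phased))
    stop("unphased genotypes ('/') found at ",
         sum(!phased), " site(s); the phased method requires '|' ",
         "genotypes - use the unphased informative-index method instead")
  alleles <- strsplit(gtStr, "[|/]")
  bad <- lengths(alleles) != 2L
  if (any(bad)) stop("non-diploid GT at line(s): ",
                     paste(utils::head(which(bad), 5L), collapse = ", "))
  a <- matrix(as.integer(unlist(alleles)), ncol = 2L, byrow = TRUE)
  out <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    a1 = a[, 1L], a2 = a[, 2L], phased = phased,
    QUAL = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE)
  present <- vapply(INFO_KEYS, function(k)
    grepl(sprintf("##INFO=<ID=%s,", k), paste(vcf@meta, collapse = "\n"),
          fixed = TRUE), logical(1L))
  for (k in INFO_KEYS) {
    out[[k]] <- if (present[[k]]) {
      suppressWarnings(vcfR::extract.info(vcf, element = k,
                                          as.numeric = TRUE))
    } else NA_real_
  }
  if (any(!present))
    warning("missing INFO key(s): ",
            paste(INFO_KEYS[!present], collapse = ", "),
            "; their predicates will be treated as non-evaluable")
  rownames(out) <- NULL
  attr(out, "contigs") <- contigs
  out
}

.parseContigs <- function(meta) {
  lines <- grep("^##contig=", meta, value = TRUE)
  if (!length(lines)) return(stats::setNames(numeric(), character()))
  ids <- sub(".*ID=([^,>]+).*", "\\1", lines)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                          lines)))
  stats::setNames(lens, ids)
}

#' Write / read a tab-separated table
#'
#' Plain TSV with a header row; `readTsv` reports malformed lines (wrong
#' field count) with their line numbers instead of silently dropping them.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `writeTsv`: invisibly, the path. `readTsv`: a data.frame.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop("malformed line(s) in ", path, ": ",
         paste(utils::head(bad, 5L), collapse = ", "))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a plain-text fragment-size list
#'
#' One fragment size (bp) per line.
#'
#' @param path file path.
#' @return numeric vector.
#' @export
readFragmentSizes <- function(path) {
  as.numeric(readLines(path))
}
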