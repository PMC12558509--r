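# Shared fixtures: small configs and hand-built genotype/count tables.

smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    chromLengths = c(chr1 = 30000, chr2 = 30000, chr3 = 30000,
                     ctrl = 5000),
    controlChrom = "ctrl", seed = 42L)
  do.call(simulationConfig, utils::modifyList(defaults, args))
}

# genotype data.frame from parallel vectors of allele-index pairs
makeGt <- function(chrom, pos, ref, alt, a1, a2, phased = TRUE) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             a1 = a1, a2 = a2, phased = phased, stringsAsFactors = FALSE)
}

makeCounts <- function(chrom, pos, allele, count) {
  data.frame(chrom = chrom, pos = pos, allele = allele, count = count,
             stringsAsFactors = FALSE)
}

# Delta-method standard error of the background-corrected read-fraction
# estimator, computed from the model truth (true f and epsilon) plus the
# realised depths: binomial variance of the weighted discriminating-read
# sum, plus the propagated variance of the background-rate estimate.
readFractionSE <- function(idx, counts, f, eps) {
  sites <- indexSites(idx)
  depthBySite <- tapply(counts$count, paste(counts$chrom, counts$pos), sum)
  depth <- as.numeric(depthBySite[paste(sites$chrom, sites$pos)])
  depth[is.na(depth)] <- 0
  recipHom <- sites$recipA1 == sites$recipA2
  used <- recipHom & sites$donorDisc != ""
  copies <- (sites$donorA1 != sites$recipA1) +
    (sites$donorA2 != sites$recipA1)
  w <- 2 / copies[used]
  n <- depth[used]
  cc <- copies[used]
  q <- f * (cc / 2) * (1 - eps) + f * (1 - cc / 2) * eps + (1 - f) * eps
  varRaw <- sum(w^2 * n * q * (1 - q)) / sum(n)^2
  wBar <- sum(w * n) / sum(n)
  nShared <- sum(depth[sites$class == "shared" & recipHom])
  varEps <- if (eps > 0 && nShared > 0) eps * (1 - eps) / nShared else 0
  sqrt(varRaw + wBar^2 * varEps) / (1 - 2 * eps)
}

# nominal annotation row that passes every hard filter
nominalAnn <- function(class = "SNP", ...) {
  ann <- list(class = class, QD = 20, QUAL = 500, SOR = 1, FS = 10,
              MQ = 55, MQRankSum = 0, ReadPosRankSum = 0)
  utils::modifyList(ann, list(...))
}
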