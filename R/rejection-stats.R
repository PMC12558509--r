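# Rejection-marker statistics: Pearson correlations of percent ddcfDNA
# against troponin, time to rejection and fragment size, the paired
# fragment-size test, and phased/unphased per-chromosome concordance.

#' The six-animal study table
#'
#' Per-animal troponin (ng/L), time to rejection (days; the one
#' non-rejecting animal carries its sacrifice day, 106, with
#' `rejection_censored = TRUE`), windowed mean cfDNA fragment sizes at
#' baseline and endpoint (bp), and percent ddcfDNA by the phased and
#' unphased methods. Shipped as a TSV fixture in `extdata`.
#'
#' @return data.frame with one row per animal A-F.
#' @examples
#' animalTable()
#' @export
animalTable <- function() {
  path <- system.file("extdata", "animal_table.tsv", package = "ddcfdna")
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal", "troponin_ng_per_l", "time_to_rejection_days",
            "rejection_censored", "baseline_fragment_bp",
            "endpoint_fragment_bp", "pct_ddcfdna_phased",
            "pct_ddcfdna_unphased")
  if (!all(need %in% names(tbl)) || nrow(tbl) != 6L)
    stop("animal table fixture is incomplete")
  tbl
}

#' Pearson correlation with t-based p-value
#'
#' Standard Pearson r with a two-tailed p from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return A [CorrelationResult-class].
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  new("CorrelationResult", r = unname(ct$estimate),
      n = length(x), statistic = unname(ct$statistic),
      df = unname(ct$parameter), p = ct$p.value)
}

#' Significance band notation
#'
#' Maps a p-value to the conventional bands: p > 0.05 "ns", p < 0.05 "*",
#' p < 0.01 "**", p < 0.001 "***", p < 0.0001 "****".
#'
#' @param p p-value(s).
#' @return character vector of band labels.
#' @export
significanceBand <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1L))
}

#' Rejection-marker report
#'
#' From the animal table, computes the four marker statistics: Pearson r
#' of unphased percent ddcfDNA against (A) log-transformed troponin,
#' (B) time to rejection with the censored animal included at its
#' sacrifice day, and (C) endpoint fragment size; plus (D) the paired
#' one-tailed t-test of endpoint vs baseline fragment size. A sensitivity
#' recomputation of (B) without the censored animal is always included.
#' Troponin uses the natural log; Pearson r is invariant to the log base.
#'
#' @param tbl the animal table (default [animalTable()]).
#' @return list of labelled results: `troponinLog`, `rejectionTime`,
#'   `rejectionTimeUncensored` ([CorrelationResult-class]s),
#'   `endpointFragment`, and `fragmentIncrease` (paired t result from
#'   [compareConditions()]); each element carries an `inputs` attribute
#'   naming the columns used.
#' @export
rejectionMarkerStats <- function(tbl = animalTable()) {
  need <- c("troponin_ng_per_l", "time_to_rejection_days",
            "baseline_fragment_bp", "endpoint_fragment_bp",
            "pct_ddcfdna_unphased", "rejection_censored")
  if (!all(need %in% names(tbl))) stop("animal table is incomplete")
  dd <- tbl$pct_ddcfdna_unphased
  lab <- function(res, inputs) { attr(res, "inputs") <- inputs; res }
  unc <- !tbl$rejection_censored
  list(
    troponinLog = lab(pearsonTest(dd, log(tbl$troponin_ng_per_l)),
                      c("pct_ddcfdna_unphased", "log(troponin_ng_per_l)")),
    rejectionTime = lab(pearsonTest(dd, tbl$time_to_rejection_days),
                        c("pct_ddcfdna_unphased",
                          "time_to_rejection_days (censored at day 106)")),
    rejectionTimeUncensored = lab(
      pearsonTest(dd[unc], tbl$time_to_rejection_days[unc]),
      c("pct_ddcfdna_unphased", "time_to_rejection_days (rejectors only)")),
    endpointFragment = lab(pearsonTest(dd, tbl$endpoint_fragment_bp),
                           c("pct_ddcfdna_unphased",
                             "endpoint_fragment_bp")),
    fragmentIncrease = lab(compareConditions(tbl$baseline_fragment_bp,
                                             tbl$endpoint_fragment_bp),
                           c("baseline_fragment_bp",
                             "endpoint_fragment_bp")))
}

#' Phased vs unphased per-chromosome concordance
#'
#' Pearson correlation between the two methods' per-chromosome percent
#' vectors: percent donor-derived (each chromosome's percent ddcfDNA) and
#' percent recipient-derived (its complement within the matched counts).
#' With these definitions the two correlations coincide numerically; both
#' are reported because they answer for the two variant-set origins. The
#' chromosome sets must match.
#'
#' @param phased,unphased [DonorFractionEstimate-class]s with matched
#'   per-chromosome tables.
#' @return list with `donor` and `recipient` [CorrelationResult-class]s.
#' @export
concordanceReport <- function(phased, unphased) {
  pc <- perChromosome(phased)
  uc <- perChromosome(unphased)
  if (!identical(sort(pc$chrom), sort(uc$chrom)))
    stop("mismatched chromosome sets between the two methods")
  uc <- uc[match(pc$chrom, uc$chrom), ]
  pct <- function(n, d) ifelse(d > 0, 100 * n / d, NA_real_)
  list(
    donor = pearsonTest(pct(pc$numerator, pc$denominator),
                        pct(uc$numerator, uc$denominator)),
    recipient = pearsonTest(
      pct(pc$denominator - pc$numerator, pc$denominator),
      pct(uc$denominator - uc$numerator, uc$denominator)))
}
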