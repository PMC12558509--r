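# cfDNA fragment-size statistics: windowed means and the paired
# baseline-vs-endpoint comparison.

#' Windowed mean cfDNA fragment size
#'
#' Arithmetic mean of the sizes inside the closed window (default
#' \[40, 10000\] bp, the instrument's measurement range). An empty input,
#' or a sample with nothing in-window, is flagged rather than reported
#' as 0.
#'
#' @param sizes numeric vector of fragment sizes (bp, > 0).
#' @param window closed \[min, max\] window in bp.
#' @return list with `mean` (NA when flagged), `nUsed` and `flagged`.
#' @examples
#' meanFragmentSize(c(30, 100, 200, 12000))  # mean 150 over 2 fragments
#' @export
meanFragmentSize <- function(sizes, window = c(40, 10000)) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(min, max) with min < max")
  if (length(sizes) && any(sizes <= 0, na.rm = TRUE))
    stop("fragment sizes must be > 0")
  inWin <- sizes >= window[1] & sizes <= window[2]
  used <- sizes[which(inWin)]
  if (!length(used))
    return(list(mean = NA_real_, nUsed = 0L, flagged = TRUE))
  list(mean = mean(used), nUsed = length(used), flagged = FALSE)
}

#' Paired one-tailed comparison of fragment sizes across conditions
#'
#' Paired Student's t-test of per-animal endpoint means against baseline
#' means, one-tailed for the alternative endpoint > baseline (fragment
#' sizes grow with apoptosis at rejection).
#'
#' @param baseline,endpoint equal-length paired numeric vectors of
#'   per-animal mean fragment sizes (n >= 2).
#' @return list with `t`, `df`, `p` (one-tailed) and `meanDifference`.
#' @export
compareConditions <- function(baseline, endpoint) {
  if (length(baseline) != length(endpoint))
    stop("baseline and endpoint must be paired vectors of equal length")
  if (length(baseline) < 2L) stop("need at least 2 pairs")
  d <- endpoint - baseline
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t-test undefined")
  tt <- stats::t.test(endpoint, baseline, paired = TRUE,
                      alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDifference = mean(d))
}
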