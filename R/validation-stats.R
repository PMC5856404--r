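# Analytical-validation statistics: exact binomial confidence intervals,
# pooled sensitivity, per-base specificity, precision (%CV), extraction
# efficiency and cross-method allele-fraction concordance.

#' Exact (Clopper-Pearson) binomial confidence interval, in percent
#'
#' Two-sided exact interval via beta quantiles. Boundary cases use the
#' closed forms: at `x = n` the upper limit is 100% and the lower limit
#' `100 * (alpha/2)^(1/n)`; at `x = 0` the lower limit is 0% and the upper
#' `100 * (1 - (alpha/2)^(1/n))`.
#'
#' @param x successes (0 <= x <= n).
#' @param n trials (>= 1).
#' @param level confidence level in (0, 1), e.g. 0.90 or 0.95.
#' @return named numeric: `estimate`, `lower`, `upper` (percent).
#' @export
clopperPearson <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n with n >= 1")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(estimate = 100 * x / n, lower = 100 * lower, upper = 100 * upper)
}

#' Pool sensitivity across strata (e.g. two laboratories)
#'
#' With explicit `(x, n)` strata the pooled estimate is `sum(x) / sum(n)`.
#' When only stratum percentages are available, equal trial counts are
#' assumed (and recorded in the output), making the pooled value the mean of
#' the percentages. Display values are rounded half-up to 2 decimals;
#' computation stays at full precision.
#'
#' @param strata either a data.frame with columns `x` and `n`, or a numeric
#'   vector of stratum sensitivities in percent.
#' @return list with `pooled` (full precision, percent), `display` (rounded),
#'   `assumed_equal_n` (logical), `x`, `n` (totals when available).
#' @export
pooledSensitivity <- function(strata) {
  if (is.data.frame(strata)) {
    if (!all(c("x", "n") %in% colnames(strata)))
      stop("stratum data.frame needs columns x and n")
    pooled <- 100 * sum(strata$x) / sum(strata$n)
    list(pooled = pooled, display = roundHalfUp(pooled, 2),
         assumed_equal_n = FALSE, x = sum(strata$x), n = sum(strata$n))
  } else if (is.numeric(strata)) {
    if (!length(strata)) stop("no strata supplied")
    pooled <- mean(strata)
    list(pooled = pooled, display = roundHalfUp(pooled, 2),
         assumed_equal_n = TRUE, x = NA_real_, n = NA_real_)
  } else stop("strata must be a data.frame with x/n or a numeric vector ",
              "of percentages")
}

#' Per-base specificity of a cohort screen
#'
#' `100 * (1 - FP / (nSamples * footprintBases))`: one minus false-positive
#' calls per interrogated base across the cohort. The denominator convention
#' (bases, not bases x substitutions) is explicit in the returned record.
#'
#' @param falsePositives false-positive call count.
#' @param nSamples samples screened.
#' @param footprintBases unique panel bases interrogated per sample.
#' @return list with `specificity` (percent), `fp_per_base`, `denominator`,
#'   `denominator_definition`.
#' @export
perBaseSpecificity <- function(falsePositives, nSamples, footprintBases) {
  if (any(c(falsePositives, nSamples, footprintBases) < 0))
    stop("counts must be >= 0")
  den <- nSamples * footprintBases
  if (den <= 0) stop("denominator must be positive")
  rate <- falsePositives / den
  list(specificity = 100 * (1 - rate), fp_per_base = rate, denominator = den,
       denominator_definition = "samples x unique panel footprint bases")
}

#' Precision as percent coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param x numeric measurements (>= 2 values, non-zero mean).
#' @return %CV as a single number.
#' @export
percentCv <- function(x) {
  if (length(x) < 2) stop("need >= 2 measurements")
  m <- mean(x)
  if (m == 0) stop("mean is zero; %CV undefined")
  100 * stats::sd(x) / m
}

#' Extraction efficiency of a spike-in control
#'
#' Measured recovered copies relative to the expected spiked amount; values
#' above 1 are allowed but flagged as over-recovery.
#'
#' @param measuredCopies recovered copies (e.g. quantified by dPCR).
#' @param expectedSpikedCopies spiked copies (> 0).
#' @return list with `efficiency` (fraction) and `over_recovery` flag.
#' @export
extractionEfficiency <- function(measuredCopies, expectedSpikedCopies) {
  if (expectedSpikedCopies <= 0) stop("expected spiked copies must be > 0")
  eff <- measuredCopies / expectedSpikedCopies
  list(efficiency = eff, over_recovery = eff > 1)
}

#' Cross-method allele-fraction concordance
#'
#' Summarizes paired AF measurements from two quantification methods (e.g.
#' sequencing vs droplet PCR): mean signed difference (A - B), ratio of
#' means, and Pearson correlation (guarded against constant input).
#'
#' @param afA,afB paired allele fractions (>= 3 pairs).
#' @return list with `mean_difference`, `ratio_of_means`, `pearson_r`
#'   (`NA` with `constant_input = TRUE` when either side is constant), and
#'   the per-pair table.
#' @export
afConcordance <- function(afA, afB) {
  if (length(afA) != length(afB)) stop("afA and afB must be paired")
  if (length(afA) < 3) stop("need >= 3 pairs")
  constant <- stats::sd(afA) == 0 || stats::sd(afB) == 0
  list(mean_difference = mean(afA - afB),
       ratio_of_means = mean(afA) / mean(afB),
       pearson_r = if (constant) NA_real_ else stats::cor(afA, afB),
       constant_input = constant,
       pairs = data.frame(af_a = afA, af_b = afB,
                          difference = afA - afB))
}
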