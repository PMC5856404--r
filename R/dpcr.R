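# Digital PCR quantification and the dual-binomial limit-of-detection
# statistics. Discrete binomial percentiles are defined as the smallest
# integer whose CDF reaches the target probability, which makes the
# alpha/beta round-trip hold conservatively.

#' Poisson quantification of a dPCR reaction
#'
#' Converts a positive-droplet count into the mean occupancy per droplet
#' (`lambda = -ln(1 - k/n)`) and a concentration in copies per microliter
#' using the partition volume.
#'
#' @param kPositive positive droplets.
#' @param nDroplets accepted droplets (`kPositive < nDroplets`; a saturated
#'   reaction has undefined occupancy).
#' @param partitionVolumeNl droplet volume in nL (default 0.85).
#' @return list with `lambda` (copies per droplet) and `copiesPerUl`.
#' @export
poissonConcentration <- function(kPositive, nDroplets,
                                 partitionVolumeNl = 0.85) {
  if (any(kPositive < 0) || any(nDroplets <= 0))
    stop("counts must satisfy 0 <= kPositive < nDroplets")
  if (any(kPositive >= nDroplets))
    stop("saturated reaction (k = n): lambda undefined")
  lambda <- -log(1 - kPositive / nDroplets)
  list(lambda = lambda, copiesPerUl = lambda / (partitionVolumeNl * 1e-3))
}

#' Estimate the per-droplet false-positive rate from wild-type controls
#'
#' Pools mutant-positive droplets (single plus double positive) over all
#' wild-type control reactions and divides by total accepted droplets.
#'
#' @param wtControls data.frame of droplet counts (columns `n_droplets`,
#'   `mut_single_pos`, `double_pos`), one row per reaction.
#' @return the pooled false-positive rate per droplet (lambda).
#' @export
estimateFpr <- function(wtControls) {
  if (!nrow(wtControls)) stop("need at least one wild-type control reaction")
  tot <- sum(wtControls$n_droplets)
  if (tot <= 0) stop("zero accepted droplets")
  pos <- sum(wtControls$mut_single_pos + wtControls$double_pos)
  pos / tot
}

#' Limit of detection from two binomial distributions
#'
#' The critical level is the 95th percentile (alpha = 0.05 by default) of
#' `Binomial(n, fprLambda)` — the largest droplet count plausibly produced by
#' false positives alone. The detectable per-droplet positive probability is
#' the smallest `p` for which the beta-quantile of `Binomial(n, p)` does not
#' fall below the critical level, i.e. `P(X <= critical) <= beta`, solved by
#' bisection on the exact CDF. The LOD in mutant copies per reaction is
#' `n * -ln(1 - p)`; expressed as AF% it is relative to total target copies
#' (`n * wtLambda` wild-type plus the mutant copies).
#'
#' With `fprLambda = 0` the critical level is 0 and the LOD reduces to the
#' closed form `-ln(beta)` copies per reaction (about 3.00 for beta = 0.05),
#' independent of droplet count.
#'
#' @param fprLambda false-positive rate per droplet (< 1).
#' @param nDroplets mean accepted droplets per reaction.
#' @param wtLambda wild-type copies per droplet (for the AF% conversion).
#' @param alpha,beta false-positive / false-negative probabilities
#'   (defaults 0.05).
#' @return an [LODResult-class].
#' @export
computeLod <- function(fprLambda, nDroplets, wtLambda = 0,
                       alpha = 0.05, beta = 0.05) {
  if (fprLambda < 0 || fprLambda >= 1) stop("fprLambda must lie in [0, 1)")
  if (nDroplets < 1) stop("nDroplets must be >= 1")
  n <- round(nDroplets)
  critical <- stats::qbinom(1 - alpha, n, fprLambda)  # smallest k, CDF >= 1-alpha
  # smallest p with P(X <= critical) <= beta
  f <- function(p) stats::pbinom(critical, n, p) - beta
  lo <- fprLambda; hi <- 1 - 1e-12
  if (f(lo) < 0) {
    pDet <- lo  # degenerate: even the FPR alone clears the critical level
  } else {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-12 * hi) break
    }
    pDet <- hi
  }
  lodCopies <- n * -log(1 - pDet)
  lodAf <- if (wtLambda > 0 || lodCopies > 0)
    min(max(100 * lodCopies / (n * wtLambda + lodCopies), 0), 100) else 0
  methods::new("LODResult", fprLambda = fprLambda, nDroplets = as.numeric(n),
               criticalLevel = as.integer(critical), pDet = pDet,
               lodCopies = lodCopies, lodAfPercent = lodAf,
               wtLambda = wtLambda, alpha = alpha, beta = beta)
}

#' Read / write droplet-count CSV
#'
#' Columns: `reaction_id`, `n_droplets`, `mut_single_pos`, `wt_single_pos`,
#' `double_pos`, `negative`, optional `partition_volume_nl`.
#'
#' @param path CSV path.
#' @return data.frame of droplet counts.
#' @export
readDropletCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "n_droplets", "mut_single_pos", "wt_single_pos",
            "double_pos", "negative")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("droplet CSV missing columns: ", paste(miss, collapse = ", "))
  sums <- df$mut_single_pos + df$wt_single_pos + df$double_pos + df$negative
  if (any(sums != df$n_droplets))
    stop("droplet classes must sum to n_droplets")
  if (!"partition_volume_nl" %in% colnames(df))
    df$partition_volume_nl <- 0.85
  df
}

#' @rdname readDropletCsv
#' @param droplets data.frame of droplet counts.
#' @export
writeDropletCsv <- function(droplets, path) {
  utils::write.csv(droplets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
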