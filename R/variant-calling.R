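# Replicate-aware maximum-likelihood variant calling against the
# beta-binomial background null, threshold calibration to a per-base
# specificity budget, SNP contamination checks and CNV inference from
# normalized depth.

#' Per-replicate log-likelihood under the mixture model
#'
#' A replicate's alt count is modeled as beta-binomial with success rate
#' `af + (1 - af) * mu` — the true variant fraction plus background error on
#' the non-mutant molecules — and the overdispersion `rho` of the background
#' entry. At `af = 0` this reduces exactly to the null (background-only)
#' likelihood.
#'
#' @param alt,depth integer vectors (recycled) of alt counts and depths.
#' @param mu background mean error rate.
#' @param rho background intra-class correlation (0 = binomial).
#' @param af candidate allele fraction in `[0, 1]`.
#' @return numeric vector of per-replicate log-likelihoods.
#' @export
replicateLoglik <- function(alt, depth, mu, rho, af) {
  if (af < 0 || af > 1) stop("af must lie in [0, 1]")
  p <- af + (1 - af) * mu
  dbetabinomLog(alt, depth, p, rho)
}

# Vectorized golden-section maximization of the joint (shared-af) likelihood
# for many loci at once. altMat/depthMat are loci x replicates; mu, rho per
# locus. One new likelihood evaluation per iteration (the other interior
# point is reused). 45 iterations bracket the maximizer to ~4e-10.
# Returns afHat, llHat, ll0.
.jointMleVec <- function(altMat, depthMat, mu, rho, iters = 45L) {
  L <- nrow(altMat); R <- ncol(altMat)
  altV <- as.vector(altMat); depthV <- as.vector(depthMat)
  rhoR <- rep(rho, times = R)
  evalLL <- function(af) {
    p <- rep(af + (1 - af) * mu, times = R)
    rowSums(matrix(dbetabinomLog(altV, depthV, p, rhoR), nrow = L))
  }
  gr <- (sqrt(5) - 1) / 2
  a <- rep(0, L); b <- rep(1, L)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- evalLL(x1); f2 <- evalLL(x2)
  for (it in seq_len(iters)) {
    left <- f1 >= f2  # maximum in [a, x2]
    b <- ifelse(left, x2, b)
    a <- ifelse(left, a, x1)
    x2New <- ifelse(left, x1, a + gr * (b - a))
    x1New <- ifelse(left, b - gr * (b - a), x2)
    fKnown <- ifelse(left, f1, f2)       # value carried to the reused point
    knownIsX2 <- left                    # reused point becomes x2 when left
    xEval <- ifelse(left, x1New, x2New)
    fEval <- evalLL(xEval)
    x1 <- x1New; x2 <- x2New
    f1 <- ifelse(knownIsX2, fEval, fKnown)
    f2 <- ifelse(knownIsX2, fKnown, fEval)
  }
  afHat <- (a + b) / 2
  llHat <- evalLL(afHat)
  ll0 <- evalLL(0)
  poolAlt <- rowSums(altMat)
  zero <- poolAlt == 0
  afHat[zero] <- 0
  llHat[zero] <- ll0[zero]
  list(afHat = afHat, llHat = llHat, ll0 = ll0)
}

#' Integrate evidence across replicates by maximum likelihood
#'
#' Maximizes the sum of per-replicate log-likelihoods over a shared allele
#' fraction; the decision statistic is the likelihood-ratio
#' `lr = 2 (loglik(afHat) - loglik(0))`. Replicates with zero depth are
#' excluded from the locus rather than failing the sample.
#'
#' @param alt,depth integer vectors, one entry per replicate (>= 2
#'   replicates).
#' @param mu,rho background entry parameters.
#' @return list with `afMle`, `lr`, `afPooled`, `nReplicates`; or status
#'   `"no_coverage"` when all depths are zero.
#' @export
integrateReplicates <- function(alt, depth, mu, rho) {
  if (length(alt) < 2 || length(alt) != length(depth))
    stop("need >= 2 replicates with matching alt/depth vectors")
  keep <- depth > 0
  if (!any(keep))
    return(list(afMle = NA_real_, lr = NA_real_, afPooled = NA_real_,
                nReplicates = 0L, status = "no_coverage"))
  alt <- alt[keep]; depth <- depth[keep]
  res <- .jointMleVec(matrix(alt, nrow = 1), matrix(depth, nrow = 1),
                      mu, rho)
  lr <- max(0, 2 * (res$llHat - res$ll0))
  list(afMle = res$afHat, lr = lr, afPooled = sum(alt) / sum(depth),
       nReplicates = sum(keep), status = "ok")
}

#' Calibrate the likelihood-ratio call threshold to a specificity budget
#'
#' Simulates wild-type samples from the fitted background model (beta-
#' binomial counts at every position x substitution across replicates) and
#' finds the smallest threshold whose per-base false-call rate stays within
#' the budget. The budget's tail probability (about 1e-6 per test) cannot be
#' resolved by counting alone at a feasible number of simulations, so the
#' simulated null is extrapolated with an exponential fit to its upper
#' excesses (a peaks-over-threshold tail model): the returned threshold is
#' the largest of (i) the empirical smallest-threshold rule, (ii) the
#' extrapolated tail quantile at the per-test budget divided by
#' `safetyFactor`, and (iii) the asymptotic chi-square quantile. The safety
#' factor (default 2) covers the estimation uncertainty of the background
#' parameters themselves; signal likelihood ratios are orders of magnitude
#' above the threshold, so sensitivity is essentially unaffected.
#'
#' @param background a [BackgroundModel-class].
#' @param budget expected false calls per interrogated base (default 3e-6,
#'   consistent with a per-base specificity of 99.9997%).
#' @param nSim number of simulated wild-type samples (default 50).
#' @param nReplicates,depthPerReplicate simulated replicate structure.
#' @param safetyFactor conservatism applied to the per-test budget in the
#'   tail extrapolation (default 2).
#' @param seed integer seed.
#' @return list of class `CallThresholds` with elements `snv`, `indel`,
#'   `budget`, `nSim`, `nullMax` (largest simulated null statistic) and the
#'   three candidate thresholds.
#' @export
calibrateThreshold <- function(background, budget = 3e-6, nSim = 50,
                               nReplicates = 8, depthPerReplicate = 4000,
                               safetyFactor = 2, seed = 1) {
  bg <- background@snv
  if (!nrow(bg)) stop("background model has no SNV entries")
  nBases <- nrow(unique(bg[, c("chrom", "pos")]))
  set.seed(seed)
  L <- nrow(bg)
  allLr <- numeric(0)
  for (s in seq_len(nSim)) {
    depthMat <- matrix(stats::rpois(L * nReplicates, depthPerReplicate),
                       nrow = L)
    altMat <- matrix(rbetabinom(L * nReplicates, as.vector(depthMat),
                                rep(bg$mean, nReplicates),
                                rep(bg$rho, nReplicates)), nrow = L)
    nz <- rowSums(altMat) > 0
    if (!any(nz)) next
    res <- .jointMleVec(altMat[nz, , drop = FALSE],
                        depthMat[nz, , drop = FALSE],
                        bg$mean[nz], bg$rho[nz])
    lr <- pmax(0, 2 * (res$llHat - res$ll0))
    allLr <- c(allLr, lr[lr > 0])
  }
  nTests <- as.numeric(nSim) * L          # position x substitution tests
  budgetPerTest <- budget * nBases / L    # budget is per base (3 tests/base)
  # (i) empirical smallest-threshold rule on the per-base rate
  kMax <- floor(budget * as.numeric(nSim) * nBases)
  srt <- sort(allLr, decreasing = TRUE)
  empThr <- if (length(srt) > kMax) srt[kMax + 1] + 1e-9 else 0
  # (ii) exponential peaks-over-threshold extrapolation of the null tail
  evtThr <- 0
  if (length(allLr) >= 50) {
    u <- stats::quantile(allLr, 0.99, names = FALSE)
    exc <- allLr[allLr > u] - u
    if (length(exc) >= 10) {
      pU <- length(exc) / nTests
      pTarget <- budgetPerTest / safetyFactor
      if (pU > pTarget)
        evtThr <- u + mean(exc) * log(pU / pTarget)
    }
  }
  # (iii) asymptotic floor
  asympThr <- stats::qchisq(1 - budgetPerTest, df = 1)
  thr <- max(empThr, evtThr, asympThr)
  structure(list(snv = thr, indel = thr, budget = budget, nSim = nSim,
                 nullMax = if (length(srt)) srt[1] else 0,
                 empirical = empThr, tail_extrapolated = evtThr,
                 asymptotic = asympThr),
            class = "CallThresholds")
}

# Reshape one sample's snv counts into per-substitution matrices.
.sampleSubMatrices <- function(snv) {
  dt <- data.table::as.data.table(snv)
  reps <- sort(unique(dt$replicate))
  key <- paste(dt$chrom, dt$pos, sep = ":")
  loci <- dt[!duplicated(key), c("amplicon_id", "chrom", "pos", "ref")]
  lkey <- paste(loci$chrom, loci$pos, sep = ":")
  L <- nrow(loci); R <- length(reps)
  depth <- matrix(0L, L, R)
  baseCounts <- list(A = matrix(0L, L, R), C = matrix(0L, L, R),
                     G = matrix(0L, L, R), T = matrix(0L, L, R))
  rowI <- match(key, lkey)
  colI <- match(dt$replicate, reps)
  for (b in c("A", "C", "G", "T"))
    baseCounts[[b]][cbind(rowI, colI)] <- dt[[b]]
  depth <- baseCounts$A + baseCounts$C + baseCounts$G + baseCounts$T
  list(loci = as.data.frame(loci), reps = reps, depth = depth,
       baseCounts = baseCounts)
}

#' Call variants in a sample against a calibrated background
#'
#' Evaluates every panel position x substitution (and every observed indel
#' allele) with [integrateReplicates()]-style joint MLE, and reports loci
#' whose likelihood-ratio statistic reaches the calibrated threshold.
#' Positions whose background entry is flagged `low_confidence` are reported
#' with status `low_confidence_region` unless `ackLowConfidence = TRUE`.
#'
#' @param tensor an [AlleleCountTensor-class] for one sample (multiple
#'   replicates).
#' @param background a [BackgroundModel-class] fitted on the same panel.
#' @param thresholds a `CallThresholds` from [calibrateThreshold()].
#' @param panel the [PanelDesign-class].
#' @param reportAll also return not-called loci with alt evidence (default
#'   FALSE: only calls).
#' @param minMeanDepth QC gate: mean per-replicate panel depth required to
#'   call the sample (default 0 = no gate).
#' @param ackLowConfidence evaluate low-confidence background positions as
#'   normal (default FALSE).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `af_mle`, `af_pooled`, `lr`, `status`, `alt_counts`, `depths`.
#' @export
callVariants <- function(tensor, background, thresholds, panel,
                         reportAll = FALSE, minMeanDepth = 0,
                         ackLowConfidence = FALSE) {
  snv <- snvCounts(tensor)
  if (length(unique(snv$sample)) != 1)
    stop("callVariants expects a single-sample tensor; split first")
  sm <- .sampleSubMatrices(snv)
  bg <- background@snv
  key <- function(ch, po, al) paste(ch, po, al, sep = ":")
  bgKey <- key(bg$chrom, bg$pos, bg$alt)
  pp <- panelPositions(panel)
  if (!all(paste(sm$loci$chrom, sm$loci$pos) %in% paste(pp$chrom, pp$pos)))
    stop("sample tensor contains loci outside the panel")
  out <- list()
  for (altBase in c("A", "C", "G", "T")) {
    rows <- which(sm$loci$ref != altBase)
    if (!length(rows)) next
    altMat <- sm$baseCounts[[altBase]][rows, , drop = FALSE]
    depthMat <- sm$depth[rows, , drop = FALSE]
    bgIdx <- match(key(sm$loci$chrom[rows], sm$loci$pos[rows], altBase), bgKey)
    if (anyNA(bgIdx))
      stop("background model does not cover all panel positions ",
           "(panel/background mismatch)")
    mu <- bg$mean[bgIdx]; rho <- bg$rho[bgIdx]; flag <- bg$flag[bgIdx]
    nz <- rowSums(altMat) > 0 & rowSums(depthMat) > 0
    if (!any(nz)) next
    res <- .jointMleVec(altMat[nz, , drop = FALSE],
                        depthMat[nz, , drop = FALSE], mu[nz], rho[nz])
    lr <- pmax(0, 2 * (res$llHat - res$ll0))
    idx <- which(nz)
    status <- ifelse(lr >= thresholds$snv & res$afHat > 0, "called",
                     "not_called")
    lowc <- flag[nz] == "low_confidence" & !ackLowConfidence
    status[lowc & status == "called"] <- "low_confidence_region"
    out[[altBase]] <- data.frame(
      chrom = sm$loci$chrom[rows][idx], pos = sm$loci$pos[rows][idx],
      ref = sm$loci$ref[rows][idx], alt = altBase, class = "SNV",
      af_mle = res$afHat, af_pooled = rowSums(altMat[nz, , drop = FALSE]) /
        rowSums(depthMat[nz, , drop = FALSE]),
      lr = lr, status = status,
      alt_counts = apply(altMat[nz, , drop = FALSE], 1, paste, collapse = ","),
      depths = apply(depthMat[nz, , drop = FALSE], 1, paste, collapse = ","),
      stringsAsFactors = FALSE)
  }
  # indel alleles
  ind <- indelCounts(tensor)
  if (nrow(ind)) {
    sampleName <- unique(snv$sample)
    ibg <- background@indel
    loci <- unique(ind[, c("chrom", "pos", "ref", "allele")])
    reps <- sm$reps
    lkey <- paste(sm$loci$chrom, sm$loci$pos, sep = ":")
    for (i in seq_len(nrow(loci))) {
      rowI <- match(paste(loci$chrom[i], loci$pos[i], sep = ":"), lkey)
      if (is.na(rowI)) next
      depth <- sm$depth[rowI, ]
      altv <- integer(length(reps))
      sel <- ind$chrom == loci$chrom[i] & ind$pos == loci$pos[i] &
        ind$allele == loci$allele[i]
      altv[match(ind$replicate[sel], reps)] <- ind$count[sel]
      # sample-specific (leave-one-out) entry preferred, then generic
      cand <- which(ibg$chrom == loci$chrom[i] & ibg$pos == loci$pos[i] &
                      ibg$allele == loci$allele[i])
      entry <- NULL
      if (length(cand)) {
        own <- cand[ibg$exclude_sample[cand] %in% sampleName]
        entry <- if (length(own)) ibg[own[1], ] else ibg[cand[1], ]
      }
      if (is.null(entry)) {
        mu <- 0.5 / (stats::median(depth) + 1); rho <- 0
        flag <- "no_background"
      } else {
        mu <- entry$mean; rho <- entry$rho; flag <- entry$flag
      }
      r <- integrateReplicates(altv, depth, mu, rho)
      cls <- if (grepl("^del:", loci$allele[i])) "deletion" else "insertion"
      status <- if (!identical(r$status, "ok")) "no_coverage"
      else if (r$lr >= thresholds$indel && r$afMle > 0) "called"
      else "not_called"
      if (identical(flag, "low_confidence") && !ackLowConfidence &&
          status == "called") status <- "low_confidence_region"
      out[[paste0("indel", i)]] <- data.frame(
        chrom = loci$chrom[i], pos = loci$pos[i], ref = loci$ref[i],
        alt = loci$allele[i], class = cls,
        af_mle = r$afMle, af_pooled = r$afPooled, lr = r$lr, status = status,
        alt_counts = paste(altv, collapse = ","),
        depths = paste(depth, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), class = character(), af_mle = numeric(),
               af_pooled = numeric(), lr = numeric(), status = character(),
               alt_counts = character(), depths = character(),
               stringsAsFactors = FALSE)
  if (minMeanDepth > 0 && mean(sm$depth) < minMeanDepth)
    stop(sprintf("sample fails depth QC: mean depth %.0f < %.0f",
                 mean(sm$depth), minMeanDepth))
  if (!reportAll) res <- res[res$status == "called", , drop = FALSE]
  res <- res[order(res$chrom, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-sample contamination check from common SNPs
#'
#' A clean sample shows SNP allele fractions near 0, 0.5 or 1. Three or more
#' SNPs pulled toward intermediate fractions indicate cross-sample
#' contamination; a genotype fingerprint that disagrees with the previous
#' sample of the same patient indicates a possible swap.
#'
#' @param snpAf numeric vector of SNP allele fractions.
#' @param depth per-SNP depths (same length).
#' @param hetTol tolerance around 0.5 for heterozygous calls (default 0.05).
#' @param homTol maximum AF for hom-ref / minimum distance from 1 for
#'   hom-alt (default 0.02).
#' @param minLoci,minDepth coverage requirements (defaults 10 and 500).
#' @param previousAf optional AF vector from an earlier sample of the same
#'   patient, matched by position.
#' @return list with `status` in `{clean, contaminated, possible_swap,
#'   indeterminate}` plus supporting counts.
#' @export
checkContamination <- function(snpAf, depth = rep(1000, length(snpAf)),
                               hetTol = 0.05, homTol = 0.02,
                               minLoci = 10, minDepth = 500,
                               previousAf = NULL) {
  ok <- depth >= minDepth
  if (sum(ok) < minLoci)
    return(list(status = "indeterminate",
                n_usable = sum(ok), n_deviant = NA_integer_))
  af <- snpAf[ok]
  genotype <- function(a) ifelse(a <= homTol, "hom_ref",
                          ifelse(a >= 1 - homTol, "hom_alt",
                          ifelse(abs(a - 0.5) <= hetTol, "het", "deviant")))
  g <- genotype(af)
  nDev <- sum(g == "deviant")
  if (nDev >= 3)
    return(list(status = "contaminated", n_usable = length(af),
                n_deviant = nDev))
  if (!is.null(previousAf)) {
    gPrev <- genotype(previousAf[ok])
    mismatch <- sum(g != gPrev & g != "deviant" & gPrev != "deviant")
    if (mismatch >= 4)
      return(list(status = "possible_swap", n_usable = length(af),
                  n_deviant = nDev, n_genotype_mismatch = mismatch))
  }
  status <- if (nDev == 0) "clean" else "indeterminate"
  list(status = status, n_usable = length(af), n_deviant = nDev)
}

# Lower median: for even counts take the lower of the two central values
# (conservative toward copy number 2 for amplifications).
.loMedian <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Infer gene copy number from normalized amplicon depths
#'
#' Median-of-ratios normalization: each amplicon's depth is scaled by its
#' baseline median (the amplicon effect), each sample by the median of its
#' scaled depths (the sample / library-size effect); gene copy number is 2x
#' the lower-median normalized ratio over the gene's amplicons. Genes with a
#' single amplicon are reported but flagged low-confidence.
#'
#' @param depthMat numeric matrix samples x amplicons (column names =
#'   amplicon ids).
#' @param baseline numeric matrix of >= 5 baseline (copy-neutral) samples,
#'   same amplicon columns.
#' @param panel the [PanelDesign-class] (supplies the gene map).
#' @param amplifiedCn copy number at or above which status is `amplified`
#'   (default 3).
#' @return data.frame with `sample`, `gene`, `copy_number`, `n_amplicons`,
#'   `status`, `flag`.
#' @export
inferCnv <- function(depthMat, baseline, panel, amplifiedCn = 3) {
  if (nrow(baseline) < 5) stop("baseline cohort must have >= 5 samples")
  depthMat <- as.matrix(depthMat); baseline <- as.matrix(baseline)
  if (!identical(colnames(depthMat), colnames(baseline)))
    stop("depth matrix and baseline must share amplicon columns")
  ampFactor <- apply(baseline, 2, stats::median)
  if (any(ampFactor <= 0)) stop("baseline contains zero-depth amplicons")
  geneMap <- panelGenes(panel)
  out <- list()
  for (s in seq_len(nrow(depthMat))) {
    ratios <- depthMat[s, ] / ampFactor
    sampleFactor <- stats::median(ratios)
    norm <- ratios / sampleFactor
    for (g in names(geneMap)) {
      amps <- intersect(geneMap[[g]], colnames(depthMat))
      if (!length(amps)) next
      cn <- 2 * .loMedian(norm[amps])
      out[[length(out) + 1L]] <- data.frame(
        sample = if (!is.null(rownames(depthMat))) rownames(depthMat)[s]
        else paste0("S", s),
        gene = g, copy_number = cn, n_amplicons = length(amps),
        status = if (cn >= amplifiedCn) "amplified" else "normal",
        flag = if (length(amps) < 2) "low_confidence" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
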