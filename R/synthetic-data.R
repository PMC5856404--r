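# Synthetic-data stack: panels, reference-standard dilution series, molecule
# sampling, replicate splits, count/FASTQ simulation, full-process plasma
# controls and dPCR droplet reactions. Every generator is deterministic given
# (inputs, seed).

.randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate synthetic amplicon panels
#'
#' `toyPanel()` builds a small panel for unit tests and calibration studies;
#' `syntheticPanel()` builds a panel at the scale of a clinical ctDNA
#' hotspot panel: 35 genes tiled by 3 amplicons each with ~100 bp inserts,
#' giving a unique footprint of ~10.6 kb, with 20 bp primers so full amplicon
#' lengths stay within the 72-154 bp range typical of assays designed for
#' fragmented cell-free DNA.
#'
#' @param nAmplicons number of amplicons (toy panel).
#' @param insertLen insert length per amplicon in bp.
#' @param nGenes number of genes (synthetic panel).
#' @param ampliconsPerGene amplicons tiled per gene.
#' @param primerLen primer length in bp.
#' @param seed integer seed.
#' @return a [PanelDesign-class].
#' @export
toyPanel <- function(nAmplicons = 4, insertLen = 100, primerLen = 20,
                     seed = 101) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    gap <- 50L
    df <- data.frame(
      amplicon_id = sprintf("AMP%03d", seq_len(nAmplicons)),
      chrom = "chrT",
      insert_start = (seq_len(nAmplicons) - 1L) * (insertLen + gap) + 1000L,
      gene = sprintf("GENE%d", ((seq_len(nAmplicons) - 1L) %% 2L) + 1L),
      stringsAsFactors = FALSE
    )
    df$insert_end <- df$insert_start + insertLen
    df$fwd_primer <- vapply(seq_len(nAmplicons), function(i) .randDna(primerLen),
                            character(1))
    df$rev_primer <- vapply(seq_len(nAmplicons), function(i) .randDna(primerLen),
                            character(1))
    df$insert_seq <- vapply(seq_len(nAmplicons), function(i) .randDna(insertLen),
                            character(1))
    PanelDesign(df)
  })
}

#' @rdname toyPanel
#' @export
syntheticPanel <- function(nGenes = 35, ampliconsPerGene = 3, insertLen = 101,
                           primerLen = 20, seed = 2024) {
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (g in seq_len(nGenes)) {
    for (a in seq_len(ampliconsPerGene)) {
      k <- k + 1L
      start0 <- (a - 1L) * (insertLen + 60L) + 5000L
      rows[[k]] <- data.frame(
        amplicon_id = sprintf("G%02dA%d", g, a),
        chrom = sprintf("chr%02d", g),
        insert_start = start0,
        insert_end = start0 + insertLen,
        fwd_primer = .randDna(primerLen),
        rev_primer = .randDna(primerLen),
        insert_seq = .randDna(insertLen),
        gene = sprintf("GENE%02d", g),
        stringsAsFactors = FALSE
      )
    }
  }
  PanelDesign(do.call(rbind, rows))
}

#' Draw a synthetic truth set on a panel
#'
#' Places `n` variants at distinct interior positions of the panel inserts
#' with the given stock allele fractions (recycled). Useful for building
#' dilution-series truth sets mirroring multi-variant cell-line reference
#' standards.
#'
#' @param panel a [PanelDesign-class].
#' @param n number of variants.
#' @param stockAf numeric vector of stock allele fractions, recycled to `n`.
#' @param classes variant classes to draw from (default all SNV).
#' @param seed integer seed.
#' @return a validated truth data.frame (see [validateTruth()]).
#' @export
syntheticTruthSet <- function(panel, n, stockAf = 0.013, classes = "SNV",
                              seed = 7) {
  set.seed(seed)
  gr <- amplicons(panel)
  mc <- S4Vectors::mcols(gr)
  ampIdx <- sample(length(gr), n, replace = n > length(gr))
  rows <- lapply(seq_len(n), function(i) {
    j <- ampIdx[i]
    insStart0 <- GenomicRanges::start(gr)[j] - 1L
    w <- GenomicRanges::width(gr)[j]
    off <- sample(seq(5L, w - 20L), 1)  # interior; leaves room for indels
    refBase <- substr(mc$insert_seq[j], off + 1L, off + 1L)
    cls <- sample(classes, 1)
    if (cls == "SNV") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1)
    } else if (cls == "deletion") {
      dl <- sample(3:15, 1)
      del <- substr(mc$insert_seq[j], off + 1L, off + dl)
      la <- leftAlignIndel(mc$insert_seq[j], insStart0, insStart0 + off,
                           deleted = del)
      off <- la$pos - insStart0
      refBase <- substr(mc$insert_seq[j], off + 1L, off + 1L)
      alt <- la$allele
    } else {
      ins <- .randDna(sample(3:9, 1))
      la <- leftAlignIndel(mc$insert_seq[j], insStart0, insStart0 + off,
                           inserted = ins)
      off <- la$pos - insStart0
      refBase <- substr(mc$insert_seq[j], off + 1L, off + 1L)
      alt <- la$allele
    }
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[j],
               pos = insStart0 + off, ref = refBase, alt = alt, class = cls,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  truth$stock_af <- rep_len(stockAf, n)
  truth$expected_af <- truth$stock_af
  truth <- truth[!duplicated(paste(truth$chrom, truth$pos)), , drop = FALSE]
  validateTruth(truth)
  truth
}

#' Dilute a truth set into wild-type diluent
#'
#' Models diluting a mutant reference standard into wild-type DNA: every
#' variant's expected allele fraction becomes `stock_af * dilutionFactor`.
#'
#' @param truth truth data.frame (see [validateTruth()]).
#' @param dilutionFactor fraction of mutant standard in the final mix,
#'   in (0, 1].
#' @return the truth table with updated `expected_af`, order preserved.
#' @export
diluteTruth <- function(truth, dilutionFactor) {
  if (!is.numeric(dilutionFactor) || length(dilutionFactor) != 1 ||
      dilutionFactor <= 0 || dilutionFactor > 1)
    stop("dilutionFactor must be a single value in (0, 1]")
  validateTruth(truth)
  truth$expected_af <- truth$stock_af * dilutionFactor
  truth
}

#' Sample mutant molecules into a pool of amplifiable copies
#'
#' Draws, for each truth variant independently, the number of mutant
#' molecules among `inputAC` amplifiable copies:
#' `Binomial(inputAC, expected_af)`. This is the stochastic-sampling step
#' that dominates sensitivity at very low allele fractions.
#'
#' @param truth truth data.frame with `expected_af`.
#' @param inputAC amplifiable copies per locus (e.g. 2000 / 8000 / 16000 for
#'   low / medium / high input tiers).
#' @param seed integer seed.
#' @return a [MoleculePool-class].
#' @export
sampleMolecules <- function(truth, inputAC, seed) {
  if (inputAC <= 0) stop("inputAC must be positive")
  validateTruth(truth)
  set.seed(seed)
  truth$mutant_copies <- stats::rbinom(nrow(truth), inputAC, truth$expected_af)
  methods::new("MoleculePool", totalAC = as.integer(inputAC),
               variants = truth, seed = as.integer(seed))
}

#' Split a molecule pool across technical replicates
#'
#' Multinomial split with equal probabilities: total amplifiable copies and
#' each variant's mutant copies are partitioned independently across
#' replicates; totals are conserved exactly.
#'
#' @param pool a [MoleculePool-class].
#' @param nReplicates number of replicates (>= 2; default 8).
#' @param seed integer seed.
#' @return list with `repTotals` (integer vector of amplifiable copies per
#'   replicate) and `mutantCopies` (matrix, variants x replicates).
#' @export
splitReplicates <- function(pool, nReplicates = 8, seed) {
  if (nReplicates < 2) stop("nReplicates must be >= 2")
  set.seed(seed)
  prob <- rep(1 / nReplicates, nReplicates)
  repTotals <- as.vector(stats::rmultinom(1, pool@totalAC, prob))
  nv <- nrow(pool@variants)
  mut <- matrix(0L, nrow = nv, ncol = nReplicates)
  if (nv) for (i in seq_len(nv)) {
    mc <- pool@variants$mutant_copies[i]
    if (mc > 0) mut[i, ] <- as.vector(stats::rmultinom(1, mc, prob))
  }
  list(repTotals = repTotals, mutantCopies = mut, variants = pool@variants)
}

#' Oxidative-damage artifact configuration
#'
#' Acoustic shearing of reference-standard DNA creates 8-oxoguanine lesions
#' that present as elevated G>T (and C>A on the opposite strand) error rates.
#' `gtMultiplier` scales only those two substitution classes in the simulator.
#'
#' @param oxidative logical, enable the artifact mode.
#' @param gtMultiplier fold-increase of G>T / C>A error rates (>= 1).
#' @return a list with class `"ArtifactConfig"`.
#' @export
artifactConfig <- function(oxidative = FALSE, gtMultiplier = 1) {
  if (gtMultiplier < 1) stop("gtMultiplier must be >= 1")
  structure(list(oxidative = isTRUE(oxidative), gtMultiplier = gtMultiplier),
            class = "ArtifactConfig")
}

#' Synthetic per-position substitution error rates
#'
#' Builds a "true" error-rate table for the simulator: per (position, alt)
#' rates log-normally spread around `meanRate` with intra-class correlation
#' `rho` (the overdispersion the beta-binomial background model is meant to
#' capture).
#'
#' @param panel a [PanelDesign-class].
#' @param meanRate geometric-mean substitution error rate per base read
#'   (default 1e-4, typical of amplicon sequencing after quality filtering).
#' @param sdLog10 log10 standard deviation of per-position rates.
#' @param rho intra-class correlation of error counts across libraries.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos` (0-based), `ref`, `alt`, `mean`,
#'   `rho` for every panel position x non-reference base.
#' @export
syntheticErrorRates <- function(panel, meanRate = 1e-4, sdLog10 = 0.3,
                                rho = 2e-4, seed = 11) {
  set.seed(seed)
  pp <- panelPositions(panel)
  bases <- c("A", "C", "G", "T")
  out <- do.call(rbind, lapply(bases, function(b) {
    d <- pp[pp$ref != b, , drop = FALSE]
    d$alt <- b
    d
  }))
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  out$mean <- pmin(10^(stats::rnorm(nrow(out), log10(meanRate), sdLog10)), 0.01)
  out$rho <- rho
  rownames(out) <- NULL
  out
}

#' Enumerate panel positions
#'
#' @param panel a [PanelDesign-class].
#' @return data.frame `amplicon_id`, `chrom`, `pos` (0-based), `ref` for every
#'   insert base.
#' @export
panelPositions <- function(panel) {
  gr <- amplicons(panel)
  mc <- S4Vectors::mcols(gr)
  do.call(rbind, lapply(seq_along(gr), function(i) {
    w <- GenomicRanges::width(gr)[i]
    start0 <- GenomicRanges::start(gr)[i] - 1L
    data.frame(amplicon_id = mc$amplicon_id[i],
               chrom = as.character(GenomicRanges::seqnames(gr))[i],
               pos = start0 + seq_len(w) - 1L,
               ref = strsplit(mc$insert_seq[i], "")[[1]],
               stringsAsFactors = FALSE)
  }))
}

# Effective error-rate lookup with the oxidative multiplier applied to
# G>T and C>A entries only.
.applyArtifact <- function(rates, artifact) {
  if (!is.null(artifact) && artifact$oxidative) {
    gt <- (rates$ref == "G" & rates$alt == "T") |
      (rates$ref == "C" & rates$alt == "A")
    rates$mean[gt] <- pmin(rates$mean[gt] * artifact$gtMultiplier, 0.5)
  }
  rates
}

#' Simulate an allele-count tensor for one sample
#'
#' Generates per-replicate base counts over the whole panel. Depth per
#' amplicon and replicate is Poisson around `replicate copies x
#' meanReadsPerMolecule` (amplification is modeled as a per-molecule read
#' multiplicity with Poisson dispersion, not a branching process). At truth
#' loci, alt reads are a binomial thinning of depth at the replicate's
#' molecule-level mutant fraction; everywhere, substitution errors are drawn
#' from the (optionally artifact-scaled) background error distribution.
#'
#' @param split replicate split from [splitReplicates()] (or `NULL` for a
#'   wild-type sample, in which case `inputAC` must be given).
#' @param panel a [PanelDesign-class].
#' @param errorRates data.frame from [syntheticErrorRates()] (or `NULL` for
#'   error-free data); columns `chrom`, `pos`, `alt`, `mean`, `rho`.
#' @param meanReadsPerMolecule mean sequenced read count per input molecule.
#' @param artifact an [artifactConfig()].
#' @param nReplicates used only when `split` is `NULL`.
#' @param inputAC used only when `split` is `NULL`.
#' @param sampleName sample identifier in the tensor.
#' @param seed integer seed.
#' @return an [AlleleCountTensor-class].
#' @export
simulateCounts <- function(split, panel, errorRates = NULL,
                           meanReadsPerMolecule = 4,
                           artifact = artifactConfig(),
                           nReplicates = 8, inputAC = 8000,
                           sampleName = "S1", seed = 1) {
  set.seed(seed)
  if (is.null(split)) {
    repTotals <- as.vector(stats::rmultinom(1, inputAC,
                                            rep(1 / nReplicates, nReplicates)))
    split <- list(repTotals = repTotals,
                  mutantCopies = matrix(0L, 0, nReplicates),
                  variants = data.frame())
  }
  nRep <- length(split$repTotals)
  pp <- panelPositions(panel)
  nPos <- nrow(pp)

  # per-amplicon per-replicate depth
  ampIds <- unique(pp$amplicon_id)
  depthByAmp <- matrix(stats::rpois(length(ampIds) * nRep,
                                    rep(split$repTotals * meanReadsPerMolecule,
                                        each = length(ampIds))),
                       nrow = length(ampIds), ncol = nRep,
                       dimnames = list(ampIds, NULL))

  snvList <- vector("list", nRep)
  indelList <- list()
  # error-rate lookup keyed by chrom:pos:alt
  if (!is.null(errorRates)) {
    errorRates <- .applyArtifact(errorRates, artifact)
    errKey <- paste(errorRates$chrom, errorRates$pos, errorRates$alt, sep = ":")
  }
  vs <- split$variants
  hasVar <- nrow(vs) > 0
  for (r in seq_len(nRep)) {
    depth <- depthByAmp[pp$amplicon_id, r]
    counts <- matrix(0L, nrow = nPos, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    refIdx <- match(pp$ref, c("A", "C", "G", "T"))
    counts[cbind(seq_len(nPos), refIdx)] <- depth

    # substitution errors
    if (!is.null(errorRates)) {
      rowIdx <- match(paste(errorRates$chrom, errorRates$pos, sep = ":"),
                      paste(pp$chrom, pp$pos, sep = ":"))
      dOk <- depth[rowIdx]
      errCnt <- rbetabinom(nrow(errorRates), dOk, errorRates$mean,
                           errorRates$rho)
      pos2 <- rowIdx[errCnt > 0]
      alt2 <- errorRates$alt[errCnt > 0]
      cnt2 <- errCnt[errCnt > 0]
      if (length(pos2)) {
        altIdx <- match(alt2, c("A", "C", "G", "T"))
        counts[cbind(pos2, altIdx)] <- counts[cbind(pos2, altIdx)] + cnt2
        counts[cbind(pos2, refIdx[pos2])] <-
          pmax(counts[cbind(pos2, refIdx[pos2])] - cnt2, 0L)
      }
    }

    # truth variants: binomial thinning of depth at the molecule fraction
    if (hasVar) {
      mf <- split$mutantCopies[, r] / max(split$repTotals[r], 1L)
      for (i in seq_len(nrow(vs))) {
        rowI <- which(pp$chrom == vs$chrom[i] & pp$pos == vs$pos[i])
        if (!length(rowI)) next
        mutReads <- stats::rbinom(1, depth[rowI], min(mf[i], 1))
        if (mutReads == 0) next
        if (vs$class[i] == "SNV") {
          aI <- match(vs$alt[i], c("A", "C", "G", "T"))
          counts[rowI, aI] <- counts[rowI, aI] + mutReads
          counts[rowI, refIdx[rowI]] <-
            pmax(counts[rowI, refIdx[rowI]] - mutReads, 0L)
        } else {
          counts[rowI, refIdx[rowI]] <-
            pmax(counts[rowI, refIdx[rowI]] - mutReads, 0L)
          indelList[[length(indelList) + 1L]] <- data.frame(
            sample = sampleName, replicate = r,
            amplicon_id = pp$amplicon_id[rowI],
            chrom = vs$chrom[i], pos = vs$pos[i], ref = vs$ref[i],
            allele = vs$alt[i], count = mutReads, stringsAsFactors = FALSE)
        }
      }
    }

    snvList[[r]] <- data.frame(
      sample = sampleName, replicate = r, amplicon_id = pp$amplicon_id,
      chrom = pp$chrom, pos = pp$pos, ref = pp$ref,
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
      T = counts[, "T"], stringsAsFactors = FALSE)
  }
  indel <- if (length(indelList)) do.call(rbind, indelList) else
    .emptyIndelTable()
  AlleleCountTensor(do.call(rbind, snvList), indel)
}

#' Simulate a spiked full-process plasma control
#'
#' Mutant reference standard spiked into pooled plasma before extraction:
#' recovered spike copies are `Binomial(spikeCopies, extractionEfficiency)`,
#' and the measured allele fraction is diluted by the plasma's own wild-type
#' background DNA, so it can never exceed the spike's nominal AF.
#'
#' @param spikeAf nominal allele fraction(s) of the reference standard
#'   (scalar, or one per truth variant).
#' @param spikeCopies amplifiable copies of spiked standard added to plasma.
#' @param plasmaBackgroundAc amplifiable copies contributed by the plasma.
#' @param extractionEfficiency recovery fraction in [0, 1] (default 0.5, the
#'   recovery level typical of spike-in extraction controls).
#' @param seed integer seed.
#' @param truth optional truth table giving variant loci; when omitted a
#'   single placeholder locus is used.
#' @return a [MoleculePool-class]; `expected_af` holds the post-extraction
#'   measured AF expectation.
#' @export
simulateFullProcessControl <- function(spikeAf, spikeCopies,
                                       plasmaBackgroundAc,
                                       extractionEfficiency = 0.5, seed = 1,
                                       truth = NULL) {
  if (extractionEfficiency < 0 || extractionEfficiency > 1)
    stop("extractionEfficiency must lie in [0, 1]")
  set.seed(seed)
  recovered <- stats::rbinom(1, spikeCopies, extractionEfficiency)
  totalAC <- recovered + plasmaBackgroundAc
  if (is.null(truth)) {
    truth <- data.frame(chrom = "chrFPC", pos = seq_along(spikeAf) * 100L,
                        ref = "A", alt = "T", class = "SNV",
                        stringsAsFactors = FALSE)
  }
  spikeAf <- rep_len(spikeAf, nrow(truth))
  truth$stock_af <- spikeAf
  truth$expected_af <- if (totalAC > 0)
    spikeAf * recovered / totalAC else 0
  truth$mutant_copies <- stats::rbinom(nrow(truth), recovered, spikeAf)
  methods::new("MoleculePool", totalAC = as.integer(max(totalAC, 1L)),
               variants = truth, seed = as.integer(seed))
}

#' Simulate a droplet digital PCR reaction
#'
#' Per-droplet occupancy is Poisson per channel; false positives are added to
#' the mutant channel at rate `fprLambda`. Droplets are classified into
#' mutant-single, wild-type-single, double-positive and negative.
#'
#' @param mutLambda mutant copies per droplet.
#' @param wtLambda wild-type copies per droplet.
#' @param nDroplets accepted droplets.
#' @param fprLambda false-positive rate per droplet in the mutant channel.
#' @param partitionVolumeNl droplet volume in nL (default 0.85).
#' @param seed integer seed.
#' @param reactionId reaction label.
#' @return one-row data.frame with columns `reaction_id`, `n_droplets`,
#'   `mut_single_pos`, `wt_single_pos`, `double_pos`, `negative`,
#'   `partition_volume_nl`.
#' @export
simulateDroplets <- function(mutLambda, wtLambda, nDroplets, fprLambda = 0,
                             partitionVolumeNl = 0.85, seed = 1,
                             reactionId = "R1") {
  if (any(c(mutLambda, wtLambda, fprLambda) < 0) || nDroplets <= 0)
    stop("rates must be >= 0 and nDroplets > 0")
  set.seed(seed)
  pm <- 1 - exp(-(mutLambda + fprLambda))
  pw <- 1 - exp(-wtLambda)
  cls <- stats::rmultinom(1, nDroplets,
                          c(pm * pw, pm * (1 - pw), (1 - pm) * pw,
                            (1 - pm) * (1 - pw)))
  data.frame(reaction_id = reactionId, n_droplets = nDroplets,
             mut_single_pos = cls[2], wt_single_pos = cls[3],
             double_pos = cls[1], negative = cls[4],
             partition_volume_nl = partitionVolumeNl,
             stringsAsFactors = FALSE)
}

#' Simulate per-replicate counts at a single locus
#'
#' Fast path used for sensitivity grids: for one variant at a given expected
#' AF and input, draws mutant molecules, splits them across replicates,
#' then draws depth and alt reads per replicate (binomial thinning plus
#' background errors from `bgMean`/`bgRho`).
#'
#' @param expectedAf expected allele fraction after dilution.
#' @param inputAC amplifiable copies.
#' @param nReplicates technical replicates (default 8).
#' @param meanReadsPerMolecule mean reads per molecule.
#' @param bgMean,bgRho background error rate and overdispersion at the locus.
#' @param seed integer seed.
#' @return list with integer vectors `alt` and `depth` (length
#'   `nReplicates`) and `mutantCopies` (total drawn).
#' @export
simulateLocusReplicates <- function(expectedAf, inputAC, nReplicates = 8,
                                    meanReadsPerMolecule = 4,
                                    bgMean = 0, bgRho = 0, seed = 1) {
  set.seed(seed)
  mut <- stats::rbinom(1, inputAC, expectedAf)
  prob <- rep(1 / nReplicates, nReplicates)
  repTotals <- as.vector(stats::rmultinom(1, inputAC, prob))
  mutRep <- if (mut > 0) as.vector(stats::rmultinom(1, mut, prob)) else
    integer(nReplicates)
  depth <- stats::rpois(nReplicates, repTotals * meanReadsPerMolecule)
  mutReads <- stats::rbinom(nReplicates, depth,
                            pmin(mutRep / pmax(repTotals, 1L), 1))
  errReads <- if (bgMean > 0)
    rbetabinom(nReplicates, pmax(depth - mutReads, 0L), bgMean, bgRho) else
    integer(nReplicates)
  list(alt = mutReads + errReads, depth = depth, mutantCopies = mut)
}
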