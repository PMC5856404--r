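# Background-model fitting: method-of-moments recovery, pseudocount floors,
# monotonicity, leave-one-out indel backgrounds and the oxidative signature.

test_that("clean controls fall to the pseudocount floor with zero rho", {
  tens <- .syntheticControlTensor(function() 0L, nControls = 5,
                                  nReplicates = 4, depth = 10000)
  bg <- fitBackground(tens)
  e <- bg@snv[bg@snv$alt == "G", ]
  expect_equal(e$mean, 0.5 / 10001, tolerance = 1e-10)
  expect_equal(e$rho, 0)
  expect_equal(e$n_controls, 5)
  expect_identical(e$flag, "")
})

test_that("a constant true error rate is recovered within 20%", {
  set.seed(71)
  tens <- .syntheticControlTensor(function() stats::rbinom(1, 10000, 1e-3),
                                  nControls = 20, nReplicates = 1,
                                  depth = 10000)
  bg <- fitBackground(tens)
  e <- bg@snv[bg@snv$alt == "G", ]
  expect_lt(abs(e$mean - 1e-3) / 1e-3, 0.2)
})

test_that("beta-binomial parameters are recovered on average", {
  # known (mean, rho) in a moderate-skew regime (beta shape ~5, where the
  # moment estimator is near-unbiased); repeated fits straddle the truth
  mu <- 5e-3; rho <- 1e-3; depth <- 20000
  a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
  set.seed(72)
  fits <- t(replicate(60, {
    tens <- .syntheticControlTensor(
      function() stats::rbinom(1, depth, stats::rbeta(1, a, b)),
      nControls = 24, nReplicates = 1, depth = depth)
    e <- fitBackground(tens, rhoFloor = "none")@snv
    e <- e[e$alt == "G", ]
    c(mean = e$mean, rho = e$rho)
  }))
  expect_lt(abs(mean(fits[, "mean"]) - mu) / mu, 0.1)
  expect_lt(abs(mean(fits[, "rho"]) - rho) / rho, 0.15)  # ~3 SE of the mean
})

test_that("adding a noisier control never decreases the fitted mean", {
  base <- .syntheticControlTensor(function() 5L, nControls = 6,
                                  nReplicates = 1, depth = 10000)
  m0 <- fitBackground(base)@snv
  m0 <- m0[m0$alt == "G", "mean"]
  extra <- snvCounts(.syntheticControlTensor(function() 60L, nControls = 1,
                                             nReplicates = 1, depth = 10000))
  extra$sample <- "C99"
  both <- AlleleCountTensor(rbind(snvCounts(base), extra))
  m1 <- fitBackground(both)@snv
  m1 <- m1[m1$alt == "G", "mean"]
  expect_gt(m1, m0)
})

test_that("minimum cohort size is enforced", {
  tens <- .syntheticControlTensor(function() 0L, nControls = 2,
                                  nReplicates = 4, depth = 1000)
  expect_error(fitBackground(tens), ">= 3 control")
})

test_that("oxidative-artifact controls elevate only G>T entries", {
  pan <- toyPanel(nAmplicons = 2, insertLen = 100, seed = 81)
  er <- syntheticErrorRates(pan, meanRate = 2e-4, sdLog10 = 0, rho = 0,
                            seed = 82)
  mk <- function(artifact) {
    ctl <- do.call(rbind, lapply(1:6, function(i)
      snvCounts(simulateCounts(NULL, pan, er, artifact = artifact,
                               inputAC = 4000, sampleName = paste0("C", i),
                               seed = 300 + i))))
    fitBackground(AlleleCountTensor(ctl))@snv
  }
  clean <- mk(artifactConfig(FALSE))
  oxo <- mk(artifactConfig(TRUE, gtMultiplier = 20))
  m <- merge(clean, oxo, by = c("chrom", "pos", "ref", "alt"),
             suffixes = c(".clean", ".oxo"))
  isGT <- (m$ref == "G" & m$alt == "T") | (m$ref == "C" & m$alt == "A")
  expect_gt(mean(m$mean.oxo[isGT]) / mean(m$mean.clean[isGT]), 5)
  expect_lt(abs(mean(m$mean.oxo[!isGT]) / mean(m$mean.clean[!isGT]) - 1),
            0.25)
})

# --- indel backgrounds ------------------------------------------------------

.batchWithIndels <- function(indelCountsBySample, depth = 5000,
                             nReplicates = 2) {
  samples <- names(indelCountsBySample)
  snv <- do.call(rbind, lapply(samples, function(s)
    do.call(rbind, lapply(seq_len(nReplicates), function(r)
      data.frame(sample = s, replicate = r, amplicon_id = "amp1",
                 chrom = "chr1", pos = 50L, ref = "A",
                 A = depth, C = 0L, G = 0L, T = 0L,
                 stringsAsFactors = FALSE)))))
  ind <- do.call(rbind, lapply(samples, function(s) {
    k <- indelCountsBySample[[s]]
    if (k == 0) return(NULL)
    data.frame(sample = s, replicate = 1L, amplicon_id = "amp1",
               chrom = "chr1", pos = 50L, ref = "A", allele = "del:15",
               count = k, stringsAsFactors = FALSE)
  }))
  if (is.null(ind)) ind <- plasmacall:::.emptyIndelTable()
  AlleleCountTensor(snv, ind)
}

test_that("leave-one-out indel background excludes the tested sample", {
  # one sample carries a true 5% indel; its own background must stay clean
  depth <- 5000; nRep <- 2
  batch <- .batchWithIndels(list(S1 = as.integer(0.05 * depth * nRep),
                                 S2 = 0L, S3 = 0L, S4 = 0L, S5 = 0L))
  loc <- list(chrom = "chr1", pos = 50L, allele = "del:15", ref = "A")
  own <- batchIndelBackground(batch, excludeSample = "S1", locus = loc)
  floorRate <- 0.5 / (4 * depth * nRep + 1)
  expect_equal(own$mean, floorRate, tolerance = 1e-9)
  # the other samples see S1's indel in their background
  other <- batchIndelBackground(batch, excludeSample = "S2", locus = loc)
  expect_gt(other$mean, 100 * floorRate)
})

test_that("uniform artifact indels give every sample the same background", {
  depth <- 5000; nRep <- 2
  k <- as.integer(1e-3 * depth * nRep)
  batch <- .batchWithIndels(list(S1 = k, S2 = k, S3 = k, S4 = k, S5 = k))
  all5 <- batchIndelBackground(batch)
  expect_equal(nrow(all5), 5)
  expect_equal(all5$mean, rep(all5$mean[1], 5))
  expect_lt(abs(all5$mean[1] - 1e-3) / 1e-3, 0.1)
})

test_that("small batches are rejected with a pointer to the control cohort", {
  batch <- .batchWithIndels(list(S1 = 0L, S2 = 0L, S3 = 0L))
  expect_error(batchIndelBackground(batch), "control cohort")
})

test_that("background models serialize and restore as TSV", {
  tens <- .syntheticControlTensor(function() stats::rbinom(1, 5000, 2e-4),
                                  nControls = 4, nReplicates = 2,
                                  depth = 5000)
  bg <- fitBackground(tens)
  batch <- .batchWithIndels(list(S1 = 3L, S2 = 0L, S3 = 0L, S4 = 0L))
  bg <- setIndelBackground(bg, batchIndelBackground(batch))
  tsv <- tempfile(fileext = ".tsv")
  writeBackground(bg, tsv)
  back <- readBackground(tsv)
  expect_equal(back@snv$mean, bg@snv$mean)
  expect_equal(back@snv$rho, bg@snv$rho)
  expect_equal(back@indel$mean, bg@indel$mean)
  expect_identical(back@indel$exclude_sample, bg@indel$exclude_sample)
})
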