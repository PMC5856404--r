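# Generator stack: dilution arithmetic, molecule sampling, replicate
# splits, count simulation, full-process controls and droplet reactions.

test_that("dilution scales expected AF and preserves order", {
  truth <- data.frame(chrom = "chr1", pos = c(10L, 50L), ref = c("A", "G"),
                      alt = c("T", "C"), class = "SNV",
                      stock_af = c(0.013, 0.025),
                      expected_af = c(0.013, 0.025), stringsAsFactors = FALSE)
  d <- diluteTruth(truth, 0.5)
  expect_equal(d$expected_af, c(0.0065, 0.0125))   # 1.3% -> 0.65%
  expect_equal(diluteTruth(truth, 1)$expected_af, truth$stock_af)
  d16 <- diluteTruth(truth, 1 / 16)
  expect_equal(d16$expected_af[1], 0.0008125)      # 1.3% / 16 = 0.08125%
  expect_identical(d$pos, truth$pos)
  expect_error(diluteTruth(truth, 0), "0, 1")
  expect_error(diluteTruth(truth, 1.2), "0, 1")
})

test_that("molecule sampling is binomial with the expected mean", {
  # degenerate AFs
  t0 <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "T", class = "SNV",
                   stock_af = 1, expected_af = 0, stringsAsFactors = FALSE)
  expect_equal(sampleMolecules(t0, 100, seed = 1)@variants$mutant_copies, 0)
  t1 <- t0; t1$expected_af <- 1
  expect_equal(sampleMolecules(t1, 100, seed = 1)@variants$mutant_copies, 100)

  # mean of Binomial(8000, 0.25%) over many independent draws
  nRep <- 10000
  tm <- do.call(rbind, replicate(1, {
    data.frame(chrom = "c", pos = seq_len(nRep), ref = "A", alt = "T",
               class = "SNV", stock_af = 0.01, expected_af = 0.0025,
               stringsAsFactors = FALSE)
  }, simplify = FALSE))
  draws <- sampleMolecules(tm, 8000, seed = 7)@variants$mutant_copies
  se <- sqrt(8000 * 0.0025 * 0.9975 / nRep)
  expect_lt(abs(mean(draws) - 20), 3 * se)
})

test_that("replicate splits conserve molecules exactly", {
  truth <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "T",
                      class = "SNV", stock_af = 0.5, expected_af = 0.01,
                      stringsAsFactors = FALSE)
  pool <- sampleMolecules(truth, 2000, seed = 3)
  sp <- splitReplicates(pool, 8, seed = 4)
  expect_equal(sum(sp$repTotals), 2000)
  expect_equal(sum(sp$mutantCopies), pool@variants$mutant_copies)
  expect_error(splitReplicates(pool, 1, seed = 1), ">= 2")

  # zero mutant copies stay zero everywhere
  t0 <- truth; t0$expected_af <- 0
  sp0 <- splitReplicates(sampleMolecules(t0, 2000, seed = 3), 8, seed = 4)
  expect_true(all(sp0$mutantCopies == 0))

  # multinomial expectation: per-replicate share of a large pool
  t1 <- truth; t1$stock_af <- 1; t1$expected_af <- 1
  sp1 <- splitReplicates(sampleMolecules(t1, 100000, seed = 5), 8, seed = 6)
  se <- sqrt(100000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(sp1$mutantCopies - 100000 / 8) < 3 * se))
})

test_that("count simulation reproduces molecule fractions and stays clean", {
  fwd <- randPrimer(seed = 31); rev <- randPrimer(seed = 32)
  set.seed(33)
  ins <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  pan <- PanelDesign(panelRow("amp1", "chr5", 100, ins, fwd, rev))
  refBase <- substr(ins, 31, 31)
  truth <- data.frame(chrom = "chr5", pos = 130L, ref = refBase,
                      alt = setdiff(c("A", "C", "G", "T"), refBase)[1],
                      class = "SNV", stock_af = 0.05, expected_af = 0.02,
                      stringsAsFactors = FALSE)
  pool <- sampleMolecules(truth, 5000, seed = 8)
  sp <- splitReplicates(pool, 8, seed = 9)

  # no background, no variant reads anywhere except the truth locus
  tensor <- simulateCounts(sp, pan, errorRates = NULL,
                           meanReadsPerMolecule = 25, seed = 10)
  s <- snvCounts(tensor)
  altCount <- function(d) vapply(seq_len(nrow(d)), function(i)
    sum(d[i, setdiff(c("A", "C", "G", "T"), d$ref[i])]), numeric(1))
  off <- s$pos != 130L
  expect_true(all(altCount(s[off, ]) == 0))

  # law of large numbers: observed alt fraction approaches the molecule
  # fraction (depth ~ 5000 x 25 = 125k per replicate tier)
  at <- s[s$pos == 130L, ]
  obs <- sum(at[[truth$alt]]) / sum(at$A + at$C + at$G + at$T)
  molFrac <- pool@variants$mutant_copies / 5000
  expect_lt(abs(obs - molFrac) / molFrac, 0.05)

  # bit-reproducibility
  t2 <- simulateCounts(sp, pan, errorRates = NULL,
                       meanReadsPerMolecule = 25, seed = 10)
  expect_identical(snvCounts(t2), s)
})

test_that("oxidative artifact mode scales only G>T / C>A error rates", {
  pan <- toyPanel(nAmplicons = 2, insertLen = 100, seed = 55)
  er <- syntheticErrorRates(pan, meanRate = 1e-3, sdLog10 = 0, rho = 0,
                            seed = 56)
  runRates <- function(artifact, seeds) {
    agg <- NULL
    for (sd in seeds) {
      t <- simulateCounts(NULL, pan, er, artifact = artifact,
                          inputAC = 4000, seed = sd)
      s <- snvCounts(t)
      dep <- s$A + s$C + s$G + s$T
      gt <- s$ref == "G"
      ca <- s$ref == "C"
      oth <- s$ref %in% c("A", "T")
      agg <- rbind(agg, c(
        gt = sum(s$T[gt]) / sum(dep[gt]),
        ca = sum(s$A[ca]) / sum(dep[ca]),
        at = (sum(s$C[oth]) + sum(s$G[oth])) / (2 * sum(dep[oth]))))
    }
    colMeans(agg)
  }
  base <- runRates(artifactConfig(FALSE), 1:6)
  oxo <- runRates(artifactConfig(TRUE, gtMultiplier = 10), 1:6)
  expect_gt(oxo[["gt"]] / base[["gt"]], 5)
  expect_gt(oxo[["ca"]] / base[["ca"]], 5)
  expect_lt(abs(oxo[["at"]] / base[["at"]] - 1), 0.3)
})

test_that("full-process controls dilute the spike and never exceed it", {
  expect_equal(simulateFullProcessControl(0.05, 4000, 4000, 0,
                                          seed = 1)@variants$expected_af, 0)
  fpc <- simulateFullProcessControl(0.05, 4000, 4000, 1, seed = 2)
  expect_equal(fpc@variants$expected_af, 0.025)    # equal copies, full recovery
  half <- simulateFullProcessControl(0.05, 4000, 4000, 0.5, seed = 3)
  expect_lt(half@variants$expected_af, 0.05)
  expect_lt(half@variants$expected_af, fpc@variants$expected_af)
  # property over seeds: measured AF never above nominal
  for (sd in 1:20) {
    x <- simulateFullProcessControl(0.01, 2000, 5000,
                                    extractionEfficiency = stats::runif(1),
                                    seed = sd)
    expect_lte(x@variants$expected_af, 0.01)
  }
})

test_that("droplet simulation follows Poisson occupancy", {
  d0 <- simulateDroplets(0, 0, 1000, 0, seed = 1)
  expect_equal(d0$negative, 1000)
  expect_equal(d0$n_droplets,
               d0$mut_single_pos + d0$wt_single_pos + d0$double_pos +
                 d0$negative)

  # wt lambda 1: positive fraction ~ 1 - exp(-1)
  d1 <- simulateDroplets(0, 1, 20000, 0, seed = 2)
  wtPos <- d1$wt_single_pos + d1$double_pos
  p <- 1 - exp(-1)
  expect_lt(abs(wtPos - 20000 * p), 3 * sqrt(20000 * p * (1 - p)))

  # false positives alone: mean mutant positives ~ n * fpr
  mp <- vapply(1:1000, function(sd) {
    d <- simulateDroplets(0, 0, 20000, 1e-4, seed = sd)
    d$mut_single_pos + d$double_pos
  }, numeric(1))
  expect_lt(abs(mean(mp) - 20000 * (1 - exp(-1e-4))), 3 * sqrt(2 / 1000))
})
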