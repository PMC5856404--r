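# Replicate-aware ML calling: likelihood properties, MLE accuracy against a
# grid-search oracle, threshold behaviour, contamination and CNV.

test_that("af = 0 reduces exactly to the null likelihood", {
  ll0 <- replicateLoglik(0, 1000, 1e-4, 0, 0)
  expect_equal(ll0, stats::dbinom(0, 1000, 1e-4, log = TRUE))
  # alt 0 at af 0 under overdispersion: same value twice (null consistency)
  expect_identical(replicateLoglik(0, 1000, 1e-4, 1e-3, 0),
                   replicateLoglik(0, 1000, 1e-4, 1e-3, 0))
})

test_that("the joint MLE matches a grid-search oracle", {
  # 5% alt fraction, negligible background: maximum near 0.05
  alt <- rep(50L, 4); depth <- rep(1000L, 4)
  grid <- seq(0, 1, by = 1e-4)
  gridLL <- vapply(grid, function(a)
    sum(replicateLoglik(alt, depth, 1e-4, 0, a)), numeric(1))
  oracle <- grid[which.max(gridLL)]
  r <- integrateReplicates(alt, depth, 1e-4, 0)
  expect_lt(abs(r$afMle - oracle), 1e-4)
  expect_lt(abs(r$afMle - 0.05), 1e-3)
  # likelihood at the MLE never below the null
  expect_gte(r$lr, 0)

  # same check under overdispersion and an asymmetric configuration
  alt2 <- c(3L, 9L, 5L, 7L); depth2 <- c(800L, 1200L, 1000L, 950L)
  gridLL2 <- vapply(grid, function(a)
    sum(replicateLoglik(alt2, depth2, 5e-4, 2e-3, a)), numeric(1))
  oracle2 <- grid[which.max(gridLL2)]
  r2 <- integrateReplicates(alt2, depth2, 5e-4, 2e-3)
  expect_lt(abs(r2$afMle - oracle2), 1e-4)
})

test_that("replicate integration handles nulls, pooling and zero depth", {
  # all-zero alt: af 0, lr 0
  r0 <- integrateReplicates(rep(0L, 8), rep(1000L, 8), 1e-4, 1e-4)
  expect_equal(r0$afMle, 0)
  expect_equal(r0$lr, 0)

  # 8 x 50/1000 with negligible background: joint MLE ~ pooled fraction
  r <- integrateReplicates(rep(50L, 8), rep(1000L, 8), 1e-4, 0)
  expect_lt(abs(r$afMle - 0.05), 1e-3)
  expect_equal(r$afPooled, 0.05)

  # zero-depth replicates are excluded, not fatal
  rz <- integrateReplicates(c(50L, 0L), c(1000L, 0L), 1e-4, 0)
  expect_equal(rz$nReplicates, 1L)
  rAll0 <- integrateReplicates(c(0L, 0L), c(0L, 0L), 1e-4, 0)
  expect_identical(rAll0$status, "no_coverage")

  # same pooled fraction: evidence spread across replicates scores at least
  # as high as evidence concentrated in one, under overdispersion
  spread <- integrateReplicates(rep(50L, 8), rep(1000L, 8), 1e-4, 5e-3)
  conc <- integrateReplicates(c(400L, rep(0L, 7)), rep(1000L, 8), 1e-4, 5e-3)
  expect_gte(spread$lr, conc$lr)
})

test_that("thresholds respond monotonically to the specificity budget", {
  cal <- fixtureCalibration()
  thrLoose <- calibrateThreshold(cal$background, budget = 3e-5, nSim = 5,
                                 seed = 91)
  thrTight <- calibrateThreshold(cal$background, budget = 3e-6, nSim = 5,
                                 seed = 91)
  expect_lte(thrLoose$snv, thrTight$snv)
})

test_that("a zero-noise background never calls a lone alt read", {
  tens <- .syntheticControlTensor(function() 0L, nControls = 4,
                                  nReplicates = 2, depth = 4000)
  bg <- fitBackground(tens)
  thr <- calibrateThreshold(bg, nSim = 3, depthPerReplicate = 4000,
                            seed = 92)
  e <- bg@snv[bg@snv$alt == "G", ]
  one <- integrateReplicates(c(1L, 0L), c(4000L, 4000L), e$mean, e$rho)
  expect_lt(one$lr, thr$snv)
})

test_that("simulated variants are called with accurate allele fractions", {
  cal <- fixtureCalibration()
  pan <- cal$panel; bg <- cal$background; thr <- cal$thresholds
  truth <- syntheticTruthSet(pan, 4, stockAf = 0.05, seed = 93)
  truth <- diluteTruth(truth, 0.5)   # 2.5% expected AF
  pool <- sampleMolecules(truth, 2000, seed = 94)
  sp <- splitReplicates(pool, 8, seed = 95)
  tensor <- simulateCounts(sp, pan, errorRates = bg@snv, sampleName = "PT1",
                           seed = 96)
  calls <- callVariants(tensor, bg, thr, pan)
  found <- merge(calls, truth, by = c("chrom", "pos"))
  expect_equal(nrow(found), nrow(truth))
  expect_true(all(found$alt.x == found$alt.y))
  expect_true(all(found$af_mle > 0.015 & found$af_mle < 0.035))
  # the call report is sorted by locus
  expect_false(is.unsorted(order(calls$chrom, calls$pos)))
})

test_that("indel alleles are evaluated against their batch background", {
  cal <- fixtureCalibration()
  pan <- cal$panel; bg <- cal$background; thr <- cal$thresholds
  truth <- syntheticTruthSet(pan, 2, stockAf = 0.04, classes = "deletion",
                             seed = 97)
  pool <- sampleMolecules(truth, 4000, seed = 98)
  sp <- splitReplicates(pool, 8, seed = 99)
  tensor <- simulateCounts(sp, pan, errorRates = bg@snv, sampleName = "PT2",
                           seed = 100)
  calls <- callVariants(tensor, bg, thr, pan)
  dels <- calls[calls$class == "deletion", ]
  expect_equal(nrow(dels), nrow(truth))
  expect_true(all(dels$status == "called"))
})

test_that("contamination status follows the SNP allele-fraction pattern", {
  ok <- checkContamination(c(0.00, 0.49, 1.00, 0.51, 0.01, 0.99, 0.50,
                             0.48, 0.52, 0.02))
  expect_identical(ok$status, "clean")

  # five hom-ref SNPs pulled to 6%: a 6% cross-sample mixture
  mixed <- checkContamination(c(0.06, 0.06, 0.07, 0.06, 0.05,
                                0.49, 0.51, 1.00, 0.99, 0.50))
  expect_identical(mixed$status, "contaminated")

  # genotype fingerprint flip vs the previous sample of the same patient
  nowAf <- c(rep(0, 4), rep(1, 4), 0, 1, 0.5, 0.5)
  prevAf <- c(rep(0.5, 4), rep(1, 4), 0, 1, 0.5, 0.5)
  swap <- checkContamination(nowAf, previousAf = prevAf)
  expect_identical(swap$status, "possible_swap")

  # insufficient informative loci
  expect_identical(checkContamination(rep(0.5, 5))$status, "indeterminate")
  low <- checkContamination(rep(0.5, 12), depth = rep(100, 12))
  expect_identical(low$status, "indeterminate")
})

test_that("copy number is 2 on null data and doubles with depth", {
  # 10 amplicons over 5 genes so one amplified gene stays a minority of the
  # panel (median-of-ratios normalization needs a copy-neutral majority)
  set.seed(111)
  rows <- do.call(rbind, lapply(1:10, function(i)
    panelRow(sprintf("A%02d", i), "chrC", 1000 + i * 200,
             paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = ""),
             randPrimer(), randPrimer(),
             gene = sprintf("CNVG%d", (i - 1) %/% 2 + 1))))
  pan <- PanelDesign(rows)
  ampDepth <- c(1000, 2000, 1500, 800, 1200, 900, 1600, 700, 1100, 1300)
  base <- matrix(rep(ampDepth, each = 6), nrow = 6,
                 dimnames = list(paste0("B", 1:6), rows$amplicon_id))
  # identical depths: copy number exactly 2 everywhere
  cn <- inferCnv(base[1:2, ], base, pan)
  expect_true(all(cn$copy_number == 2))
  expect_true(all(cn$status == "normal"))

  # doubling one gene's amplicons: that gene 4.0, the rest still 2.0
  g1amps <- panelGenes(pan)[["CNVG1"]]
  s <- base[1, , drop = FALSE]
  s[, g1amps] <- s[, g1amps] * 2
  cn2 <- inferCnv(s, base, pan)
  expect_equal(cn2$copy_number[cn2$gene == "CNVG1"], 4.0, tolerance = 0.025)
  expect_true(all(cn2$copy_number[cn2$gene != "CNVG1"] == 2))
  expect_identical(cn2$status[cn2$gene == "CNVG1"], "amplified")

  # a whole-sample library-size effect changes nothing
  cn3 <- inferCnv(base[1, , drop = FALSE] * 3, base, pan)
  expect_true(all(cn3$copy_number == 2))

  expect_error(inferCnv(base[1:2, ], base[1:3, ], pan), ">= 5")
})
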