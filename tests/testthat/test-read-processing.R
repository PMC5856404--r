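# Pair merging, primer-anchored amplicon assignment and Q30 pileup.

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

randSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("merging handles full overlap, partial overlap and discordance", {
  # identical 100-base reads (r2 is the reverse complement): full overlap
  s <- randSeq(100, 1)
  m <- mergePair(s, rep(35L, 100), rc(s), rep(35L, 100))
  expect_equal(nchar(m$sequence), 100)
  expect_identical(m$sequence, s)
  expect_length(m$discordant, 0)

  # 150 + 150 overlapping by 80 -> merged length 220
  full <- randSeq(220, 2)
  r1 <- substr(full, 1, 150)
  r2 <- rc(substr(full, 71, 220))
  m2 <- mergePair(r1, rep(35L, 150), r2, rep(35L, 150))
  expect_equal(nchar(m2$sequence), 220)
  expect_identical(m2$sequence, full)

  # a discordant overlap base keeps the higher-quality base at Phred 2
  s1 <- s
  substr(s1, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                substr(s, 50, 50))[1]
  q1 <- rep(35L, 100); q1[50] <- 35L
  m3 <- mergePair(s1, q1, rc(s), rep(20L, 100))
  expect_identical(substr(m3$sequence, 50, 50), substr(s1, 50, 50))
  expect_equal(m3$qualities[50], 2L)
  expect_equal(m3$discordant, 49L)  # 0-based offset

  # no acceptable overlap -> no-merge sentinel
  expect_null(mergePair(randSeq(50, 3), rep(35L, 50),
                        randSeq(50, 4), rep(35L, 50)))
})

test_that("merging is symmetric under swapping the pair", {
  full <- randSeq(180, 5)
  r1 <- substr(full, 1, 120)
  r2 <- rc(substr(full, 61, 180))
  a <- mergePair(r1, rep(35L, 120), r2, rep(30L, 120))
  # swapping the reads reconstructs the reverse-complement strand
  b <- mergePair(r2, rep(30L, 120), r1, rep(35L, 120))
  expect_identical(b$sequence, rc(a$sequence))
  expect_equal(nchar(a$sequence), 180)
})

test_that("amplicon assignment requires a unique primer match", {
  pan <- fixturePanel()
  gr <- amplicons(pan)
  mc <- S4Vectors::mcols(gr)
  top <- paste0(mc$fwd_primer[1], mc$insert_seq[1], rc(mc$rev_primer[1]))
  merged <- list(sequence = top, qualities = rep(35L, nchar(top)))
  a <- assignAmplicon(merged, pan)
  expect_equal(a$amplicon_id, mc$amplicon_id[1])
  expect_identical(a$sequence, mc$insert_seq[1])

  # 3 mismatches in the forward primer exceed the default tolerance of 2
  bad <- top
  for (i in 1:3) {
    substr(bad, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, i, i))[1]
  }
  expect_true(is.na(assignAmplicon(list(sequence = bad,
                                        qualities = rep(35L, nchar(bad))),
                                   pan)$amplicon_id))

  # a read matching two amplicons equally is left unassigned
  fwd <- randPrimer(seed = 41); rev <- randPrimer(seed = 42)
  insA <- randSeq(60, 43); insB <- randSeq(60, 44)
  twin <- PanelDesign(rbind(
    panelRow("t1", "chr2", 100, insA, fwd, rev),
    panelRow("t2", "chr2", 500, insB, fwd, rev)))
  readT <- paste0(fwd, insA, rc(rev))
  expect_true(is.na(assignAmplicon(list(sequence = readT,
                                        qualities = rep(35L, nchar(readT))),
                                   twin)$amplicon_id))
})

test_that("pileup enforces the Q30 rule and counts indel alleles", {
  fwd <- randPrimer(seed = 51); rev <- randPrimer(seed = 52)
  ins <- randSeq(60, 53)
  pan <- PanelDesign(panelRow("p1", "chr3", 100, ins, fwd, rev))

  # 100 clean reference reads at Q40: full depth, no alt anywhere
  reads <- replicate(100, list(amplicon_id = "p1", sequence = ins,
                               qualities = rep(40L, 60)), simplify = FALSE)
  pc <- pileupCounts(reads, pan)
  s <- pc$tensor@snv
  expect_true(all(s$A + s$C + s$G + s$T == 100))
  altTot <- vapply(seq_len(nrow(s)), function(i)
    sum(s[i, setdiff(c("A", "C", "G", "T"), s$ref[i])]), numeric(1))
  expect_true(all(altTot == 0))

  # an alt base at Q29 contributes nothing, and depth there excludes it
  mut <- ins
  substr(mut, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ins, 30, 30))[1]
  q <- rep(40L, 60); q[30] <- 29L
  pc2 <- pileupCounts(c(reads, list(list(amplicon_id = "p1", sequence = mut,
                                         qualities = q))), pan)
  s2 <- pc2$tensor@snv
  at30 <- s2[s2$pos == 100 + 29, ]
  expect_equal(sum(at30[, c("A", "C", "G", "T")]), 100)  # Q29 base dropped
  expect_equal(at30[[substr(mut, 30, 30)]], 0)

  # 10 reads carrying a 15-base deletion -> del:15 with count 10
  del <- paste0(substr(ins, 1, 20), substr(ins, 36, 60))
  readsDel <- replicate(10, list(amplicon_id = "p1", sequence = del,
                                 qualities = rep(40L, 45)), simplify = FALSE)
  pc3 <- pileupCounts(c(reads, readsDel), pan)
  ind <- indelCounts(pc3$tensor)
  expect_equal(nrow(ind), 1)
  expect_equal(ind$allele, "del:15")
  expect_equal(ind$count, 10)
  la <- leftAlignIndel(ins, 100, 120, deleted = substr(ins, 21, 35))
  expect_equal(ind$pos, la$pos)

  # counts conservation: no position exceeds the number of covering reads
  s3 <- pc3$tensor@snv
  expect_true(all(s3$A + s3$C + s3$G + s3$T <= 110))
})

test_that("error-free FASTQ round-trips to exact molecule fractions", {
  fwd <- randPrimer(seed = 61); rev <- randPrimer(seed = 62)
  ins <- randSeq(80, 63)
  pan <- PanelDesign(panelRow("f1", "chr4", 100, ins, fwd, rev))
  refBase <- substr(ins, 41, 41)
  truth <- data.frame(chrom = "chr4", pos = 140L, ref = refBase,
                      alt = setdiff(c("A", "C", "G", "T"), refBase)[1],
                      class = "SNV", stock_af = 0.5, expected_af = 0.1,
                      stringsAsFactors = FALSE)
  r1 <- tempfile(fileext = "_R1.fastq.gz")
  r2 <- tempfile(fileext = "_R2.fastq.gz")
  nMol <- 200L; nMut <- 23L
  simulateFastq(pan, nMolecules = nMol, truth = truth, mutantCopies = nMut,
                readsPerMolecule = 2, r1Path = r1, r2Path = r2, seed = 64)
  out <- processFastq(r1, r2, pan)
  expect_equal(out$qc$pairs_in, nMol * 2L)
  expect_equal(out$qc$merged, out$qc$pairs_in)     # clean data all merge
  expect_equal(out$qc$assigned, out$qc$pairs_in)
  s <- snvCounts(out$tensor)
  at <- s[s$pos == 140L, ]
  expect_equal(at[[truth$alt]] / (at$A + at$C + at$G + at$T), nMut / nMol)
  # every other position is pure reference at full depth
  off <- s[s$pos != 140L, ]
  altTot <- vapply(seq_len(nrow(off)), function(i)
    sum(off[i, setdiff(c("A", "C", "G", "T"), off$ref[i])]), numeric(1))
  expect_true(all(altTot == 0))
})
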