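# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small 4-amplicon panel for unit tests.
fixturePanel <- function() {
  if (is.null(.fixtures$panel)) .fixtures$panel <- toyPanel(seed = 101)
  .fixtures$panel
}

# 1 kb toy panel with true error rates, a fitted background from 12 control
# samples and a calibrated threshold; used by the calling and acceptance
# tests.
fixtureCalibration <- function() {
  if (is.null(.fixtures$cal)) {
    pan <- toyPanel(nAmplicons = 10, insertLen = 100, seed = 42)
    er <- syntheticErrorRates(pan, seed = 12)
    ctrl <- do.call(rbind, lapply(1:12, function(i)
      snvCounts(simulateCounts(NULL, pan, er,
                               sampleName = paste0("C", i), seed = 200 + i))))
    bg <- fitBackground(AlleleCountTensor(ctrl))
    thr <- calibrateThreshold(bg, budget = 3e-6, nSim = 50, seed = 77)
    .fixtures$cal <- list(panel = pan, trueRates = er, background = bg,
                          thresholds = thr)
  }
  .fixtures$cal
}

# A panel data.frame row, convenient for building tiny bespoke panels.
panelRow <- function(id, chrom, start0, insert, fwd, rev, gene = "G1") {
  data.frame(amplicon_id = id, chrom = chrom, insert_start = start0,
             insert_end = start0 + nchar(insert), fwd_primer = fwd,
             rev_primer = rev, insert_seq = insert, gene = gene,
             stringsAsFactors = FALSE)
}

randPrimer <- function(n = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a control tensor directly from per-library (alt, depth) draws at a
# single locus, replicated over dummy positions for speed of construction.
.syntheticControlTensor <- function(altFun, nControls, nReplicates, depth,
                                    ref = "A", alt = "G") {
  rows <- list()
  for (s in seq_len(nControls)) for (r in seq_len(nReplicates)) {
    a <- altFun()
    cnt <- stats::setNames(c(0L, 0L, 0L, 0L), c("A", "C", "G", "T"))
    cnt[alt] <- a
    cnt[ref] <- depth - a
    rows[[length(rows) + 1L]] <- data.frame(
      sample = paste0("C", s), replicate = r, amplicon_id = "amp1",
      chrom = "chr1", pos = 10L, ref = ref,
      A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
      stringsAsFactors = FALSE)
  }
  AlleleCountTensor(do.call(rbind, rows))
}
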