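# Paired-end read handling: overlap merging, primer-anchored amplicon
# assignment (which replaces alignment, since every template is a known
# amplicon), and quality-filtered pileup into the allele-count tensor.

#' Merge a read pair by best ungapped overlap
#'
#' Reverse-complements the second read and scans all overlap lengths
#' `>= minOverlap` for the one with the most matching bases. In the overlap,
#' concordant bases keep the higher of the two qualities; discordant bases
#' take the higher-quality base and are assigned Phred quality 2, which
#' guarantees they are later excluded by the Q30 pileup filter. Ties for the
#' best overlap are treated as unmergeable.
#'
#' @param seq1,seq2 read sequences (characters); `seq2` as sequenced
#'   (opposite strand).
#' @param qual1,qual2 integer Phred qualities per base.
#' @param minOverlap minimum acceptable overlap (default 10).
#' @param maxMismatchFrac maximum tolerated mismatch fraction within the
#'   overlap (default 0.1); spurious overlaps between unrelated reads match
#'   only ~25% of bases and are rejected by this rule.
#' @return a list with `sequence`, `qualities`, `discordant` (0-based offsets
#'   into the merged read) — or `NULL` when no acceptable overlap exists.
#' @export
mergePair <- function(seq1, qual1, seq2, qual2, minOverlap = 10,
                      maxMismatchFrac = 0.1) {
  if (!nchar(seq1) || !nchar(seq2)) stop("reads must be non-empty")
  if (minOverlap < 1) stop("minOverlap must be >= 1")
  s1 <- utf8ToInt(seq1)
  s2r <- utf8ToInt(revComp(seq2))
  q2r <- rev(qual2)
  n1 <- length(s1); n2 <- length(s2r)
  if (min(n1, n2) < minOverlap) return(NULL)
  best <- -1L; bestK <- NA_integer_; tied <- FALSE
  for (k in seq.int(min(n1, n2), minOverlap)) {
    m <- sum(s1[(n1 - k + 1):n1] == s2r[1:k])
    if (k - m > maxMismatchFrac * k) next
    if (m > best) { best <- m; bestK <- k; tied <- FALSE }
    else if (m == best) tied <- TRUE
  }
  if (is.na(bestK) || tied) return(NULL)
  k <- bestK
  i1 <- (n1 - k + 1):n1
  i2 <- 1:k
  ovSeq <- s1[i1]; ovQ <- pmax(qual1[i1], q2r[i2])
  disc <- which(s1[i1] != s2r[i2])
  if (length(disc)) {
    useR2 <- q2r[i2][disc] > qual1[i1][disc]
    ovSeq[disc[useR2]] <- s2r[i2][disc[useR2]]
    ovQ[disc] <- 2L
  }
  mergedSeq <- intToUtf8(c(s1[seq_len(n1 - k)], ovSeq,
                           s2r[seq.int(k + 1, length.out = n2 - k)]))
  mergedQ <- c(qual1[seq_len(n1 - k)], ovQ,
               q2r[seq.int(k + 1, length.out = n2 - k)])
  list(sequence = mergedSeq, qualities = mergedQ,
       discordant = (n1 - k) + disc - 1L)
}

#' Assign a merged read to an amplicon by its primers and clip them
#'
#' The forward primer must match the 5' end and the (as-synthesized) reverse
#' primer the 3' end, each within `maxMismatch` substitutions. Exactly one
#' qualifying amplicon is required; zero or several leave the read
#' unassigned.
#'
#' @param merged a merged read from [mergePair()].
#' @param panel a [PanelDesign-class].
#' @param maxMismatch maximum mismatches tolerated in each primer (default 2).
#' @return list with `amplicon_id` (or `NA`), clipped `sequence` and
#'   `qualities` covering the insert only.
#' @export
assignAmplicon <- function(merged, panel, maxMismatch = 2) {
  gr <- amplicons(panel)
  mc <- S4Vectors::mcols(gr)
  n <- nchar(merged$sequence)
  hits <- integer(0)
  for (i in seq_along(gr)) {
    fp <- mc$fwd_primer[i]
    rp <- revComp(mc$rev_primer[i])  # top-strand 3' end
    lf <- nchar(fp); lr <- nchar(rp)
    if (n < lf + lr) next
    mmF <- .hamming(substr(merged$sequence, 1, lf), fp)
    if (mmF > maxMismatch) next
    mmR <- .hamming(substr(merged$sequence, n - lr + 1, n), rp)
    if (mmR > maxMismatch) next
    hits <- c(hits, i)
  }
  if (length(hits) != 1)
    return(list(amplicon_id = NA_character_, sequence = NULL, qualities = NULL))
  i <- hits
  lf <- nchar(mc$fwd_primer[i]); lr <- nchar(mc$rev_primer[i])
  list(amplicon_id = mc$amplicon_id[i],
       sequence = substr(merged$sequence, lf + 1, n - lr),
       qualities = merged$qualities[seq.int(lf + 1, n - lr)])
}

# Longest common prefix / suffix lengths of two integer base vectors.
.lcp <- function(a, b) {
  n <- min(length(a), length(b))
  if (!n) return(0L)
  d <- which(a[1:n] != b[1:n])
  if (!length(d)) n else d[1] - 1L
}

#' Pile assigned reads into an allele-count tensor
#'
#' Counts each read base at its panel position, excluding bases below
#' `minPhred` (default 30) — so merged-discordant Q2 bases never count.
#' Reads whose length differs from the insert are explained by a single
#' indel (longest common prefix/suffix decomposition), keyed by the
#' left-normalized allele; reads that cannot be explained that way are
#' dropped and counted in the QC summary.
#'
#' @param reads list of assigned reads from [assignAmplicon()] (entries with
#'   `NA` amplicon are skipped).
#' @param panel a [PanelDesign-class].
#' @param minPhred minimum base quality for inclusion (default 30).
#' @param sampleName,replicate labels for the output tensor.
#' @return list with `tensor` (an [AlleleCountTensor-class]) and `qc`
#'   (reads used / dropped).
#' @export
pileupCounts <- function(reads, panel, minPhred = 30, sampleName = "S1",
                         replicate = 1L) {
  gr <- amplicons(panel)
  mc <- S4Vectors::mcols(gr)
  idx <- stats::setNames(seq_along(gr), mc$amplicon_id)
  pp <- panelPositions(panel)
  nPos <- nrow(pp)
  counts <- matrix(0L, nrow = nPos, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  ppStart <- stats::setNames(match(mc$amplicon_id, pp$amplicon_id),
                             mc$amplicon_id)
  indelTab <- list()
  used <- 0L; unresolved <- 0L
  baseIdx <- stats::setNames(1:4, c("A", "C", "G", "T"))
  for (rd in reads) {
    if (is.null(rd$amplicon_id) || is.na(rd$amplicon_id)) next
    i <- idx[[rd$amplicon_id]]
    refSeq <- mc$insert_seq[i]
    insStart0 <- GenomicRanges::start(gr)[i] - 1L
    w <- nchar(refSeq)
    rv <- utf8ToInt(rd$sequence); fv <- utf8ToInt(refSeq)
    q <- rd$qualities
    off0 <- ppStart[[rd$amplicon_id]] - 1L
    nr <- length(rv)
    if (nr == w) {
      keep <- which(q >= minPhred)
      if (length(keep)) {
        bi <- baseIdx[strsplit(rd$sequence, "")[[1]][keep]]
        rows <- off0 + keep
        for (j in seq_along(rows))
          counts[rows[j], bi[j]] <- counts[rows[j], bi[j]] + 1L
      }
      used <- used + 1L
    } else {
      if (nr > w + 0L) {  # insertion candidate
        d <- nr - w
        p <- .lcp(rv, fv); s <- .lcp(rev(rv), rev(fv))
        if (p + s < w) { unresolved <- unresolved + 1L; next }
        p <- min(p, w - 0L)
        insSeq <- intToUtf8(rv[(p + 1):(p + d)])
        la <- leftAlignIndel(refSeq, insStart0, insStart0 + p,
                             inserted = insSeq)
        jq <- q[max(p, 1):min(p + d + 1, nr)]
        if (all(jq >= minPhred)) {
          indelTab[[length(indelTab) + 1L]] <- data.frame(
            sample = sampleName, replicate = replicate,
            amplicon_id = rd$amplicon_id, chrom = pp$chrom[off0 + 1L],
            pos = la$pos,
            ref = substr(refSeq, la$pos - insStart0 + 1L,
                         la$pos - insStart0 + 1L),
            allele = la$allele, count = 1L, stringsAsFactors = FALSE)
        }
        # count flanking matched bases
        aligned <- c(seq_len(p), seq.int(p + d + 1, length.out = nr - p - d))
        refPos <- c(seq_len(p), seq.int(p + 1, length.out = nr - p - d))
      } else {  # deletion
        d <- w - nr
        p <- .lcp(rv, fv); s <- .lcp(rev(rv), rev(fv))
        if (p + s < nr) { unresolved <- unresolved + 1L; next }
        p <- min(p, nr)
        delSeq <- substr(refSeq, p + 1, p + d)
        la <- leftAlignIndel(refSeq, insStart0, insStart0 + p,
                             deleted = delSeq)
        jq <- q[max(p, 1):min(p + 1, nr)]
        if (all(jq >= minPhred)) {
          indelTab[[length(indelTab) + 1L]] <- data.frame(
            sample = sampleName, replicate = replicate,
            amplicon_id = rd$amplicon_id, chrom = pp$chrom[off0 + 1L],
            pos = la$pos,
            ref = substr(refSeq, la$pos - insStart0 + 1L,
                         la$pos - insStart0 + 1L),
            allele = la$allele, count = 1L, stringsAsFactors = FALSE)
        }
        aligned <- seq_len(nr)
        refPos <- c(seq_len(p), seq.int(p + d + 1, length.out = nr - p))
      }
      keep <- which(q[aligned] >= minPhred)
      if (length(keep)) {
        bases <- strsplit(rd$sequence, "")[[1]][aligned[keep]]
        rows <- off0 + refPos[keep]
        if (any(refPos[keep] > w) || any(refPos[keep] < 1))
          stop("read extends outside its amplicon insert (clipping bug)")
        bi <- baseIdx[bases]
        for (j in seq_along(rows))
          counts[rows[j], bi[j]] <- counts[rows[j], bi[j]] + 1L
      }
      used <- used + 1L
    }
  }
  indel <- if (length(indelTab)) {
    agg <- do.call(rbind, indelTab)
    out <- stats::aggregate(count ~ sample + replicate + amplicon_id + chrom +
                              pos + ref + allele, data = agg, FUN = sum)
    out
  } else .emptyIndelTable()
  snv <- data.frame(sample = sampleName, replicate = replicate,
                    amplicon_id = pp$amplicon_id, chrom = pp$chrom,
                    pos = pp$pos, ref = pp$ref,
                    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
                    T = counts[, "T"], stringsAsFactors = FALSE)
  list(tensor = AlleleCountTensor(snv, indel),
       qc = list(reads_used = used, reads_unresolved = unresolved))
}

# --- FASTQ ------------------------------------------------------------------

#' Simulate paired-end FASTQ for a panel
#'
#' Emits 2x`readLen` read pairs per molecule with primers attached and flat
#' Phred quality strings. With `exactReads = TRUE` every molecule yields
#' exactly `readsPerMolecule` pairs, so downstream pileup fractions equal the
#' molecule fractions exactly on error-free data; otherwise the multiplicity
#' is Poisson.
#'
#' @param panel a [PanelDesign-class].
#' @param nMolecules wild-type molecules per amplicon.
#' @param truth optional truth table; `mutantCopies` gives mutant molecules
#'   per truth row (those replace wild-type molecules on their amplicon).
#' @param mutantCopies integer vector aligned with `truth` rows.
#' @param readLen read length (default 150).
#' @param readsPerMolecule read pairs per molecule (default 2).
#' @param exactReads deterministic multiplicity (default TRUE).
#' @param baseQual flat Phred quality (default 37).
#' @param r1Path,r2Path output FASTQ paths (".gz" honoured).
#' @param seed integer seed.
#' @return invisible list with read-pair count.
#' @export
simulateFastq <- function(panel, nMolecules, truth = NULL, mutantCopies = NULL,
                          readLen = 150, readsPerMolecule = 2,
                          exactReads = TRUE, baseQual = 37,
                          r1Path, r2Path, seed = 1) {
  set.seed(seed)
  gr <- amplicons(panel)
  mc <- S4Vectors::mcols(gr)
  seqs1 <- character(0); seqs2 <- character(0)
  for (i in seq_along(gr)) {
    top <- paste0(mc$fwd_primer[i], mc$insert_seq[i],
                  revComp(mc$rev_primer[i]))
    variantsHere <- if (!is.null(truth)) {
      insStart0 <- GenomicRanges::start(gr)[i] - 1L
      which(truth$chrom == as.character(GenomicRanges::seqnames(gr))[i] &
              truth$pos >= insStart0 &
              truth$pos < GenomicRanges::end(gr)[i])
    } else integer(0)
    tops <- top
    mols <- nMolecules
    if (length(variantsHere)) {
      insStart0 <- GenomicRanges::start(gr)[i] - 1L
      for (v in variantsHere) {
        mcv <- if (is.null(mutantCopies)) 0L else mutantCopies[v]
        if (mcv <= 0) next
        offset <- truth$pos[v] - insStart0  # 0-based into insert
        ins <- mc$insert_seq[i]
        if (truth$class[v] == "SNV") {
          mutIns <- paste0(substr(ins, 1, offset), truth$alt[v],
                           substr(ins, offset + 2, nchar(ins)))
        } else if (truth$class[v] == "deletion") {
          dl <- as.integer(sub("^del:", "", truth$alt[v]))
          mutIns <- paste0(substr(ins, 1, offset),
                           substr(ins, offset + dl + 1, nchar(ins)))
        } else {
          insSeq <- sub("^ins:", "", truth$alt[v])
          mutIns <- paste0(substr(ins, 1, offset), insSeq,
                           substr(ins, offset + 1, nchar(ins)))
        }
        tops <- c(tops, paste0(mc$fwd_primer[i], mutIns,
                               revComp(mc$rev_primer[i])))
        mols <- c(mols, mcv)
        mols[1] <- max(mols[1] - mcv, 0L)
      }
    }
    for (t in seq_along(tops)) {
      nm <- mols[t]
      if (nm <= 0) next
      nReads <- if (exactReads) rep(readsPerMolecule, nm) else
        stats::rpois(nm, readsPerMolecule)
      tot <- sum(nReads)
      if (!tot) next
      L <- nchar(tops[t])
      r1 <- substr(tops[t], 1, min(readLen, L))
      bot <- revComp(tops[t])
      r2 <- substr(bot, 1, min(readLen, L))
      seqs1 <- c(seqs1, rep(r1, tot))
      seqs2 <- c(seqs2, rep(r2, tot))
    }
  }
  n <- length(seqs1)
  ord <- if (n) sample.int(n) else integer(0)
  .writeFastq(seqs1[ord], baseQual, r1Path)
  .writeFastq(seqs2[ord], baseQual, r2Path)
  invisible(list(pairs = n))
}

.writeFastq <- function(seqs, baseQual, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("read_%06d", seq_along(dna))
  quals <- Biostrings::PhredQuality(
    vapply(nchar(seqs), function(n)
      paste(rep(intToUtf8(baseQual + 33L), n), collapse = ""), character(1)))
  q <- Biostrings::QualityScaledDNAStringSet(dna, quals)
  # Biostrings warns about dropped metadata columns on the container; benign
  suppressWarnings(
    Biostrings::writeQualityScaledXStringSet(q, path,
                                             compress = grepl("\\.gz$", path)))
  invisible(path)
}

#' Read paired FASTQ files into sequence/quality lists
#'
#' @param r1Path,r2Path FASTQ paths (gzipped allowed).
#' @return list of pairs; each a list `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
readFastqPairs <- function(r1Path, r2Path) {
  # Biostrings warns about metadata columns it drops on construction; benign
  f1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1Path))
  f2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2Path))
  if (length(f1) != length(f2)) stop("R1/R2 read counts differ")
  q1 <- as(Biostrings::quality(f1), "IntegerList")
  q2 <- as(Biostrings::quality(f2), "IntegerList")
  lapply(seq_along(f1), function(i) {
    list(seq1 = as.character(f1[[i]]), qual1 = q1[[i]],
         seq2 = as.character(f2[[i]]), qual2 = q2[[i]])
  })
}

#' Full FASTQ-to-tensor processing
#'
#' Merges pairs, assigns amplicons, clips primers and piles up counts under
#' the Q30 rule; failures at each stage are counted, not silently dropped.
#'
#' @inheritParams readFastqPairs
#' @param panel a [PanelDesign-class].
#' @param minOverlap,maxMismatch,minPhred stage parameters (see
#'   [mergePair()], [assignAmplicon()], [pileupCounts()]).
#' @param sampleName,replicate tensor labels.
#' @return list with `tensor` and `qc` (pairs in, merged, assigned,
#'   discordant base fraction).
#' @export
processFastq <- function(r1Path, r2Path, panel, minOverlap = 10,
                         maxMismatch = 2, minPhred = 30,
                         sampleName = "S1", replicate = 1L) {
  pairs <- readFastqPairs(r1Path, r2Path)
  merged <- 0L; discBases <- 0L; totBases <- 0L
  assigned <- list()
  for (p in pairs) {
    m <- mergePair(p$seq1, p$qual1, p$seq2, p$qual2, minOverlap = minOverlap)
    if (is.null(m)) next
    merged <- merged + 1L
    discBases <- discBases + length(m$discordant)
    totBases <- totBases + nchar(m$sequence)
    a <- assignAmplicon(m, panel, maxMismatch = maxMismatch)
    if (!is.na(a$amplicon_id)) assigned[[length(assigned) + 1L]] <- a
  }
  pc <- pileupCounts(assigned, panel, minPhred = minPhred,
                     sampleName = sampleName, replicate = replicate)
  list(tensor = pc$tensor,
       qc = list(pairs_in = length(pairs), merged = merged,
                 assigned = length(assigned),
                 discordant_base_fraction =
                   if (totBases) discBases / totBases else 0,
                 reads_unresolved = pc$qc$reads_unresolved))
}
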