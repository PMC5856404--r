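# VCF 4.3 emission for variant calls. Internally everything is 0-based
# half-open; this is the one place 1-based coordinates are produced.
# Reading back goes through VariantAnnotation (htslib), so round-trip tests
# check our output against the standard parser rather than a parser of ours.

.vcfHeader <- function(sampleName) {
  c("##fileformat=VCFv4.3",
    "##source=plasmacall",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Joint maximum-likelihood allele fraction across replicates\">",
    "##INFO=<ID=PAF,Number=1,Type=Float,Description=\"Pooled alt-read fraction across replicates\">",
    "##INFO=<ID=LR,Number=1,Type=Float,Description=\"Log-likelihood-ratio statistic vs the background null\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth across replicates\">",
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class (SNV, insertion, deletion)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (placeholder for somatic calls)\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Per-replicate alt read counts\">",
    "##FORMAT=<ID=DPR,Number=.,Type=Integer,Description=\"Per-replicate depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleName, sep = "\t"))
}

# Fetch reference base(s) at 0-based [pos0, pos0+len) from the panel insert
# containing them; errors if outside the footprint.
.panelRefSeq <- function(panel, chrom, pos0, len = 1L) {
  gr <- amplicons(panel)
  hit <- which(as.character(GenomicRanges::seqnames(gr)) == chrom &
                 GenomicRanges::start(gr) - 1L <= pos0 &
                 GenomicRanges::end(gr) >= pos0 + len)
  if (!length(hit))
    stop(sprintf("locus %s:%d (+%d) lies outside the panel footprint",
                 chrom, pos0, len))
  i <- hit[1]
  insStart0 <- GenomicRanges::start(gr)[i] - 1L
  substr(S4Vectors::mcols(gr)$insert_seq[i],
         pos0 - insStart0 + 1L, pos0 - insStart0 + len)
}

#' Write variant calls as VCF 4.3
#'
#' Emits one record per call with the joint MLE allele fraction (`AF`), the
#' pooled alt fraction (`PAF`), the likelihood-ratio statistic (`LR`), total
#' depth and per-replicate support. Positions are converted from the internal
#' 0-based convention to 1-based VCF `POS`; indels are emitted VCF-style with
#' the anchor base preceding the left-normalized event.
#'
#' @param calls data.frame of calls as returned by [callVariants()] (columns
#'   `chrom`, `pos`, `ref`, `alt`, `class`, `af_mle`, `af_pooled`, `lr`,
#'   `status`, `alt_counts`, `depths`).
#' @param panel the [PanelDesign-class] the calls were made against (supplies
#'   reference context for indel anchors and footprint checks).
#' @param path output file.
#' @param sampleName sample column name in the VCF.
#' @return `path`, invisibly.
#' @export
writeCallsVcf <- function(calls, panel, path, sampleName = "SAMPLE") {
  lines <- .vcfHeader(sampleName)
  if (nrow(calls)) {
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    recs <- vapply(seq_len(nrow(calls)), function(i) {
      x <- calls[i, ]
      if (x$class == "SNV") {
        refObs <- .panelRefSeq(panel, x$chrom, x$pos)
        if (refObs != x$ref)
          stop(sprintf("call ref '%s' disagrees with panel reference '%s' at %s:%d",
                       x$ref, refObs, x$chrom, x$pos))
        pos1 <- x$pos + 1L; ref <- x$ref; alt <- x$alt
      } else if (x$class == "deletion") {
        dl <- as.integer(sub("^del:", "", x$alt))
        anchor <- .panelRefSeq(panel, x$chrom, x$pos - 1L)
        ref <- paste0(anchor, .panelRefSeq(panel, x$chrom, x$pos, dl))
        alt <- anchor
        pos1 <- x$pos  # anchor is 0-based pos-1 -> 1-based pos
      } else if (x$class == "insertion") {
        insSeq <- sub("^ins:", "", x$alt)
        anchor <- .panelRefSeq(panel, x$chrom, x$pos - 1L)
        ref <- anchor
        alt <- paste0(anchor, insSeq)
        pos1 <- x$pos
      } else stop("unknown variant class: ", x$class)
      info <- sprintf("AF=%.6g;PAF=%.6g;LR=%.6g;DP=%d;VCLASS=%s",
                      x$af_mle, x$af_pooled, x$lr,
                      sum(as.integer(strsplit(x$depths, ",")[[1]])), x$class)
      fmt <- paste0("0/1:", gsub("\\s", "", x$alt_counts), ":",
                    gsub("\\s", "", x$depths))
      paste(x$chrom, pos1, ".", ref, alt,
            sprintf("%.2f", max(0, x$lr)),
            if (identical(x$status, "called")) "PASS" else "lowLR",
            info, "GT:AD:DPR", fmt, sep = "\t")
    }, character(1))
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a plasmacall VCF back into a call table
#'
#' Parses with `VariantAnnotation::readVcf()` and reshapes into the same
#' data.frame layout [callVariants()] produces, restoring the internal 0-based
#' positions and `ins:`/`del:` allele strings.
#'
#' @param path VCF file written by [writeCallsVcf()].
#' @param panel optional [PanelDesign-class]; when supplied, the `ref` base
#'   of insertion records (the base the insertion precedes, which a VCF
#'   record does not carry) is restored from the panel reference. Without a
#'   panel the VCF anchor base is reported instead.
#' @return data.frame of calls.
#' @export
readCallsVcf <- function(path, panel = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE) ||
      !requireNamespace("SummarizedExperiment", quietly = TRUE))
    stop("readCallsVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  n <- length(vcf)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), class = character(),
                      af_mle = numeric(), af_pooled = numeric(),
                      lr = numeric(), status = character(),
                      alt_counts = character(), depths = character(),
                      stringsAsFactors = FALSE)
  if (!n) return(empty)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)
  refs <- as.character(rr$REF)
  alts <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  cls <- as.character(info$VCLASS)
  pos1 <- GenomicRanges::start(rr)
  pos0 <- integer(n); refOut <- character(n); altOut <- character(n)
  for (i in seq_len(n)) {
    if (cls[i] == "SNV") {
      pos0[i] <- pos1[i] - 1L; refOut[i] <- refs[i]; altOut[i] <- alts[i]
    } else if (cls[i] == "deletion") {
      pos0[i] <- pos1[i]  # first deleted base, 0-based
      refOut[i] <- substr(refs[i], 2, 2)
      altOut[i] <- paste0("del:", nchar(refs[i]) - nchar(alts[i]))
    } else {
      pos0[i] <- pos1[i]
      refOut[i] <- if (is.null(panel)) refs[i] else
        .panelRefSeq(panel, as.character(GenomicRanges::seqnames(rr))[i],
                     pos0[i])
      altOut[i] <- paste0("ins:", substr(alts[i], 2, nchar(alts[i])))
    }
  }
  fmtJoin <- function(m) vapply(seq_len(n), function(i)
    paste(unlist(m[i, 1]), collapse = ","), character(1))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = pos0, ref = refOut, alt = altOut, class = cls,
    af_mle = as.numeric(info$AF), af_pooled = as.numeric(info$PAF),
    lr = as.numeric(info$LR),
    status = ifelse(unlist(VariantAnnotation::filt(vcf)) == "PASS",
                    "called", "not_called"),
    alt_counts = fmtJoin(gt$AD), depths = fmtJoin(gt$DPR),
    stringsAsFactors = FALSE
  )
}

#' Write the flat TSV call report
#'
#' @inheritParams writeCallsVcf
#' @export
writeCallsTsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
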