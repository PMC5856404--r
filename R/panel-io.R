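# Panel / truth-set / count-tensor text formats. All files are TSV with
# 0-based half-open coordinates; VCF emission (1-based) lives in vcf-io.R.

#' Construct a PanelDesign from a data.frame
#'
#' @param df data.frame with columns `amplicon_id`, `chrom`, `insert_start`
#'   (0-based inclusive), `insert_end` (0-based exclusive), `fwd_primer`,
#'   `rev_primer`, `insert_seq`, `gene`.
#' @param lengthBounds numeric(2): allowed full amplicon length (primers +
#'   insert). The default `c(72, 154)` matches short-amplicon panels designed
#'   for fragmented cell-free DNA; override for toy panels outside that range.
#' @return a validated [PanelDesign-class].
#' @export
PanelDesign <- function(df, lengthBounds = c(72, 154)) {
  need <- c("amplicon_id", "chrom", "insert_start", "insert_end",
            "fwd_primer", "rev_primer", "insert_seq", "gene")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("panel table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$insert_end <= df$insert_start))
    stop("insert_end must exceed insert_start (0-based half-open)")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$insert_start + 1L,
                              end = df$insert_end)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    amplicon_id = as.character(df$amplicon_id),
    gene = as.character(df$gene),
    fwd_primer = toupper(as.character(df$fwd_primer)),
    rev_primer = toupper(as.character(df$rev_primer)),
    insert_seq = toupper(as.character(df$insert_seq))
  )
  methods::new("PanelDesign", amplicons = gr, lengthBounds = lengthBounds)
}

#' Read an amplicon panel from TSV
#'
#' @param path TSV file with the columns documented in [PanelDesign()].
#' @inheritParams PanelDesign
#' @return a [PanelDesign-class].
#' @export
readPanel <- function(path, lengthBounds = c(72, 154)) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(insert_start = "integer",
                                     insert_end = "integer")),
    error = function(e) stop("malformed panel TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  bad <- which(!grepl("^[ACGT]+$", df$insert_seq) |
                 !grepl("^[ACGT]+$", df$fwd_primer) |
                 !grepl("^[ACGT]+$", df$rev_primer) |
                 is.na(df$insert_start) | is.na(df$insert_end))
  if (length(bad))
    stop(sprintf("malformed panel row at line %d of %s", bad[1] + 1L, path))
  PanelDesign(df, lengthBounds = lengthBounds)
}

#' Write an amplicon panel to TSV
#'
#' @param panel a [PanelDesign-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  gr <- amplicons(panel)
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(
    amplicon_id = mc$amplicon_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    insert_start = GenomicRanges::start(gr) - 1L,
    insert_end = GenomicRanges::end(gr),
    fwd_primer = mc$fwd_primer,
    rev_primer = mc$rev_primer,
    insert_seq = mc$insert_seq,
    gene = mc$gene,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- truth sets -------------------------------------------------------------

#' Validate / read / write truth-variant tables
#'
#' A truth set describes the variants engineered into a reference standard:
#' position (0-based), ref/alt alleles, variant class, the allele fraction in
#' the undiluted stock (`stock_af`) and the fraction expected after dilution
#' or spiking (`expected_af`). Indels use the left-normalized allele string
#' convention (`alt` is `"ins:<seq>"` or `"del:<len>"` with `ref` the base at
#' `pos`).
#'
#' @param truth data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `class` (one of `SNV`, `insertion`, `deletion`), `stock_af`,
#'   `expected_af`.
#' @return `validateTruth()` returns the table invisibly after checking
#'   invariants; readers return the validated data.frame.
#' @export
validateTruth <- function(truth) {
  need <- c("chrom", "pos", "ref", "alt", "class", "stock_af", "expected_af")
  miss <- setdiff(need, colnames(truth))
  if (length(miss))
    stop("truth table missing columns: ", paste(miss, collapse = ", "))
  if (!all(truth$class %in% c("SNV", "insertion", "deletion")))
    stop("variant class must be SNV, insertion or deletion")
  if (any(truth$stock_af < 0 | truth$stock_af > 1))
    stop("stock_af must lie in [0, 1]")
  bad <- truth$expected_af < 0 | truth$expected_af > truth$stock_af
  if (any(bad))
    stop("expected_af must lie in [0, stock_af]")
  same <- truth$class == "SNV" & truth$ref == truth$alt
  if (any(same)) stop("ref and alt must differ")
  invisible(truth)
}

#' @rdname validateTruth
#' @param path TSV path.
#' @export
readTruthSet <- function(path) {
  # explicit classes: a ref/alt value of "T" must stay a string
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character",
                                         class = "character"))
  validateTruth(df)
  df
}

#' @rdname validateTruth
#' @export
writeTruthSet <- function(truth, path) {
  validateTruth(truth)
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- indel normalization ----------------------------------------------------

#' Left-align an indel within a reference context
#'
#' Indels in repetitive sequence have several equivalent placements; the
#' package stores every indel at its left-most position ("ins:<seq>" /
#' "del:<len>" alleles), the same normalization VCF uses.
#'
#' @param refSeq reference sequence (character) covering the indel locus.
#' @param refStart0 0-based genomic position of the first base of `refSeq`.
#' @param pos0 0-based position of the first affected base: first deleted base
#'   for deletions, the base before which the sequence is inserted for
#'   insertions.
#' @param deleted for deletions, the deleted sequence (must match the
#'   reference at `pos0`).
#' @param inserted for insertions, the inserted sequence.
#' @return list with `pos` (0-based, left-aligned), `allele` (allele string)
#'   and for deletions the shifted deleted sequence.
#' @export
leftAlignIndel <- function(refSeq, refStart0, pos0, deleted = NULL,
                           inserted = NULL) {
  if (is.null(deleted) == is.null(inserted))
    stop("provide exactly one of deleted / inserted")
  off <- pos0 - refStart0  # 0-based offset into refSeq
  refv <- strsplit(refSeq, "")[[1]]
  if (!is.null(deleted)) {
    dl <- nchar(deleted)
    if (off + dl > length(refv) || off < 0)
      stop("deletion outside supplied reference context")
    if (paste(refv[(off + 1):(off + dl)], collapse = "") != deleted)
      stop("deleted sequence does not match the reference at pos0")
    while (off > 0 && refv[off] == refv[off + dl]) off <- off - 1
    seqOut <- paste(refv[(off + 1):(off + dl)], collapse = "")
    list(pos = refStart0 + off, allele = paste0("del:", dl), seq = seqOut)
  } else {
    ins <- strsplit(inserted, "")[[1]]
    while (off > 0 && ins[length(ins)] == refv[off]) {
      ins <- c(ins[length(ins)], ins[-length(ins)])
      off <- off - 1
    }
    seqOut <- paste(ins, collapse = "")
    list(pos = refStart0 + off, allele = paste0("ins:", seqOut), seq = seqOut)
  }
}

# --- allele-count tensor I/O ------------------------------------------------

#' Construct an AlleleCountTensor from its tables
#'
#' @param snv base-count data.frame (see [AlleleCountTensor-class]).
#' @param indel indel-count data.frame; defaults to empty.
#' @return an [AlleleCountTensor-class].
#' @export
AlleleCountTensor <- function(snv, indel = .emptyIndelTable()) {
  if (!"amplicon_id" %in% colnames(indel)) indel$amplicon_id <- NA_character_
  methods::new("AlleleCountTensor",
               snv = as.data.frame(snv), indel = as.data.frame(indel))
}

#' Read / write allele-count tensors as TSV
#'
#' The TSV has fixed columns `sample`, `replicate`, `amplicon_id`, `chrom`,
#' `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, plus one column per observed
#' indel allele named `ins:<seq>` or `del:<len>` holding the supporting read
#' count at that row's locus.
#'
#' @param path TSV path.
#' @return `readCountTensor()` returns an [AlleleCountTensor-class];
#'   `writeCountTensor()` returns `path` invisibly.
#' @export
readCountTensor <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("sample", "amplicon_id", "chrom", "ref")))
  fixed <- c("sample", "replicate", "amplicon_id", "chrom", "pos", "ref",
             "A", "C", "G", "T")
  extra <- setdiff(colnames(dt), fixed)
  snv <- as.data.frame(dt[, fixed, with = FALSE])
  indel <- .emptyIndelTable()
  if (length(extra)) {
    badCols <- extra[!grepl("^(ins:[ACGT]+|del:[0-9]+)$", extra)]
    if (length(badCols))
      stop("unrecognized count columns: ", paste(badCols, collapse = ", "))
    long <- data.table::melt(
      dt, id.vars = c("sample", "replicate", "amplicon_id", "chrom", "pos", "ref"),
      measure.vars = extra, variable.name = "allele", value.name = "count",
      variable.factor = FALSE)
    long <- long[!is.na(long$count) & long$count > 0, ]
    indel <- as.data.frame(long)
  }
  AlleleCountTensor(snv, indel)
}

#' @rdname readCountTensor
#' @param tensor an [AlleleCountTensor-class].
#' @export
writeCountTensor <- function(tensor, path) {
  snv <- data.table::as.data.table(snvCounts(tensor))
  ind <- indelCounts(tensor)
  if (nrow(ind)) {
    wide <- data.table::dcast(
      data.table::as.data.table(ind),
      sample + replicate + chrom + pos ~ allele,
      value.var = "count", fun.aggregate = sum, fill = 0L)
    out <- merge(snv, wide, by = c("sample", "replicate", "chrom", "pos"),
                 all.x = TRUE)
    alleleCols <- setdiff(colnames(wide),
                          c("sample", "replicate", "chrom", "pos"))
    for (cc in alleleCols) data.table::set(out, which(is.na(out[[cc]])), cc, 0L)
    data.table::setcolorder(out, c("sample", "replicate", "amplicon_id",
                                   "chrom", "pos", "ref", "A", "C", "G", "T",
                                   alleleCols))
  } else {
    out <- snv
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
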