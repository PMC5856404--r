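#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' PanelDesign: an amplicon panel
#'
#' Holds the amplicons of a multiplex PCR panel: insert coordinates (the
#' interrogated bases between the primers), primer sequences, insert reference
#' sequences and a gene assignment. Coordinates are stored in a
#' [GenomicRanges::GRanges] (1-based closed, the Bioconductor convention);
#' all text I/O for this package uses 0-based half-open coordinates and the
#' converters live in the panel readers/writers.
#'
#' The reverse primer is stored as synthesized, i.e. as the reverse complement
#' of the reference top strand at its binding site; all counting in the
#' package is done on the top strand.
#'
#' @slot amplicons `GRanges` of insert intervals with metadata columns
#'   `amplicon_id`, `gene`, `fwd_primer`, `rev_primer`, `insert_seq`.
#' @slot lengthBounds numeric(2), allowed full amplicon length range
#'   (primers + insert); default `c(72, 154)`.
#'
#' @examples
#' pan <- toyPanel()
#' pan
#' footprintBases(pan)
#' @export
setClass("PanelDesign",
  slots = c(amplicons = "GRanges", lengthBounds = "numeric"),
  prototype = prototype(lengthBounds = c(72, 154))
)

setValidity("PanelDesign", function(object) {
  gr <- object@amplicons
  mc <- S4Vectors::mcols(gr)
  need <- c("amplicon_id", "gene", "fwd_primer", "rev_primer", "insert_seq")
  if (!all(need %in% colnames(mc)))
    return(paste("missing amplicon metadata columns:",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (anyDuplicated(mc$amplicon_id))
    return("duplicate amplicon_id values")
  if (length(gr)) {
    if (!all(grepl("^[ACGT]+$", mc$fwd_primer)) ||
        !all(grepl("^[ACGT]+$", mc$rev_primer)))
      return("primer sequences must be non-empty over {A,C,G,T}")
    if (!all(nchar(mc$insert_seq) == GenomicRanges::width(gr)))
      return("insert_seq length must equal insert interval width")
    full <- nchar(mc$fwd_primer) + nchar(mc$rev_primer) + GenomicRanges::width(gr)
    lb <- object@lengthBounds
    if (any(full < lb[1] | full > lb[2]))
      return(sprintf("full amplicon length outside [%d, %d] for: %s",
                     lb[1], lb[2],
                     paste(mc$amplicon_id[full < lb[1] | full > lb[2]],
                           collapse = ", ")))
  }
  TRUE
})

#' AlleleCountTensor: per sample/replicate/position allele counts
#'
#' The substrate of the caller: base counts per (sample, replicate, panel
#' position), plus a long table of indel allele counts keyed by their
#' left-normalized representation. Positions are 0-based here and in the TSV
#' serialization, matching the internal convention (1-based coordinates appear
#' only in VCF output).
#'
#' @slot snv `data.frame` with columns `sample`, `replicate`, `amplicon_id`,
#'   `chrom`, `pos` (0-based), `ref`, `A`, `C`, `G`, `T`.
#' @slot indel `data.frame` with columns `sample`, `replicate`, `amplicon_id`,
#'   `chrom`, `pos` (0-based), `ref`, `allele` (`"ins:<seq>"` or `"del:<len>"`),
#'   `count`.
#' @export
setClass("AlleleCountTensor",
  slots = c(snv = "data.frame", indel = "data.frame")
)

.emptyIndelTable <- function() {
  data.frame(sample = character(), replicate = integer(),
             amplicon_id = character(), chrom = character(),
             pos = integer(), ref = character(), allele = character(),
             count = integer(), stringsAsFactors = FALSE)
}

setValidity("AlleleCountTensor", function(object) {
  needS <- c("sample", "replicate", "amplicon_id", "chrom", "pos", "ref",
             "A", "C", "G", "T")
  if (!all(needS %in% colnames(object@snv)))
    return(paste("snv table missing columns:",
                 paste(setdiff(needS, colnames(object@snv)), collapse = ", ")))
  needI <- c("sample", "replicate", "chrom", "pos", "ref", "allele", "count")
  if (!all(needI %in% colnames(object@indel)))
    return(paste("indel table missing columns:",
                 paste(setdiff(needI, colnames(object@indel)), collapse = ", ")))
  cnt <- as.matrix(object@snv[, c("A", "C", "G", "T")])
  if (length(cnt) && any(cnt < 0)) return("negative base counts")
  if (nrow(object@indel) && any(object@indel$count < 0))
    return("negative indel counts")
  TRUE
})

#' BackgroundModel: position-specific error-rate null
#'
#' Per (position, substitution) beta-binomial background error distributions
#' fitted from a control cohort, and a separate registry of indel backgrounds
#' with batch provenance. Parameterization is (mean, rho): `mean` is the
#' expected error fraction, `rho` the intra-class correlation (overdispersion;
#' 0 = binomial).
#'
#' @slot snv `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `mean`,
#'   `rho`, `n_controls`, `flag` (`""` or `"low_confidence"`).
#' @slot indel `data.frame` with columns `chrom`, `pos`, `ref`, `allele`,
#'   `mean`, `rho`, `n_controls`, `batch`, `flag`.
#' @slot pseudocount numeric(2): pseudocount added to (alt numerator,
#'   depth denominator) of each control fraction; default `c(0.5, 1)`.
#' @export
setClass("BackgroundModel",
  slots = c(snv = "data.frame", indel = "data.frame", pseudocount = "numeric"),
  prototype = prototype(pseudocount = c(0.5, 1))
)

setValidity("BackgroundModel", function(object) {
  need <- c("chrom", "pos", "ref", "alt", "mean", "rho", "n_controls", "flag")
  if (!all(need %in% colnames(object@snv)))
    return(paste("snv table missing columns:",
                 paste(setdiff(need, colnames(object@snv)), collapse = ", ")))
  if (nrow(object@snv)) {
    if (any(object@snv$mean < 0 | object@snv$mean >= 1))
      return("background mean rates must lie in [0, 1)")
    if (any(object@snv$rho < 0)) return("overdispersion rho must be >= 0")
  }
  TRUE
})

#' MoleculePool: amplifiable copies of a sample before library preparation
#'
#' The molecule-level description of a (possibly diluted / spiked) DNA sample:
#' total amplifiable copies per locus and, for each truth variant, the number
#' of those copies carrying the mutant allele.
#'
#' @slot totalAC integer, amplifiable copies per locus.
#' @slot variants `data.frame`: truth-variant columns (`chrom`, `pos`, `ref`,
#'   `alt`, `class`, `stock_af`, `expected_af`) plus `mutant_copies`.
#' @slot seed integer seed that generated the pool.
#' @export
setClass("MoleculePool",
  slots = c(totalAC = "integer", variants = "data.frame", seed = "integer")
)

setValidity("MoleculePool", function(object) {
  if (length(object@totalAC) != 1 || object@totalAC <= 0)
    return("totalAC must be a single positive integer")
  v <- object@variants
  if (nrow(v)) {
    if (!"mutant_copies" %in% colnames(v)) return("variants need mutant_copies")
    if (any(v$mutant_copies < 0 | v$mutant_copies > object@totalAC))
      return("mutant_copies must lie in [0, totalAC]")
  }
  TRUE
})

#' LODResult: dual-binomial limit of detection for a dPCR assay
#'
#' Limit of detection computed from two binomial distributions: the critical
#' droplet count is the 95th percentile of the false-positive binomial
#' (alpha = 0.05), and the detectable per-droplet positive probability is the
#' smallest one whose 5th percentile reaches that critical level
#' (beta = 0.05). Copies per reaction follow from Poisson occupancy.
#'
#' @slot fprLambda false-positive rate per droplet.
#' @slot nDroplets mean accepted droplets per reaction.
#' @slot criticalLevel integer droplet-count threshold; a reaction is called
#'   positive when its mutant-positive droplets exceed it.
#' @slot pDet per-droplet positive probability at the LOD.
#' @slot lodCopies LOD in mutant copies per reaction.
#' @slot lodAfPercent LOD as allele fraction (%), relative to total target
#'   copies (wild-type plus mutant).
#' @slot wtLambda wild-type copies per droplet used for the AF conversion.
#' @slot alpha,beta the two error probabilities (defaults 0.05 each).
#' @export
setClass("LODResult",
  slots = c(fprLambda = "numeric", nDroplets = "numeric",
            criticalLevel = "integer", pDet = "numeric",
            lodCopies = "numeric", lodAfPercent = "numeric",
            wtLambda = "numeric", alpha = "numeric", beta = "numeric")
)

setValidity("LODResult", function(object) {
  if (object@criticalLevel < 0) return("criticalLevel must be >= 0")
  if (object@lodCopies < 0) return("lodCopies must be >= 0")
  if (object@lodAfPercent < 0 || object@lodAfPercent > 100)
    return("lodAfPercent must lie in [0, 100]")
  TRUE
})
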