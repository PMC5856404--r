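#' @include AllClasses.R
NULL

#' Accessors for panel and count objects
#'
#' `amplicons()` returns the insert `GRanges`; `footprintBases()` the number
#' of unique interrogated bases (size of the union of insert intervals);
#' `panelGenes()` the gene -> amplicon_id map; `snvCounts()`/`indelCounts()`
#' the underlying tables of an [AlleleCountTensor].
#'
#' @param x a `PanelDesign` or `AlleleCountTensor`.
#' @return See individual descriptions.
#' @name accessors
#' @aliases amplicons footprintBases panelGenes snvCounts indelCounts
#' @examples
#' footprintBases(toyPanel())
NULL

#' @rdname accessors
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))

#' @rdname accessors
#' @export
setGeneric("footprintBases", function(x) standardGeneric("footprintBases"))

#' @rdname accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname accessors
#' @export
setGeneric("snvCounts", function(x) standardGeneric("snvCounts"))

#' @rdname accessors
#' @export
setGeneric("indelCounts", function(x) standardGeneric("indelCounts"))

#' @rdname accessors
setMethod("amplicons", "PanelDesign", function(x) x@amplicons)

#' @rdname accessors
setMethod("footprintBases", "PanelDesign", function(x) {
  sum(GenomicRanges::width(GenomicRanges::reduce(x@amplicons)))
})

#' @rdname accessors
setMethod("panelGenes", "PanelDesign", function(x) {
  mc <- S4Vectors::mcols(x@amplicons)
  split(as.character(mc$amplicon_id), as.character(mc$gene))
})

#' @rdname accessors
setMethod("snvCounts", "AlleleCountTensor", function(x) x@snv)

#' @rdname accessors
setMethod("indelCounts", "AlleleCountTensor", function(x) x@indel)

setMethod("show", "PanelDesign", function(object) {
  gr <- object@amplicons
  cat(sprintf("PanelDesign: %d amplicons over %d genes, footprint %d bases\n",
              length(gr), length(unique(S4Vectors::mcols(gr)$gene)),
              footprintBases(object)))
  if (length(gr)) {
    fl <- nchar(S4Vectors::mcols(gr)$fwd_primer) +
      nchar(S4Vectors::mcols(gr)$rev_primer) + GenomicRanges::width(gr)
    cat(sprintf("  amplicon lengths (primers+insert): %d-%d bp\n",
                min(fl), max(fl)))
  }
})

setMethod("show", "AlleleCountTensor", function(object) {
  s <- object@snv
  cat(sprintf(paste0("AlleleCountTensor: %d samples x %d replicates, ",
                     "%d positions, %d indel records\n"),
              length(unique(s$sample)),
              length(unique(s$replicate)),
              length(unique(paste(s$chrom, s$pos))),
              nrow(object@indel)))
})

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf(paste0("BackgroundModel: %d SNV entries (%d low-confidence), ",
                     "%d indel entries\n"),
              nrow(object@snv), sum(object@snv$flag == "low_confidence"),
              nrow(object@indel)))
  if (nrow(object@snv))
    cat(sprintf("  mean error rate: median %.2e, max %.2e\n",
                stats::median(object@snv$mean), max(object@snv$mean)))
})

setMethod("show", "MoleculePool", function(object) {
  cat(sprintf("MoleculePool: %d amplifiable copies, %d truth variants (seed %d)\n",
              object@totalAC, nrow(object@variants), object@seed))
})

setMethod("show", "LODResult", function(object) {
  cat(sprintf("dPCR limit of detection (alpha = %.2f, beta = %.2f)\n",
              object@alpha, object@beta))
  cat(sprintf("  false-positive rate/droplet: %.3g over %d droplets\n",
              object@fprLambda, as.integer(object@nDroplets)))
  cat(sprintf("  critical level: %d positive droplets\n", object@criticalLevel))
  cat(sprintf("  LOD: %.2f mutant copies/reaction (%.4f%% AF at wt lambda %.3g)\n",
              object@lodCopies, object@lodAfPercent, object@wtLambda))
})
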