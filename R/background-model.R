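# Background error calibration. SNV backgrounds come from a control cohort;
# indel backgrounds from the other samples of the same batch, leave-one-out,
# so a sample's true indel never masks itself.

# Per-library (control x replicate) (alt, depth) table for every position x
# substitution. Replicate libraries are the unit the caller models, so the
# background is fitted at the same level; pooling replicates would average
# away the within-sample overdispersion the null needs to carry.
.controlFractions <- function(tensor) {
  dt <- data.table::as.data.table(snvCounts(tensor))
  dt[, "depth" := dt$A + dt$C + dt$G + dt$T]
  long <- data.table::melt(dt, id.vars = c("sample", "replicate", "chrom",
                                           "pos", "ref", "depth"),
                           measure.vars = c("A", "C", "G", "T"),
                           variable.name = "alt", value.name = "alt_count",
                           variable.factor = FALSE)
  long[long$alt != long$ref, ]
}

#' Fit the SNV background error model from a control cohort
#'
#' For every (position, substitution), forms pseudocounted error fractions
#' `(alt + 0.5) / (depth + 1)` across the control replicate libraries and
#' fits a beta-binomial by method of moments: the mean is the average control
#' fraction and the intra-class correlation `rho` is solved from the excess
#' of the between-library variance over binomial sampling variance. Because
#' the per-locus moment estimate of `rho` is noisy with a small cohort, each
#' locus's estimate is floored at the panel-wide mean of the raw (unclamped)
#' estimates — errors at different positions share the same chemistry, and
#' the floor keeps the null conservative where the local estimate collapses
#' to zero by chance. Positions with fewer than 3 usable controls are flagged
#' `low_confidence`.
#'
#' @param controls an [AlleleCountTensor-class] over >= 3 control samples
#'   (replicate libraries are the fitting unit).
#' @param minDepth libraries below this depth at a position are skipped
#'   for that position (default 100).
#' @param pseudocount numeric(2), added to (alt, depth) of each library
#'   fraction; default `c(0.5, 1)` prevents zero-variance nulls at clean
#'   positions.
#' @param rhoFloor `"global"` (default) floors per-locus overdispersion at
#'   the panel-level estimate; `"none"` uses the raw clamped local estimates.
#' @return a [BackgroundModel-class].
#' @export
fitBackground <- function(controls, minDepth = 100, pseudocount = c(0.5, 1),
                          rhoFloor = c("global", "none")) {
  rhoFloor <- match.arg(rhoFloor)
  nCtrl <- length(unique(snvCounts(controls)$sample))
  if (nCtrl < 3) stop("need >= 3 control samples to fit a background")
  long <- .controlFractions(controls)
  long <- long[long$depth >= minDepth, ]
  long[, "p" := (long$alt_count + pseudocount[1]) / (long$depth + pseudocount[2])]
  fit <- long[, {
    m <- mean(p)
    nc <- length(unique(sample))
    rhoRaw <- NA_real_
    if (.N >= 2 && m > 0 && m < 1) {
      v <- stats::var(p)
      rhoRaw <- (v / (m * (1 - m)) - mean(1 / depth)) / mean((depth - 1) / depth)
    }
    list(mean = m, rho_raw = rhoRaw, n_controls = nc)
  }, by = c("chrom", "pos", "ref", "alt")]
  globalRho <- if (rhoFloor == "global")
    max(0, mean(fit$rho_raw, na.rm = TRUE)) else 0
  fit[, "rho" := pmin(pmax(fit$rho_raw, globalRho, 0, na.rm = TRUE), 0.99)]
  fit[, "rho_raw" := NULL]
  fit[, "flag" := ifelse(fit$n_controls < 3, "low_confidence", "")]
  snv <- as.data.frame(fit[order(fit$chrom, fit$pos, fit$alt), ])
  methods::new("BackgroundModel", snv = snv, indel = .emptyIndelBackground(),
               pseudocount = pseudocount)
}

.emptyIndelBackground <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             allele = character(), mean = numeric(), rho = numeric(),
             n_controls = integer(), batch = character(),
             exclude_sample = character(), flag = character(),
             stringsAsFactors = FALSE)
}

#' Indel background from the same batch, leave-one-out
#'
#' Estimates the background rate of an indel allele from the other samples of
#' the batch: the tested sample is excluded from its own background so a true
#' somatic indel cannot suppress itself. The rate uses the same pseudocount
#' policy as the SNV fit; with fewer than 4 batch samples the function stops
#' and instructs to fall back to the control cohort.
#'
#' @param batch an [AlleleCountTensor-class] holding all samples of a batch.
#' @param excludeSample sample to leave out (the one being tested), or `NULL`
#'   to produce entries for every sample in the batch.
#' @param locus optional list/data.frame with `chrom`, `pos`, `allele` to
#'   restrict to one indel allele; default: all observed indel alleles.
#' @param pseudocount numeric(2) as in [fitBackground()].
#' @param batchId provenance label stored on the entries.
#' @return data.frame of indel background entries (`chrom`, `pos`, `ref`,
#'   `allele`, `mean`, `rho`, `n_controls`, `batch`, `exclude_sample`,
#'   `flag`).
#' @export
batchIndelBackground <- function(batch, excludeSample = NULL, locus = NULL,
                                 pseudocount = c(0.5, 1), batchId = "batch1") {
  samples <- unique(snvCounts(batch)$sample)
  if (length(samples) < 4)
    stop("batch has fewer than 4 samples; fall back to the control cohort ",
         "for indel backgrounds")
  ind <- indelCounts(batch)
  if (is.null(locus)) {
    loci <- unique(ind[, c("chrom", "pos", "ref", "allele")])
  } else {
    loci <- as.data.frame(locus, stringsAsFactors = FALSE)
    if (!"ref" %in% colnames(loci)) loci$ref <- NA_character_
  }
  if (!nrow(loci)) return(.emptyIndelBackground())
  testedSamples <- if (is.null(excludeSample)) samples else excludeSample
  dt <- data.table::as.data.table(snvCounts(batch))
  depthBySample <- dt[, list(depth = sum(A + C + G + T)),
                      by = c("sample", "chrom", "pos")]
  out <- list()
  for (s in testedSamples) {
    others <- setdiff(samples, s)
    for (i in seq_len(nrow(loci))) {
      dsel <- depthBySample[depthBySample$sample %in% others &
                              depthBySample$chrom == loci$chrom[i] &
                              depthBySample$pos == loci$pos[i], ]
      isel <- ind[ind$sample %in% others & ind$chrom == loci$chrom[i] &
                    ind$pos == loci$pos[i] & ind$allele == loci$allele[i], ]
      totDepth <- sum(dsel$depth)
      totAlt <- sum(isel$count)
      rate <- (totAlt + pseudocount[1]) / (totDepth + pseudocount[2])
      # between-sample overdispersion, method of moments as in the SNV fit
      ps <- (vapply(others, function(o)
        sum(isel$count[isel$sample == o]), numeric(1)) + pseudocount[1]) /
        (vapply(others, function(o)
          sum(dsel$depth[dsel$sample == o]), numeric(1)) + pseudocount[2])
      d <- vapply(others, function(o)
        sum(dsel$depth[dsel$sample == o]), numeric(1))
      m <- mean(ps)
      rho <- 0
      if (length(ps) >= 2 && m > 0 && m < 1 && all(d > 0)) {
        v <- stats::var(ps)
        rho <- max(0, min((v / (m * (1 - m)) - mean(1 / d)) /
                            mean((d - 1) / d), 0.99))
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = loci$chrom[i], pos = loci$pos[i],
        ref = loci$ref[i], allele = loci$allele[i],
        mean = rate, rho = rho, n_controls = length(others),
        batch = batchId, exclude_sample = s,
        flag = if (length(others) < 3) "low_confidence" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Attach indel background entries to a model
#'
#' @param model a [BackgroundModel-class].
#' @param indelEntries data.frame from [batchIndelBackground()].
#' @return the updated model.
#' @export
setIndelBackground <- function(model, indelEntries) {
  model@indel <- indelEntries
  methods::validObject(model)
  model
}

#' Serialize / restore a background model as TSV
#'
#' Two tables are written: `<path>` with the SNV entries and
#' `<path>.indel` with the indel registry (if any), for audit and reuse
#' across runs.
#'
#' @param model a [BackgroundModel-class].
#' @param path TSV path.
#' @return `readBackground()` returns the model; `writeBackground()` the
#'   path, invisibly.
#' @export
writeBackground <- function(model, path) {
  utils::write.table(model@snv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(model@indel))
    utils::write.table(model@indel, paste0(path, ".indel"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBackground
#' @export
readBackground <- function(path) {
  snv <- utils::read.delim(path, stringsAsFactors = FALSE)
  snv$flag[is.na(snv$flag)] <- ""
  ipath <- paste0(path, ".indel")
  indel <- if (file.exists(ipath)) {
    x <- utils::read.delim(ipath, stringsAsFactors = FALSE)
    x$flag[is.na(x$flag)] <- ""
    x
  } else .emptyIndelBackground()
  methods::new("BackgroundModel", snv = snv, indel = indel)
}
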