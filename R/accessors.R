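# Accessor generics for the core containers.

#' Unit identifiers
#' @param x a SpikeSet or BinnedCounts.
#' @return character vector of unit ids.
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' Region labels per unit
#' @param x a SpikeSet or BinnedCounts.
#' @return character vector of region labels.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname unitIds
#' @export
setMethod("unitIds", "SpikeSet", function(x) x@unitIds)

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "SpikeSet", function(x) x@region)

#' @rdname unitIds
#' @export
setMethod("unitIds", "BinnedCounts", function(x) rownames(x))

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "BinnedCounts", function(x)
  SummarizedExperiment::rowData(x)$region)

#' Count matrix in analysis orientation (time bins by units)
#'
#' @param x a [BinnedCounts-class].
#' @return numeric matrix, T bins x N units, column names = unit ids.
#' @export
countsMatrix <- function(x) {
  stopifnot(is(x, "BinnedCounts"))
  t(SummarizedExperiment::assay(x, "counts"))
}

#' Bin start times of a BinnedCounts
#' @param x a [BinnedCounts-class].
#' @return numeric vector of bin start times (seconds).
#' @export
binTimes <- function(x) SummarizedExperiment::colData(x)$bin_start

#' Bin width of a BinnedCounts
#' @param x a [BinnedCounts-class].
#' @return bin width in seconds.
#' @export
binWidth <- function(x) S4Vectors::metadata(x)$bin_s

#' Was this BinnedCounts z-scored?
#' @param x a [BinnedCounts-class].
#' @return logical flag.
#' @export
isZscored <- function(x) isTRUE(S4Vectors::metadata(x)$zscored)

#' Units flagged as zero-variance at z-scoring time
#' @param x a [BinnedCounts-class].
#' @return character vector of unit ids (possibly empty).
#' @export
zeroVarUnits <- function(x) S4Vectors::metadata(x)$zero_var

#' Subset a BinnedCounts to a set of units, preserving order
#' @param x a [BinnedCounts-class].
#' @param ids unit ids to keep (in the order given).
#' @return a [BinnedCounts-class].
#' @export
selectUnits <- function(x, ids) {
  stopifnot(all(ids %in% unitIds(x)))
  x[match(ids, unitIds(x)), ]
}

#' Window count of a WindowSet
#' @param x a [WindowSet-class].
#' @return integer number of windows.
#' @export
windowCount <- function(x) length(x@start)

#' Window intervals as a data.frame
#' @param x a [WindowSet-class].
#' @return data.frame with columns start, stop, state, level.
#' @export
windowTable <- function(x)
  data.frame(start = x@start, stop = x@stop, state = x@state,
             level = x@level)

#' Time span of a synthetic session
#' @param x a [SyntheticSession-class].
#' @return numeric length-2 (start, end) in seconds.
#' @export
sessionSpan <- function(x) {
  p <- x@config@params
  c(0, p$n_epochs * p$epoch_duration_s)
}

#' Ground truth of a synthetic session
#' @param x a [SyntheticSession-class].
#' @return the [GroundTruth-class] component.
#' @export
groundTruth <- function(x) x@truth

#' Optimal rank stored in an RrrFit
#' @param x an [RrrFit-class].
#' @return integer optimal rank. See [optimalRank()] for the rule.
#' @export
fittedRank <- function(x) x@mHat

#' Cross-validated R^2 curve of an RrrFit
#' @param x an [RrrFit-class].
#' @return numeric vector: mean held-out R^2 per rank.
#' @export
rankCurve <- function(x) colMeans(x@r2)

#' Canonical correlations of a CcaFit
#' @param x a [CcaFit-class].
#' @param which "train" (full-data fit) or "heldout" (mean across CV folds).
#' @return numeric vector of correlations.
#' @export
canonicalCorrelations <- function(x, which = c("train", "heldout")) {
  which <- match.arg(which)
  if (which == "train") x@rhoTrain else x@rhoHeldout
}
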