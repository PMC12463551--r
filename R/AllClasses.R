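#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx ave coef cor fft lm median p.adjust
#'   pnorm predict quantile rbinom rnorm rpois runif sd setNames t.test var
#'   aov kruskal.test wilcox.test glm binomial gaussian AIC complete.cases
NULL

# ---------------------------------------------------------------------------
# Spike-train container
# ---------------------------------------------------------------------------

#' SpikeSet: spike times for a two-region ensemble
#'
#' Holds per-unit spike times (seconds) together with a unit identifier and a
#' region label (\code{"CA1"} or \code{"PFC"}) for every unit.
#'
#' @slot times list of numeric vectors, one per unit, sorted ascending.
#' @slot unitIds character vector of unit identifiers.
#' @slot region character vector of region labels, one per unit.
#' @exportClass SpikeSet
setClass("SpikeSet",
  representation(times = "list", unitIds = "character", region = "character"))

setValidity("SpikeSet", function(object) {
  n <- length(object@times)
  if (length(object@unitIds) != n) return("unitIds length must match times")
  if (length(object@region) != n) return("region length must match times")
  if (anyDuplicated(object@unitIds)) return("unitIds must be unique")
  for (tt in object@times) {
    if (!is.numeric(tt)) return("spike times must be numeric")
    if (is.unsorted(tt)) return("spike times must be sorted ascending")
  }
  if (!all(object@region %in% c("CA1", "PFC")))
    return("region labels must be 'CA1' or 'PFC'")
  TRUE
})

#' Construct a SpikeSet
#'
#' @param times list of numeric spike-time vectors (seconds), one per unit.
#' @param unitIds character unit identifiers; default \code{u1, u2, ...}.
#' @param region character region label per unit (\code{"CA1"}/\code{"PFC"}).
#' @return A [SpikeSet-class] object.
#' @export
SpikeSet <- function(times, unitIds = paste0("u", seq_along(times)), region) {
  times <- lapply(times, function(tt) sort(as.numeric(tt)))
  new("SpikeSet", times = times, unitIds = as.character(unitIds),
      region = as.character(region))
}

# ---------------------------------------------------------------------------
# Binned counts: a SummarizedExperiment with units as rows, time bins as cols
# ---------------------------------------------------------------------------

#' BinnedCounts: binned spike counts as a SummarizedExperiment
#'
#' Rows are units (with a \code{region} column in \code{rowData}), columns are
#' time bins (with \code{bin_start} in \code{colData}). Metadata records the
#' bin width, whether columns were z-scored, and which units had zero variance
#' at z-scoring time. Analysis code consumes the transposed \eqn{T \times N}
#' matrix via [countsMatrix()].
#'
#' @exportClass BinnedCounts
setClass("BinnedCounts", contains = "SummarizedExperiment")

setValidity("BinnedCounts", function(object) {
  md <- S4Vectors::metadata(object)
  if (is.null(md$bin_s) || md$bin_s <= 0) return("bin_s must be positive")
  if (!"region" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must contain a 'region' column")
  if (!"bin_start" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'bin_start' column")
  TRUE
})

newBinnedCounts <- function(mat_units_by_bins, bin_start, bin_s, unitIds,
                            region, zscored = FALSE, zero_var = NULL) {
  rownames(mat_units_by_bins) <- unitIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat_units_by_bins),
    rowData = S4Vectors::DataFrame(region = region, row.names = unitIds),
    colData = S4Vectors::DataFrame(bin_start = bin_start),
    metadata = list(bin_s = bin_s, zscored = zscored,
                    zero_var = zero_var %||% character(0)))
  new("BinnedCounts", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# LFP containers
# ---------------------------------------------------------------------------

#' LfpTrace: a single-region LFP trace
#'
#' @slot samples numeric vector of samples (reference-relative microvolts).
#' @slot fs sampling rate in Hz.
#' @slot region region label.
#' @slot t0 time of the first sample (seconds).
#' @exportClass LfpTrace
setClass("LfpTrace",
  representation(samples = "numeric", fs = "numeric", region = "character",
                 t0 = "numeric"))

setValidity("LfpTrace", function(object) {
  if (length(object@fs) != 1 || object@fs <= 0) return("fs must be > 0")
  if (any(!is.finite(object@samples))) return("samples must be finite")
  TRUE
})

#' Construct an LfpTrace
#' @param samples numeric samples.
#' @param fs sampling rate (Hz).
#' @param region region label.
#' @param t0 time of first sample (s).
#' @return An [LfpTrace-class].
#' @export
LfpTrace <- function(samples, fs, region = "CA1", t0 = 0)
  new("LfpTrace", samples = as.numeric(samples), fs = fs,
      region = region, t0 = t0)

#' BandEnvelope: band-filtered trace plus its amplitude envelope
#'
#' @slot band band name (e.g. "theta").
#' @slot passband numeric length-2 passband (Hz).
#' @slot filtered zero-phase band-filtered trace.
#' @slot envelope non-negative amplitude envelope (Hilbert magnitude, smoothed).
#' @slot fs sampling rate (Hz).
#' @slot t0 time of first sample (s).
#' @exportClass BandEnvelope
setClass("BandEnvelope",
  representation(band = "character", passband = "numeric", filtered = "numeric",
                 envelope = "numeric", fs = "numeric", t0 = "numeric"))

setValidity("BandEnvelope", function(object) {
  if (any(object@envelope < 0)) return("envelope must be non-negative")
  if (length(object@filtered) != length(object@envelope))
    return("filtered and envelope must have equal length")
  TRUE
})

# ---------------------------------------------------------------------------
# Window sets
# ---------------------------------------------------------------------------

#' WindowSet: equal-duration half-open state windows
#'
#' Intervals \code{[start, stop)} in seconds, sorted and pairwise disjoint,
#' all of one duration, labelled by the state series that generated them
#' (band or "speed") and the level (\code{"high"}/\code{"low"}).
#'
#' @slot start,stop numeric interval bounds (seconds).
#' @slot state state label.
#' @slot level \code{"high"} or \code{"low"}.
#' @slot matched logical: has count-balancing been applied.
#' @exportClass WindowSet
setClass("WindowSet",
  representation(start = "numeric", stop = "numeric", state = "character",
                 level = "character", matched = "logical"))

setValidity("WindowSet", function(object) {
  if (length(object@start) != length(object@stop))
    return("start/stop length mismatch")
  if (length(object@start)) {
    if (any(object@stop <= object@start)) return("windows must have stop > start")
    if (is.unsorted(object@start)) return("windows must be sorted by start")
    if (any(object@start[-1] < object@stop[-length(object@stop)]))
      return("windows must be pairwise disjoint")
    dur <- object@stop - object@start
    if (diff(range(dur)) > 1e-9) return("all windows must share one duration")
  }
  TRUE
})

#' Construct a WindowSet
#' @param start,stop numeric vectors of interval bounds (seconds).
#' @param state state label (band name or "speed").
#' @param level "high" or "low".
#' @param matched logical, has balancing been applied.
#' @return A [WindowSet-class].
#' @export
WindowSet <- function(start, stop, state = "state", level = "high",
                      matched = FALSE) {
  o <- order(start)
  new("WindowSet", start = as.numeric(start)[o], stop = as.numeric(stop)[o],
      state = state, level = level, matched = matched)
}

# ---------------------------------------------------------------------------
# Partitions
# ---------------------------------------------------------------------------

#' Partition: a mean-matched source/target unit split
#'
#' @slot source character source unit ids (CA1).
#' @slot target character target unit ids.
#' @slot targetRegion \code{"CA1"} or \code{"PFC"}.
#' @slot index repetition index.
#' @slot seed seed used for the random per-bin draws.
#' @exportClass Partition
setClass("Partition",
  representation(source = "character", target = "character",
                 targetRegion = "character", index = "integer",
                 seed = "integer"))

setValidity("Partition", function(object) {
  if (length(object@target) < 1) return("target must contain >= 1 unit")
  if (object@targetRegion == "CA1" &&
      length(intersect(object@source, object@target)))
    return("CA1 targets must be disjoint from sources")
  TRUE
})

# ---------------------------------------------------------------------------
# Reduced-rank regression fits
# ---------------------------------------------------------------------------

#' RrrFit: reduced-rank regression dimensionality/performance result
#'
#' @slot bOls full ordinary-least-squares coefficient matrix (p x q).
#' @slot v principal directions of the training predictions (q x mMax),
#'   orthonormal columns.
#' @slot r2 per-fold cross-validated R^2, folds x mMax.
#' @slot semFull standard error of the mean full-rank R^2 across folds.
#' @slot mHat optimal rank (one-standard-error rule).
#' @exportClass RrrFit
setClass("RrrFit",
  representation(bOls = "matrix", v = "matrix", r2 = "matrix",
                 semFull = "numeric", mHat = "integer"))

setValidity("RrrFit", function(object) {
  mMax <- ncol(object@r2)
  if (object@mHat < 1L || object@mHat > mMax) return("mHat out of range")
  g <- crossprod(object@v)
  if (max(abs(g - diag(ncol(object@v)))) > 1e-6)
    return("v columns must be orthonormal")
  TRUE
})

# ---------------------------------------------------------------------------
# CCA fits and variate series
# ---------------------------------------------------------------------------

#' CcaFit: cross-validated canonical correlation fit between two regions
#'
#' @slot a CA1 weight matrix (p x k).
#' @slot b PFC weight matrix (q x k).
#' @slot rhoTrain training canonical correlations (full-data fit), nonincreasing.
#' @slot rhoHeldout mean held-out canonical correlations across folds.
#' @slot k number of components.
#' @slot folds number of cross-validation folds.
#' @slot foldId fold assignment of each time bin.
#' @exportClass CcaFit
setClass("CcaFit",
  representation(a = "matrix", b = "matrix", rhoTrain = "numeric",
                 rhoHeldout = "numeric", k = "integer", folds = "integer",
                 foldId = "integer"))

setValidity("CcaFit", function(object) {
  if (ncol(object@a) != object@k || ncol(object@b) != object@k)
    return("weight matrices must have k columns")
  if (is.unsorted(rev(object@rhoTrain + 1e-9)))
    return("rhoTrain must be nonincreasing")
  if (any(object@rhoTrain < -1e-9 | object@rhoTrain > 1 + 1e-9))
    return("training correlations must lie in [0, 1]")
  TRUE
})

#' VariateSeries: canonical variate time series for both regions
#'
#' @slot u CA1 variates (T x k).
#' @slot v PFC variates (T x k).
#' @slot times bin start times (seconds).
#' @exportClass VariateSeries
setClass("VariateSeries",
  representation(u = "matrix", v = "matrix", times = "numeric"))

setValidity("VariateSeries", function(object) {
  if (!identical(dim(object@u), dim(object@v)))
    return("u and v must have identical dimensions")
  if (length(object@times) != nrow(object@u))
    return("times must match row count")
  TRUE
})

#' SharedLocalSeries: aligned/orthogonal decomposition of canonical variates
#'
#' \code{aligned = (U + V) / sqrt(2)} captures reciprocated (shared) activity;
#' \code{local = (U - V) / sqrt(2)} captures unreciprocated activity. The
#' transform is a per-component rotation, so row-wise squared norms are
#' conserved.
#'
#' @slot aligned shared activity (T x k).
#' @slot local unreciprocated activity (T x k).
#' @slot times bin start times (seconds).
#' @exportClass SharedLocalSeries
setClass("SharedLocalSeries",
  representation(aligned = "matrix", local = "matrix", times = "numeric"))

setValidity("SharedLocalSeries", function(object) {
  if (!identical(dim(object@aligned), dim(object@local)))
    return("aligned and local must have identical dimensions")
  TRUE
})

# ---------------------------------------------------------------------------
# Synthetic-session types
# ---------------------------------------------------------------------------

#' SynthConfig: configuration of the synthetic two-region session generator
#'
#' Defaults mirror the recorded-session structure the pipeline targets: eight
#' 15 min run epochs, 50 ms count bins, 1.5 kHz LFP, theta/ripple/delta
#' carriers at 8/180/2 Hz. Communication structure is planted as
#' \code{comm_rank} shared latents whose gain switches between
#' \code{comm_gain_high} (theta-high bins) and \code{comm_gain_low}.
#'
#' @slot params named list of generator parameters; see [synthConfig()].
#' @exportClass SynthConfig
setClass("SynthConfig", representation(params = "list"))

setValidity("SynthConfig", function(object) {
  p <- object@params
  for (f in c("n_ca1", "n_pfc", "n_epochs", "trials_per_epoch"))
    if (p[[f]] < 1) return(paste(f, "must be >= 1"))
  if (p$epoch_duration_s <= 0) return("epoch_duration_s must be > 0")
  if (p$bin_s <= 0) return("bin_s must be > 0")
  if (p$comm_rank > min(p$n_ca1, p$n_pfc))
    return("comm_rank must be <= min(n_ca1, n_pfc)")
  if (p$comm_gain_high < 0 || p$comm_gain_low < 0)
    return("gains must be >= 0")
  if (p$lfp_fs_hz < 2 * p$ripple_hz)
    return("lfp_fs_hz must exceed twice the ripple carrier (aliasing)")
  TRUE
})

#' GroundTruth: planted structure of a synthetic session
#'
#' @slot sharedLatents k x T shared latent series (post-behavior coupling).
#' @slot gate per-bin theta-state indicator ("high"/"low").
#' @slot thetaDrive continuous per-bin theta amplitude drive the gate is cut from.
#' @slot loadingsCa1,loadingsPfc unit loading matrices (units x (k + private)).
#' @slot privateCa1,privatePfc private latent series per region.
#' @slot behaviorLoadings named list echoing the planted behavior couplings.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(sharedLatents = "matrix", gate = "character",
                 thetaDrive = "numeric", loadingsCa1 = "matrix",
                 loadingsPfc = "matrix", privateCa1 = "matrix",
                 privatePfc = "matrix", behaviorLoadings = "list"))

setValidity("GroundTruth", function(object) {
  if (length(object@gate) != ncol(object@sharedLatents))
    return("gate length must equal latent time steps")
  if (!all(object@gate %in% c("high", "low")))
    return("gate values must be 'high' or 'low'")
  TRUE
})

#' SyntheticSession: a full generated session plus its ground truth
#'
#' @slot spikes a [SpikeSet-class].
#' @slot lfp named list of [LfpTrace-class], one per region.
#' @slot behavior behavior table (data.frame, 30 samples/s).
#' @slot truth a [GroundTruth-class].
#' @slot config the [SynthConfig-class] that produced the session.
#' @exportClass SyntheticSession
setClass("SyntheticSession",
  representation(spikes = "SpikeSet", lfp = "list", behavior = "data.frame",
                 truth = "GroundTruth", config = "SynthConfig"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SpikeSet", function(object) {
  cat("SpikeSet with", length(object@times), "units (",
      sum(object@region == "CA1"), "CA1,", sum(object@region == "PFC"),
      "PFC ),", sum(lengths(object@times)), "spikes\n")
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet '%s' (%s): %d windows of %.3f s%s\n", object@state,
              object@level, length(object@start),
              if (length(object@start)) object@stop[1] - object@start[1] else NA,
              if (object@matched) " [matched]" else ""))
})

setMethod("show", "RrrFit", function(object) {
  cat(sprintf("RrrFit: p=%d source units, q=%d targets, mHat=%d, cv R2(full)=%.3f\n",
              nrow(object@bOls), ncol(object@bOls), object@mHat,
              mean(object@r2[, ncol(object@r2)])))
})

setMethod("show", "CcaFit", function(object) {
  cat(sprintf("CcaFit: k=%d components, %d-fold CV\n", object@k, object@folds))
  cat("  train rho:  ", paste(sprintf("%.3f", utils::head(object@rhoTrain, 5)),
                              collapse = " "), "\n")
  cat("  heldout rho:", paste(sprintf("%.3f", utils::head(object@rhoHeldout, 5)),
                              collapse = " "), "\n")
})

setMethod("show", "SynthConfig", function(object) {
  p <- object@params
  cat(sprintf(paste0("SynthConfig: %d CA1 + %d PFC units, %d epochs x %.0f s, ",
                     "comm rank %d (gain %.2f/%.2f), seed %d\n"),
              p$n_ca1, p$n_pfc, p$n_epochs, p$epoch_duration_s, p$comm_rank,
              p$comm_gain_high, p$comm_gain_low, p$seed))
})

setMethod("show", "SyntheticSession", function(object) {
  cat("SyntheticSession spanning", sprintf("%.1f", sessionSpan(object)[2]),
      "s\n")
  show(object@config)
  show(object@spikes)
})
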