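# Preprocessing: spike binning, low-rate exclusion, z-scoring, and band
# filtering of LFP.

#' Bin spike times into counts
#'
#' Counts spikes in half-open bins \code{[t, t + bin_s)} anchored at the span
#' start; spikes outside the span are dropped.
#'
#' @param spikes a [SpikeSet-class].
#' @param bin_s bin width in seconds (default 0.05).
#' @param span numeric length-2 interval \code{c(start, end)}.
#' @return A [BinnedCounts-class] (units x bins, integer counts).
#' @export
binSpikes <- function(spikes, bin_s = 0.05, span) {
  if (span[2] <= span[1]) stop("inverted or empty span")
  assertScalar(bin_s, "bin_s", lower = 1e-12)
  nbin <- floor((span[2] - span[1]) / bin_s)
  breaks <- span[1] + (0:nbin) * bin_s
  n_units <- length(spikes@times)
  mat <- matrix(0L, n_units, nbin)
  for (i in seq_len(n_units)) {
    tt <- spikes@times[[i]]
    tt <- tt[tt >= span[1] & tt < span[1] + nbin * bin_s]
    if (length(tt)) {
      idx <- floor((tt - span[1]) / bin_s) + 1L
      tabu <- tabulate(idx, nbins = nbin)
      mat[i, ] <- tabu
    }
  }
  newBinnedCounts(mat, bin_start = breaks[-length(breaks)], bin_s = bin_s,
                  unitIds = spikes@unitIds, region = spikes@region)
}

#' Exclude units firing below 0.1 spikes/s
#'
#' Units whose mean rate over the binned span falls strictly below
#' \code{min_rate_hz} are removed; surviving unit order is preserved.
#'
#' @param counts an un-z-scored [BinnedCounts-class].
#' @param min_rate_hz exclusion threshold (default 0.1 Hz; a unit at exactly
#'   the threshold is retained).
#' @return A [BinnedCounts-class] with the surviving units.
#' @export
filterLowRateUnits <- function(counts, min_rate_hz = 0.1) {
  if (isZscored(counts)) stop("filterLowRateUnits expects raw counts")
  mat <- SummarizedExperiment::assay(counts, "counts")
  rate <- rowMeans(mat) / binWidth(counts)
  keep <- rate >= min_rate_hz * (1 - 1e-12)   # strict "below" excluded
  if (!any(keep)) stop("all units fall below the rate threshold")
  counts[keep, ]
}

#' Z-score binned counts per unit
#'
#' Column (unit) means and sds are computed over the masked bins, and the
#' whole series is standardized with them, so the masked region has mean 0
#' and sd 1 per unit. Zero-variance units are set to all-zero and recorded in
#' the metadata flag queried by [zeroVarUnits()].
#'
#' @param counts a [BinnedCounts-class].
#' @param bins_mask logical vector selecting the bins over which moments are
#'   computed (default: all bins). Must select at least 2 bins.
#' @return A z-scored [BinnedCounts-class].
#' @export
zscoreCounts <- function(counts, bins_mask = NULL) {
  mat <- SummarizedExperiment::assay(counts, "counts")
  if (is.null(bins_mask)) bins_mask <- rep(TRUE, ncol(mat))
  if (sum(bins_mask) < 2) stop("bins_mask must select at least 2 bins")
  mu <- rowMeans(mat[, bins_mask, drop = FALSE])
  sdv <- apply(mat[, bins_mask, drop = FALSE], 1, sd)
  zv <- sdv <= 0
  sdv[zv] <- 1
  z <- (mat - mu) / sdv
  z[zv, ] <- 0
  newBinnedCounts(z, bin_start = binTimes(counts), bin_s = binWidth(counts),
                  unitIds = unitIds(counts), region = regionLabels(counts),
                  zscored = TRUE, zero_var = unitIds(counts)[zv])
}

#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (zero-phase) 4th-order-per-pass Butterworth filtering.
#'
#' @param lfp an [LfpTrace-class] or numeric vector.
#' @param band numeric length-2 passband in Hz, inside \code{(0, fs/2)}.
#' @param fs sampling rate, required when \code{lfp} is a bare vector.
#' @param order filter order per pass (default 4).
#' @return numeric filtered trace, same length as the input.
#' @export
bandpassFilter <- function(lfp, band, fs = NULL, order = 4) {
  if (is(lfp, "LfpTrace")) { x <- lfp@samples; fs <- lfp@fs } else x <- lfp
  if (is.null(fs)) stop("fs required for a bare numeric trace")
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band edges must lie strictly inside (0, fs/2)")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Amplitude envelope of a band-filtered trace
#'
#' Envelope is the magnitude of the analytic signal, optionally smoothed with
#' a boxcar (default 100 ms).
#'
#' @param filtered numeric band-filtered trace.
#' @param fs sampling rate (Hz).
#' @param band band name for labelling.
#' @param passband numeric length-2 passband (Hz), for the record.
#' @param smooth_s boxcar smoothing width in seconds (0 disables).
#' @return A [BandEnvelope-class].
#' @export
bandEnvelope <- function(filtered, fs, band = "band",
                         passband = c(NA_real_, NA_real_), smooth_s = 0.1) {
  if (any(!is.finite(filtered))) stop("trace must be finite")
  env <- Mod(analyticSignal(filtered))
  if (smooth_s > 0) env <- pmax(boxcarSmooth(env, max(1, round(smooth_s * fs))), 0)
  new("BandEnvelope", band = band, passband = as.numeric(passband),
      filtered = as.numeric(filtered), envelope = env, fs = fs, t0 = 0)
}

#' Convenience: band envelope straight from an LfpTrace
#' @param lfp an [LfpTrace-class].
#' @param band numeric length-2 passband (Hz).
#' @param name band name.
#' @param smooth_s envelope smoothing (s).
#' @return A [BandEnvelope-class].
#' @export
lfpBandEnvelope <- function(lfp, band, name = "band", smooth_s = 0.1) {
  filt <- bandpassFilter(lfp, band)
  env <- bandEnvelope(filt, lfp@fs, band = name, passband = band,
                      smooth_s = smooth_s)
  env@t0 <- lfp@t0
  env
}
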