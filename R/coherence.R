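# Spectral interaction measures: multitaper coherence and the weighted phase
# lag index, per-animal normalization, learning-epoch trends, spatial binning,
# and power-vs-coherence statistics.

#' SpectralSeries: time- and frequency-resolved spectral values
#'
#' @slot freqs frequencies (Hz).
#' @slot times window centers (seconds); empty for aggregated measures.
#' @slot values time x frequency matrix of values.
#' @slot method method tag (\code{"multitaper"}, \code{"wpli"},
#'   \code{"mtpower"}).
#' @slot params taper/window parameters.
#' @exportClass SpectralSeries
setClass("SpectralSeries",
  representation(freqs = "numeric", times = "numeric", values = "matrix",
                 method = "character", params = "list"))

setValidity("SpectralSeries", function(object) {
  if (ncol(object@values) != length(object@freqs))
    return("values must have one column per frequency")
  if (object@method %in% c("multitaper", "wpli")) {
    v <- object@values[is.finite(object@values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      return("coherence/WPLI values must lie in [0, 1]")
  }
  TRUE
})

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Percival & Walden); cached per (n, nw, k).
.dpssCache <- new.env(parent = emptyenv())

dpssTapers <- function(n, nw = 3, k = 5) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpssCache[[key]])) return(.dpssCache[[key]])
  w <- nw / n
  tvec <- 0:(n - 1)
  dv <- ((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * w)
  ev <- tvec[-1] * (n - tvec[-1]) / 2
  A <- diag(dv)
  A[cbind(2:n, 1:(n - 1))] <- ev
  A[cbind(1:(n - 1), 2:n)] <- ev
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  for (j in seq_len(k)) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  .dpssCache[[key]] <- V
  V
}

# Windowed multitaper auto/cross spectra over non-overlapping windows.
mtSpectra <- function(x, y = NULL, fs, window_s = 1, nw = 3, n_tapers = 5) {
  nwin_len <- round(window_s * fs)
  n_win <- floor(length(x) / nwin_len)
  if (n_win < 1) stop("signal shorter than one window")
  tap <- dpssTapers(nwin_len, nw, n_tapers)
  nf <- floor(nwin_len / 2) + 1
  freqs <- (seq_len(nf) - 1) * fs / nwin_len
  sxx <- matrix(0, n_win, nf)
  syy <- if (!is.null(y)) matrix(0, n_win, nf) else NULL
  sxy <- if (!is.null(y)) matrix(0 + 0i, n_win, nf) else NULL
  for (wix in seq_len(n_win)) {
    idx <- ((wix - 1) * nwin_len + 1):(wix * nwin_len)
    xs <- x[idx]; ys <- if (!is.null(y)) y[idx] else NULL
    for (kk in seq_len(n_tapers)) {
      Xf <- fft(xs * tap[, kk])[seq_len(nf)]
      sxx[wix, ] <- sxx[wix, ] + Mod(Xf)^2
      if (!is.null(y)) {
        Yf <- fft(ys * tap[, kk])[seq_len(nf)]
        syy[wix, ] <- syy[wix, ] + Mod(Yf)^2
        sxy[wix, ] <- sxy[wix, ] + Xf * Conj(Yf)
      }
    }
  }
  list(freqs = freqs, times = (seq_len(n_win) - 0.5) * window_s,
       sxx = sxx, syy = syy, sxy = sxy)
}

#' Sliding-window multitaper coherence
#'
#' Magnitude-squared coherence per non-overlapping window, averaged across
#' DPSS tapers: \code{|sum_k S_xy|^2 / (sum_k S_xx sum_k S_yy)}. With
#' \code{n_tapers} tapers the expected coherence of independent noise is
#' approximately \code{1 / n_tapers} (the estimator's bias floor).
#'
#' @param x,y [LfpTrace-class] objects (equal sample rates and lengths) or
#'   numeric vectors with \code{fs} supplied.
#' @param window_s window length in seconds (default 1).
#' @param nw time-bandwidth product (default 3).
#' @param n_tapers number of tapers (default 5).
#' @param fs sample rate for bare vectors.
#' @return A [SpectralSeries-class] (method \code{"multitaper"}).
#' @export
multitaperCoherence <- function(x, y, window_s = 1, nw = 3, n_tapers = 5,
                                fs = NULL) {
  if (is(x, "LfpTrace")) { fs <- x@fs; x <- x@samples }
  if (is(y, "LfpTrace")) {
    if (!is.null(fs) && abs(y@fs - fs) > 1e-9) stop("unequal sample rates")
    fs <- y@fs; y <- y@samples
  }
  if (length(x) != length(y)) stop("unequal signal lengths")
  sp <- mtSpectra(x, y, fs, window_s, nw, n_tapers)
  coh <- Mod(sp$sxy)^2 / pmax(sp$sxx * sp$syy, .Machine$double.xmin)
  new("SpectralSeries", freqs = sp$freqs, times = sp$times,
      values = pmin(coh, 1), method = "multitaper",
      params = list(window_s = window_s, nw = nw, n_tapers = n_tapers,
                    fs = fs))
}

#' Multitaper power spectrogram
#'
#' @inheritParams multitaperCoherence
#' @return A [SpectralSeries-class] (method \code{"mtpower"}).
#' @export
multitaperPower <- function(x, window_s = 1, nw = 3, n_tapers = 5, fs = NULL) {
  if (is(x, "LfpTrace")) { fs <- x@fs; x <- x@samples }
  sp <- mtSpectra(x, NULL, fs, window_s, nw, n_tapers)
  new("SpectralSeries", freqs = sp$freqs, times = sp$times,
      values = sp$sxx / n_tapers, method = "mtpower",
      params = list(window_s = window_s, nw = nw, n_tapers = n_tapers,
                    fs = fs))
}

#' Weighted phase lag index
#'
#' \code{WPLI(f) = |E[Im S_xy]| / E[|Im S_xy|]} over windows, computed from
#' windowed multitaper cross-spectra restricted to \code{band}. Frequencies
#' whose imaginary cross-spectra are all zero are undefined and reported as
#' \code{NA}. The debiased (squared) estimator is available behind a flag.
#'
#' @inheritParams multitaperCoherence
#' @param band numeric length-2 frequency band (Hz), default theta 6-12.
#' @param debias use the debiased squared WPLI estimator (default FALSE).
#' @return A [SpectralSeries-class] (method \code{"wpli"}, one row).
#' @export
wpli <- function(x, y, band = c(6, 12), window_s = 1, nw = 3, n_tapers = 5,
                 fs = NULL, debias = FALSE) {
  if (is(x, "LfpTrace")) { fs <- x@fs; x <- x@samples }
  if (is(y, "LfpTrace")) { fs <- y@fs; y <- y@samples }
  if (length(x) != length(y)) stop("unequal signal lengths")
  sp <- mtSpectra(x, y, fs, window_s, nw, n_tapers)
  keep <- sp$freqs >= band[1] & sp$freqs <= band[2]
  im <- Im(sp$sxy[, keep, drop = FALSE])
  vals <- vapply(seq_len(ncol(im)), function(j) {
    ij <- im[, j]
    denom <- mean(abs(ij))
    if (denom == 0) return(NA_real_)
    if (debias) {
      num <- sum(ij)^2 - sum(ij^2)
      den <- sum(abs(ij))^2 - sum(ij^2)
      if (den == 0) NA_real_ else max(num / den, 0)
    } else abs(mean(ij)) / denom
  }, numeric(1))
  new("SpectralSeries", freqs = sp$freqs[keep], times = numeric(0),
      values = matrix(vals, 1), method = "wpli",
      params = list(window_s = window_s, nw = nw, n_tapers = n_tapers,
                    fs = fs, band = band, debias = debias))
}

#' Per-animal normalization of spectral values
#'
#' \code{"zscore"}: mean 0, sd 1 within animal and frequency band;
#' \code{"minmax"}: scaled to \code{[0, 1]} within animal and frequency over
#' the animal's full dataset. Constant groups are undefined under minmax and
#' flagged as \code{NA}.
#'
#' @param df data.frame with columns \code{animal}, \code{value}, and
#'   \code{band} (zscore) or \code{frequency} (minmax); a missing grouping
#'   column falls back to animal-only grouping.
#' @param method \code{"zscore"} or \code{"minmax"}.
#' @return \code{df} with a \code{normalized} column added.
#' @export
normalizeSpectral <- function(df, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  gcol <- if (method == "zscore") "band" else "frequency"
  grp <- if (gcol %in% names(df))
    interaction(df$animal, df[[gcol]], drop = TRUE) else factor(df$animal)
  df$normalized <- if (method == "zscore") {
    ave(df$value, grp, FUN = function(v)
      if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v))
  } else {
    ave(df$value, grp, FUN = function(v) {
      r <- range(v)
      if (diff(r) == 0) rep(NA_real_, length(v)) else (v - r[1]) / diff(r)
    })
  }
  df
}

#' Epoch-wise trend with balanced bootstrap confidence intervals
#'
#' Per epoch, the mean is estimated with every animal contributing equal
#' samples per bootstrap draw; percentile 95% CIs from \code{n_boot} draws.
#' The trend across the observed epoch means (each animal weighted equally)
#' is tested with [mannKendall()]; a one-way ANOVA across epochs is also
#' reported. Animals missing an epoch are excluded from that epoch with a
#' message.
#'
#' @param df data.frame with columns \code{animal}, \code{epoch},
#'   \code{value}.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @return list with \code{summary} (per-epoch mean and CI), \code{trend}
#'   ([testResult()]) and \code{anova_p}.
#' @export
epochTrend <- function(df, n_boot = 1000, seed = 1L) {
  epochs <- sort(unique(df$epoch))
  all_animals <- unique(df$animal)
  rows <- list(); means <- numeric(0)
  for (e in epochs) {
    sub <- df[df$epoch == e, ]
    have <- unique(sub$animal)
    if (length(have) < length(all_animals))
      message("epoch ", e, ": missing animal(s) ",
              paste(setdiff(all_animals, have), collapse = ", "))
    groups <- Filter(length, split(sub$value, sub$animal))
    bc <- bootstrapCi(groups, mean, n_boot,
                      seed = substreamSeed(seed, paste0("epoch", e)))
    m <- mean(vapply(groups, mean, numeric(1)))
    means <- c(means, m)
    rows[[length(rows) + 1]] <- data.frame(epoch = e, mean = m,
                                           lo = bc$ci[1], hi = bc$ci[2])
  }
  trend <- if (length(epochs) >= 4) mannKendall(means) else NULL
  anova_p <- if (length(epochs) > 1)
    summary(aov(value ~ factor(epoch), data = df))[[1]][["Pr(>F)"]][1]
  else NA_real_
  list(summary = do.call(rbind, rows), trend = trend, anova_p = anova_p)
}

#' Coherence binned over linearized position
#'
#' Spectral time centers are matched to the nearest behavior sample (within
#' half a window); values are z-scored and averaged per linear-distance bin,
#' split by trajectory direction and epoch, with bootstrap CIs over samples.
#'
#' @param times spectral window centers (seconds).
#' @param values one value per window (e.g. mean theta coherence).
#' @param behavior behavior table.
#' @param n_bins linear-distance bins (default 20).
#' @param window_s matching tolerance = \code{window_s / 2} (default 1).
#' @param n_boot bootstrap draws per bin (default 200).
#' @param seed integer seed.
#' @return data.frame with \code{direction, epoch, bin, n, mean, lo, hi}.
#' @export
spatialBinnedCoherence <- function(times, values, behavior, n_bins = 20,
                                   window_s = 1, n_boot = 200, seed = 1L) {
  idx <- findInterval(times, behavior$time)
  idx[idx == 0] <- 1
  ok <- abs(behavior$time[idx] - times) <= window_s / 2 + 1 / 30
  z <- if (sd(values) == 0) rep(0, length(values))
       else as.numeric(scale(values))
  lin <- behavior$lin_pos[idx]
  bin <- pmin(floor(lin * n_bins) + 1L, n_bins)
  dir_ <- behavior$direction[idx]
  ep <- behavior$epoch[idx]
  rows <- list()
  for (d in unique(dir_[ok])) for (e in sort(unique(ep[ok]))) {
    sel <- ok & dir_ == d & ep == e
    for (b in sort(unique(bin[sel]))) {
      v <- z[sel & bin == b]
      if (!length(v)) next
      bc <- bootstrapCi(list(v), mean, n_boot,
                        seed = substreamSeed(seed, paste(d, e, b)))
      rows[[length(rows) + 1]] <- data.frame(direction = d, epoch = e,
        bin = b, n = length(v), mean = mean(v), lo = bc$ci[1], hi = bc$ci[2])
    }
  }
  do.call(rbind, rows)
}

#' Power-power vs power-coherence statistics
#'
#' Per animal, correlates CA1 vs PFC theta power and CA1 theta power vs
#' CA1-PFC theta coherence; the paired correlations are compared across
#' animals with a Wilcoxon signed-rank test. Given per-animal spectra, peak
#' frequencies of CA1 power, PFC power and coherence are extracted and
#' compared with a Kruskal-Wallis test. With fewer than 3 animals only
#' descriptives are returned.
#'
#' @param df_time data.frame with \code{animal, ca1_power, pfc_power,
#'   coherence} (time-aligned samples).
#' @param df_spec optional data.frame with \code{animal, frequency,
#'   ca1_power, pfc_power, coherence} for peak extraction.
#' @return list with per-animal correlations, the signed-rank test, peak
#'   frequencies and the Kruskal-Wallis test (the tests NULL when skipped).
#' @export
powerCoherenceStats <- function(df_time, df_spec = NULL) {
  an <- unique(df_time$animal)
  r_pp <- vapply(an, function(a) {
    s <- df_time[df_time$animal == a, ]
    cor(s$ca1_power, s$pfc_power)
  }, numeric(1))
  r_pc <- vapply(an, function(a) {
    s <- df_time[df_time$animal == a, ]
    cor(s$ca1_power, s$coherence)
  }, numeric(1))
  wsr <- if (length(an) >= 3 && sd(r_pp - r_pc) > 0) {
    wt <- wilcox.test(r_pp, r_pc, paired = TRUE, exact = FALSE)
    testResult(unname(wt$statistic), wt$p.value, "Wilcoxon signed-rank",
               length(an))
  } else NULL
  peaks <- kw <- NULL
  if (!is.null(df_spec)) {
    peakOf <- function(a, col) {
      s <- df_spec[df_spec$animal == a, ]
      s$frequency[which.max(s[[col]])]
    }
    peaks <- data.frame(
      animal = an,
      ca1 = vapply(an, peakOf, numeric(1), col = "ca1_power"),
      pfc = vapply(an, peakOf, numeric(1), col = "pfc_power"),
      coherence = vapply(an, peakOf, numeric(1), col = "coherence"))
    if (length(an) >= 3) {
      k <- kruskal.test(list(peaks$ca1, peaks$pfc, peaks$coherence))
      kw <- testResult(unname(k$statistic), k$p.value, "Kruskal-Wallis",
                       3 * length(an))
    }
  }
  list(correlations = data.frame(animal = an, power_power = r_pp,
                                 power_coherence = r_pc),
       signed_rank = wsr, peaks = peaks, kruskal = kw)
}
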