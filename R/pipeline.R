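# One-command pipeline: session in, all stage outputs and a summary out.

#' Analysis configuration for the pipeline
#'
#' @param bin_s count bin width (s).
#' @param theta_band,ripple_band passbands (Hz).
#' @param window_s state window duration (s).
#' @param high_q,low_q state quantile thresholds.
#' @param n_partitions mean-matched partition repetitions.
#' @param folds cross-validation folds.
#' @param k_cca canonical components to fit.
#' @param decode_k components per feature class for decoding.
#' @param behaviors behaviors to decode.
#' @param n_distance_bins pseudopopulation distance bins.
#' @param seed master seed; every random stage derives a named substream.
#' @param stages character vector of stages to run, any of
#'   \code{c("rrr", "cca", "decode", "coherence", "manifold")}.
#' @return named list of class \code{AnalysisConfig}.
#' @export
analysisConfig <- function(bin_s = 0.05, theta_band = c(6, 12),
                           ripple_band = c(150, 250), window_s = 0.3,
                           high_q = 0.85, low_q = 0.15, n_partitions = 10,
                           folds = 5, k_cca = 10, decode_k = 10,
                           behaviors = c("lin_pos", "velocity"),
                           n_distance_bins = 50, seed = 1L,
                           stages = c("rrr", "cca", "decode", "coherence",
                                      "manifold")) {
  cfg <- as.list(environment())
  structure(cfg, class = "AnalysisConfig", hash = configHash(cfg))
}

# Order-stable structural checksum; changes iff any parameter changes.
configHash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full analysis pipeline on a session
#'
#' Stages run in dependency order: preprocessing (binning, low-rate
#' exclusion, z-scoring) always; then reduced-rank dimensionality over
#' theta-state windows, CCA with the shared/local decomposition, behavioral
#' decoding, LFP coherence, and manifold geometry, as toggled in the config.
#' A failed stage is recorded in \code{$errors} and the bundle keeps the
#' completed stages. Fully deterministic under (config, session).
#'
#' @param session a [SyntheticSession-class] (LFP-dependent stages are
#'   skipped when the session has no LFP).
#' @param config an [analysisConfig()].
#' @return list of class \code{ReportBundle}: stage outputs, \code{config}
#'   echo with its hash, and \code{errors}.
#' @export
runPipeline <- function(session, config = analysisConfig()) {
  out <- list(config = config, config_hash = attr(config, "hash"),
              errors = list())
  tryStage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      out$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) out[[name]] <<- res
    invisible(NULL)
  }
  span <- sessionSpan(session)
  counts_raw <- filterLowRateUnits(
    binSpikes(session@spikes, config$bin_s, span))
  counts <- zscoreCounts(counts_raw)
  out$preprocess <- list(n_units = length(unitIds(counts)),
                         n_bins = length(binTimes(counts)))

  has_lfp <- length(session@lfp) > 0
  theta_env <- NULL
  if (has_lfp)
    theta_env <- lfpBandEnvelope(session@lfp$CA1, config$theta_band, "theta")

  if ("rrr" %in% config$stages) tryStage("rrr", {
    state <- if (!is.null(theta_env)) theta_env else {
      drive <- session@truth@thetaDrive
      list(series = drive, fs = 1 / config$bin_s)
    }
    wsets <- if (is(state, "BandEnvelope"))
      thresholdWindows(state, window_s = config$window_s,
                       high_q = config$high_q, low_q = config$low_q)
    else thresholdWindows(state$series, fs = state$fs,
                          window_s = config$window_s,
                          high_q = config$high_q, low_q = config$low_q,
                          state_label = "theta")
    wsets <- pruneOverlaps(wsets)
    wsets <- balanceWindows(wsets, seed = substreamSeed(config$seed, "bal"))
    names(wsets) <- c("theta.high", "theta.low")
    parts <- generatePartitions(counts_raw, config$n_partitions,
                                seed = substreamSeed(config$seed, "part"))
    dp <- dimPerfTable(counts, parts, wsets, folds = config$folds,
                       seed = substreamSeed(config$seed, "rrr"))
    list(windows = wsets, dimperf = dp, contrast = stateContrast(dp))
  })

  sl <- NULL
  if (any(c("cca", "decode", "manifold") %in% config$stages)) tryStage("cca", {
    region <- regionLabels(counts)
    x <- counts[region == "CA1", ]; y <- counts[region == "PFC", ]
    k <- min(config$k_cca, sum(region == "CA1"), sum(region == "PFC"))
    fit <- fitCca(x, y, k = k, folds = config$folds)
    vs <- projectVariates(fit, x, y)
    sl <- alignedOrthogonal(vs)
    list(fit = fit, shared_local = sl)
  })

  if ("decode" %in% config$stages && !is.null(sl)) tryStage("decode", {
    feats <- buildFeatures(sl, k = min(config$decode_k, ncol(sl@aligned)))
    bt <- sl@times + config$bin_s / 2
    idx <- findInterval(bt, session@behavior$time); idx[idx == 0] <- 1
    beh <- session@behavior[idx, ]
    evaluateDecoding(feats, beh, config$behaviors, family = "gaussian",
                     seed = substreamSeed(config$seed, "decode"))
  })

  if ("coherence" %in% config$stages && has_lfp) tryStage("coherence", {
    coh <- multitaperCoherence(session@lfp$CA1, session@lfp$PFC)
    th <- coh@freqs >= config$theta_band[1] & coh@freqs <= config$theta_band[2]
    theta_coh <- rowMeans(coh@values[, th, drop = FALSE])
    idx <- findInterval(coh@times, session@behavior$time); idx[idx == 0] <- 1
    tr <- epochTrend(data.frame(animal = 1, epoch =
                                  session@behavior$epoch[idx],
                                value = theta_coh),
                     seed = substreamSeed(config$seed, "coh"))
    wp <- wpli(session@lfp$CA1, session@lfp$PFC, band = config$theta_band)
    list(coherence = coh, theta_coherence = theta_coh, trend = tr, wpli = wp)
  })

  if ("manifold" %in% config$stages) tryStage("manifold", {
    pp <- buildPseudopopulation(list(session),
                                n_distance_bins = config$n_distance_bins,
                                bin_s = config$bin_s)
    emb <- embedCca(pp)
    list(pseudopopulation = pp, embedding = emb,
         contrast = ringDistanceContrast(emb))
  })

  structure(out, class = "ReportBundle")
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle (config", x$config_hash, ")\n")
  cat("  stages:", paste(setdiff(names(x), c("config", "config_hash",
                                             "errors")), collapse = ", "),
      "\n")
  if (length(x$errors))
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
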