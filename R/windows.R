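# State windowing: high/low windows from any scalar state series, overlap
# pruning, count balancing, and per-window sample extraction.

#' Threshold a state series into high/low windows
#'
#' A high window \code{[t, t + window_s)} opens at each upward crossing of the
#' \code{high_q} quantile of the state's empirical distribution; low windows
#' open at downward crossings of the \code{low_q} quantile. Crossings falling
#' inside an already-open window are ignored. Quantile thresholds (rather than
#' fractions of the maximum) make the windowing robust to outliers.
#'
#' @param state numeric state series (band power, coherence, speed, ...) or a
#'   [BandEnvelope-class] (its envelope is used).
#' @param fs sampling rate of the state series (Hz); taken from the envelope
#'   when one is supplied.
#' @param high_q,low_q quantile thresholds (defaults 0.85 / 0.15).
#' @param window_s window duration in seconds (default 0.3).
#' @param state_label label stored in the resulting sets.
#' @return list with [WindowSet-class] elements \code{high} and \code{low}.
#' @export
thresholdWindows <- function(state, fs = NULL, high_q = 0.85, low_q = 0.15,
                             window_s = 0.3, state_label = NULL) {
  if (is(state, "BandEnvelope")) {
    if (is.null(state_label)) state_label <- state@band
    fs <- state@fs
    t0 <- state@t0
    state <- state@envelope
  } else t0 <- 0
  if (is.null(fs)) stop("fs required for a bare numeric state series")
  if (is.null(state_label)) state_label <- "state"
  if (!(low_q > 0 && low_q < high_q && high_q < 1))
    stop("need 0 < low_q < high_q < 1")
  thr_hi <- quantile(state, high_q, names = FALSE)
  thr_lo <- quantile(state, low_q, names = FALSE)
  if (diff(range(state)) == 0) {
    warning("degenerate state distribution: no windows")
    return(list(high = WindowSet(numeric(0), numeric(0), state_label, "high"),
                low = WindowSet(numeric(0), numeric(0), state_label, "low")))
  }
  crossTimes <- function(idx) t0 + (idx - 1) / fs
  openGreedy <- function(cand) {
    keep <- numeric(0); last_stop <- -Inf
    for (tc in cand) {
      if (tc >= last_stop) { keep <- c(keep, tc); last_stop <- tc + window_s }
    }
    keep
  }
  # "exceeded" / "fell below" the quantile: strict crossings
  up <- which(state[-1] > thr_hi & state[-length(state)] <= thr_hi) + 1L
  dn <- which(state[-1] < thr_lo & state[-length(state)] >= thr_lo) + 1L
  hi <- openGreedy(crossTimes(up))
  lo <- openGreedy(crossTimes(dn))
  list(high = WindowSet(hi, hi + window_s, state_label, "high"),
       low = WindowSet(lo, lo + window_s, state_label, "low"))
}

#' Remove windows that overlap between sets
#'
#' Any window intersecting a window of another set is deleted from both sets
#' (symmetric removal; within-set overlaps are impossible by construction).
#'
#' @param sets list of [WindowSet-class].
#' @return list of pruned [WindowSet-class], same order.
#' @export
pruneOverlaps <- function(sets) {
  if (!length(sets)) stop("need at least one WindowSet")
  if (length(sets) == 1) return(sets)
  drop <- lapply(sets, function(w) logical(windowCount(w)))
  for (i in seq_along(sets)[-length(sets)]) {
    for (j in (i + 1):length(sets)) {
      a <- sets[[i]]; b <- sets[[j]]
      if (!windowCount(a) || !windowCount(b)) next
      for (ia in seq_along(a@start)) {
        ov <- b@start < a@stop[ia] & b@stop > a@start[ia]
        if (any(ov)) {
          drop[[i]][ia] <- TRUE
          drop[[j]][ov] <- TRUE
        }
      }
    }
  }
  mapply(function(w, d) {
    WindowSet(w@start[!d], w@stop[!d], w@state, w@level, w@matched)
  }, sets, drop, SIMPLIFY = FALSE)
}

#' Balance window counts across sets
#'
#' Each set is subsampled to the global minimum count. Sampling is stratified
#' over \code{n_strata} equal time segments of the joint span so that retained
#' windows stay near-uniform across the recording; when a stratum holds fewer
#' windows than its quota the deficit spills over to the remaining windows,
#' drawn uniformly.
#'
#' @param sets list of non-empty [WindowSet-class].
#' @param n_strata number of equal time segments (default 10).
#' @param seed integer seed for the subsampling.
#' @return list of [WindowSet-class] with equal counts and \code{matched} set.
#' @export
balanceWindows <- function(sets, n_strata = 10, seed = 1L) {
  counts <- vapply(sets, windowCount, integer(1))
  if (any(counts == 0)) {
    lab <- vapply(sets, function(w) paste(w@state, w@level), character(1))
    stop("empty window set: ", paste(lab[counts == 0], collapse = ", "))
  }
  n_min <- min(counts)
  lo <- min(vapply(sets, function(w) w@start[1], numeric(1)))
  hi <- max(vapply(sets, function(w) w@stop[windowCount(w)], numeric(1)))
  edges <- seq(lo, hi, length.out = n_strata + 1)
  withSubstream(seed, "balance", {
    lapply(sets, function(w) {
      n <- windowCount(w)
      if (n == n_min) {
        return(WindowSet(w@start, w@stop, w@state, w@level, matched = TRUE))
      }
      stratum <- pmin(findInterval(w@start, edges, rightmost.closed = TRUE),
                      n_strata)
      # equal per-stratum quotas; the remainder goes to the earliest strata
      quota <- rep(floor(n_min / n_strata), n_strata)
      if (n_min %% n_strata) quota[seq_len(n_min %% n_strata)] <-
          quota[seq_len(n_min %% n_strata)] + 1L
      keep <- integer(0)
      for (s in seq_len(n_strata)) {
        idx <- which(stratum == s)
        keep <- c(keep, if (length(idx) <= quota[s]) idx else
          sort(sample(idx, quota[s])))
      }
      deficit <- n_min - length(keep)
      if (deficit > 0) {
        pool <- setdiff(seq_len(n), keep)
        keep <- c(keep, sort(sample(pool, deficit)))
      }
      keep <- sort(keep)
      WindowSet(w@start[keep], w@stop[keep], w@state, w@level, matched = TRUE)
    })
  })
}

#' Gather per-window sample rows from binned counts
#'
#' Extracts the \code{t_w = window_s / bin_s} consecutive bins covering each
#' window (starting at the bin containing the window onset) and stacks them
#' in time order. Windows extending past the binned data are dropped with a
#' warning.
#'
#' @param counts a [BinnedCounts-class].
#' @param ws a [WindowSet-class].
#' @return numeric matrix (\code{N * t_w} rows x units) with attribute
#'   \code{window} giving each row's window index.
#' @export
gatherSamples <- function(counts, ws) {
  bin_s <- binWidth(counts)
  bt <- binTimes(counts)
  mat <- countsMatrix(counts)
  if (!windowCount(ws)) {
    out <- mat[integer(0), , drop = FALSE]
    attr(out, "window") <- integer(0)
    return(out)
  }
  dur <- ws@stop[1] - ws@start[1]
  t_w <- dur / bin_s
  if (abs(t_w - round(t_w)) > 1e-6)
    stop("window duration must be divisible by the bin width")
  t_w <- as.integer(round(t_w))
  t0 <- bt[1]
  first <- floor((ws@start - t0) / bin_s) + 1L
  ok <- first >= 1L & (first + t_w - 1L) <= nrow(mat)
  if (any(!ok)) warning(sum(!ok), " window(s) extend past the data; dropped")
  first <- first[ok]
  rows <- as.vector(vapply(first, function(f) f:(f + t_w - 1L),
                           integer(t_w)))
  out <- mat[rows, , drop = FALSE]
  attr(out, "window") <- rep(seq_along(first), each = t_w)
  out
}
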