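# Reduced-rank regression: OLS, rank truncation via principal directions of
# the training predictions, cross-validated R^2(m), and the one-standard-error
# optimal rank, plus the high/low state contrast table.

#' Ordinary least squares coefficient matrix
#'
#' Solves the normal equations \eqn{B = (X^T X)^{-1} X^T Y}, falling back to
#' the Moore-Penrose
#' pseudoinverse when \eqn{X^T X} is ill-conditioned (condition number above
#' \code{cond_tol}).
#'
#' @param X T x p source matrix (columns centered upstream).
#' @param Y T x q target matrix.
#' @param cond_tol condition-number threshold for the pseudoinverse fallback
#'   (default 1e10).
#' @return p x q coefficient matrix.
#' @export
olsFit <- function(X, Y, cond_tol = 1e10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0) stop("no samples")
  G <- crossprod(X)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_tol) {
    pinv(X) %*% Y
  } else {
    solve(G, crossprod(X, Y))
  }
}

# Principal directions (right singular vectors) of the training predictions
# Yhat = X B; the rank-m predictor projects onto the leading m of them.
predictionDirections <- function(bOls, X_train) {
  yhat <- X_train %*% bOls
  svd(yhat, nu = 0)$v
}

#' Rank-truncate an OLS coefficient matrix
#'
#' \eqn{B_{RRR}(m) = B_{OLS} V_{1:m} V_{1:m}^T}, with \eqn{V} the principal
#' directions of the training predictions \code{X_train B_OLS}.
#'
#' @param bOls p x q OLS coefficients.
#' @param X_train T x p training sources used to form the predictions.
#' @param m target rank, \code{1 <= m <= q}.
#' @return p x q coefficient matrix of rank at most \code{m}.
#' @export
rrrTruncate <- function(bOls, X_train, m) {
  q <- ncol(bOls)
  if (m < 1 || m > q) stop("m must lie in [1, q]")
  V <- predictionDirections(bOls, X_train)
  Vm <- V[, seq_len(min(m, ncol(V))), drop = FALSE]
  bOls %*% Vm %*% t(Vm)
}

#' Cross-validated R^2(m) curve for reduced-rank regression
#'
#' Folds are formed over windows (never over bins within a window, which
#' would leak within-window autocorrelation). Per fold, \code{B_OLS} and the
#' prediction directions are estimated on the training windows and held-out
#' performance \code{R^2 = 1 - SSE/SST} is evaluated at every rank, with SST
#' taken around the training mean of \code{Y}.
#'
#' @param X T x p source matrix.
#' @param Y T x q target matrix.
#' @param window integer window index per row (default: every row its own
#'   window).
#' @param folds number of CV folds (default 5).
#' @param m_max maximum rank (default \code{ncol(Y)}).
#' @param seed seed for the fold assignment.
#' @return folds x m_max matrix of held-out R^2 values.
#' @export
cvRankCurve <- function(X, Y, window = seq_len(nrow(X)), folds = 5,
                        m_max = ncol(Y), seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  uw <- unique(window)
  if (length(uw) < folds) stop("fewer windows than folds")
  fold_of <- withSubstream(seed, "cvfolds",
    setNames(sample(rep(seq_len(folds), length.out = length(uw))), uw))
  r2 <- matrix(NA_real_, folds, m_max)
  for (f in seq_len(folds)) {
    test_w <- uw[fold_of[as.character(uw)] == f]
    te <- window %in% test_w
    Xtr <- X[!te, , drop = FALSE]; Ytr <- Y[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]; Yte <- Y[te, , drop = FALSE]
    mx <- colMeans(Xtr); my <- colMeans(Ytr)
    Xtr <- sweep(Xtr, 2, mx); Ytr <- sweep(Ytr, 2, my)
    Xte <- sweep(Xte, 2, mx); Yte <- sweep(Yte, 2, my)
    B <- olsFit(Xtr, Ytr)
    V <- predictionDirections(B, Xtr)
    P <- Xte %*% B %*% V                       # projections onto directions
    sst <- sum(Yte^2)                          # Yte already around train mean
    for (m in seq_len(m_max)) {
      Vm <- V[, seq_len(min(m, ncol(V))), drop = FALSE]
      pred <- P[, seq_len(min(m, ncol(V))), drop = FALSE] %*% t(Vm)
      r2[f, m] <- 1 - sum((Yte - pred)^2) / sst
    }
  }
  r2
}

#' Optimal rank by the one-standard-error rule
#'
#' The optimal rank is the smallest \code{m} whose mean held-out
#' \code{R^2(m)} lies within one standard error of the full-rank model's mean.
#'
#' @param r2 folds x m_max matrix from [cvRankCurve()].
#' @return integer optimal rank.
#' @export
optimalRank <- function(r2) {
  if (nrow(r2) < 2) stop("need >= 2 folds for a standard error")
  means <- colMeans(r2)
  m_max <- ncol(r2)
  sem_full <- sd(r2[, m_max]) / sqrt(nrow(r2))
  as.integer(which(means >= means[m_max] - sem_full)[1])
}

#' Fit a reduced-rank regression with cross-validated dimensionality
#'
#' Convenience wrapper: runs [cvRankCurve()], applies [optimalRank()], and
#' returns the full-data OLS fit and prediction directions.
#'
#' @inheritParams cvRankCurve
#' @return An [RrrFit-class].
#' @export
fitRrr <- function(X, Y, window = seq_len(nrow(X)), folds = 5,
                   m_max = ncol(Y), seed = 1L) {
  r2 <- cvRankCurve(X, Y, window, folds, m_max, seed)
  B <- olsFit(as.matrix(X), as.matrix(Y))
  V <- predictionDirections(B, as.matrix(X))[, seq_len(m_max), drop = FALSE]
  new("RrrFit", bOls = B, v = V, r2 = r2,
      semFull = sd(r2[, m_max]) / sqrt(nrow(r2)),
      mHat = optimalRank(r2))
}

#' Dimensionality/performance over partitions and window states
#'
#' Runs the windowed reduced-rank analysis for every partition under every
#' named window condition and returns one record per (partition, state,
#' target region): the optimal rank and the cross-validated performance at
#' the optimal rank and at full rank.
#'
#' @param counts a z-scored [BinnedCounts-class] spanning both regions.
#' @param partitions list of [Partition-class] from [generatePartitions()].
#' @param window_sets named list of [WindowSet-class]; names should encode
#'   state and level, e.g. \code{"theta.high"}.
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return data.frame with columns \code{partition, target, state, level,
#'   m_hat, r2_opt, r2_full}.
#' @export
dimPerfTable <- function(counts, partitions, window_sets, folds = 5,
                         seed = 1L) {
  stopifnot(length(names(window_sets)) == length(window_sets))
  recs <- list()
  samples <- lapply(window_sets, function(ws) gatherSamples(counts, ws))
  for (pi in seq_along(partitions)) {
    pt <- partitions[[pi]]
    for (wn in names(window_sets)) {
      S <- samples[[wn]]
      if (!nrow(S)) next
      X <- S[, pt@source, drop = FALSE]
      Y <- S[, pt@target, drop = FALSE]
      wid <- attr(S, "window")
      r2 <- cvRankCurve(X, Y, wid, folds = folds, seed = seed)
      mh <- optimalRank(r2)
      means <- colMeans(r2)
      lv <- strsplit(wn, ".", fixed = TRUE)[[1]]
      recs[[length(recs) + 1]] <- data.frame(
        partition = pt@index, target = pt@targetRegion,
        state = lv[1], level = if (length(lv) > 1) lv[2] else NA_character_,
        m_hat = mh, r2_opt = means[mh], r2_full = means[length(means)])
    }
  }
  do.call(rbind, recs)
}

#' High/low state contrast statistics
#'
#' Pairs high and low records per (partition, state, target), reports means
#' with SEM, paired high-low differences, t-tests across partitions, and
#' Benjamini-Hochberg adjusted decisions.
#'
#' @param dimperf data.frame from [dimPerfTable()].
#' @param q FDR level for the adjusted decisions (default 0.05).
#' @return data.frame with one row per (state, target) contrast.
#' @export
stateContrast <- function(dimperf, q = 0.05) {
  keys <- unique(dimperf[, c("state", "target")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    st <- keys$state[i]; tg <- keys$target[i]
    hi <- dimperf[dimperf$state == st & dimperf$target == tg &
                    dimperf$level == "high", ]
    lo <- dimperf[dimperf$state == st & dimperf$target == tg &
                    dimperf$level == "low", ]
    common <- intersect(hi$partition, lo$partition)
    if (length(common) < 2) { message("skipping ", st, "/", tg,
                                      ": missing pairs"); next }
    hi <- hi[match(common, hi$partition), ]
    lo <- lo[match(common, lo$partition), ]
    d_m <- hi$m_hat - lo$m_hat
    d_r2 <- hi$r2_opt - lo$r2_opt
    sem <- function(x) sd(x) / sqrt(length(x))
    tm <- if (sd(d_m) > 0) t.test(hi$m_hat, lo$m_hat)$p.value else 1
    tr <- if (sd(d_r2) > 0) t.test(hi$r2_opt, lo$r2_opt)$p.value else 1
    rows[[length(rows) + 1]] <- data.frame(
      state = st, target = tg, n_pairs = length(common),
      m_high = mean(hi$m_hat), m_low = mean(lo$m_hat),
      m_diff = mean(d_m), m_diff_sem = sem(d_m), p_m = tm,
      r2_high = mean(hi$r2_opt), r2_low = mean(lo$r2_opt),
      r2_diff = mean(d_r2), r2_diff_sem = sem(d_r2), p_r2 = tr)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$q_m <- p.adjust(out$p_m, method = "BH")
    out$q_r2 <- p.adjust(out$p_r2, method = "BH")
    out$sig_m <- out$q_m <= q
    out$sig_r2 <- out$q_r2 <= q
  }
  out
}
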