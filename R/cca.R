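# Canonical correlation between regions, cross-validated, with the
# aligned/orthogonal (shared/local) decomposition and spatial summaries.

# Core CCA: SVD of the whitened cross-covariance, with a small ridge on the
# within-region covariances (scaled by their mean diagonal) for rank safety.
ccaCore <- function(X, Y, k, lambda = 1e-8) {
  n <- nrow(X)
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  Cxx <- crossprod(X) / (n - 1)
  Cyy <- crossprod(Y) / (n - 1)
  Cxy <- crossprod(X, Y) / (n - 1)
  Wx <- invSqrtm(Cxx, lambda)
  Wy <- invSqrtm(Cyy, lambda)
  s <- svd(Wx %*% Cxy %*% Wy)
  A <- Wx %*% s$u[, seq_len(k), drop = FALSE]
  B <- Wy %*% s$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude CA1 loading positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(A[, j]))
    if (A[i_max, j] < 0) { A[, j] <- -A[, j]; B[, j] <- -B[, j] }
  }
  list(a = A, b = B, rho = pmin(s$d[seq_len(k)], 1))
}

#' Fit a cross-validated CCA between two populations
#'
#' Canonical weights are the whitened-cross-covariance SVD solution with a
#' trace-scaled ridge \code{lambda} on each within-region covariance. Held-out
#' canonical correlations are estimated by refitting on each training split
#' (contiguous time blocks, to respect autocorrelation) and correlating the
#' projected held-out data; the reported weights and training correlations
#' come from a final full-data fit. Signs are fixed so each training
#' correlation is non-negative and the largest-magnitude CA1 loading per
#' component is positive.
#'
#' @param x_ca1,y_pfc z-scored [BinnedCounts-class] (or bare T x p matrices)
#'   for the two regions, on a common bin grid.
#' @param k number of components; must not exceed \code{min(p, q)}.
#' @param folds CV folds (default 5).
#' @param lambda ridge scale (default 1e-8).
#' @return A [CcaFit-class].
#' @export
fitCca <- function(x_ca1, y_pfc, k = NULL, folds = 5, lambda = 1e-8) {
  X <- if (is(x_ca1, "BinnedCounts")) countsMatrix(x_ca1) else as.matrix(x_ca1)
  Y <- if (is(y_pfc, "BinnedCounts")) countsMatrix(y_pfc) else as.matrix(y_pfc)
  if (nrow(X) != nrow(Y)) stop("regions must share the bin grid")
  p <- ncol(X); q <- ncol(Y)
  if (is.null(k)) k <- min(p, q)
  if (k > min(p, q)) stop("k must not exceed min(p, q)")
  fold_id <- as.integer(cut(seq_len(nrow(X)), folds, labels = FALSE))
  rho_cv <- matrix(NA_real_, folds, k)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    fit <- ccaCore(X[!te, , drop = FALSE], Y[!te, , drop = FALSE], k, lambda)
    U <- X[te, , drop = FALSE] %*% fit$a
    V <- Y[te, , drop = FALSE] %*% fit$b
    rho_cv[f, ] <- vapply(seq_len(k), function(j) {
      if (sd(U[, j]) == 0 || sd(V[, j]) == 0) 0 else cor(U[, j], V[, j])
    }, numeric(1))
  }
  full <- ccaCore(X, Y, k, lambda)
  new("CcaFit", a = full$a, b = full$b, rhoTrain = full$rho,
      rhoHeldout = colMeans(rho_cv), k = as.integer(k),
      folds = as.integer(folds), foldId = fold_id)
}

#' Project data onto fitted canonical weights
#'
#' \code{U = X A}, \code{V = Y B}, evaluated at every bin: a continuous
#' temporal readout of communication-subspace activity, with no windowing.
#'
#' @param fit a [CcaFit-class].
#' @param x_ca1,y_pfc data matching the populations the fit was trained on
#'   ([BinnedCounts-class] or matrices).
#' @return A [VariateSeries-class].
#' @export
projectVariates <- function(fit, x_ca1, y_pfc) {
  tms <- if (is(x_ca1, "BinnedCounts")) binTimes(x_ca1) else
    seq_len(if (is.matrix(x_ca1)) nrow(x_ca1) else length(x_ca1))
  X <- if (is(x_ca1, "BinnedCounts")) countsMatrix(x_ca1) else as.matrix(x_ca1)
  Y <- if (is(y_pfc, "BinnedCounts")) countsMatrix(y_pfc) else as.matrix(y_pfc)
  if (ncol(X) != nrow(fit@a) || ncol(Y) != nrow(fit@b))
    stop("unit count mismatch with the fitted weights")
  new("VariateSeries", u = X %*% fit@a, v = Y %*% fit@b,
      times = as.numeric(tms))
}

#' Aligned/orthogonal (shared/local) decomposition
#'
#' Rotates each canonical pair onto the unity line:
#' \code{aligned = (U + V) / sqrt(2)} (reciprocated activity) and
#' \code{local = (U - V) / sqrt(2)} (unreciprocated activity). The rotation
#' is an isometry: per-row squared norms are conserved.
#'
#' @param vs a [VariateSeries-class].
#' @return A [SharedLocalSeries-class].
#' @export
alignedOrthogonal <- function(vs) {
  new("SharedLocalSeries", aligned = (vs@u + vs@v) / sqrt(2),
      local = (vs@u - vs@v) / sqrt(2), times = vs@times)
}

#' Repeatability of aligned activity across trajectories
#'
#' Each trajectory's aligned activity is averaged into \code{n_pos_bins}
#' linearized-position bins (missing bins linearly interpolated), giving one
#' position-profile vector per trajectory and component. Cosine similarities
#' between profile pairs are categorized as \code{pure_match} (a trajectory
#' split-half against itself), \code{same_type} (different trajectories of
#' one type) or \code{different_type}.
#'
#' @param sl a [SharedLocalSeries-class].
#' @param behavior behavior table aligned in time (nearest sample).
#' @param n_pos_bins position bins per trajectory (default 100).
#' @param n_components components to use (default 10, capped at available).
#' @param min_bins trajectories occupying fewer bins are dropped with a
#'   warning (default 10).
#' @return data.frame with columns \code{component, category, cosine}.
#' @export
trajectoryRepeatability <- function(sl, behavior, n_pos_bins = 100,
                                    n_components = 10, min_bins = 10) {
  n_components <- min(n_components, ncol(sl@aligned))
  beh_idx <- findInterval(sl@times, behavior$time)
  beh_idx[beh_idx == 0] <- 1
  lin <- behavior$lin_pos[beh_idx]
  trial <- behavior$trial[beh_idx]
  ttype <- behavior$traj_type[beh_idx]
  bin <- pmin(floor(lin * n_pos_bins) + 1L, n_pos_bins)

  profileOf <- function(rows, comp) {
    m <- tapply(sl@aligned[rows, comp], bin[rows], mean)
    v <- rep(NA_real_, n_pos_bins)
    v[as.integer(names(m))] <- m
    if (sum(!is.na(v)) < min_bins) return(NULL)
    if (anyNA(v)) v <- approx(which(!is.na(v)), v[!is.na(v)],
                              xout = seq_len(n_pos_bins), rule = 2)$y
    v
  }
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

  trials <- unique(trial)
  type_of <- vapply(trials, function(tr) as.character(ttype[trial == tr][1]),
                    character(1))
  out <- list()
  for (comp in seq_len(n_components)) {
    profs <- list(); kept <- character(0)
    for (tr in trials) {
      pv <- profileOf(which(trial == tr), comp)
      if (is.null(pv)) next
      profs[[as.character(tr)]] <- pv
      kept <- c(kept, as.character(tr))
    }
    if (length(kept) < length(trials) && comp == 1)
      warning(length(trials) - length(kept),
              " trajectories with too few occupied bins dropped")
    # pure match: split-half (odd/even samples) of the same trajectory
    for (tr in kept) {
      rows <- which(trial == as.integer(tr))
      a <- profileOf(rows[seq_along(rows) %% 2 == 1], comp)
      b <- profileOf(rows[seq_along(rows) %% 2 == 0], comp)
      if (!is.null(a) && !is.null(b))
        out[[length(out) + 1]] <- data.frame(component = comp,
          category = "pure_match", cosine = cosine(a, b))
    }
    if (length(kept) > 1) {
      cmb <- utils::combn(kept, 2)
      for (ci in seq_len(ncol(cmb))) {
        t1 <- cmb[1, ci]; t2 <- cmb[2, ci]
        cat_ <- if (type_of[match(as.integer(t1), trials)] ==
                    type_of[match(as.integer(t2), trials)])
          "same_type" else "different_type"
        out[[length(out) + 1]] <- data.frame(component = comp,
          category = cat_, cosine = cosine(profs[[t1]], profs[[t2]]))
      }
    }
  }
  do.call(rbind, out)
}

#' Spatial maps of aligned-component activity
#'
#' Mean aligned activity per 2-D spatial bin, z-scored over occupied bins;
#' bins with occupancy below \code{min_occupancy} samples are masked (NA).
#'
#' @param sl a [SharedLocalSeries-class].
#' @param behavior behavior table with \code{x}, \code{y}.
#' @param grid number of bins per spatial axis (default 20).
#' @param n_components components to map (default 3).
#' @param min_occupancy minimum samples per bin (default 5).
#' @return list of \code{grid x grid} matrices, one per component, plus an
#'   \code{occupancy} matrix.
#' @export
spatialComponentMap <- function(sl, behavior, grid = 20, n_components = 3,
                                min_occupancy = 5) {
  n_components <- min(n_components, ncol(sl@aligned))
  beh_idx <- findInterval(sl@times, behavior$time)
  beh_idx[beh_idx == 0] <- 1
  gx <- pmin(floor((behavior$x[beh_idx] - min(behavior$x)) /
                     (diff(range(behavior$x)) + 1e-9) * grid) + 1L, grid)
  gy <- pmin(floor((behavior$y[beh_idx] - min(behavior$y)) /
                     (diff(range(behavior$y)) + 1e-9) * grid) + 1L, grid)
  cell <- (gy - 1L) * grid + gx
  occ <- matrix(tabulate(cell, grid * grid), grid, grid)
  maps <- lapply(seq_len(n_components), function(comp) {
    s <- tapply(sl@aligned[, comp], cell, mean)
    m <- matrix(NA_real_, grid, grid)
    m[as.integer(names(s))] <- s
    m[occ < min_occupancy] <- NA
    mu <- mean(m, na.rm = TRUE); sdv <- sd(m[!is.na(m)])
    if (is.na(sdv) || sdv == 0) m[!is.na(m)] <- 0 else m <- (m - mu) / sdv
    m
  })
  names(maps) <- paste0("component", seq_len(n_components))
  maps$occupancy <- occ
  maps
}
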