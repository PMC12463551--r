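# Behavior-binned pseudopopulation, super-animal CCA embedding, and the
# ring-separation distance contrast.

#' Pseudopopulation: behavior-state by neuron mean-rate matrix
#'
#' @slot rates states x neurons matrix of mean firing rates (Hz).
#' @slot states data.frame of row labels (direction, turn, distance bin).
#' @slot columns data.frame of column provenance (animal, unit, region).
#' @exportClass Pseudopopulation
setClass("Pseudopopulation",
  representation(rates = "matrix", states = "data.frame",
                 columns = "data.frame"))

setValidity("Pseudopopulation", function(object) {
  if (nrow(object@rates) != nrow(object@states)) return("state rows mismatch")
  if (ncol(object@rates) != nrow(object@columns)) return("column mismatch")
  if (anyDuplicated(object@states)) return("state labels must be unique")
  TRUE
})

#' ManifoldEmbedding: per-state coordinates in the top shared components
#'
#' @slot aligned states x k aligned (shared) coordinates.
#' @slot local states x k local coordinates.
#' @slot states data.frame of state labels, aligned 1:1 with rows.
#' @exportClass ManifoldEmbedding
setClass("ManifoldEmbedding",
  representation(aligned = "matrix", local = "matrix", states = "data.frame"))

#' Build a behavior-binned pseudopopulation across sessions
#'
#' For every behavioral state (trajectory direction x turn x linear-distance
#' bin) the mean firing rate of each neuron is computed from 50 ms binned
#' counts; neurons are concatenated across sessions/animals into a
#' super-animal matrix. States a session never occupied are filled by linear
#' interpolation along distance within the trajectory type (with a message),
#' keeping rows aligned across animals.
#'
#' @param sessions list of [SyntheticSession-class] (or lists with elements
#'   \code{counts} -- a raw [BinnedCounts-class] -- and \code{behavior}).
#' @param n_distance_bins linear-distance bins (default 100).
#' @param bin_s count bin width when binning from spikes (default 0.05).
#' @return A [Pseudopopulation-class].
#' @export
buildPseudopopulation <- function(sessions, n_distance_bins = 100,
                                  bin_s = 0.05) {
  states <- expand.grid(direction = c("out", "in"), turn = c("L", "R"),
                        dbin = seq_len(n_distance_bins),
                        stringsAsFactors = FALSE)
  states <- states[order(states$direction, states$turn, states$dbin), ]
  rownames(states) <- NULL
  blocks <- list(); cols <- list()
  for (si in seq_along(sessions)) {
    ss <- sessions[[si]]
    if (is(ss, "SyntheticSession")) {
      counts <- binSpikes(ss@spikes, bin_s, sessionSpan(ss))
      behavior <- ss@behavior
    } else { counts <- ss$counts; behavior <- ss$behavior }
    mat <- countsMatrix(counts) / binWidth(counts)   # rates, T x N
    bt <- binTimes(counts) + binWidth(counts) / 2
    idx <- findInterval(bt, behavior$time); idx[idx == 0] <- 1
    dbin <- pmin(floor(behavior$lin_pos[idx] * n_distance_bins) + 1L,
                 n_distance_bins)
    key <- paste(behavior$direction[idx], behavior$turn[idx], dbin)
    skey <- paste(states$direction, states$turn, states$dbin)
    block <- matrix(NA_real_, nrow(states), ncol(mat))
    for (j in seq_len(ncol(mat))) {
      m <- tapply(mat[, j], key, mean)
      block[match(names(m), skey), j] <- m
    }
    # interpolate unoccupied states along distance within trajectory type
    n_miss <- 0
    for (d in c("out", "in")) for (tu in c("L", "R")) {
      rows <- which(states$direction == d & states$turn == tu)
      for (j in seq_len(ncol(block))) {
        v <- block[rows, j]
        if (anyNA(v)) {
          n_miss <- n_miss + sum(is.na(v))
          if (all(is.na(v))) v <- rep(0, length(v))
          else v <- approx(which(!is.na(v)), v[!is.na(v)],
                           xout = seq_along(v), rule = 2)$y
          block[rows, j] <- v
        }
      }
    }
    if (n_miss > 0)
      message("session ", si, ": ", n_miss,
              " unoccupied state cells interpolated along distance")
    blocks[[si]] <- block
    cols[[si]] <- data.frame(animal = si, unit = unitIds(counts),
                             region = regionLabels(counts))
  }
  new("Pseudopopulation", rates = do.call(cbind, blocks), states = states,
      columns = do.call(rbind, cols))
}

#' Embed a pseudopopulation with super-animal CCA
#'
#' Columns (neurons) are z-scored across states, the CA1 and PFC blocks are
#' entered into a regularized CCA over states, and each state is embedded in
#' the top-\code{k} aligned components; local coordinates are returned for
#' the shared-vs-local geometry contrast.
#'
#' @param pp a [Pseudopopulation-class].
#' @param k embedding components (default 3).
#' @param lambda covariance ridge scale (default 1e-4; states typically
#'   number few relative to neurons).
#' @return A [ManifoldEmbedding-class].
#' @export
embedCca <- function(pp, k = 3, lambda = 1e-4) {
  ca1 <- which(pp@columns$region == "CA1")
  pfc <- which(pp@columns$region == "PFC")
  if (!length(ca1) || !length(pfc)) stop("both region blocks required")
  if (min(length(ca1), length(pfc)) < k)
    stop("fewer than ", k, " components available")
  zs <- function(m) {
    sdv <- apply(m, 2, sd); sdv[sdv == 0] <- 1
    sweep(sweep(m, 2, colMeans(m)), 2, sdv, "/")
  }
  X <- zs(pp@rates[, ca1, drop = FALSE])
  Y <- zs(pp@rates[, pfc, drop = FALSE])
  fit <- ccaCore(X, Y, k, lambda)
  U <- X %*% fit$a; V <- Y %*% fit$b
  new("ManifoldEmbedding", aligned = (U + V) / sqrt(2),
      local = (U - V) / sqrt(2), states = pp@states)
}

#' Ring-separation contrast of a manifold embedding
#'
#' Each trajectory type (direction x turn) traces one manifold. Distances
#' between states at the same linear-distance bin on different manifolds
#' ("between") are compared with distances between consecutive distance bins
#' along the same manifold ("within", the local step size of a ring) using a
#' Wilcoxon rank-sum test; the difference of means comes with a 95% CI.
#'
#' @param emb a [ManifoldEmbedding-class].
#' @param use \code{"aligned"} (default) or \code{"local"} coordinates.
#' @return list with \code{within}, \code{between} (distance samples), the
#'   rank-sum [testResult()], \code{mean_diff} and \code{ci}.
#' @export
ringDistanceContrast <- function(emb, use = c("aligned", "local")) {
  use <- match.arg(use)
  coords <- slot(emb, use)
  st <- emb@states
  manif <- interaction(st$direction, st$turn, drop = TRUE)
  if (nlevels(manif) < 2) stop("need >= 2 trajectory manifolds")
  within <- c(); between <- c()
  for (m in levels(manif)) {
    rows <- which(manif == m)
    rows <- rows[order(st$dbin[rows])]
    if (length(rows) > 1) {
      d <- sqrt(rowSums((coords[rows[-1], , drop = FALSE] -
                           coords[rows[-length(rows)], , drop = FALSE])^2))
      within <- c(within, d)
    }
  }
  lv <- levels(manif)
  for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1):length(lv)) {
    ri <- which(manif == lv[i]); rj <- which(manif == lv[j])
    shared <- intersect(st$dbin[ri], st$dbin[rj])
    ii <- ri[match(shared, st$dbin[ri])]
    jj <- rj[match(shared, st$dbin[rj])]
    between <- c(between, sqrt(rowSums((coords[ii, , drop = FALSE] -
                                          coords[jj, , drop = FALSE])^2)))
  }
  wt <- suppressWarnings(wilcox.test(between, within, exact = FALSE))
  md <- mean(between) - mean(within)
  ci <- tryCatch(as.numeric(t.test(between, within)$conf.int),
                 error = function(e) c(md, md))   # zero-variance samples
  list(within = within, between = between,
       test = testResult(unname(wt$statistic), wt$p.value,
                         "Wilcoxon rank-sum", c(length(between),
                                                length(within))),
       mean_diff = md, ci = ci)
}
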