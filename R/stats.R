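# Shared statistical utilities. Standard tests (t, Wilcoxon, Kruskal-Wallis,
# ANOVA) are delegated to stats::*; the procedures below are the ones needing
# exact small-sample behavior or balanced-group resampling.

#' Uniform test-result container
#' @param statistic test statistic.
#' @param p p value.
#' @param method method tag.
#' @param n sample size(s).
#' @return list of class \code{TestResult}.
#' @export
testResult <- function(statistic, p, method, n) {
  stopifnot(p >= 0, p <= 1)
  structure(list(statistic = statistic, p = p, method = method, n = n),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Benjamini-Hochberg step-up procedure
#'
#' @param pvals numeric vector of raw p values.
#' @param Q false-discovery-rate level.
#' @return list with \code{adjusted} (monotone BH-adjusted p values, in input
#'   order) and \code{reject} (logical decisions at level \code{Q}).
#' @export
benjaminiHochberg <- function(pvals, Q = 0.05) {
  stopifnot(Q > 0, Q < 1)
  if (!length(pvals)) return(list(adjusted = numeric(0), reject = logical(0)))
  adj <- p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= Q)
}

# Distribution of the concordant-minus-discordant statistic S under the
# permutation null (no ties): DP over insertion positions.
mkExactTail <- function(n, s_obs) {
  # number of inversions v of a permutation of n items: S = n(n-1)/2 - 2v
  counts <- 1
  for (i in 1:(n - 1)) {
    new <- numeric(length(counts) + i)
    for (off in 0:i)
      new[(1 + off):(length(counts) + off)] <-
        new[(1 + off):(length(counts) + off)] + counts
    counts <- new
  }
  total <- sum(counts)
  n0 <- n * (n - 1) / 2
  s_vals <- n0 - 2 * (seq_along(counts) - 1)
  p_ge <- sum(counts[s_vals >= s_obs]) / total
  p_le <- sum(counts[s_vals <= s_obs]) / total
  min(1, 2 * min(p_ge, p_le))
}

#' Mann-Kendall trend test
#'
#' \code{S} counts concordant minus discordant time-ordered pairs; tau is the
#' tie-corrected (tau-b) normalization. For series of length at most 10 with
#' no tied values the p value is computed by exact enumeration of the
#' permutation null; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used. Two-sided.
#'
#' @param series numeric vector, length >= 4.
#' @return A [testResult()] with the tau statistic.
#' @export
mannKendall <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 4) stop("need length >= 4")
  if (length(unique(x)) == 1) return(testResult(0, 1, "Mann-Kendall", n))
  S <- 0
  for (i in 1:(n - 1)) S <- S + sum(sign(x[(i + 1):n] - x[i]))
  ties <- table(x); ties <- ties[ties > 1]
  n0 <- n * (n - 1) / 2
  n1 <- sum(ties * (ties - 1) / 2)
  tau <- S / sqrt((n0 - n1) * n0)
  if (n <= 10 && !length(ties)) {
    p <- mkExactTail(n, S)
  } else {
    v <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    z <- if (S > 0) (S - 1) / sqrt(v) else if (S < 0) (S + 1) / sqrt(v) else 0
    p <- 2 * pnorm(-abs(z))
  }
  testResult(tau, min(1, p), "Mann-Kendall", n)
}

#' Permutation test for a difference of means
#'
#' Two-sided; \code{p = (1 + #(|d_perm| >= |d_obs|)) / (1 + n_perm)}.
#'
#' @param a,b numeric samples.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @return A [testResult()] with the observed mean difference.
#' @export
permutationTestMeans <- function(a, b, n_perm = 10000, seed = 1L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  d_obs <- mean(a) - mean(b)
  pool <- c(a, b); na <- length(a)
  exceed <- withSubstream(seed, "permtest", {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), na)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(d_obs) - 1e-12
    }, logical(1)))
  })
  testResult(d_obs, (1 + exceed) / (1 + n_perm), "permutation (means)",
             c(length(a), length(b)))
}

#' Balanced bootstrap mean and percentile confidence interval
#'
#' Per draw, every group (e.g. animal) contributes an equal number of samples
#' (the minimum group size), resampled with replacement, so that no group
#' dominates the estimate. Percentile 2.5/97.5% bounds.
#'
#' @param groups list of numeric vectors, one per group.
#' @param statistic function applied to the pooled balanced resample
#'   (default \code{mean}).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @return list with \code{estimate}, \code{ci} (length 2), \code{boot}
#'   (draws) and \code{degenerate} (TRUE when any group has a single sample).
#' @export
bootstrapCi <- function(groups, statistic = mean, n_boot = 1000, seed = 1L) {
  if (!is.list(groups)) groups <- list(groups)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group")
  n_min <- min(sizes)
  boot <- withSubstream(seed, "bootstrap", {
    vapply(seq_len(n_boot), function(i) {
      statistic(unlist(lapply(groups, function(g)
        g[sample.int(length(g), n_min, replace = TRUE)])))
    }, numeric(1))
  })
  list(estimate = statistic(unlist(groups)),
       ci = quantile(boot, c(0.025, 0.975), names = FALSE),
       boot = boot, degenerate = n_min < 2)
}
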