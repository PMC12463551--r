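# Firing-rate mean-matched source/target partitions.

#' Mean-match two unit populations by firing rate
#'
#' The pooled rate range is divided into \code{n_bins} equal-width bins (the
#' final bin is right-closed); from each bin, \code{min(count_src, count_tgt)}
#' units are drawn uniformly without replacement from each population, so the
#' selected source and target units have near-identical rate histograms.
#'
#' @param rates_src named numeric vector of source-unit rates (Hz).
#' @param rates_tgt named numeric vector of target-unit rates (Hz).
#' @param n_bins number of equal-range bins (default 20).
#' @param seed integer seed.
#' @return list with character vectors \code{source} and \code{target} of the
#'   selected unit ids.
#' @export
meanMatchUnits <- function(rates_src, rates_tgt, n_bins = 20, seed = 1L) {
  if (!length(rates_src) || !length(rates_tgt))
    stop("both populations must be non-empty")
  rng <- range(c(rates_src, rates_tgt))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  binOf <- function(r) pmin(findInterval(r, edges, rightmost.closed = TRUE),
                            n_bins)
  bs <- binOf(rates_src); bt <- binOf(rates_tgt)
  withSubstream(seed, "meanmatch", {
    src_sel <- character(0); tgt_sel <- character(0)
    for (b in seq_len(n_bins)) {
      is_ <- names(rates_src)[bs == b]; it <- names(rates_tgt)[bt == b]
      m <- min(length(is_), length(it))
      if (m > 0) {
        src_sel <- c(src_sel, if (length(is_) == m) is_ else sample(is_, m))
        tgt_sel <- c(tgt_sel, if (length(it) == m) it else sample(it, m))
      }
    }
    if (!length(tgt_sel)) stop("no rate-bin overlap between populations")
    list(source = src_sel, target = tgt_sel)
  })
}

#' Generate repeated mean-matched CA1->CA1 and CA1->PFC partitions
#'
#' For each repetition, CA1 units are split into a candidate source pool and a
#' candidate CA1-target pool (disjoint), then the source pool is mean-matched
#' against PFC (giving the CA1->PFC partition) and against the CA1-target pool
#' (giving the CA1->CA1 partition), with the CA1-target draw truncated to the
#' matched PFC target count so both conditions use equally sized targets.
#' The same source set serves both target conditions within a repetition, and
#' partitions are intended to be held fixed across window conditions.
#'
#' @param counts a raw (un-z-scored) [BinnedCounts-class] containing both
#'   regions.
#' @param n_partitions number of repetitions (default 50).
#' @param n_bins rate-histogram bins for matching (default 20).
#' @param seed integer seed.
#' @return list of [Partition-class]; \code{2 * n_partitions} entries,
#'   alternating CA1->PFC and CA1->CA1 per repetition.
#' @export
generatePartitions <- function(counts, n_partitions = 50, n_bins = 20,
                               seed = 1L) {
  rate <- rowMeans(SummarizedExperiment::assay(counts, "counts")) /
    binWidth(counts)
  names(rate) <- unitIds(counts)
  region <- regionLabels(counts)
  ca1 <- unitIds(counts)[region == "CA1"]
  pfc <- unitIds(counts)[region == "PFC"]
  if (!length(ca1) || !length(pfc)) stop("both regions required")
  out <- vector("list", 2L * n_partitions)
  for (r in seq_len(n_partitions)) {
    rs <- substreamSeed(seed, paste0("partition", r))
    withSubstream(rs, "split", {
      # split CA1: half as candidate sources, half as candidate CA1 targets
      ca1_perm <- sample(ca1)
      n_src <- ceiling(length(ca1) / 2)
      src_pool <- ca1_perm[seq_len(n_src)]
      tgt_pool <- ca1_perm[-seq_len(n_src)]
      mp <- meanMatchUnits(rate[src_pool], rate[pfc], n_bins,
                           seed = rs + 1L)
      mc <- meanMatchUnits(rate[mp$source], rate[tgt_pool], n_bins,
                           seed = rs + 2L)
      n_tgt <- min(length(mp$target), length(mc$target))
      if (n_tgt < 1) stop("empty matched target set in repetition ", r)
      out[[2 * r - 1]] <- new("Partition", source = mp$source,
                               target = mp$target[seq_len(n_tgt)],
                               targetRegion = "PFC", index = as.integer(r),
                               seed = as.integer(rs))
      out[[2 * r]] <- new("Partition", source = mp$source,
                           target = mc$target[seq_len(n_tgt)],
                           targetRegion = "CA1", index = as.integer(r),
                           seed = as.integer(rs))
    })
  }
  out
}
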