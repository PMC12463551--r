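# Shared fixtures: small synthetic sessions, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# 200 s, 30 + 20 units, default planted structure, no LFP (fast path).
smallSession <- function(seed = 1) {
  key <- paste0("small", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- synthConfig(n_epochs = 2, epoch_duration_s = 100,
                       trials_per_epoch = 5, seed = seed)
    .fixtures[[key]] <- generateSession(cfg, lfp = FALSE)
  }
  .fixtures[[key]]
}

# 120 s session including LFP, for filtering/coherence/pipeline tests.
lfpSession <- function(seed = 2) {
  key <- paste0("lfp", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- synthConfig(n_ca1 = 15, n_pfc = 10, n_epochs = 2,
                       epoch_duration_s = 60, trials_per_epoch = 3,
                       seed = seed)
    .fixtures[[key]] <- generateSession(cfg)
  }
  .fixtures[[key]]
}

# z-scored counts + region labels for a session.
sessionCounts <- function(ss, zscore = TRUE) {
  counts <- filterLowRateUnits(binSpikes(ss@spikes, 0.05, sessionSpan(ss)))
  if (zscore) counts <- zscoreCounts(counts)
  counts
}

# Planted low-rank regression problem: Y = X A B' + noise.
plantedRrr <- function(T, p, q, rank, noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(T * p), T, p)
  A <- matrix(rnorm(p * rank), p, rank)
  B <- matrix(rnorm(q * rank), q, rank)
  Y <- X %*% A %*% t(B) + noise * matrix(rnorm(T * q), T, q)
  list(X = X, Y = Y)
}

# Session with trajectory-type-specific shared loadings (position on latent
# 1, turn on latent 2, direction on latent 3): gives type-distinct profiles.
trajSession <- function(seed = 7) {
  key <- paste0("traj", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- synthConfig(n_epochs = 2, epoch_duration_s = 300,
                       trials_per_epoch = 15, seed = seed,
                       behavior_coupling = list(
                         list(var = "lin_pos", latent = 1, strength = 2.5),
                         list(var = "turn_sign", latent = 2, strength = 1.5),
                         list(var = "dir_sign", latent = 3, strength = 1.5)))
    .fixtures[[key]] <- generateSession(cfg, lfp = FALSE)
  }
  .fixtures[[key]]
}

# All permutations of 1:n as rows (for exact-test oracles, small n only).
permuteAll <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permuteAll(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

trainR2 <- function(X, Y, B) {
  1 - sum((Y - X %*% B)^2) / sum(sweep(Y, 2, colMeans(Y))^2)
}
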