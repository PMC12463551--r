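# Multitaper coherence, WPLI, normalization, trends, spatial binning.

test_that("multitaper coherence: identity, selectivity, symmetry, scaling", {
  fs <- 200
  tt <- (0:(fs * 60 - 1)) / fs
  set.seed(41)
  shared <- sin(2 * pi * 8 * tt)
  x <- shared + rnorm(length(tt), 0, 0.5)
  y <- shared + rnorm(length(tt), 0, 0.5)
  expect_lt(max(abs(multitaperCoherence(x, x, fs = fs)@values - 1)), 1e-10)
  co <- multitaperCoherence(x, y, fs = fs)
  at <- function(f) mean(co@values[, which.min(abs(co@freqs - f))])
  expect_gt(at(8), at(20))
  # symmetric in its arguments, invariant to per-channel rescaling
  co_ba <- multitaperCoherence(y, x, fs = fs)
  expect_equal(co@values, co_ba@values, tolerance = 1e-12)
  co_sc <- multitaperCoherence(3.7 * x, 0.2 * y, fs = fs)
  expect_equal(co@values, co_sc@values, tolerance = 1e-9)
})

test_that("independent noise stays below the multitaper bias floor", {
  set.seed(42)
  fs <- 200
  xn <- rnorm(fs * 120); yn <- rnorm(fs * 120)
  con <- multitaperCoherence(xn, yn, fs = fs, n_tapers = 5)
  expect_lt(mean(con@values), 1 / 5 + 0.05)
})

test_that("WPLI is exact for constant lags and vanishes under nulls", {
  fs <- 500
  tt <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 8 * tt)
  y <- sin(2 * pi * 8 * tt - pi / 2)       # constant 90 degree lag
  w <- wpli(x, y, fs = fs)
  expect_equal(as.vector(w@values), rep(1, length(w@freqs)))

  set.seed(43)
  xn <- rnorm(1e5); yn <- rnorm(1e5)       # 2000 half-second windows
  wn <- wpli(xn, yn, fs = 100, window_s = 0.5)
  expect_lte(mean(wn@values), 0.05)

  # zero-lag (purely real cross-spectrum) signals are undefined/zero-lag-free
  wz <- wpli(x, x, fs = fs)
  expect_true(all(is.na(wz@values) | wz@values < 0.5))
})

test_that("WPLI discounts an added zero-lag common signal", {
  fs <- 250
  tt <- (0:(fs * 60 - 1)) / fs
  set.seed(44)
  lagged <- sin(2 * pi * 8 * tt)
  x <- lagged + 0.3 * rnorm(length(tt))
  y <- sin(2 * pi * 8 * tt - pi / 3) + 0.3 * rnorm(length(tt))
  base <- mean(wpli(x, y, fs = fs)@values, na.rm = TRUE)
  common <- 2 * sin(2 * pi * 8.2 * tt + 1)  # same signal added to both
  mixed <- mean(wpli(x + common, y + common, fs = fs)@values, na.rm = TRUE)
  volume <- mean(wpli(common + 0.3 * rnorm(length(tt)),
                      common + 0.3 * rnorm(length(tt)), fs = fs)@values,
                 na.rm = TRUE)
  expect_gt(base, 0.8)
  expect_lt(volume, 0.3)                    # zero-lag coupling discounted
  expect_gt(mixed, volume)
})

test_that("normalizeSpectral matches its per-animal contracts", {
  set.seed(45)
  df <- data.frame(animal = rep(c("a1", "a2"), each = 60),
                   band = rep(rep(c("theta", "delta"), each = 30), 2),
                   frequency = rep(rep(c(8, 2), each = 30), 2),
                   value = rnorm(120))
  df$value[df$animal == "a2"] <- df$value[df$animal == "a2"] + 5  # offset
  z <- normalizeSpectral(df, "zscore")
  agg <- tapply(z$normalized, interaction(z$animal, z$band), mean)
  expect_lt(max(abs(agg)), 1e-10)
  mm <- normalizeSpectral(df, "minmax")
  rg <- tapply(mm$normalized, interaction(mm$animal, mm$frequency), range)
  for (r in rg) expect_equal(r, c(0, 1))
  # two animals differing only by offset have identical normalized trends
  df2 <- data.frame(animal = rep(c("a1", "a2"), each = 30),
                    band = "theta", frequency = 8,
                    value = c(sin(1:30 / 5), sin(1:30 / 5) + 7))
  z2 <- normalizeSpectral(df2, "zscore")
  expect_equal(z2$normalized[df2$animal == "a1"],
               z2$normalized[df2$animal == "a2"], tolerance = 1e-12)
  # constant series: minmax undefined
  df3 <- data.frame(animal = "a", frequency = 8, value = rep(2, 5))
  expect_true(all(is.na(normalizeSpectral(df3, "minmax")$normalized)))
})

test_that("epochTrend detects planted declines with balanced bootstrap CIs", {
  # identical values everywhere: zero-width CIs, tau 0
  dfc <- expand.grid(animal = c("a", "b"), epoch = 1:8, rep = 1:20)
  dfc$value <- 1
  tr <- epochTrend(dfc, n_boot = 100, seed = 1)
  expect_true(all(tr$summary$hi - tr$summary$lo == 0))
  expect_equal(tr$trend$statistic, 0)
  expect_equal(tr$trend$p, 1)

  set.seed(46)
  dfd <- expand.grid(animal = paste0("a", 1:4), epoch = 1:8, rep = 1:25)
  dfd$value <- 1 - 0.08 * dfd$epoch + rnorm(nrow(dfd), 0, 0.05)
  trd <- epochTrend(dfd, n_boot = 200, seed = 2)
  expect_lt(trd$trend$statistic, 0)
  expect_lt(trd$trend$p, 0.05)
  expect_lt(trd$anova_p, 0.05)
  expect_identical(epochTrend(dfd, n_boot = 200, seed = 2)$summary,
                   trd$summary)
  # an animal missing an epoch is excluded with a message
  dfm <- dfd[!(dfd$animal == "a1" & dfd$epoch == 3), ]
  expect_message(epochTrend(dfm, n_boot = 50, seed = 1), "missing animal")
})

test_that("spatialBinnedCoherence maps values onto occupied track bins", {
  ss <- smallSession()
  beh <- ss@behavior
  times <- seq(0.5, max(beh$time), by = 1)
  idx <- findInterval(times, beh$time)
  # constant coherence: flat zero curves after z-scoring
  flat <- spatialBinnedCoherence(times, rep(0.7, length(times)), beh,
                                 n_bins = 10, n_boot = 20, seed = 1)
  expect_true(all(is.na(flat$mean) | abs(flat$mean) < 1e-9))
  # coherence high only in the center arm (lin_pos < 0.3)
  v <- ifelse(beh$lin_pos[idx] < 0.3, 1, 0) + rnorm(length(times), 0, 0.01)
  curve <- spatialBinnedCoherence(times, v, beh, n_bins = 10, n_boot = 20,
                                  seed = 1)
  peak_bins <- curve$bin[curve$mean > 0.5]
  expect_true(all(peak_bins <= 3))
  # bin occupancy equals the direct histogram of matched samples
  occ <- table(pmin(floor(beh$lin_pos[idx] * 10) + 1, 10),
               beh$direction[idx], beh$epoch[idx])
  for (i in seq_len(nrow(curve))) {
    expect_equal(curve$n[i],
                 occ[as.character(curve$bin[i]), curve$direction[i],
                     as.character(curve$epoch[i])],
                 ignore_attr = TRUE)
  }
})

test_that("powerCoherenceStats separates common drive from coherence", {
  set.seed(47)
  animals <- paste0("a", 1:6)
  df_time <- do.call(rbind, lapply(animals, function(a) {
    drive <- rnorm(300)
    data.frame(animal = a, ca1_power = drive + rnorm(300, 0, 0.5),
               pfc_power = drive + rnorm(300, 0, 0.5),
               coherence = rnorm(300))
  }))
  st <- powerCoherenceStats(df_time)
  expect_true(all(st$correlations$power_power >
                    st$correlations$power_coherence))
  expect_lt(st$signed_rank$p, 0.05)
  # identical inputs: no difference, test skipped for degenerate pairs
  df_id <- data.frame(animal = rep(animals, each = 10),
                      ca1_power = rnorm(60))
  df_id$pfc_power <- df_id$ca1_power
  df_id$coherence <- df_id$ca1_power
  st_id <- powerCoherenceStats(df_id)
  expect_equal(st_id$correlations$power_power,
               st_id$correlations$power_coherence)
  expect_null(st_id$signed_rank)
  # peak extraction: single maximum at 8 Hz
  df_spec <- do.call(rbind, lapply(animals, function(a)
    data.frame(animal = a, frequency = 1:20,
               ca1_power = dnorm(1:20, 8, 2),
               pfc_power = dnorm(1:20, 8, 2),
               coherence = dnorm(1:20, 9, 2))))
  st2 <- powerCoherenceStats(df_time, df_spec)
  expect_true(all(st2$peaks$ca1 == 8))
  expect_true(all(st2$peaks$coherence == 9))
})
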