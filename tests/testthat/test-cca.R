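# Canonical correlation, variate projection, shared/local decomposition.

test_that("identical populations give unit training correlations", {
  set.seed(31)
  X <- matrix(rnorm(500 * 6), 500, 6)
  fit <- fitCca(X, X, k = 3)
  expect_equal(canonicalCorrelations(fit), rep(1, 3), tolerance = 1e-6)
  expect_error(fitCca(X, X, k = 7), "k must not exceed")
})

test_that("training correlations match the stats::cancor oracle", {
  set.seed(32)
  for (rep in 1:5) {
    p <- sample(4:10, 1); q <- sample(4:10, 1)
    X <- scale(matrix(rnorm(800 * p), 800, p), scale = FALSE)
    Y <- scale(matrix(rnorm(800 * q), 800, q), scale = FALSE)
    k <- min(p, q)
    fit <- fitCca(X, Y, k = k, lambda = 0)
    expect_lt(max(abs(canonicalCorrelations(fit) - cancor(X, Y)$cor[1:k])),
              1e-8)
  }
})

test_that("held-out correlations vanish for time-permuted targets", {
  set.seed(33)
  Z <- rnorm(20000)
  X <- cbind(Z, matrix(rnorm(20000 * 4), ncol = 4)) %*%
    matrix(rnorm(25), 5, 5)
  Y <- cbind(0.8 * Z + 0.6 * rnorm(20000),
             matrix(rnorm(20000 * 3), ncol = 3)) %*% matrix(rnorm(16), 4, 4)
  fit <- fitCca(scale(X), scale(Y), k = 3)
  expect_equal(canonicalCorrelations(fit, "heldout")[1], 0.8,
               tolerance = 0.05)
  expect_lt(canonicalCorrelations(fit, "heldout")[2], 0.1)
  fit0 <- fitCca(scale(X), scale(Y)[sample(20000), ], k = 3)
  expect_lt(max(abs(canonicalCorrelations(fit0, "heldout"))), 0.05)
})

test_that("projectVariates applies the fitted weights at every bin", {
  set.seed(34)
  X <- matrix(rnorm(400 * 5), 400, 5)
  Y <- matrix(rnorm(400 * 4), 400, 4)
  fit <- fitCca(X, Y, k = 3)
  vs <- projectVariates(fit, X, Y)
  expect_equal(dim(vs@u), c(400, 3))
  # projecting training data reproduces the training correlations
  rho <- vapply(1:3, function(j) cor(vs@u[, j], vs@v[, j]), numeric(1))
  expect_equal(rho, canonicalCorrelations(fit), tolerance = 1e-6)
  expect_equal(projectVariates(fit, X * 0, Y)@u, matrix(0, 400, 3))
  expect_error(projectVariates(fit, X[, 1:3], Y), "mismatch")
})

test_that("aligned/orthogonal decomposition is the expected isometry", {
  set.seed(35)
  U <- matrix(rnorm(200 * 3), 200, 3)
  V <- matrix(rnorm(200 * 3), 200, 3)
  vs <- new("VariateSeries", u = U, v = V, times = seq_len(200) * 0.05)
  sl <- alignedOrthogonal(vs)
  expect_lt(max(abs(rowSums(sl@aligned^2) + rowSums(sl@local^2) -
                      rowSums(U^2) - rowSums(V^2))), 1e-12)
  slU <- alignedOrthogonal(new("VariateSeries", u = U, v = U,
                               times = vs@times))
  expect_equal(slU@local, matrix(0, 200, 3), ignore_attr = TRUE)
  expect_equal(slU@aligned, sqrt(2) * U, tolerance = 1e-12)
  slN <- alignedOrthogonal(new("VariateSeries", u = U, v = -U,
                               times = vs@times))
  expect_equal(slN@aligned, matrix(0, 200, 3), ignore_attr = TRUE)
})

test_that("aligned activity is repeatable within trajectory types", {
  ss <- trajSession()
  counts <- sessionCounts(ss)
  region <- regionLabels(counts)
  fit <- fitCca(counts[region == "CA1", ], counts[region == "PFC", ], k = 3)
  sl <- alignedOrthogonal(projectVariates(fit, counts[region == "CA1", ],
                                          counts[region == "PFC", ]))
  tr <- trajectoryRepeatability(sl, ss@behavior, n_pos_bins = 50,
                                n_components = 3)
  expect_setequal(unique(tr$category),
                  c("pure_match", "same_type", "different_type"))
  # turn/direction load their own shared latents, so profiles are
  # trajectory-type specific: same-type pairs agree more than cross-type
  expect_gt(median(tr$cosine[tr$category == "pure_match"]), 0.6)
  expect_gt(median(tr$cosine[tr$category == "same_type"]),
            median(tr$cosine[tr$category == "different_type"]))
})

test_that("spatial component maps localize planted positional activity", {
  ss <- smallSession(seed = 21)
  beh <- ss@behavior
  times <- seq(0, max(beh$time), by = 0.05)
  idx <- findInterval(times, beh$time); idx[idx == 0] <- 1
  f_pos <- beh$y[idx] / 70                     # activity = f(position)
  sl <- new("SharedLocalSeries",
            aligned = cbind(f_pos + rnorm(length(f_pos), 0, 0.05),
                            rep(1, length(f_pos))),
            local = matrix(0, length(f_pos), 2), times = times)
  maps <- spatialComponentMap(sl, beh, grid = 10, n_components = 2)
  occ_ok <- !is.na(maps$component1)
  # map correlates with the planted positional profile
  ybin <- matrix(rep(1:10, each = 10), 10)     # row index = y bin
  f_map <- (ybin - 0.5) / 10
  expect_gt(cor(maps$component1[occ_ok], f_map[occ_ok]), 0.8)
  # constant component is flat zero after z-scoring
  expect_true(all(maps$component2[occ_ok] == 0))
  # mask matches the occupancy histogram
  expect_equal(sum(is.na(maps$component1)), sum(maps$occupancy < 5))
})
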