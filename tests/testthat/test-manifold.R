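# Pseudopopulation construction, super-animal embedding, ring contrast.

test_that("pseudopopulation matches a brute-force group-by-mean oracle", {
  ss <- smallSession()
  pp <- buildPseudopopulation(list(ss), n_distance_bins = 10)
  expect_equal(dim(pp@rates), c(2 * 2 * 10, 50))
  expect_equal(nrow(pp@states), 40)

  counts <- binSpikes(ss@spikes, 0.05, sessionSpan(ss))
  m <- countsMatrix(counts) / 0.05
  bt <- binTimes(counts) + 0.025
  idx <- findInterval(bt, ss@behavior$time); idx[idx == 0] <- 1
  dbin <- pmin(floor(ss@behavior$lin_pos[idx] * 10) + 1, 10)
  dirv <- ss@behavior$direction[idx]; turn <- ss@behavior$turn[idx]
  for (r in sample(nrow(pp@states), 8)) {
    st <- pp@states[r, ]
    sel <- dirv == st$direction & turn == st$turn & dbin == st$dbin
    if (sum(sel) > 0) {
      expect_equal(pp@rates[r, ], colMeans(m[sel, , drop = FALSE]),
                   ignore_attr = TRUE)
    }
  }
  # two sessions concatenate columns
  pp2 <- buildPseudopopulation(list(ss, ss), n_distance_bins = 10)
  expect_equal(ncol(pp2@rates), 100)
  expect_equal(pp2@columns$animal, rep(1:2, each = 50))
})

test_that("embedding recovers a planted circular latent's ordering", {
  set.seed(71)
  n_states <- 80
  ang <- seq(0, 2 * pi, length.out = n_states + 1)[1:n_states]
  latent <- cbind(cos(ang), sin(ang), 1)
  mkBlock <- function(n_units) latent %*% matrix(rnorm(3 * n_units), 3) +
    0.05 * matrix(rnorm(n_states * n_units), n_states)
  states <- data.frame(direction = "out", turn = "L", dbin = 1:n_states)
  pp <- new("Pseudopopulation",
            rates = cbind(mkBlock(12), mkBlock(10)), states = states,
            columns = data.frame(animal = 1, unit = paste0("u", 1:22),
                                 region = rep(c("CA1", "PFC"), c(12, 10))))
  emb <- embedCca(pp, k = 3)
  # angular order of embedded points matches the planted state order
  th <- atan2(emb@aligned[, 2] - mean(emb@aligned[, 2]),
              emb@aligned[, 1] - mean(emb@aligned[, 1]))
  expect_gt(Mod(mean(exp(1i * (th - ang)))) +
              Mod(mean(exp(1i * (th + ang)))), 0.9)

  # block-independent random rates: no distance structure
  pp0 <- new("Pseudopopulation",
             rates = matrix(rnorm(n_states * 22), n_states),
             states = data.frame(direction = rep(c("out", "in"),
                                                 each = n_states / 2),
                                 turn = "L",
                                 dbin = rep(1:(n_states / 2), 2)),
             columns = pp@columns)
  emb0 <- embedCca(pp0, k = 3)
  rc0 <- ringDistanceContrast(emb0)
  expect_gt(rc0$test$p, 1e-4)
  expect_error(embedCca(pp, k = 20), "components")
})

test_that("embedding geometry is invariant to column permutation", {
  ss <- smallSession()
  pp <- buildPseudopopulation(list(ss), n_distance_bins = 10)
  emb <- embedCca(pp)
  perm <- c(sample(1:30), 30 + sample(1:20))
  ppp <- new("Pseudopopulation", rates = pp@rates[, perm],
             states = pp@states, columns = pp@columns[perm, ])
  embp <- embedCca(ppp)
  d <- function(e) as.vector(dist(e@aligned))
  expect_equal(d(embp), d(emb), tolerance = 1e-6)
})

test_that("parallel rings separate by their offset; pair counts enumerate", {
  n <- 100
  ang <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  ring <- cbind(cos(ang), sin(ang), 0)
  d_off <- 5
  states <- data.frame(direction = rep("out", 2 * n),
                       turn = rep(c("L", "R"), each = n), dbin = rep(1:n, 2))
  emb <- new("ManifoldEmbedding",
             aligned = rbind(ring, sweep(ring, 2, c(0, 0, -d_off))),
             local = matrix(0, 2 * n, 3), states = states)
  rc <- ringDistanceContrast(emb)
  expect_equal(mean(rc$between) - mean(rc$within), d_off,
               tolerance = 0.1)
  expect_lt(rc$test$p, 1e-10)
  # counts: within = (n-1) consecutive steps per ring, between = n shared bins
  expect_length(rc$within, 2 * (n - 1))
  expect_length(rc$between, n)

  # two identical manifolds: between ~ 0, no separation
  emb_id <- new("ManifoldEmbedding", aligned = rbind(ring, ring),
                local = matrix(0, 2 * n, 3), states = states)
  rc_id <- ringDistanceContrast(emb_id)
  expect_true(all(rc_id$between == 0))
})

test_that("trajectory-specific shared loadings produce separated rings", {
  ss <- trajSession()
  pp <- suppressMessages(buildPseudopopulation(list(ss),
                                               n_distance_bins = 40))
  rc <- ringDistanceContrast(embedCca(pp))
  expect_gt(mean(rc$between), mean(rc$within))
  expect_lt(rc$test$p, 0.01)
})
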