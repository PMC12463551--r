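# Behavioral decoding, mixed models, rhythm coupling, state densities.

mkSl <- function(U, V, times = seq_len(nrow(U)) * 0.05)
  alignedOrthogonal(new("VariateSeries", u = U, v = V, times = times))

test_that("buildFeatures lays out aligned then local components", {
  set.seed(61)
  U <- matrix(rnorm(100 * 12), 100, 12)
  sl <- mkSl(U, U + matrix(rnorm(100 * 12), 100, 12))
  f <- buildFeatures(sl, k = 10)
  expect_equal(ncol(f), 20)
  expect_equal(colnames(f)[c(1, 11)], c("aligned_1", "local_1"))
  expect_equal(f[, 1:10], sl@aligned[, 1:10], ignore_attr = TRUE)
  slid <- mkSl(U, U)
  expect_true(all(buildFeatures(slid, 10)[, 11:20] == 0))
  expect_error(buildFeatures(mkSl(U[, 1:4], U[, 1:4]), k = 10), "available")
})

test_that("robust-t point estimates match an independent ML oracle", {
  set.seed(62)
  X <- matrix(rnorm(400 * 3), 400, 3)
  beta_true <- c(0.5, -1, 2, 0.7)
  y <- cbind(1, X) %*% beta_true + rt(400, df = 4) * 0.3
  fit <- neurocomm:::tRegression(X, as.numeric(y), nu = 4)
  # oracle: direct maximization of the t log-likelihood over (beta, log s)
  nll <- function(par) {
    r <- as.numeric(y - cbind(1, X) %*% par[1:4])
    s <- exp(par[5])
    -sum(stats::dt(r / s, df = 4, log = TRUE) - log(s))
  }
  o <- optim(c(fit$coef, log(fit$scale)), nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(fit$coef - o$par[1:4])), 1e-5)
})

test_that("decoders recover planted responses and stay at chance on nulls", {
  set.seed(63)
  U <- matrix(rnorm(2000 * 10), 2000, 10)
  V <- U + 0.1 * matrix(rnorm(2000 * 10), 2000, 10)
  sl <- mkSl(U, V)
  f <- buildFeatures(sl, 10)
  # continuous response linear in aligned features, noiseless
  y <- as.numeric(f[, 1:10] %*% seq(1, 0.1, length.out = 10))
  for (fam in c("gaussian", "robust_t")) {
    fit <- fitBehaviorGlm(f, y, family = fam, seed = 2)
    expect_gte(fit@metric[["r2"]], 0.95)
  }
  # null binary labels: F1 near the prevalence baseline
  yl <- rbinom(2000, 1, 0.5)
  fit0 <- fitBehaviorGlm(f, yl, family = "bernoulli", seed = 2)
  base <- 2 * 0.5 / (2 * 0.5 + 0.5 + 0.5)   # F1 of coin-flip vs prevalence
  expect_lt(abs(fit0@metric[["f1"]] - base), 0.1)
  # linearly separable toy: perfect held-out classification
  ysep <- as.integer(f[, 1] > 0)
  fitsep <- fitBehaviorGlm(f[, 1:2], ysep, family = "bernoulli", seed = 2)
  expect_equal(fitsep@metric[["f1"]], 1)
  # deterministic point estimates under a fixed seed
  expect_identical(fitBehaviorGlm(f, y, family = "gaussian", seed = 4)@coef,
                   fitBehaviorGlm(f, y, family = "gaussian", seed = 4)@coef)
})

test_that("time-shuffled features never beat the real ones (median over seeds)", {
  set.seed(64)
  U <- matrix(rnorm(1500 * 4), 1500, 4)
  sl <- mkSl(U, U + 0.2 * matrix(rnorm(1500 * 4), 1500, 4))
  f <- buildFeatures(sl, 4)
  y <- as.numeric(f[, 1] * 2 + rnorm(1500, 0, 0.5))
  real <- fitBehaviorGlm(f, y, family = "gaussian", seed = 1)@metric[["r2"]]
  shuf <- vapply(1:20, function(s) {
    set.seed(s)
    fitBehaviorGlm(f[sample(1500), ], y, family = "gaussian",
                   seed = 1)@metric[["r2"]]
  }, numeric(1))
  expect_gt(real, median(shuf))
})

test_that("evaluateDecoding separates aligned from local predictive power", {
  set.seed(65)
  U <- matrix(rnorm(3000 * 5), 3000, 5)
  V <- matrix(rnorm(3000 * 5), 3000, 5)
  sl <- mkSl(U, V)
  beh <- data.frame(pos = as.numeric(sl@aligned[, 1] + rnorm(3000, 0, 0.2)))
  ev <- evaluateDecoding(buildFeatures(sl, 5), beh, "pos",
                         family = "gaussian", seed = 3)
  expect_gt(ev$summary$aligned, 0.8)
  expect_lt(ev$summary$local, 0.1)
  expect_gt(ev$summary$coef_ratio, 3)
  # aligned == local blocks: identical metrics
  sl2 <- new("SharedLocalSeries", aligned = sl@aligned, local = sl@aligned,
             times = sl@times)
  f2 <- buildFeatures(sl2, 5)
  fa <- fitBehaviorGlm(f2[, 1:5], beh$pos, family = "gaussian", seed = 3)
  fl <- fitBehaviorGlm(f2[, 6:10], beh$pos, family = "gaussian", seed = 3)
  expect_equal(fa@metric, fl@metric)
  # per-epoch variant produces one record per epoch
  ev2 <- evaluateDecoding(buildFeatures(sl, 5), beh, "pos",
                          epochs = rep(1:3, each = 1000),
                          family = "gaussian", seed = 3)
  expect_equal(sort(unique(ev2$by_epoch$epoch)), 1:3)
})

test_that("mixed model comparison respects nesting and finds the source", {
  set.seed(66)
  n <- 200
  df <- expand.grid(animal = paste0("a", 1:4), epoch = 1:5)
  df <- df[rep(seq_len(nrow(df)), each = n), ]
  df$velocity <- rnorm(nrow(df))
  df$idphi <- rnorm(nrow(df))
  df$lin_pos <- runif(nrow(df))
  df$theta <- rnorm(nrow(df))
  df$response <- 1.5 * df$velocity + rnorm(nrow(df), 0, 0.5)  # behavior only
  cmp <- compareMixedModels(df, behaviors = "velocity")
  ps <- cmp$per_split
  # training nesting: R~B*theta >= R~B+theta >= R~B on every split
  for (key in unique(paste(ps$animal, ps$epoch))) {
    s <- ps[paste(ps$animal, ps$epoch) == key, ]
    expect_gte(s$r2[s$model == "B*theta"], s$r2[s$model == "B+theta"] - 1e-12)
    expect_gte(s$r2[s$model == "B+theta"], s$r2[s$model == "B"] - 1e-12)
  }
  # behavior-generated response: B beats theta on AIC in >= 90% of splits
  wide <- merge(ps[ps$model == "B", c("animal", "epoch", "aic")],
                ps[ps$model == "theta", c("animal", "epoch", "aic")],
                by = c("animal", "epoch"))
  expect_gte(mean(wide$aic.x <= wide$aic.y), 0.9)

  # planted interaction: B*theta wins on AIC in >= 90% of splits
  df$response <- df$velocity * df$theta + rnorm(nrow(df), 0, 0.3)
  cmp2 <- compareMixedModels(df, behaviors = "velocity")
  expect_gte(mean(cmp2$winners$model == "B*theta"), 0.9)
})

test_that("rhythm coupling over epochs tracks planted relationships", {
  set.seed(67)
  n <- 300
  epochs <- rep(1:6, each = n)
  a1 <- rnorm(length(epochs)); l1 <- rnorm(length(epochs))
  # response equals the aligned component exactly: R2 = 1 in every epoch
  # (lm warns about the perfect fit)
  rc <- suppressWarnings(rhythmCouplingOverEpochs(a1, l1, a1, epochs,
                                                  seed = 1))
  expect_true(all(abs(rc$mean_r2 - 1) < 1e-10))
  # independent response: R2 stays near zero
  rc0 <- rhythmCouplingOverEpochs(a1, l1, rnorm(length(epochs)), epochs,
                                  seed = 1)
  expect_true(all(rc0$mean_r2 <= 0.05))
  # coupling ramping across epochs: monotone increasing trend
  slope <- (epochs - 1) / 5
  resp <- slope * a1 + sqrt(1 - slope^2 / 2) * rnorm(length(epochs), 0, 1)
  rcr <- rhythmCouplingOverEpochs(a1, l1, resp, epochs, seed = 1)
  expect_gt(mannKendall(rcr$mean_r2)$statistic, 0)
})

test_that("state density contrast flags planted shared-axis shifts", {
  set.seed(68)
  times <- seq_len(4000) * 0.05
  aligned <- matrix(rnorm(4000), ncol = 1)
  hi_idx <- 1:1000; lo_idx <- 2001:3000
  aligned[hi_idx, 1] <- aligned[hi_idx, 1] + 1
  sl <- new("SharedLocalSeries", aligned = aligned,
            local = matrix(rnorm(4000), ncol = 1), times = times)
  mkws <- function(idx, lv) {
    s <- times[idx[seq(1, length(idx), by = 10)]]
    WindowSet(s, s + 0.3, "theta", lv)
  }
  wp <- list(theta = list(high = mkws(hi_idx, "high"),
                          low = mkws(lo_idx, "low")))
  res <- stateDensityContrast(sl, wp, n_perm = 2000, seed = 3)
  expect_lt(res$aligned_p, 0.001)
  expect_gt(res$local_p, 0.05)
  # identical high/low samples: p near 1
  wp_id <- list(theta = list(high = mkws(lo_idx, "high"),
                             low = mkws(lo_idx, "low")))
  res_id <- stateDensityContrast(sl, wp_id, n_perm = 500, seed = 3)
  expect_gt(res_id$aligned_p, 0.9)
})
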