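# Internal numerical helpers.

# All generator randomness flows from one master seed through named
# substreams, so that e.g. regenerating the LFP never perturbs the spikes.
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483563) + 1L
}

withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, name))
  force(expr)
}

# Stationary AR(1) rows: x_t = phi x_{t-1} + sqrt(1-phi^2) e_t, unit variance.
ar1Series <- function(k, n, phi = 0.8) {
  x <- matrix(rnorm(k * n), k, n)
  if (n > 1) {
    s <- sqrt(1 - phi^2)
    for (t in 2:n) x[, t] <- phi * x[, t - 1] + s * x[, t]
  }
  x
}

# Analytic signal via frequency-domain construction (one-sided spectrum).
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Centered boxcar moving average with edge shrinkage.
boxcarSmooth <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  pad <- floor(width / 2)
  xs <- c(rep(x[1], pad), x, rep(x[length(x)], width - pad - 1))
  as.numeric(stats::filter(xs, k, sides = 1))[width:(length(x) + width - 1)]
}

# 1/f ("pink") noise of unit sd via spectral shaping.
pinkNoise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE) / n)
  as.numeric(scale(x))
}

# Moore-Penrose pseudoinverse (SVD, relative tolerance).
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Symmetric inverse square root with ridge regularization.
invSqrtm <- function(S, lambda = 0) {
  if (lambda > 0) S <- S + diag(lambda * mean(diag(S)), nrow(S))
  e <- eigen(S, symmetric = TRUE)
  d <- pmax(e$values, max(e$values) * 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(d))
}

# Linear interpolation of a series onto new sample times (rule 2 at edges).
interpTo <- function(t_from, x, t_to)
  approx(t_from, x, xout = t_to, rule = 2)$y

assertScalar <- function(x, name, lower = -Inf) {
  if (length(x) != 1 || !is.finite(x) || x < lower)
    stop(sprintf("'%s' must be a finite scalar >= %s", name, lower),
         call. = FALSE)
  invisible(x)
}
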