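# Behavioral decoding from communication-subspace variates, mixed
# behavior-by-theta model comparison, rhythm coupling over epochs, and
# state-density contrasts.

#' GlmFit: a fitted behavioral decoding model
#'
#' @slot family \code{"gaussian"}, \code{"robust_t"} or \code{"bernoulli"}.
#' @slot coef named coefficient point estimates (including intercept).
#' @slot ci coefficient 95% intervals (2 columns).
#' @slot draws approximate posterior draws of the coefficients (rows), sampled
#'   from the asymptotic normal around the penalized-MLE point estimate.
#' @slot metric named held-out metric: \code{r2} (continuous) or \code{f1}
#'   (binary).
#' @slot trainIdx indices of the training rows.
#' @exportClass GlmFit
setClass("GlmFit",
  representation(family = "character", coef = "numeric", ci = "matrix",
                 draws = "matrix", metric = "numeric", trainIdx = "integer"))

setValidity("GlmFit", function(object) {
  if (nrow(object@ci) != length(object@coef)) return("ci/coef mismatch")
  if (any(object@ci[, 1] > object@ci[, 2])) return("interval bounds unordered")
  TRUE
})

#' Feature matrix of aligned-then-local canonical components
#'
#' Columns are \code{aligned_1..k} followed by \code{local_1..k}. Fewer than
#' \code{k} available components is an error (padding is not allowed).
#'
#' @param sl a [SharedLocalSeries-class].
#' @param k components per class (default 10).
#' @return numeric T x 2k matrix with a \code{times} attribute.
#' @export
buildFeatures <- function(sl, k = 10) {
  if (ncol(sl@aligned) < k)
    stop("only ", ncol(sl@aligned), " components available; k = ", k)
  out <- cbind(sl@aligned[, seq_len(k), drop = FALSE],
               sl@local[, seq_len(k), drop = FALSE])
  colnames(out) <- c(paste0("aligned_", seq_len(k)),
                     paste0("local_", seq_len(k)))
  attr(out, "times") <- sl@times
  out
}

# IRLS for a Student-t regression (fixed df): EM weights
# w_i = (nu + 1) / (nu + r_i^2 / s^2).
tRegression <- function(X, y, nu = 4, max_iter = 100, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- qr.solve(Xd, y)
  s2 <- mean((y - Xd %*% beta)^2)
  for (it in seq_len(max_iter)) {
    r <- as.numeric(y - Xd %*% beta)
    w <- (nu + 1) / (nu + r^2 / s2)
    Xw <- Xd * w
    beta_new <- solve(crossprod(Xw, Xd), crossprod(Xw, y))
    s2_new <- sum(w * (y - Xd %*% beta_new)^2) / nrow(Xd)
    delta <- max(abs(beta_new - beta))
    beta <- as.numeric(beta_new); names(beta) <- colnames(Xd)
    s2 <- max(s2_new, 1e-12)
    if (delta < tol) break
  }
  r <- as.numeric(y - Xd %*% beta)
  w <- (nu + 1) / (nu + r^2 / s2)
  cov_beta <- tryCatch(solve(crossprod(Xd * w, Xd)) * s2,
                       error = function(e) diag(NA_real_, ncol(Xd)))
  list(coef = beta, vcov = cov_beta, scale = sqrt(s2))
}

f1Score <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Fit a behavioral decoding GLM with a held-out split
#'
#' Continuous behaviors use either Gaussian least squares or a robust
#' Student-t regression (fixed df = 4, penalized-MLE via IRLS); binary
#' behaviors use Bernoulli (logistic) regression. Training uses
#' \code{train_n} randomly drawn rows (or 70% when fewer are available); the
#' rest are held out. Coefficient draws are sampled from the asymptotic
#' normal approximation around the point estimate, giving deterministic
#' point estimates with calibrated spread.
#'
#' @param features numeric feature matrix (e.g. from [buildFeatures()]).
#' @param response behavioral response vector (numeric, or logical/binary).
#' @param family \code{"gaussian"}, \code{"robust_t"} or \code{"bernoulli"};
#'   default picks \code{robust_t} for numeric and \code{bernoulli} for
#'   binary responses.
#' @param train_n training rows (default 50000, capped at 70% of T).
#' @param n_draws coefficient draws (default 2000).
#' @param seed integer seed (split + draws).
#' @return A [GlmFit-class].
#' @export
fitBehaviorGlm <- function(features, response, family = NULL,
                           train_n = 50000, n_draws = 2000, seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  binary <- is.logical(response) || all(response %in% c(0, 1))
  if (is.null(family)) family <- if (binary) "bernoulli" else "robust_t"
  y <- as.numeric(response)
  tr <- withSubstream(seed, "split", {
    n_tr <- if (n > train_n) train_n else floor(0.7 * n)
    sort(sample.int(n, n_tr))
  })
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xte <- X[-tr, , drop = FALSE]; yte <- y[-tr]

  if (family == "bernoulli") {
    dtr <- data.frame(y = ytr, Xtr)
    fit <- suppressWarnings(glm(y ~ ., data = dtr, family = binomial()))
    beta <- coef(fit)
    vc <- suppressWarnings(stats::vcov(fit))
    prob <- as.numeric(
      1 / (1 + exp(-(cbind(1, Xte) %*% ifelse(is.na(beta), 0, beta)))))
    metric <- c(f1 = f1Score(yte > 0.5, prob > 0.5))
  } else if (family == "robust_t") {
    fit <- tRegression(Xtr, ytr)
    beta <- fit$coef
    vc <- fit$vcov
    pred <- as.numeric(cbind(1, Xte) %*% beta)
    sst <- sum((yte - mean(ytr))^2)
    metric <- c(r2 = 1 - sum((yte - pred)^2) / sst)
  } else if (family == "gaussian") {
    dtr <- data.frame(y = ytr, Xtr)
    fit <- lm(y ~ ., data = dtr)
    beta <- coef(fit)
    vc <- stats::vcov(fit)
    pred <- as.numeric(cbind(1, Xte) %*% ifelse(is.na(beta), 0, beta))
    sst <- sum((yte - mean(ytr))^2)
    metric <- c(r2 = 1 - sum((yte - pred)^2) / sst)
  } else stop("unknown family: ", family)

  beta[is.na(beta)] <- 0
  se <- sqrt(pmax(diag(vc), 0)); se[!is.finite(se)] <- 0
  ci <- cbind(beta - 1.96 * se, beta + 1.96 * se)
  draws <- withSubstream(seed, "draws", {
    matrix(rnorm(n_draws * length(beta), rep(beta, each = n_draws),
                 rep(se, each = n_draws)), n_draws,
           dimnames = list(NULL, names(beta)))
  })
  new("GlmFit", family = family, coef = beta, ci = ci, draws = draws,
      metric = metric, trainIdx = as.integer(tr))
}

#' Contrast aligned-only vs local-only decoding
#'
#' Fits one decoder on the aligned components only and one on the local
#' components only for each requested behavior, plus a joint fit from which
#' the cumulative coefficient-magnitude ratio
#' \code{sum |beta_aligned| / sum |beta_local|} is taken.
#'
#' @param features full feature matrix from [buildFeatures()].
#' @param behavior_df data.frame of behavior columns aligned to the feature
#'   rows.
#' @param behaviors character vector of behavior column names.
#' @param epochs optional per-row epoch index; when supplied, per-epoch
#'   models are also fitted.
#' @param ... passed to [fitBehaviorGlm()].
#' @return list with \code{summary} (per behavior: aligned/local held-out
#'   metric and the coefficient ratio), \code{fits}, and optionally
#'   \code{by_epoch}.
#' @export
evaluateDecoding <- function(features, behavior_df, behaviors,
                             epochs = NULL, ...) {
  k <- ncol(features) / 2
  ac <- seq_len(k); lc <- k + seq_len(k)
  rows <- list(); fits <- list(); by_epoch <- list()
  for (bv in behaviors) {
    y <- behavior_df[[bv]]
    fa <- fitBehaviorGlm(features[, ac, drop = FALSE], y, ...)
    fl <- fitBehaviorGlm(features[, lc, drop = FALSE], y, ...)
    ff <- fitBehaviorGlm(features, y, ...)
    ratio <- sum(abs(ff@coef[1 + ac])) / max(sum(abs(ff@coef[1 + lc])), 1e-12)
    rows[[bv]] <- data.frame(behavior = bv, metric = names(fa@metric),
                             aligned = unname(fa@metric),
                             local = unname(fl@metric), coef_ratio = ratio)
    fits[[bv]] <- list(aligned = fa, local = fl, full = ff)
    if (!is.null(epochs)) {
      eps <- sort(unique(epochs))
      by_epoch[[bv]] <- do.call(rbind, lapply(eps, function(e) {
        sel <- epochs == e
        fae <- fitBehaviorGlm(features[sel, ac, drop = FALSE], y[sel], ...)
        fle <- fitBehaviorGlm(features[sel, lc, drop = FALSE], y[sel], ...)
        data.frame(behavior = bv, epoch = e, metric = names(fae@metric),
                   aligned = unname(fae@metric), local = unname(fle@metric))
      }))
    }
  }
  out <- list(summary = do.call(rbind, rows), fits = fits)
  if (length(by_epoch)) out$by_epoch <- do.call(rbind, by_epoch)
  out
}

#' Compare behavior-only, theta-only and combined models of shared activity
#'
#' For each data split (animal x epoch x behavior variable), fits the model
#' set \code{R ~ B}, \code{R ~ theta}, \code{R ~ B + theta},
#' \code{R ~ B * theta}, and a grouped-intercept variant
#' \code{R ~ B + theta + (1 | split group)} fitted on the pooled data, and
#' reports R-squared and AIC per split with the per-split winner.
#'
#' @param df data.frame with columns \code{response}, \code{theta},
#'   \code{animal}, \code{epoch}, and the behavior columns.
#' @param behaviors behavior column names (each defines its own splits).
#' @return list with \code{per_split} (split x model R2/AIC table),
#'   \code{summary} (mean R2/AIC with 95% CI per model) and \code{pooled_lmm}
#'   (the grouped-intercept fits, one per behavior).
#' @export
compareMixedModels <- function(df, behaviors = c("velocity", "idphi",
                                                 "lin_pos")) {
  fixed <- c(B = "response ~ b", theta = "response ~ theta",
             `B+theta` = "response ~ b + theta",
             `B*theta` = "response ~ b * theta")
  rows <- list(); pooled <- list()
  for (bv in behaviors) {
    dd <- df[, c("response", "theta", "animal", "epoch")]
    dd$b <- df[[bv]]
    dd <- dd[complete.cases(dd), ]
    for (a in unique(dd$animal)) for (e in sort(unique(dd$epoch))) {
      sp <- dd[dd$animal == a & dd$epoch == e, ]
      if (nrow(sp) < 10) next
      for (mn in names(fixed)) {
        fit <- lm(stats::as.formula(fixed[[mn]]), data = sp)
        rows[[length(rows) + 1]] <- data.frame(
          behavior = bv, animal = a, epoch = e, model = mn,
          r2 = summary(fit)$r.squared, aic = AIC(fit))
      }
    }
    dd$grp <- interaction(dd$animal, dd$epoch, drop = TRUE)
    pooled[[bv]] <- tryCatch(
      lme4::lmer(response ~ b + theta + (1 | grp), data = dd, REML = FALSE),
      error = function(e) {
        message("grouped fit singular/failed for ", bv, "; pooled lm used")
        lm(response ~ b + theta, data = dd)
      })
  }
  per_split <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_split, per_split$model),
    function(s) {
      ciw <- function(x) 1.96 * sd(x) / sqrt(length(x))
      data.frame(model = s$model[1], mean_r2 = mean(s$r2),
                 r2_lo = mean(s$r2) - ciw(s$r2), r2_hi = mean(s$r2) + ciw(s$r2),
                 mean_aic = mean(s$aic), aic_lo = mean(s$aic) - ciw(s$aic),
                 aic_hi = mean(s$aic) + ciw(s$aic))
    }))
  wins <- do.call(rbind, lapply(
    split(per_split, per_split[, c("behavior", "animal", "epoch")],
          drop = TRUE),
    function(s) s[which.min(s$aic), c("behavior", "animal", "epoch", "model")]))
  list(per_split = per_split, summary = summ, winners = wins,
       pooled_lmm = pooled)
}

#' Coupling of first-component communication activity to theta over epochs
#'
#' Per epoch and animal, linear models predict theta power (or coherence)
#' from the aligned and local first-component activity; \code{n_subsets}
#' random subsets are modeled per animal and the mean R2 with a 95% CI across
#' animals is reported per epoch.
#'
#' @param aligned1,local1 first-component aligned/local activity per sample.
#' @param response theta power or coherence per sample.
#' @param epoch,animal per-sample labels.
#' @param n_subsets random subsets per animal (default 10).
#' @param subset_frac fraction of an animal-epoch's samples per subset
#'   (default 0.7).
#' @param seed integer seed.
#' @return data.frame with \code{epoch, mean_r2, lo, hi}.
#' @export
rhythmCouplingOverEpochs <- function(aligned1, local1, response, epoch,
                                     animal = rep(1, length(response)),
                                     n_subsets = 10, subset_frac = 0.7,
                                     seed = 1L) {
  dd <- data.frame(a = aligned1, l = local1, y = response, epoch = epoch,
                   animal = animal)
  rows <- list()
  for (e in sort(unique(dd$epoch))) {
    r2_by_animal <- c()
    for (an in unique(dd$animal)) {
      sub <- dd[dd$epoch == e & dd$animal == an, ]
      if (nrow(sub) < 10) next
      r2s <- withSubstream(substreamSeed(seed, paste(e, an)), "subsets", {
        vapply(seq_len(n_subsets), function(i) {
          idx <- sample.int(nrow(sub), max(10, floor(subset_frac * nrow(sub))))
          summary(lm(y ~ a + l, data = sub[idx, ]))$r.squared
        }, numeric(1))
      })
      r2_by_animal <- c(r2_by_animal, mean(r2s))
    }
    ciw <- if (length(r2_by_animal) > 1)
      1.96 * sd(r2_by_animal) / sqrt(length(r2_by_animal)) else 0
    rows[[length(rows) + 1]] <- data.frame(
      epoch = e, mean_r2 = mean(r2_by_animal),
      lo = mean(r2_by_animal) - ciw, hi = mean(r2_by_animal) + ciw)
  }
  do.call(rbind, rows)
}

#' Shared-axis density contrast between high and low state windows
#'
#' Collects the aligned (and local) first-component values falling inside the
#' high vs low windows of each state variable and tests the difference of
#' means of the shared-axis distribution with a permutation test.
#'
#' @param sl a [SharedLocalSeries-class].
#' @param window_pairs named list; each element a list with [WindowSet-class]
#'   elements \code{high} and \code{low}.
#' @param component which component (default 1).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame with per-state sample counts, mean differences and
#'   permutation p values for the aligned and local axes.
#' @export
stateDensityContrast <- function(sl, window_pairs, component = 1,
                                 n_perm = 10000, seed = 1L) {
  inWindows <- function(ws) {
    if (!windowCount(ws)) return(logical(length(sl@times)))
    idx <- findInterval(sl@times, ws@start)
    idx > 0 & sl@times < ws@stop[pmax(idx, 1)]
  }
  rows <- list()
  for (st in names(window_pairs)) {
    hi <- inWindows(window_pairs[[st]]$high)
    lo <- inWindows(window_pairs[[st]]$low)
    if (!any(hi) || !any(lo)) { message("skipping ", st,
                                        ": empty window set"); next }
    a_hi <- sl@aligned[hi, component]; a_lo <- sl@aligned[lo, component]
    l_hi <- sl@local[hi, component]; l_lo <- sl@local[lo, component]
    pa <- permutationTestMeans(a_hi, a_lo, n_perm,
                               substreamSeed(seed, paste0(st, "a")))
    pl <- permutationTestMeans(l_hi, l_lo, n_perm,
                               substreamSeed(seed, paste0(st, "l")))
    rows[[length(rows) + 1]] <- data.frame(
      state = st, n_high = sum(hi), n_low = sum(lo),
      aligned_diff = pa$statistic, aligned_p = pa$p,
      local_diff = pl$statistic, local_p = pl$p)
  }
  do.call(rbind, rows)
}
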