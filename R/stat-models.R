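ols_fit <- function(y, X) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    # name an offending pair for the error message
    cc <- suppressWarnings(cor(X[, -1, drop = FALSE]))
    pair <- "predictors"
    if (!is.null(cc)) {
      cc[!is.finite(cc)] <- 0
      diag(cc) <- 0
      w <- which(abs(cc) > 0.999, arr.ind = TRUE)
      if (nrow(w) > 0) {
        pair <- paste(colnames(cc)[w[1, ]], collapse = " and ")
      }
    }
    stop("collinear design: ", pair, call. = FALSE)
  }
  beta <- qr.coef(qr_, y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  list(beta = beta, fitted = fitted, rss = rss)
}

# max log-likelihood of a normal linear model at the ML variance estimate;
# the RSS is floored so an exact fit (constant response) stays finite
ols_loglik <- function(rss, n) {
  -n / 2 * (log(2 * pi) + log(max(rss, 1e-12) / n) + 1)
}

#' Fit the trial-wise linear model with leave-one-out significance
#'
#' Ordinary least squares for a per-trial response (e.g. short-latency
#' simple-spike modulation) on the binary design
#' `response = b0 + b1*(air puff) + b2*(tone) + b3*(lick)`, assuming a
#' normal response. The p-value of each predictor comes from a
#' likelihood-ratio test of the full model against the model with that
#' predictor removed (chi-squared, 1 df).
#'
#' @param y per-trial response vector.
#' @param X data.frame or matrix of binary predictors (no intercept
#'   column; one is added).
#' @return object of class `glm_fit`: list with `beta` (intercept first),
#'   `p` (one per predictor), `r2`, `rss`, `loglik`, `n`.
#' @export
fit_glm <- function(y, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  stopifnot(nrow(X) == n, n >= ncol(X) + 2)
  Xi <- cbind(`(Intercept)` = 1, X)
  full <- ols_fit(y, Xi)
  tss <- sum((y - mean(y))^2)
  ll_full <- ols_loglik(full$rss, n)

  p <- vapply(seq_len(ncol(X)), function(j) {
    red <- ols_fit(y, Xi[, -(j + 1), drop = FALSE])
    lrt <- 2 * (ll_full - ols_loglik(red$rss, n))
    pchisq(max(0, lrt), df = 1, lower.tail = FALSE)
  }, numeric(1))
  names(p) <- colnames(X)

  structure(list(
    beta = full$beta, p = p,
    r2 = if (tss > 0) 1 - full$rss / tss else NA_real_,
    rss = full$rss, loglik = ll_full, n = n
  ), class = "glm_fit")
}

# profile log-likelihood machinery for the random-intercept model --------

# Sufficient statistics per candidate variance ratio gamma = sigma_b^2 /
# sigma^2: V = sigma^2 (I + gamma Z Z') is block diagonal, and for a group
# of size m, (I + gamma J)^-1 = I - gamma/(1 + gamma m) J with
# log det = log(1 + gamma m).
lmm_profile <- function(y, X, group, gamma) {
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  logdet <- 0
  for (g in split(seq_len(n), group)) {
    m <- length(g)
    w <- gamma / (1 + gamma * m)
    sx <- colSums(X[g, , drop = FALSE])
    sy <- sum(y[g])
    XtX <- XtX - w * tcrossprod(sx)
    Xty <- Xty - w * sx * sy
    yty <- yty - w * sy^2
    logdet <- logdet + log(1 + gamma * m)
  }
  beta <- solve(XtX, Xty)
  rss_v <- drop(yty - 2 * crossprod(beta, Xty) + crossprod(beta, XtX %*% beta))
  rss_v <- max(rss_v, 1e-12)
  sigma2 <- rss_v / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(beta = drop(beta), sigma2 = sigma2, loglik = ll, logdet = logdet)
}

lmm_ml <- function(y, X, group) {
  obj <- function(lg) lmm_profile(y, X, group, exp(lg))$loglik
  opt <- optimize(obj, interval = c(-12, 6), maximum = TRUE)
  at0 <- lmm_profile(y, X, group, 0)
  if (at0$loglik >= opt$objective) {
    gamma <- 0
    fit <- at0
  } else {
    gamma <- exp(opt$maximum)
    fit <- lmm_profile(y, X, group, gamma)
  }
  c(fit, list(gamma = gamma))
}

#' Fit a linear mixed model with a per-mouse random intercept
#'
#' Maximum-likelihood fit of
#' `coherence = b0 + b1*(air puff) + b2*(tone) + b3*(lick) + b_mouse + e`
#' with a single random intercept per group (mouse). The variance ratio
#' `gamma = sigma_b^2 / sigma^2` is profiled with a 1-D optimizer; at each
#' candidate the fixed effects solve generalized least squares in closed
#' form and the marginal likelihood is evaluated analytically (the
#' covariance is block diagonal). ML rather than REML is used throughout
#' so that leave-one-out likelihood-ratio tests on fixed effects are
#' coherent. With a single group the model falls back to [fit_glm()] with
#' a warning.
#'
#' @param y per-trial response (coherence level).
#' @param X binary design as in [fit_glm()].
#' @param group grouping factor (mouse id), length `n`.
#' @return object of class `lmm_fit`: list with `beta`, `p` (leave-one-out
#'   LRT per predictor), `sigma2` (residual variance),
#'   `random_intercept_var`, `loglik`, `r2` (squared correlation of
#'   conditional fitted values with the observations), `gamma`, `n`.
#' @export
fit_lmm <- function(y, X, group) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  group <- as.factor(group)
  n <- length(y)
  stopifnot(nrow(X) == n, length(group) == n)
  if (nlevels(droplevels(group)) < 2) {
    warning("single group: falling back to the fixed-effects model",
            call. = FALSE)
    return(fit_glm(y, X))
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) stop("collinear design", call. = FALSE)

  full <- lmm_ml(y, Xi, group)
  p <- vapply(seq_len(ncol(X)), function(j) {
    red <- lmm_ml(y, Xi[, -(j + 1), drop = FALSE], group)
    lrt <- 2 * (full$loglik - red$loglik)
    pchisq(max(0, lrt), df = 1, lower.tail = FALSE)
  }, numeric(1))
  names(p) <- colnames(X)

  # conditional fitted values: marginal fit plus BLUP of the intercepts
  marg <- drop(Xi %*% full$beta)
  resid <- y - marg
  blup <- vapply(split(resid, group), function(r) {
    m <- length(r)
    full$gamma * m / (1 + full$gamma * m) * mean(r)
  }, numeric(1))
  cond <- marg + blup[as.character(group)]
  r2 <- if (sd(cond) > 0 && sd(y) > 0) cor(cond, y)^2 else NA_real_

  structure(list(
    beta = full$beta, p = p,
    sigma2 = full$sigma2,
    random_intercept_var = full$gamma * full$sigma2,
    gamma = full$gamma, loglik = full$loglik, r2 = r2, n = n
  ), class = "lmm_fit")
}

#' Per-cell regression of lick latency on simple-spike modulation
#'
#' For each cell, a simple linear regression of single-trial lick latency
#' on single-trial short-latency simple-spike modulation; a cell is called
#' significant when its p-value beats the Bonferroni-corrected threshold
#' `alpha / n_cells` (0.05 / 30 = 0.0017 at the defaults of a 30-cell
#' population). A positive slope means more simple spikes delay licking.
#'
#' @param data list of per-cell data.frames with columns `latency` and
#'   `modulation` (>= 10 trials each), or a single such data.frame.
#' @param n_cells number of cells in the family (defaults to
#'   `length(data)`).
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with cell, slope, p, significant, sign; cells with
#'   zero-variance modulation are skipped (NA row). Attribute
#'   `threshold` carries `alpha / n_cells`.
#' @export
latency_regression <- function(data, n_cells = NULL, alpha = 0.05) {
  if (is.data.frame(data)) data <- list(data)
  if (is.null(n_cells)) n_cells <- length(data)
  thr <- alpha / n_cells
  rows <- lapply(seq_along(data), function(i) {
    d <- data[[i]]
    stopifnot(all(c("latency", "modulation") %in% names(d)))
    d <- d[complete.cases(d[, c("latency", "modulation")]), , drop = FALSE]
    if (nrow(d) < 10 || sd(d$modulation) == 0) {
      return(data.frame(cell = i, slope = NA_real_, p = NA_real_,
                        significant = NA, sign = NA_integer_))
    }
    fit <- lm(latency ~ modulation, data = d)
    sm <- summary(fit)$coefficients
    slope <- sm["modulation", "Estimate"]
    p <- sm["modulation", "Pr(>|t|)"]
    data.frame(cell = i, slope = slope, p = p, significant = p < thr,
               sign = as.integer(sign(slope)))
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Multiple-comparison correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjustment,
#' delegated to [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Cohen's d effect size
#'
#' `(mean_a - mean_b) / s_pooled` with the pooled standard deviation using
#' n-1 weights.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return unitless effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Simulate a trial-wise coherence table for mixed-model recovery
#'
#' Generates the tidy table the coherence mixed model consumes: one row
#' per trial with binary air/tone/lick predictors (cues drawn at the task's
#' 1:1:1 mix, lick probability 2/3), a mouse label, and
#' `coherence = b0 + b_air*air + b_tone*tone + b_lick*lick + b_mouse + e`
#' with Gaussian mouse intercepts and residual noise. Defaults mirror the
#' participation model of the session generator.
#'
#' @param n_trials total trials across mice.
#' @param n_mice number of mice (trials split evenly).
#' @param beta coefficients `c(b0, air, tone, lick)`.
#' @param mouse_sd SD of the per-mouse random intercept.
#' @param resid_sd residual SD of the coherence level.
#' @param seed RNG seed.
#' @return data.frame with coherence, air, tone, lick, mouse.
#' @export
simulate_coherence_table <- function(n_trials = 300, n_mice = 4,
                                     beta = c(0.28, 0.08, 0.01, 0.04),
                                     mouse_sd = 0.05, resid_sd = 0.10,
                                     seed = 1L) {
  set.seed(seed)
  cue <- sample(c("Go", "NoGo1", "NoGo2"), n_trials, replace = TRUE)
  air <- as.integer(cue %in% c("Go", "NoGo1"))
  tone <- as.integer(cue %in% c("Go", "NoGo2"))
  lick <- as.integer(runif(n_trials) < 2 / 3)
  mouse <- rep_len(paste0("m", seq_len(n_mice)), n_trials)
  b_mouse <- rnorm(n_mice, 0, mouse_sd)
  names(b_mouse) <- paste0("m", seq_len(n_mice))
  coherence <- beta[1] + beta[2] * air + beta[3] * tone + beta[4] * lick +
    b_mouse[mouse] + rnorm(n_trials, 0, resid_sd)
  data.frame(coherence = coherence, air = air, tone = tone, lick = lick,
             mouse = mouse)
}
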