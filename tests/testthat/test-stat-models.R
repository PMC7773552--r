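binary_design <- function(n, seed = 1) {
  set.seed(seed)
  cue <- sample(c("Go", "NoGo1", "NoGo2"), n, replace = TRUE)
  data.frame(air = as.integer(cue %in% c("Go", "NoGo1")),
             tone = as.integer(cue %in% c("Go", "NoGo2")),
             lick = as.integer(runif(n) < 0.5))
}

test_that("a constant response gives a pure intercept with p near 1", {
  X <- binary_design(50)
  f <- fit_glm(rep(5, 50), X)
  expect_equal(unname(f$beta), c(5, 0, 0, 0), tolerance = 1e-10)
  expect_true(all(f$p > 0.99))
})

test_that("a planted air effect is estimated and detected, others not", {
  X <- binary_design(200, seed = 2)
  set.seed(3)
  y <- 2 * X$air + rnorm(200, sd = 0.1)
  f <- fit_glm(y, X)
  expect_lt(abs(f$beta[["air"]] - 2), 0.05)
  expect_lt(f$p[["air"]], 1e-10)
  expect_gt(min(f$p[c("tone", "lick")]), 0.05)
  expect_gt(f$r2, 0.95)
})

test_that("the leave-one-out LRT matches brute-force RSS computation", {
  # 10-row hand dataset; oracle computes both RSS by explicit projection
  X <- data.frame(air = c(1, 1, 1, 0, 0, 0, 1, 0, 1, 0),
                  tone = c(1, 0, 1, 1, 0, 1, 0, 0, 0, 1),
                  lick = c(1, 1, 0, 0, 0, 1, 1, 0, 1, 0))
  y <- c(3.1, 2.8, 2.2, 1.1, 0.2, 2.0, 2.9, 0.1, 3.0, 1.2)
  f <- fit_glm(y, X)
  rss_of <- function(M) {
    M <- cbind(1, as.matrix(M))
    sum((y - M %*% solve(crossprod(M), crossprod(M, y)))^2)
  }
  n <- length(y)
  for (j in names(X)) {
    lrt <- n * log(rss_of(X[setdiff(names(X), j)]) / rss_of(X))
    expect_equal(f$p[[j]], pchisq(lrt, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # and the LRT agrees with the F-test ordering of evidence
  fstat <- ((rss_of(X[c("tone", "lick")]) - rss_of(X)) / 1) /
    (rss_of(X) / (n - 4))
  p_f <- pf(fstat, 1, n - 4, lower.tail = FALSE)
  expect_equal(f$p[["air"]] < 0.05, p_f < 0.05)
})

test_that("collinear designs are rejected with the offending pair named", {
  X <- binary_design(50, seed = 4)
  X$lick <- X$air
  expect_error(fit_glm(rnorm(50), X), "air and lick|lick and air")
})

test_that("adding an irrelevant predictor never decreases r2", {
  X <- binary_design(100, seed = 5)
  set.seed(6)
  y <- X$air + rnorm(100)
  r2_small <- fit_glm(y, X[, c("air", "tone")])$r2
  r2_full <- fit_glm(y, X)$r2
  expect_gte(r2_full, r2_small - 1e-12)
})

test_that("with no group variance the LMM reduces to OLS", {
  d <- simulate_coherence_table(n_trials = 200, mouse_sd = 0, seed = 8)
  l <- fit_lmm(d$coherence, d[, c("air", "tone", "lick")], d$mouse)
  g <- fit_glm(d$coherence, d[, c("air", "tone", "lick")])
  # the ML variance-component estimate sits near its true value of zero
  expect_lt(l$random_intercept_var, 1e-3)
  expect_equal(l$beta, g$beta, tolerance = 0.01)
  # when the boundary estimate is exactly zero the fits coincide
  if (l$random_intercept_var == 0) {
    expect_equal(l$beta, g$beta, tolerance = 1e-6)
  }
  # nesting: the LMM likelihood is never below the OLS likelihood
  expect_gte(l$loglik, g$loglik - 1e-8)
})

test_that("the LMM marginal likelihood matches a direct MVN density", {
  d <- simulate_coherence_table(n_trials = 12, n_mice = 3, seed = 9)
  X <- as.matrix(d[, c("air", "tone", "lick")])
  l <- fit_lmm(d$coherence, X, d$mouse)
  # oracle: evaluate the multivariate-normal density at the optimum via
  # an explicit covariance matrix and Cholesky solve
  Z <- outer(d$mouse, unique(d$mouse), "==") * 1
  V <- l$random_intercept_var * tcrossprod(Z) + l$sigma2 * diag(12)
  r <- d$coherence - cbind(1, X) %*% l$beta
  ch <- chol(V)
  ll <- -0.5 * (12 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                  sum(backsolve(ch, r, transpose = TRUE)^2))
  expect_equal(l$loglik, as.numeric(ll), tolerance = 1e-6)
})

test_that("the LMM agrees with an independent ML mixed-model fitter", {
  skip_if_not_installed("lme4")
  d <- simulate_coherence_table(n_trials = 300, seed = 10)
  l <- fit_lmm(d$coherence, d[, c("air", "tone", "lick")], d$mouse)
  m <- lme4::lmer(coherence ~ air + tone + lick + (1 | mouse), data = d,
                  REML = FALSE)
  expect_equal(unname(l$beta), unname(lme4::fixef(m)), tolerance = 1e-5)
  expect_equal(l$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
})

test_that("LMM parameter recovery over 20 seeds hits the planted values", {
  fits <- sapply(1:20, function(s) {
    d <- simulate_coherence_table(seed = 400 + s)
    l <- fit_lmm(d$coherence, d[, c("air", "tone", "lick")], d$mouse)
    c(lick = l$beta[["lick"]], var_ok = abs(l$random_intercept_var -
                                              0.05^2) < 0.5 * 0.05^2 + 0.002)
  })
  expect_lt(abs(mean(fits["lick", ]) - 0.04), 0.01)
})

test_that("a single group falls back to the fixed-effects model", {
  d <- simulate_coherence_table(n_trials = 60, n_mice = 1, seed = 11)
  expect_warning(l <- fit_lmm(d$coherence, d[, c("air", "tone", "lick")],
                              d$mouse), "single group")
  expect_s3_class(l, "glm_fit")
})

test_that("latency regression applies the Bonferroni family threshold", {
  set.seed(12)
  cells <- lapply(1:30, function(i) {
    mod <- rnorm(100, 0, 5)
    data.frame(modulation = mod, latency = 0.2 + rnorm(100, 0, 0.05))
  })
  out <- latency_regression(cells)
  expect_equal(attr(out, "threshold"), 0.05 / 30)
  expect_equal(signif(attr(out, "threshold"), 2), 0.0017)
  # null calibration: about alpha/n_cells of null cells cross it
  expect_lte(sum(out$significant, na.rm = TRUE), 2)

  # planted slope 2 ms per spikes/s is recovered and flagged
  set.seed(13)
  mod <- rnorm(100, 0, 5)
  planted <- data.frame(modulation = mod,
                        latency = 0.2 + 0.002 * mod + rnorm(100, 0, 0.01))
  fit1 <- latency_regression(list(planted), n_cells = 30)
  expect_lt(abs(fit1$slope - 0.002), 0.0003)
  expect_true(fit1$significant)
  expect_equal(fit1$sign, 1L)

  # zero-variance modulation is skipped, not an error
  degen <- data.frame(modulation = rep(1, 20), latency = rnorm(20))
  expect_true(is.na(latency_regression(list(degen))$slope))
})

test_that("p-value adjustment reproduces hand-computed cases", {
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bh"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.3, 5), "bonferroni"), rep(1, 5))
  p <- c(0.001, 0.02, 0.5, 0.04)
  expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
  bh <- adjust_pvalues(p, "bh")
  expect_true(all(diff(bh[order(p)]) >= 0))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's d matches pooled-SD arithmetic and sampling", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(14)
  expect_equal(cohens_d(rnorm(1e4, 1), rnorm(1e4, 0)), 1, tolerance = 0.05)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("full pipeline detects the coherence-lick coupling when planted", {
  # study-scale zones (50 dendrites) keep the binomial participation
  # noise low enough for the 0.04 lick gain to be detectable at expert
  # trial counts pooled over 4 mice
  detect_lick <- function(gain, s) {
    cfg <- session_config(n_zones = 1, rois_per_zone = 50,
                          duration_s = 500, within_zone_coherence = 0.15,
                          coherence_gain_on_lick = gain, stage = "expert",
                          evoked_prob = list(Go = 0.9, NoGo1 = 0.9,
                                             NoGo2 = 0.9),
                          seed = 600 + s)
    tabs <- lapply(1:4, function(mi) {
      cfg$seed <- cfg$seed + 1000L * mi
      b <- generate_session(cfg)
      ev <- detect_cocs_all(b$raster, rep(1L, 50),
                            frame_rate_hz = cfg$frame_rate_hz)
      al <- align_to_trials(ev, NULL, b$trials,
                            frame_rate_hz = cfg$frame_rate_hz)
      coh <- al$trial_coherence[, 1]
      keep <- !is.na(coh)
      data.frame(coherence = coh[keep],
                 air = as.integer(b$trials$cue[keep] %in% c("Go", "NoGo1")),
                 tone = as.integer(b$trials$cue[keep] %in% c("Go", "NoGo2")),
                 lick = as.integer(al$lick[keep]),
                 mouse = paste0("m", mi))
    })
    d <- do.call(rbind, tabs)
    l <- fit_lmm(d$coherence, d[, c("air", "tone", "lick")], d$mouse)
    l$p[["lick"]] < 0.05
  }
  hits <- sapply(1:10, function(s) detect_lick(0.04, s))
  nulls <- sapply(1:10, function(s) detect_lick(0, s))
  expect_gte(mean(hits), 0.8)
  expect_lte(mean(nulls), 0.2)
})
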