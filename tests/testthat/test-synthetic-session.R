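test_that("identical configurations give bit-identical sessions", {
  cfg <- tiny_config(seed = 7L)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$raster, b$raster)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_identical(a$trials, b$trials)
  expect_identical(lapply(a$spike_trains, `[[`, "times_s"),
                   lapply(b$spike_trains, `[[`, "times_s"))
})

test_that("per-ROI event rate matches the configured complex-spike rate", {
  cfg <- session_config(n_zones = 3, rois_per_zone = 20, duration_s = 300,
                        cs_rate_hz = 1.24, seed = 2L)
  b <- generate_session(cfg)
  rate <- mean(colSums(b$raster)) / cfg$duration_s
  # 60 ROIs x 300 s of thinning-model events; SE of the mean rate
  se <- sqrt(1.24 / (cfg$duration_s * ncol(b$raster)) * 10)
  expect_lt(abs(rate - 1.24), 3 * max(se, 0.02))
})

test_that("zero within-zone coherence yields uncorrelated zone members", {
  cfg <- session_config(n_zones = 2, rois_per_zone = 10, duration_s = 600,
                        within_zone_coherence = 0, evoked_prob = list(
                          Go = 0, NoGo1 = 0, NoGo2 = 0),
                        spont_bout_prob = 0, seed = 5L)
  b <- generate_session(cfg)
  cc <- cor(b$raster[, 1:10])
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.02)
})

test_that("within-zone correlation exceeds across-zone by the planted gap", {
  # participation chosen for within ~0.4 and across ~0.05 event correlation
  cfg <- session_config(n_zones = 4, rois_per_zone = 40, duration_s = 600,
                        within_zone_coherence = sqrt(0.35),
                        across_zone_coherence = sqrt(0.05),
                        evoked_prob = list(Go = 0, NoGo1 = 0, NoGo2 = 0),
                        seed = 9L)
  b <- generate_session(cfg)
  cc <- cor(b$raster)
  zone <- b$truth$zone
  same <- outer(zone, zone, "==") & upper.tri(cc)
  diff <- outer(zone, zone, "!=") & upper.tri(cc)
  expect_gte(mean(cc[same]) - mean(cc[diff]), 0.2)
})

test_that("within-zone correlation is nondecreasing in the coherence knob", {
  cors <- sapply(c(0.1, 0.4, 0.7), function(cw) {
    cfg <- session_config(n_zones = 1, rois_per_zone = 15, duration_s = 300,
                          within_zone_coherence = cw,
                          evoked_prob = list(Go = 0, NoGo1 = 0, NoGo2 = 0),
                          seed = 21L)
    b <- generate_session(cfg)
    cc <- cor(b$raster)
    mean(cc[upper.tri(cc)])
  })
  expect_true(all(diff(cors) > 0))
})

test_that("cue sequence honours the consecutive-cue cap and the trial mix", {
  cfg <- session_config(duration_s = 50010, trial_period_s = 5, seed = 3L,
                        n_zones = 1, rois_per_zone = 2)
  set.seed(cfg$seed)
  frame <- cocs:::draw_trial_frame(cfg)   # 10,001 trials
  r <- rle(frame$cue)
  expect_lte(max(r$lengths), 3)
  freqs <- table(frame$cue) / nrow(frame)
  expect_true(all(abs(freqs - 1 / 3) < 0.01))
})

test_that("lick latencies follow the configured set-points", {
  cfg <- session_config(duration_s = 3000, trial_period_s = 5,
                        opto_fraction = 0.5, seed = 8L,
                        n_zones = 1, rois_per_zone = 2)
  tr <- generate_behavior(cfg)
  hit <- tr$outcome == "Hit" & !tr$opto
  hit_s <- tr$outcome == "Hit" & tr$opto & tr$first_lick_latency_s < 0.5
  expect_lt(abs(mean(tr$first_lick_latency_s[hit]) - 0.21), 0.02)
  expect_lt(abs(mean(tr$first_lick_latency_s[hit_s]) - 0.36), 0.03)
  # opto delays and abolishes licks
  expect_lt(mean(tr$outcome[tr$cue == "Go" & tr$opto] == "Hit"),
            mean(tr$outcome[tr$cue == "Go" & !tr$opto] == "Hit"))
})

test_that("zero lick probability yields only Miss and CR trials", {
  cfg <- tiny_config(lick_prob = list(Go = 0, NoGo1 = 0, NoGo2 = 0),
                     spont_bout_prob = 0)
  tr <- generate_behavior(cfg)
  expect_true(all(tr$outcome %in% c("Miss", "CR1", "CR2")))
})

test_that("fluorescence synthesis follows the calcium kernel exactly", {
  cfg <- tiny_config(noise_sd = 0, duration_s = 10, n_zones = 1,
                     rois_per_zone = 1)
  n <- round(cfg$duration_s * cfg$frame_rate_hz)

  empty <- matrix(0L, n, 1)
  f <- synthesize_fluorescence(empty, cfg)
  expect_equal(sd(f[, 1]), 0)

  single <- empty
  single[50, 1] <- 1L
  f1 <- synthesize_fluorescence(single, cfg)
  base <- f1[1, 1]
  fb <- attr(f1, "fb")[1]
  dffv <- (f1[, 1] - base) / (base - fb)
  expect_equal(which.max(dffv), 50)
  expect_equal(max(dffv), cfg$amp, tolerance = 1e-10)
  # decay to 1/e of the peak after tau seconds, within one frame
  k_tau <- 50 + round(cfg$tau_s * cfg$frame_rate_hz)
  expect_equal(dffv[k_tau] / dffv[50], exp(-1), tolerance = 0.15)

  # superposition: two events one frame apart equal the sum of kernels
  double <- empty
  double[c(50, 51), 1] <- 1L
  f2 <- synthesize_fluorescence(double, cfg)
  shift1 <- c(0, (f1[, 1] - base)[-n])
  expect_equal(f2[, 1] - base, (f1[, 1] - base) + shift1, tolerance = 1e-9)
})

test_that("ephys generator hits the simple-spike rate set-point", {
  cfg <- session_config(duration_s = 600, n_units = 8, seed = 4L,
                        n_zones = 1, rois_per_zone = 2)
  eph <- generate_ephys(cfg)
  ss <- Filter(function(t) t$truth == "SS", eph)
  rates <- vapply(ss, `[[`, numeric(1), "rate_hz")
  se <- sqrt(84.1 / cfg$duration_s / length(ss))
  expect_lt(abs(mean(rates) - 84.1), 3 * se)
})

test_that("pause deletion empties the post-complex-spike window", {
  cfg <- session_config(duration_s = 300, n_units = 2, seed = 6L,
                        n_zones = 1, rois_per_zone = 2)
  eph <- generate_ephys(cfg)
  ss <- eph[[1]]$times_s
  cs <- eph[[2]]$times_s
  in_pause <- vapply(cs, function(t0) any(ss > t0 & ss <= t0 + 0.010),
                     logical(1))
  expect_false(any(in_pause))

  # with the pause disabled the cross-correlogram is flat at short lags
  cfg0 <- session_config(duration_s = 600, n_units = 2, pause_s = 0,
                         seed = 6L, n_zones = 1, rois_per_zone = 2)
  eph0 <- generate_ephys(cfg0)
  p <- cs_triggered_pause(eph0[[1]]$times_s, eph0[[2]]$times_s)
  expect_gt(p$ratio, 0.8)
  expect_false(p$pause)
})

test_that("planted simple-spike modulation is recovered by counting", {
  cfg <- session_config(duration_s = 1002, trial_period_s = 5, n_units = 1,
                        ss_mod_hz = 20, seed = 12L,
                        n_zones = 1, rois_per_zone = 2)
  tr <- generate_behavior(cfg)       # 200 trials
  eph <- generate_ephys(cfg, tr)
  m <- ss_modulation(eph[[1]], tr)
  expect_lt(abs(mean(m$modulation_hz) - 20), 3)

  cfgn <- session_config(duration_s = 1002, trial_period_s = 5, n_units = 1,
                         ss_mod_hz = -30, seed = 13L,
                         n_zones = 1, rois_per_zone = 2)
  trn <- generate_behavior(cfgn)
  ephn <- generate_ephys(cfgn, trn)
  mn <- ss_modulation(ephn[[1]], trn)
  expect_lt(abs(mean(mn$modulation_hz) + 30), 3.5)
})

test_that("generator rejects invalid configurations", {
  expect_error(session_config(n_zones = 0), "at least one zone")
  expect_error(session_config(duration_s = -1))
  expect_error(session_config(within_zone_coherence = 1.2), "probability")
  expect_error(session_config(latency_model = list(
    air = list(mean = -0.1, cv = 0.2), tone = list(mean = 0.2, cv = 0.2))),
    "positive mean")
  cfg <- tiny_config()
  expect_error(synthesize_fluorescence(matrix(2, 5, 2), cfg), "binary")
})
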