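test_that("co-activation trace is the member fraction per frame", {
  r <- matrix(0L, 100, 10)
  expect_equal(coactivation_trace(r, 1:10), rep(0, 100))
  r[5, 1:7] <- 1L
  expect_equal(coactivation_trace(r, 1:10)[5], 0.7)
  expect_error(coactivation_trace(r, integer(0)), "empty zone")

  set.seed(7)
  rr <- matrix(rbinom(5000 * 10, 1, 0.04), 5000, 10)
  tr <- coactivation_trace(rr, 1:10)
  se <- sqrt(0.04 * 0.96 / (10 * 5000))
  expect_lt(abs(mean(tr) - 0.04), 3 * se)
})

test_that("CoCS detection finds standardized strict local peaks", {
  expect_warning(ev0 <- detect_cocs(rep(0.3, 50)), "zero-variance")
  expect_equal(nrow(ev0), 0)

  set.seed(8)
  tr <- pmax(0, rnorm(2000, 0.02, 0.01))
  tr[700] <- 0.9
  ev <- detect_cocs(tr, z_thresh = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_frame, 700)
  expect_equal(ev$coherence, 0.9)
  expect_gt(ev$zscore, 3)
  expect_equal(ev$peak_time_s, 699 / 30.03)

  # a plateau is stamped at its first frame
  tr2 <- rep(0.02, 300) + rnorm(300, 0, 1e-4)
  tr2[100:102] <- 0.8
  ev2 <- detect_cocs(tr2)
  expect_equal(ev2$peak_frame, 100)
})

test_that("planted coherence produces more CoCS events than independence", {
  counts <- sapply(1:20, function(s) {
    mk <- function(cw) {
      cfg <- session_config(n_zones = 1, rois_per_zone = 20,
                            duration_s = 120, within_zone_coherence = cw,
                            evoked_prob = list(Go = 0, NoGo1 = 0, NoGo2 = 0),
                            seed = 100L + s)
      b <- generate_session(cfg)
      nrow(detect_cocs(coactivation_trace(b$raster, 1:20)))
    }
    c(indep = mk(0), coh = mk(0.6))
  })
  expect_true(all(counts["coh", ] > counts["indep", ]))
})

test_that("coherence of detected events exceeds the trace mean", {
  cfg <- session_config(n_zones = 1, rois_per_zone = 20, duration_s = 120,
                        seed = 41L)
  b <- generate_session(cfg)
  tr <- coactivation_trace(b$raster, 1:20)
  ev <- detect_cocs(tr)
  expect_true(all(ev$coherence <= 1))
  expect_true(all(ev$coherence > mean(tr)))
})

test_that("trial alignment counts planted events at the right probability", {
  # hand-built: 20 Go trials, events planted inside the window on 15
  trials <- make_trials(rep("Go", 20), as.list(1 + (0:19) * 5 + 0.2))
  fr <- 30.03
  ev_times <- align_event_time(trials$cue_onset_s[1:15], fr) + 0.1
  events <- data.frame(zone_id = 1,
                       peak_frame = round(ev_times * fr) + 1,
                       peak_time_s = ev_times,
                       coherence = 0.5, zscore = 5)
  al <- align_to_trials(events, NULL, trials, fr)
  expect_equal(al$zone_prob["zone1", "Hit"], 0.75)

  # no events anywhere: all probabilities zero
  al0 <- align_to_trials(events[0, ], NULL, trials, fr)
  expect_true(all(is.na(al0$zone_prob)) || all(al0$zone_prob == 0,
                                               na.rm = TRUE))

  # window monotonicity: a larger window can only add trials
  al2 <- align_to_trials(events, NULL, trials, fr, window_s = 0.5)
  expect_true(all(al2$zone_prob["zone1", "Hit"] >=
                    al$zone_prob["zone1", "Hit"]))
})

test_that("alignment conserves licking trials across CoCS groups", {
  cfg <- session_config(n_zones = 2, rois_per_zone = 15, duration_s = 300,
                        seed = 43L)
  b <- generate_session(cfg)
  ev <- detect_cocs_all(b$raster, rep(1:2, each = 15),
                        frame_rate_hz = cfg$frame_rate_hz)
  al <- align_to_trials(ev, b$raster, b$trials,
                        frame_rate_hz = cfg$frame_rate_hz)
  sp <- split_by_cocs(al, b$trials, zone = 1, min_per_group = 7)
  n_licking_ok <- sum(b$trials$outcome %in% c("Hit", "FA1", "FA2") &
                        !is.na(al$trial_flags[, 1]))
  expect_equal(sp$n_plus + sp$n_minus, n_licking_ok)
})

test_that("a generator-coupled lick probability difference is recovered", {
  diffs <- sapply(1:20, function(s) {
    # low background coherence + strong evoked participation, so that
    # window CoCS events are (almost) exactly the planted ones
    cfg <- session_config(n_zones = 1, rois_per_zone = 20,
                          duration_s = 500, lick_coupling_delta = 0.3,
                          within_zone_coherence = 0.15,
                          participation = list(base = 0.5, air = 0,
                                               tone = 0),
                          lick_prob = list(Go = 0.5, NoGo1 = 0.5,
                                           NoGo2 = 0.5),
                          evoked_prob = list(Go = 0.5, NoGo1 = 0.5,
                                             NoGo2 = 0.5),
                          seed = 200L + s)
    b <- generate_session(cfg)
    ev <- detect_cocs_all(b$raster, rep(1L, 20),
                          frame_rate_hz = cfg$frame_rate_hz)
    al <- align_to_trials(ev, NULL, b$trials,
                          frame_rate_hz = cfg$frame_rate_hz)
    sp <- split_by_cocs(al, b$trials, zone = 1)
    sp$lick_prob_plus - sp$lick_prob_minus
  })
  expect_lt(abs(mean(diffs) - 0.3), 0.1)
})

test_that("coherence-linked residual shrinkage shows up in CoCS+ trials", {
  wins <- sapply(1:20, function(s) {
    cfg <- session_config(n_zones = 1, rois_per_zone = 20,
                          duration_s = 500, residual_shrink_on_cocs = 0.4,
                          evoked_prob = list(Go = 0.6, NoGo1 = 0.6,
                                             NoGo2 = 0.6),
                          seed = 300L + s)
    b <- generate_session(cfg)
    ev <- detect_cocs_all(b$raster, rep(1L, 20),
                          frame_rate_hz = cfg$frame_rate_hz)
    al <- align_to_trials(ev, NULL, b$trials,
                          frame_rate_hz = cfg$frame_rate_hz)
    sp <- split_by_cocs(al, b$trials, zone = 1)
    sp$residual_plus < sp$residual_minus
  })
  expect_gte(sum(wins), 18)
})

test_that("sessions without both CoCS groups are flagged and excluded", {
  trials <- make_trials(rep("Go", 10), as.list(1 + (0:9) * 5 + 0.2))
  fr <- 30.03
  ev_times <- align_event_time(trials$cue_onset_s, fr) + 0.1
  events <- data.frame(zone_id = 1, peak_frame = round(ev_times * fr) + 1,
                       peak_time_s = ev_times, coherence = 0.5, zscore = 5)
  al <- align_to_trials(events, NULL, trials, fr)
  sp <- split_by_cocs(al, trials, zone = 1)
  expect_equal(sp$n_minus, 0)
  expect_false(sp$included)
})

test_that("independent-raster CoCS rate matches a brute-force oracle", {
  # the oracle applies the standardize / strict-local-max / z >= 3 rule by
  # a plain frame loop, independently of the vectorized implementation
  oracle_count <- function(tr) {
    mu <- mean(tr); s <- sd(tr)
    cnt <- 0
    for (t in 2:(length(tr) - 1)) {
      if (tr[t] > tr[t - 1] && tr[t] >= tr[t + 1] &&
          (tr[t] - mu) / s >= 3) cnt <- cnt + 1
    }
    cnt
  }
  set.seed(77)
  impl <- 0; orac <- 0
  for (s in 1:50) {
    rr <- matrix(rbinom(2000 * 20, 1, 0.04), 2000, 20)
    tr <- coactivation_trace(rr, 1:20)
    impl <- impl + nrow(detect_cocs(tr))
    orac <- orac + oracle_count(tr)
  }
  expect_gt(orac, 0)
  expect_lt(abs(log2(impl / orac)), 1)  # within a factor of 2
})
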