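#' Construct a spike train
#'
#' @param unit_id unit identifier (character or integer).
#' @param times_s spike times in seconds; sorted, duplicates removed.
#' @param label `"SS"`, `"CS"` or `"unknown"`.
#' @param duration_s recording duration (s); defaults to the last spike.
#' @param paired_unit optional id of the paired unit (SS <-> CS of the same
#'   Purkinje cell).
#' @param truth optional ground-truth label kept for recovery tests.
#' @return object of class `spike_train` with a derived `rate_hz`.
#' @export
spike_train <- function(unit_id, times_s, label = "unknown",
                        duration_s = NULL, paired_unit = NA_character_,
                        truth = NA_character_) {
  times_s <- sort(unique(as.numeric(times_s)))
  if (any(times_s < 0)) stop("spike times must be non-negative")
  if (is.null(duration_s)) {
    duration_s <- if (length(times_s)) max(times_s) else 0
  }
  structure(list(
    unit_id = as.character(unit_id), times_s = times_s,
    label = match.arg(label, c("SS", "CS", "unknown")),
    duration_s = duration_s,
    rate_hz = if (duration_s > 0) length(times_s) / duration_s else NA_real_,
    paired_unit = as.character(paired_unit), truth = truth
  ), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s> %d spikes, %.1f Hz, label %s\n",
              x$unit_id, length(x$times_s), x$rate_hz, x$label))
  invisible(x)
}

# rate of `ss` in a window relative to each spike of `cs`, spikes/s
ccg_rate <- function(ss, cs, from_s, to_s) {
  if (length(cs) == 0 || to_s <= from_s) return(NA_real_)
  cnt <- sum(vapply(cs, function(t0) {
    sum(ss >= t0 + from_s & ss < t0 + to_s)
  }, numeric(1)))
  cnt / (length(cs) * (to_s - from_s))
}

#' Simple-spike pause after complex spikes
#'
#' Cross-correlogram test for the characteristic post-complex-spike pause:
#' the SS rate in the 0-10 ms bin after CS spikes is compared with the SS
#' rate in the -50 to -10 ms baseline bins.
#'
#' @param ss,cs spike time vectors (s).
#' @param pause_window_s pause bin (default `c(0, 0.010)`).
#' @param base_window_s baseline bins (default `c(-0.050, -0.010)`).
#' @return list with `ratio` (pause rate / baseline rate; `NA` when either
#'   is undefined) and `pause` (`TRUE` when ratio < 0.5).
#' @export
cs_triggered_pause <- function(ss, cs, pause_window_s = c(0, 0.010),
                               base_window_s = c(-0.050, -0.010)) {
  r_pause <- ccg_rate(ss, cs, pause_window_s[1], pause_window_s[2])
  r_base <- ccg_rate(ss, cs, base_window_s[1], base_window_s[2])
  if (!is.finite(r_pause) || !is.finite(r_base) || r_base == 0) {
    return(list(ratio = NA_real_, pause = FALSE))
  }
  ratio <- r_pause / r_base
  list(ratio = ratio, pause = ratio < 0.5)
}

#' Classify units into simple-spike and complex-spike clusters
#'
#' Rate-based heuristics: units firing above 40 spikes/s are simple-spike
#' (SS) clusters; units at 25-40 spikes/s are rescued as SS only when they
#' show a post-complex-spike pause against some CS candidate; units in the
#' 0.5-3 spikes/s band are complex-spike (CS) clusters when a pause-showing
#' SS partner exists; everything else is `unknown`. Paired units share the
#' strongest pause.
#'
#' @param trains list of [spike_train()] objects.
#' @param ss_rate_min rate above which a unit is SS outright (40 Hz).
#' @param ss_rescue_min lower rate bound for pause-rescued SS (25 Hz).
#' @param cs_band CS rate band (default `c(0.5, 3)` Hz).
#' @param pause_ratio_max CCG pause/baseline ratio below which a pause is
#'   called (default 0.5).
#' @return the list with `label` and `paired_unit` filled in.
#' @export
classify_units <- function(trains, ss_rate_min = 40, ss_rescue_min = 25,
                           cs_band = c(0.5, 3), pause_ratio_max = 0.5) {
  stopifnot(length(trains) >= 1)
  if (any(vapply(trains, function(t) t$duration_s, numeric(1)) < 60)) {
    warning("recording shorter than 60 s: rates are unstable",
            call. = FALSE)
  }
  rates <- vapply(trains, function(t) t$rate_hz, numeric(1))
  labels <- rep("unknown", length(trains))
  labels[rates > ss_rate_min] <- "SS"
  cs_cand <- which(rates >= cs_band[1] & rates <= cs_band[2])
  ss_pending <- which(rates > ss_rescue_min & rates <= ss_rate_min)

  paired <- rep(NA_character_, length(trains))
  for (ci in cs_cand) {
    ratios <- vapply(c(which(labels == "SS"), ss_pending), function(si) {
      if (si == ci) return(NA_real_)
      cs_triggered_pause(trains[[si]]$times_s, trains[[ci]]$times_s)$ratio
    }, numeric(1))
    partners <- c(which(labels == "SS"), ss_pending)
    good <- which(is.finite(ratios) & ratios < pause_ratio_max)
    if (length(good) > 0) {
      best <- partners[good[which.min(ratios[good])]]
      labels[ci] <- "CS"
      labels[best] <- "SS"
      paired[ci] <- trains[[best]]$unit_id
      paired[best] <- trains[[ci]]$unit_id
    }
  }
  for (i in seq_along(trains)) {
    trains[[i]]$label <- labels[i]
    trains[[i]]$paired_unit <- paired[i]
  }
  trains
}

#' Trial-aligned simple-spike rate modulation
#'
#' Per trial, the modulation is the firing rate in the response window
#' minus the rate in the baseline window (spikes/s). The default response
#' window (0-100 ms from cue onset) precedes the earliest licks, so the
#' modulation is sensory/initiation-related rather than movement feedback.
#' With `align = "lick"` the windows are taken relative to the first lick
#' (pre-lick modulation, response window -100 to 0 ms); non-licking trials
#' are aligned to the mean first-lick latency of the matching licking
#' trial type so they can enter a lick predictor.
#'
#' @param train a [spike_train()].
#' @param trials classified trial table.
#' @param resp_window response window in seconds relative to the alignment
#'   point (default `c(0, 0.1)`; use `c(-0.1, 0)` for `align = "lick"`).
#' @param base_window baseline window (default `c(-0.5, 0)` relative to the
#'   cue).
#' @param align `"cue"` or `"lick"`.
#' @param z_window window of the z-scored rate trace returned for heatmaps
#'   (default -100 to +200 ms in 10-ms bins).
#' @return data.frame with trial_id, outcome, modulation_hz (trials whose
#'   windows leave the recording are dropped); attribute `z_trace` carries
#'   the trial-averaged z-scored rate trace.
#' @export
ss_modulation <- function(train, trials, resp_window = c(0, 0.1),
                          base_window = c(-0.5, 0),
                          align = c("cue", "lick"),
                          z_window = c(-0.1, 0.2)) {
  align <- match.arg(align)
  st <- train$times_s
  dur <- train$duration_s

  ref <- trials$cue_onset_s
  if (align == "lick") {
    lat <- trials$first_lick_latency_s
    # align non-licking trials to the mean latency of the matching type
    mean_lat <- c(Go = mean(lat[trials$outcome == "Hit"], na.rm = TRUE),
                  NoGo1 = mean(lat[trials$outcome == "FA1"], na.rm = TRUE),
                  NoGo2 = mean(lat[trials$outcome == "FA2"], na.rm = TRUE))
    fill <- mean_lat[trials$cue]
    lat[is.na(lat)] <- fill[is.na(lat)]
    ref <- ref + lat
  }

  keep <- is.finite(ref) &
    ref + min(resp_window, base_window) >= 0 &
    ref + max(resp_window, base_window) <= dur
  ref_k <- ref[keep]
  rate_in <- function(w) {
    vapply(ref_k, function(r) {
      sum(st >= r + w[1] & st < r + w[2]) / (w[2] - w[1])
    }, numeric(1))
  }
  mod <- rate_in(resp_window) - rate_in(base_window)

  # z-scored rate trace in 10-ms bins for heatmaps
  bins <- seq(z_window[1], z_window[2], by = 0.01)
  nb <- length(bins) - 1
  cnt <- vapply(ref_k, function(r) {
    rel <- st[st >= r + z_window[1] & st < r + z_window[2]] - r
    tabulate(findInterval(rel, bins), nb)
  }, numeric(nb))
  avg <- if (length(ref_k)) rowMeans(matrix(cnt, nrow = nb)) / 0.01
         else numeric(0)
  z_trace <- if (length(avg) && sd(avg) > 0) (avg - mean(avg)) / sd(avg)
             else avg * 0

  out <- data.frame(trial_id = trials$trial_id[keep],
                    outcome = trials$outcome[keep],
                    modulation_hz = mod)
  attr(out, "z_trace") <- z_trace
  attr(out, "dropped") <- trials$trial_id[!keep]
  out
}

#' Millisecond complex-spike synchrony with a per-trial permutation null
#'
#' Per trial, complex spikes of all units are binned at `bin_ms` over the
#' post-cue window; the synchrony trace is the fraction of units firing in
#' each bin and the observed statistic is its peak. The null preserves each
#' unit's spike count in the window and redraws the times uniformly
#' (`n_shuffle` surrogates); a trial yields a synchrony event when the
#' observed peak strictly exceeds the 97.5th percentile of the surrogate
#' peaks. Ties at the percentile therefore never count, which makes the
#' test conservative when spikes are sparse.
#'
#' @param cs_trains list of at least 2 CS [spike_train()] objects.
#' @param trials classified trial table.
#' @param window window after cue onset in seconds (default `c(0, 0.05)`).
#' @param bin_ms bin width in milliseconds (default 1).
#' @param n_shuffle surrogates per trial (default 1000).
#' @param percentile surrogate percentile defining the threshold (97.5).
#' @return data.frame with one row per analysed trial: trial_id, outcome,
#'   peak_sync (fraction of units in the best bin), threshold,
#'   significant. Trials without spikes in the window have peak 0.
#' @export
synchrony_events <- function(cs_trains, trials, window = c(0, 0.05),
                             bin_ms = 1, n_shuffle = 1000,
                             percentile = 97.5) {
  stopifnot(length(cs_trains) >= 2)
  n_units <- length(cs_trains)
  n_bins <- round((window[2] - window[1]) * 1000 / bin_ms)
  stopifnot(n_bins >= 1)

  res <- lapply(seq_len(nrow(trials)), function(i) {
    t0 <- trials$cue_onset_s[i] + window[1]
    t1 <- trials$cue_onset_s[i] + window[2]
    unit <- integer(0)
    bin <- integer(0)
    for (u in seq_len(n_units)) {
      sp <- cs_trains[[u]]$times_s
      sp <- sp[sp >= t0 & sp < t1]
      if (length(sp)) {
        unit <- c(unit, rep(u, length(sp)))
        bin <- c(bin, pmin(n_bins, floor((sp - t0) * 1000 / bin_ms) + 1L))
      }
    }
    n_sp <- length(bin)
    peak_units <- function(u, b) {
      keep <- !duplicated(u * (n_bins + 1L) + b)
      max(tabulate(b[keep], n_bins))
    }
    obs <- if (n_sp) peak_units(unit, bin) / n_units else 0

    if (n_sp < 2 || length(unique(unit)) < 2) {
      # peak is invariant under the shuffle: never significant
      thr <- obs
      sig <- FALSE
    } else {
      peaks <- vapply(seq_len(n_shuffle), function(s) {
        peak_units(unit, sample.int(n_bins, n_sp, replace = TRUE))
      }, numeric(1)) / n_units
      thr <- quantile(peaks, percentile / 100, names = FALSE, type = 7)
      sig <- obs > thr
    }
    data.frame(trial_id = trials$trial_id[i], outcome = trials$outcome[i],
               peak_sync = obs, threshold = thr, significant = sig)
  })
  do.call(rbind, res)
}

#' Shift-predictor-corrected joint peri-stimulus time histogram
#'
#' For a pair of complex-spike trains, bins each trial at `bin_ms` over
#' `window` around the cue, forms the trial-averaged joint histogram,
#' subtracts the outer product of the marginal PSTHs (the predictor
#' expected under independence), and normalizes each cell by the product
#' of the bin-wise standard deviations across trials. Cells with a
#' zero-variance margin are `NA`. The main diagonal is the synchrony time
#' course.
#'
#' @param train_a,train_b [spike_train()] objects.
#' @param trials classified trial table (>= 10 trials recommended).
#' @param window window around cue onset in seconds (default `c(0, 0.25)`).
#' @param bin_ms bin width (default 5 ms).
#' @return list with `jpsth` (bins x bins matrix), `psth_a`, `psth_b`
#'   (spikes/s), `diagonal`, `bin_centers_s`.
#' @export
jpsth <- function(train_a, train_b, trials, window = c(0, 0.25),
                  bin_ms = 5) {
  n_bins <- round((window[2] - window[1]) * 1000 / bin_ms)
  stopifnot(n_bins >= 1)
  binize <- function(st, t0) {
    x <- integer(n_bins)
    sp <- st[st >= t0 + window[1] & st < t0 + window[2]]
    if (length(sp)) {
      idx <- pmin(n_bins, floor((sp - t0 - window[1]) * 1000 / bin_ms) + 1L)
      x[unique(idx)] <- 1L  # binary per bin
    }
    x
  }
  A <- t(vapply(trials$cue_onset_s, function(t0) binize(train_a$times_s, t0),
                integer(n_bins)))
  B <- t(vapply(trials$cue_onset_s, function(t0) binize(train_b$times_s, t0),
                integer(n_bins)))
  n_tr <- nrow(A)
  raw <- crossprod(A, B) / n_tr          # E[a_i b_j] over trials
  pa <- colMeans(A)
  pb <- colMeans(B)
  pred <- outer(pa, pb)
  # population moments so a pair of identical trains normalizes to 1
  sda <- sqrt(pmax(0, colMeans(A^2) - pa^2))
  sdb <- sqrt(pmax(0, colMeans(B^2) - pb^2))
  denom <- outer(sda, sdb)
  corr <- (raw - pred) / denom
  corr[denom == 0] <- NA_real_
  bw <- bin_ms / 1000
  list(jpsth = corr,
       psth_a = pa / bw, psth_b = pb / bw,
       diagonal = diag(corr),
       bin_centers_s = window[1] + (seq_len(n_bins) - 0.5) * bw)
}

#' Average JPSTH over a set of complex-spike pairs
#'
#' @param trains list of CS [spike_train()] objects.
#' @param trials classified trial table.
#' @param ... passed to [jpsth()].
#' @return list with the pairwise-averaged `jpsth`, `diagonal`,
#'   `bin_centers_s`, `n_pairs`.
#' @export
jpsth_pairs <- function(trains, trials, ...) {
  n <- length(trains)
  stopifnot(n >= 2)
  acc <- NULL
  cnt <- NULL
  centers <- NULL
  n_pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jj <- jpsth(trains[[i]], trains[[j]], trials, ...)
      m <- jj$jpsth
      if (is.null(acc)) {
        acc <- matrix(0, nrow(m), ncol(m))
        cnt <- matrix(0, nrow(m), ncol(m))
        centers <- jj$bin_centers_s
      }
      ok <- is.finite(m)
      acc[ok] <- acc[ok] + m[ok]
      cnt[ok] <- cnt[ok] + 1
      n_pairs <- n_pairs + 1
    }
  }
  avg <- acc / cnt
  avg[cnt == 0] <- NA_real_
  list(jpsth = avg, diagonal = diag(avg), bin_centers_s = centers,
       n_pairs = n_pairs)
}
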