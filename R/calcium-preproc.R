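#' Rolling-percentile baseline of a fluorescence trace
#'
#' For every frame `t`, the baseline `F0(t)` is the `percentile`-th
#' percentile (linear-interpolation convention, i.e. R's default type-7
#' quantile) of the raw trace over frames `[t - half_window, t +
#' half_window]` (31 frames at the defaults), truncated to shorter windows
#' at the trace ends.
#'
#' @param x numeric trace.
#' @param percentile percentile rank in (0, 100); default 8.
#' @param half_window half window length in frames; default 15.
#' @return numeric baseline trace of the same length.
#' @export
rolling_percentile <- function(x, percentile = 8, half_window = 15) {
  stopifnot(length(x) >= 1, percentile > 0, percentile < 100,
            half_window >= 0)
  n <- length(x)
  p <- percentile / 100
  vapply(seq_len(n), function(t) {
    w <- x[max(1, t - half_window):min(n, t + half_window)]
    quantile(w, p, names = FALSE, type = 7)
  }, numeric(1))
}

#' Baseline-normalized fluorescence (dF/F)
#'
#' Computes `(F - F0) / (F0 - Fb)` where `F0` is the rolling 8th-percentile
#' baseline over a 31-frame window (about 1 s at 30.03 frames/s) and `Fb`
#' is the floor fluorescence of the field. The normalisation is invariant
#' to adding a constant to both `F` and `Fb`.
#'
#' @param f numeric trace (one ROI) or frames x ROIs matrix.
#' @param fb floor fluorescence; scalar or one value per ROI.
#' @param percentile,half_window baseline parameters; see
#'   [rolling_percentile()].
#' @return dF/F trace or matrix of the same shape.
#' @export
dff <- function(f, fb = 0, percentile = 8, half_window = 15) {
  if (is.matrix(f)) {
    fb <- rep_len(fb, ncol(f))
    out <- f
    for (j in seq_len(ncol(f))) {
      out[, j] <- dff(f[, j], fb[j], percentile, half_window)
    }
    return(out)
  }
  f0 <- rolling_percentile(f, percentile, half_window)
  denom <- f0 - fb
  bad <- which(denom <= 0)
  if (length(bad) > 0) {
    stop(sprintf("baseline does not exceed the floor (F0 <= Fb) at frame %d",
                 bad[1]), call. = FALSE)
  }
  (f - f0) / denom
}

#' Parameters of the exponential-kernel event detector
#'
#' @param tau_s indicator decay constant (s).
#' @param amp unitary event amplitude in dF/F units.
#' @param dt_s frame interval (s); default 1/30.03.
#' @param accept_fraction fraction of `amp` the fitted amplitude must reach
#'   for an event to be accepted.
#' @param z_gate noise-adaptive part of the acceptance rule: the fitted
#'   amplitude must also exceed `z_gate` robust standard deviations of the
#'   matched-filter amplitude (noise level from the MAD of the trace's
#'   first difference), so that at high noise the detector does not accept
#'   noise excursions that happen to clear the fixed amplitude gate.
#' @return list of class `event_detect_params`.
#' @export
event_detect_params <- function(tau_s = 0.15, amp = 0.65, dt_s = 1 / 30.03,
                                accept_fraction = 0.5, z_gate = 3.5) {
  stopifnot(tau_s > 0, amp > 0, dt_s > 0, accept_fraction > 0,
            accept_fraction <= 1, z_gate >= 0)
  structure(list(tau_s = tau_s, amp = amp, dt_s = dt_s,
                 accept_fraction = accept_fraction, z_gate = z_gate),
            class = "event_detect_params")
}

#' Detect complex-spike events in a dF/F trace
#'
#' Greedy template matching against the calcium kernel
#' `k(n) = amp * exp(-n * dt_s / tau_s)` (one-frame rise): the frame whose
#' least-squares kernel fit to the current residual explains the most
#' signal is located, accepted while the fitted amplitude is at least
#' `accept_fraction * amp`, the fitted kernel is subtracted, and the search
#' repeats. The amplitude is fit jointly with a local constant (the
#' template is centred within its window), which makes detection invariant
#' to the positive offset a percentile baseline leaves in dF/F traces.
#' Events detected in consecutive frames are merged and stamped at the
#' first frame of the run, and the output is binarized.
#'
#' @param x dF/F trace (finite values).
#' @param params an [event_detect_params()].
#' @return integer 0/1 vector of the same length; attribute `residual`
#'   carries the trace after subtraction of all accepted kernels.
#' @export
detect_events <- function(x, params = event_detect_params()) {
  stopifnot(all(is.finite(x)))
  n <- length(x)
  dt <- params$dt_s
  len <- max(2, min(n, ceiling(params$tau_s / dt * log(1000)) + 1))
  kern <- params$amp * exp(-(seq_len(len) - 1) * dt / params$tau_s)
  kc <- kern - mean(kern)          # offset-invariant matched template
  kk <- sum(kc^2)
  # cross-correlation of the raw kernel with the centred template at lags
  # -(len-1)..(len-1), used to update scores after a subtraction
  ack <- vapply(-(len - 1):(len - 1), function(d) {
    j <- seq_len(len)
    ok <- j + d >= 1 & j + d <= len
    sum(kc[j[ok]] * kern[j[ok] + d])
  }, numeric(1))

  xp <- c(x, rep(0, len))
  score <- numeric(n)
  for (j in seq_len(len)) {
    score <- score + kc[j] * xp[j:(n + j - 1)]
  }

  # `a` is the fitted multiple of the unitary kernel, so the acceptance
  # gate "fitted dF/F amplitude >= accept_fraction * amp" reads a >=
  # accept_fraction; the noise gate adds z_gate robust SDs of a, with the
  # noise level taken from the first difference of the trace (robust to
  # the sparse transients themselves)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  sd_a <- sigma / sqrt(kk)
  min_amp <- max(params$accept_fraction,
                 (params$z_gate %||% 0) * sd_a)
  events <- integer(0)
  resid <- x
  for (iter in seq_len(n)) {
    t0 <- which.max(score)
    a <- score[t0] / kk
    if (a < min_amp) break
    events <- c(events, t0)
    idx <- t0:min(n, t0 + len - 1)
    resid[idx] <- resid[idx] - a * kern[seq_along(idx)]
    lo <- max(1, t0 - len + 1)
    hi <- min(n, t0 + len - 1)
    score[lo:hi] <- score[lo:hi] - a * ack[(lo:hi) - t0 + len]
  }

  out <- integer(n)
  if (length(events) > 0) {
    ev <- sort(unique(events))
    first <- ev[c(TRUE, diff(ev) > 1)]  # merge consecutive-frame runs
    out[first] <- 1L
  }
  attr(out, "event_frames") <- sort(unique(events))
  attr(out, "residual") <- resid
  out
}

#' Detect events in every column of a dF/F matrix
#'
#' @param dmat frames x ROIs dF/F matrix.
#' @param params an [event_detect_params()].
#' @return binary matrix of the same shape.
#' @export
detect_events_matrix <- function(dmat, params = event_detect_params()) {
  out <- matrix(0L, nrow(dmat), ncol(dmat))
  for (j in seq_len(ncol(dmat))) {
    out[, j] <- as.integer(detect_events(dmat[, j], params))
  }
  attr(out, "frame_rate_hz") <- 1 / params$dt_s
  out
}

#' Merge over-segmented dendritic ROIs
#'
#' Iteratively merges the pair of ROIs with the highest trace correlation
#' among pairs whose centroids are within `dist_um` and whose correlation
#' is at least `corr_min`, replacing the pair by a pixel-count-weighted
#' average (trace and centroid), until no pair qualifies. Ties are broken
#' by the lowest ROI index. Default thresholds (10 um, 0.6) sit inside the
#' ranges used in practice (5-20 um, 0.5-0.75).
#'
#' @param roi_table data.frame with `roi_id`, `ml_um`, `ap_um`, `n_pixels`.
#' @param traces frames x ROIs fluorescence matrix (columns follow
#'   `roi_table` rows).
#' @param dist_um centroid distance threshold (um).
#' @param corr_min correlation threshold.
#' @return list with merged `roi_table` (extra column `n_merged`) and
#'   `traces`.
#' @export
merge_rois <- function(roi_table, traces, dist_um = 10, corr_min = 0.6) {
  stopifnot(nrow(roi_table) == ncol(traces))
  tab <- roi_table
  tab$n_merged <- 1L
  tr <- traces
  repeat {
    m <- nrow(tab)
    if (m < 2) break
    cc <- suppressWarnings(cor(tr))
    dx <- outer(tab$ml_um, tab$ml_um, "-")
    dy <- outer(tab$ap_um, tab$ap_um, "-")
    dist <- sqrt(dx^2 + dy^2)
    ok <- !is.na(cc) & cc >= corr_min & dist <= dist_um
    ok[lower.tri(ok, diag = TRUE)] <- FALSE
    if (!any(ok)) break
    cand <- which(ok, arr.ind = TRUE)
    best <- cand[order(-cc[cand], cand[, 1], cand[, 2])[1], ]
    i <- best[1]; j <- best[2]
    wi <- tab$n_pixels[i]; wj <- tab$n_pixels[j]
    w <- c(wi, wj) / (wi + wj)
    tr[, i] <- w[1] * tr[, i] + w[2] * tr[, j]
    tab$ml_um[i] <- w[1] * tab$ml_um[i] + w[2] * tab$ml_um[j]
    tab$ap_um[i] <- w[1] * tab$ap_um[i] + w[2] * tab$ap_um[j]
    tab$n_pixels[i] <- wi + wj
    tab$n_merged[i] <- tab$n_merged[i] + tab$n_merged[j]
    tab <- tab[-j, , drop = FALSE]
    tr <- tr[, -j, drop = FALSE]
  }
  rownames(tab) <- NULL
  list(roi_table = tab, traces = tr)
}
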