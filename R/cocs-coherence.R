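#' Co-activation trace of a zone
#'
#' Per frame, the fraction of the zone's ROIs with a complex-spike event:
#' the population signal on which coherent complex-spike (CoCS) events are
#' detected.
#'
#' @param raster binary frames x ROIs event matrix.
#' @param members column indices of the zone's ROIs.
#' @return numeric trace in `[0, 1]`, one value per frame.
#' @export
coactivation_trace <- function(raster, members) {
  if (length(members) < 1) stop("empty zone", call. = FALSE)
  rowMeans(raster[, members, drop = FALSE])
}

#' Detect coherent complex-spike (CoCS) events
#'
#' Standardizes the co-activation trace by its full-session mean and SD and
#' reports strict local maxima (`c[t] > c[t-1]` and `c[t] >= c[t+1]`, so a
#' plateau is stamped at its first frame) with a z-score of at least
#' `z_thresh`. The coherence level of an event is the raw co-activation
#' value at its peak: the fraction of the zone's dendrites co-active in
#' that frame.
#'
#' @param trace co-activation trace (length >= 3).
#' @param z_thresh z-score threshold (default 3).
#' @param frame_rate_hz frame rate used to report peak times (frames are
#'   1-based; peak time is `(frame - 1) / frame_rate_hz`).
#' @param zone_id optional zone label stored with the events.
#' @return data.frame with zone_id, peak_frame, peak_time_s, coherence,
#'   zscore; zero rows when nothing crosses threshold. A zero-variance
#'   trace yields zero rows with a warning.
#' @export
detect_cocs <- function(trace, z_thresh = 3, frame_rate_hz = 30.03,
                        zone_id = NA_integer_) {
  stopifnot(length(trace) >= 3)
  mu <- mean(trace)
  sdv <- sd(trace)
  empty <- data.frame(zone_id = integer(0), peak_frame = integer(0),
                      peak_time_s = numeric(0), coherence = numeric(0),
                      zscore = numeric(0))
  if (sdv == 0) {
    warning("zero-variance co-activation trace: no events", call. = FALSE)
    return(empty)
  }
  n <- length(trace)
  t_ <- 2:(n - 1)
  is_peak <- trace[t_] > trace[t_ - 1] & trace[t_] >= trace[t_ + 1]
  z <- (trace[t_] - mu) / sdv
  keep <- which(is_peak & z >= z_thresh)
  if (length(keep) == 0) return(empty)
  pf <- t_[keep]
  data.frame(zone_id = zone_id, peak_frame = pf,
             peak_time_s = (pf - 1) / frame_rate_hz,
             coherence = trace[pf], zscore = z[keep])
}

#' Detect CoCS events for every zone of a partition
#'
#' @param raster binary frames x ROIs event matrix.
#' @param assignment integer zone label per ROI (column).
#' @param z_thresh z-score threshold.
#' @param frame_rate_hz imaging frame rate.
#' @return data.frame of events across zones (see [detect_cocs()]).
#' @export
detect_cocs_all <- function(raster, assignment, z_thresh = 3,
                            frame_rate_hz = 30.03) {
  zs <- sort(unique(assignment))
  out <- lapply(zs, function(z) {
    detect_cocs(coactivation_trace(raster, which(assignment == z)),
                z_thresh = z_thresh, frame_rate_hz = frame_rate_hz,
                zone_id = z)
  })
  do.call(rbind, out)
}

#' Align CoCS events and ROI events to trials
#'
#' Maps every cue onset onto the imaging frame timeline (half a frame
#' before the first frame triggered after the cue) and asks, per trial and
#' zone, whether at least one CoCS event falls in the half-open response
#' window `[cue, cue + window_s)`. Also computes the per-trial coherence
#' level (maximum event coherence in the window), a matching baseline flag
#' in `[cue - window_s, cue)`, per-zone CoCS probabilities by trial type,
#' and the per-ROI response probability (fraction of trials with at least
#' one event of that ROI in the window). Trials whose window leaves the
#' recording are skipped and listed in `skipped`.
#'
#' @param events CoCS event table from [detect_cocs_all()].
#' @param raster binary frames x ROIs event matrix (per-ROI response
#'   probability); pass `NULL` to skip.
#' @param trials classified trial table.
#' @param frame_rate_hz imaging frame rate.
#' @param window_s response window (default 0.25 s).
#' @return object of class `aligned_coherence`: list with `trial_flags`
#'   and `trial_coherence` (trials x zones matrices), `baseline_flags`,
#'   `zone_prob` (zones x trial types), `roi_response_prob`, `lick`
#'   (per-trial lick-initiation flag), `skipped`, `window_s`.
#' @export
align_to_trials <- function(events, raster, trials, frame_rate_hz = 30.03,
                            window_s = 0.25) {
  zones <- if (nrow(events) > 0) sort(unique(events$zone_id)) else integer(0)
  n_tr <- nrow(trials)
  n_frames <- if (!is.null(raster)) nrow(raster) else Inf
  dur_s <- n_frames / frame_rate_hz

  cue_al <- align_event_time(trials$cue_onset_s, frame_rate_hz)
  ok <- cue_al + window_s <= dur_s & cue_al - window_s >= 0
  skipped <- trials$trial_id[!ok]

  nz <- max(1, length(zones))
  flags <- matrix(NA, n_tr, nz,
                  dimnames = list(NULL, paste0("zone", if (length(zones))
                    zones else 1)))
  coh <- flags
  base_flags <- flags
  for (zi in seq_along(zones)) {
    ev <- events[events$zone_id == zones[zi], , drop = FALSE]
    for (i in seq_len(n_tr)) {
      if (!ok[i]) next
      inwin <- ev$peak_time_s >= cue_al[i] &
        ev$peak_time_s < cue_al[i] + window_s
      flags[i, zi] <- any(inwin)
      coh[i, zi] <- if (any(inwin)) max(ev$coherence[inwin]) else NA_real_
      base_flags[i, zi] <- any(ev$peak_time_s >= cue_al[i] - window_s &
                                 ev$peak_time_s < cue_al[i])
    }
  }

  types <- c("Hit", "Miss", "FA1", "CR1", "FA2", "CR2")
  zone_prob <- matrix(NA_real_, nz, length(types),
                      dimnames = list(colnames(flags), types))
  for (ty in types) {
    sel <- which(trials$outcome == ty & ok)
    if (length(sel) > 0) {
      zone_prob[, ty] <- colMeans(flags[sel, , drop = FALSE])
    }
  }

  roi_prob <- NULL
  if (!is.null(raster)) {
    ft <- (seq_len(n_frames) - 1) / frame_rate_hz
    sel <- which(ok)
    hit <- matrix(FALSE, length(sel), ncol(raster))
    for (k in seq_along(sel)) {
      i <- sel[k]
      fidx <- which(ft >= cue_al[i] & ft < cue_al[i] + window_s)
      hit[k, ] <- colSums(raster[fidx, , drop = FALSE]) > 0
    }
    roi_prob <- colMeans(hit)
  }

  structure(list(
    trial_flags = flags, trial_coherence = coh,
    baseline_flags = base_flags, zone_prob = zone_prob,
    roi_response_prob = roi_prob,
    lick = !is.na(trials$first_lick_latency_s),
    skipped = skipped, window_s = window_s, zones = zones
  ), class = "aligned_coherence")
}

#' Split licking trials by the presence of coherent complex spikes
#'
#' For one zone, licking trials (Hit, FA1, FA2) are divided into CoCS+ and
#' CoCS- groups; sessions where either group has fewer than `min_per_group`
#' trials are flagged and excluded from comparisons. Reports, per group,
#' the lick-initiation probability over all (analysable) trials, the mean
#' first-lick latency and the mean latency residual.
#'
#' @param aligned an [align_to_trials()] result.
#' @param trials the classified trial table used for the alignment.
#' @param zone zone id (must be in `aligned$zones`).
#' @param min_per_group minimum licking trials per group (default 7).
#' @return list with counts, `lick_prob_plus`/`minus`, `latency_plus`/
#'   `minus` (s), `residual_plus`/`minus` (percent), and `included`
#'   (FALSE when the session is excluded).
#' @export
split_by_cocs <- function(aligned, trials, zone, min_per_group = 7) {
  zi <- match(zone, aligned$zones)
  if (is.na(zi)) stop("zone not present in aligned result", call. = FALSE)
  flags <- aligned$trial_flags[, zi]
  ok <- !is.na(flags)
  licking <- trials$outcome %in% c("Hit", "FA1", "FA2")

  res <- latency_stats(trials, window_s = unique(trials$window_s)[1])
  resid <- res$residual_pct

  plus_l <- which(ok & licking & flags)
  minus_l <- which(ok & licking & !flags)
  included <- length(plus_l) >= min_per_group &&
    length(minus_l) >= min_per_group

  grp_mean <- function(x, idx) {
    if (length(idx) == 0) NA_real_ else mean(x[idx], na.rm = TRUE)
  }
  list(
    zone = zone,
    n_plus = length(plus_l), n_minus = length(minus_l),
    lick_prob_plus = grp_mean(as.numeric(licking), which(ok & flags)),
    lick_prob_minus = grp_mean(as.numeric(licking), which(ok & !flags)),
    latency_plus = grp_mean(trials$first_lick_latency_s, plus_l),
    latency_minus = grp_mean(trials$first_lick_latency_s, minus_l),
    residual_plus = grp_mean(resid, plus_l),
    residual_minus = grp_mean(resid, minus_l),
    included = included
  )
}
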