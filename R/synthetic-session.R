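#' Generate the trial frame (cues, onsets, opto flags) of a session
#'
#' Internal first stage of behaviour generation: a pseudo-randomized cue
#' sequence at the configured Go : No-go 1 : No-go 2 mix with at most
#' `max_consecutive` identical cues in a row, evenly spaced cue onsets, an
#' opto flag on a random subset of Go trials, and per-trial tone levels.
#'
#' @param config a [session_config()].
#' @return data.frame with trial_id, cue, cue_onset_s, window_s, opto,
#'   stage, tone_level_db.
#' @keywords internal
draw_trial_frame <- function(config) {
  n_trials <- floor((config$duration_s - 1.5) / config$trial_period_s)
  if (n_trials < 1) {
    stop("duration_s too short for a single trial", call. = FALSE)
  }
  lvls <- c("Go", "NoGo1", "NoGo2")
  mix <- config$trial_mix
  cap <- config$max_consecutive
  cues <- character(n_trials)
  if (sum(mix > 0) == 1) {
    cues[] <- lvls[mix > 0]
  } else {
    last <- ""
    run <- 0L
    for (i in seq_len(n_trials)) {
      repeat {
        cand <- sample(lvls, 1, prob = mix)
        if (cand != last || run < cap) break
      }
      if (cand == last) run <- run + 1L else run <- 1L
      last <- cand
      cues[i] <- cand
    }
  }
  opto <- cues == "Go" & runif(n_trials) < config$opto_fraction

  tone_level <- rep(NA_real_, n_trials)
  has_tone <- cues %in% c("Go", "NoGo2")
  tone_level[has_tone] <- max(config$tone_level_db)
  att_levels <- setdiff(config$tone_level_db, max(config$tone_level_db))
  if (length(att_levels) > 0) {
    attenuate <- has_tone & runif(n_trials) < 0.10
    tone_level[attenuate] <- sample(att_levels, sum(attenuate), replace = TRUE)
  }

  data.frame(
    trial_id = seq_len(n_trials),
    cue = cues,
    cue_onset_s = 1 + (seq_len(n_trials) - 1) * config$trial_period_s,
    window_s = config$window_s,
    opto = opto,
    stage = config$stage,
    tone_level_db = tone_level,
    stringsAsFactors = FALSE
  )
}

# Draw lick times for each trial of a trial frame. `planted` is an optional
# logical vector (one per trial): TRUE when a coherent complex-spike event is
# planted in the driver zone (zone 1), used to couple lick probability
# (lick_coupling_delta) and latency precision (residual_shrink_on_cocs) to
# the imaging ground truth.
draw_licks <- function(config, frame, planted = NULL) {
  n <- nrow(frame)
  if (is.null(planted)) planted <- rep(FALSE, n)
  stopifnot(length(planted) == n)

  cv_mult <- if (config$stage == "apprentice") config$apprentice_cv_mult else 1
  lat_par <- function(cue) {
    if (cue %in% c("Go", "NoGo1")) config$latency_model$air
    else config$latency_model$tone
  }

  lick_times <- vector("list", n)
  ref_level <- max(config$tone_level_db)
  for (i in seq_len(n)) {
    cue <- frame$cue[i]
    p_lick <- config$lick_prob[[cue]]
    if (cue %in% c("Go", "NoGo2") && !is.na(frame$tone_level_db[i])) {
      att <- ref_level - frame$tone_level_db[i]
      p_lick <- max(0, p_lick - config$tone_attenuation_slope * att)
    }
    p_lick <- min(1, p_lick + config$lick_coupling_delta * planted[i])

    will_lick <- runif(1) < p_lick
    first <- NA_real_
    if (will_lick) {
      par <- lat_par(cue)
      cv <- par$cv * cv_mult
      if (planted[i]) cv <- cv * config$residual_shrink_on_cocs
      if (frame$opto[i]) {
        u <- runif(1)
        if (u < config$opto_abolish_prob) {
          will_lick <- FALSE
        } else if (u < config$opto_abolish_prob + config$opto_delay_prob) {
          first <- runif(1, 0.5, 1.0)
        } else {
          first <- rgamma_mcv(1, config$opto_latency_mean_s, cv)
        }
      } else {
        first <- rgamma_mcv(1, par$mean, cv)
      }
    }

    licks <- numeric(0)
    if (will_lick && is.finite(first)) {
      licks <- frame$cue_onset_s[i] +
        seq(first, first + config$bout_duration_s, by = 1 / config$lick_rate_hz)
    } else if (runif(1) < config$spont_bout_prob) {
      # spontaneous bout, outside the cue window
      margin <- config$trial_period_s - config$window_s - 1.5
      if (margin > 0) {
        start <- frame$cue_onset_s[i] + config$window_s + 0.3 +
          runif(1) * margin
        licks <- start + seq(0, 1, by = 1 / config$lick_rate_hz)
      }
    }
    lick_times[[i]] <- licks
  }

  frame$lick_times <- I(lick_times)
  classify_trials(frame)
}

#' Generate a synthetic go/no-go trial table
#'
#' Draws a pseudo-randomized cue sequence (maximum of `max_consecutive`
#' identical cues in a row), first-lick latencies from a right-skewed gamma
#' distribution with modality-specific mean/CV (air-puff-containing cues are
#' faster and less variable than the tone-only cue), lick bouts, spontaneous
#' licking, and the effect of optogenetic stimulation on a subset of Go
#' trials (a mixture of abolished and delayed licks plus a shifted latency
#' mean). Trials are classified into Hit/Miss/FA/CR outcomes on the way out.
#'
#' @param config a [session_config()].
#' @return a classified trial table (see [classify_trials()]).
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(stage_seed(config, "behavior"))
  frame <- draw_trial_frame(config)
  draw_licks(config, frame)
}

# Draw the planted evoked-event table: for each trial x zone, whether a
# zone-level CS event is evoked in the 0-250 ms window and at which frame.
draw_evoked <- function(config, frame) {
  n_trials <- nrow(frame)
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    p <- config$evoked_prob[[frame$cue[i]]]
    hit <- runif(config$n_zones) < p
    if (!any(hit)) next
    offs <- runif(sum(hit)) * 0.25
    out[[i]] <- data.frame(
      trial_id = frame$trial_id[i],
      zone = which(hit),
      frame = first_frame_after(
        align_event_time(frame$cue_onset_s[i], config$frame_rate_hz) + offs,
        config$frame_rate_hz) + 1L  # 1-based frame index
    )
  }
  planted <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(planted)) {
    planted <- data.frame(trial_id = integer(0), zone = integer(0),
                          frame = integer(0))
  }
  planted
}

# Background raster from the mother-process thinning model plus planted
# evoked events with lick-dependent participation.
draw_raster <- function(config, trials, planted) {
  n_frames <- round(config$duration_s * config$frame_rate_hz)
  n_rois <- config$n_zones * config$rois_per_zone
  if (n_frames < 1 || n_rois < 1) {
    stop("raster must have at least one frame and one ROI", call. = FALSE)
  }
  p0 <- config$cs_rate_hz / config$frame_rate_hz
  cw <- config$within_zone_coherence
  cg <- config$across_zone_coherence
  p_ind <- p0 * (1 - cw - cg)

  zone_of <- rep(seq_len(config$n_zones), each = config$rois_per_zone)
  zone_mother <- matrix(runif(n_frames * config$n_zones) < p0,
                        n_frames, config$n_zones)
  global_mother <- runif(n_frames) < p0

  raster <- matrix(0L, n_frames, n_rois)
  for (j in seq_len(n_rois)) {
    ev <- (zone_mother[, zone_of[j]] & runif(n_frames) < cw) |
      (global_mother & runif(n_frames) < cg) |
      (runif(n_frames) < p_ind)
    raster[, j] <- as.integer(ev)
  }

  # evoked zone-level events
  if (nrow(planted) > 0) {
    licked <- !is.na(trials$first_lick_latency_s)
    gain <- if (config$stage == "expert") config$coherence_gain_on_lick else 0
    part <- config$participation
    for (k in seq_len(nrow(planted))) {
      tr <- planted$trial_id[k]
      cue <- trials$cue[tr]
      air <- cue %in% c("Go", "NoGo1")
      tone <- cue %in% c("Go", "NoGo2")
      p_part <- part$base + part$air * air + part$tone * tone +
        gain * licked[tr]
      p_part <- min(1, max(0, p_part))
      f <- planted$frame[k]
      if (f < 1 || f > n_frames) next
      members <- which(zone_of == planted$zone[k])
      on <- members[runif(length(members)) < p_part]
      raster[f, on] <- 1L
    }
  }
  attr(raster, "frame_rate_hz") <- config$frame_rate_hz
  raster
}

#' Synthesize raw fluorescence traces from a binary event raster
#'
#' Convolves each ROI's event train with a one-frame-rise, exponential-decay
#' kernel `exp(-t / tau_s)` and scales to raw fluorescence units:
#' `F = fb + f0_roi + f0_roi * amp * (events (*) kernel) + noise`, with
#' i.i.d. Gaussian noise of standard deviation `noise_sd * f0_roi`. The
#' floor `fb` and per-ROI baseline are recorded as attributes, so that the
#' rolling-percentile dF/F of a noiseless trace recovers events of amplitude
#' `amp`.
#'
#' @param raster binary frames x ROIs event matrix.
#' @param config a [session_config()] (uses `tau_s`, `amp`, `noise_sd`,
#'   `f0`, `fb`, `frame_rate_hz`, `seed`).
#' @return numeric frames x ROIs matrix of raw fluorescence with attributes
#'   `fb` (per-ROI floor) and `frame_rate_hz`.
#' @export
synthesize_fluorescence <- function(raster, config) {
  stopifnot(inherits(config, "session_config"))
  if (config$tau_s <= 0) stop("tau_s must be positive", call. = FALSE)
  raster <- as.matrix(raster)
  if (!all(raster %in% c(0, 1))) {
    stop("raster must be binary", call. = FALSE)
  }
  set.seed(stage_seed(config, "fluor"))
  n <- nrow(raster)
  m <- ncol(raster)
  dt <- 1 / config$frame_rate_hz
  len <- min(n, ceiling(config$tau_s / dt * log(100)) + 1)
  kern <- exp(-(seq_len(len) - 1) * dt / config$tau_s)

  sig <- matrix(0, n, m)
  for (j in seq_along(kern)) {
    idx <- j:n
    sig[idx, ] <- sig[idx, ] + kern[j] * raster[seq_len(n - j + 1), ,
                                                drop = FALSE]
  }
  f0_roi <- config$f0 * runif(m, 0.8, 1.2)
  noise <- if (config$noise_sd > 0) {
    matrix(rnorm(n * m), n, m) %*% diag(config$noise_sd * f0_roi, m)
  } else {
    0
  }
  fluo <- config$fb +
    matrix(f0_roi, n, m, byrow = TRUE) * (1 + config$amp * sig) + noise
  attr(fluo, "fb") <- rep(config$fb, m)
  attr(fluo, "frame_rate_hz") <- config$frame_rate_hz
  fluo
}

#' Generate paired simple/complex spike trains
#'
#' Simulates `n_units` Purkinje cells recorded on an electrode: a simple
#' spike (SS) train (homogeneous Poisson; the base rate is chosen so the
#' realized rate after pause deletion matches `ss_rate_hz`) and a complex
#' spike (CS) train (Poisson at `cs_rate_ephys_hz`). Simple spikes within
#' `pause_s` after each complex spike of the same cell are deleted. When a
#' trial table and a nonzero `ss_mod_hz` are supplied, each unit's SS rate
#' is additively modulated (sign and magnitude per unit) in the 0-100 ms
#' window after every cue onset.
#'
#' @param config a [session_config()].
#' @param trials optional classified trial table for cue-locked modulation.
#' @return list of `spike_train` objects (alternating SS and CS per unit,
#'   labelled `"unknown"`; see [classify_units()] for rate/pause-based
#'   labelling).
#' @export
generate_ephys <- function(config, trials = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (config$duration_s <= 0) stop("duration_s must be positive")
  set.seed(stage_seed(config, "ephys"))
  dur <- config$duration_s
  base <- config$ss_rate_hz /
    max(1e-12, 1 - config$cs_rate_ephys_hz * config$pause_s)
  mods <- rep_len(config$ss_mod_hz, config$n_units)

  trains <- list()
  for (u in seq_len(config$n_units)) {
    ss <- sort(runif(rpois(1, base * dur), 0, dur))
    cs <- sort(runif(rpois(1, config$cs_rate_ephys_hz * dur), 0, dur))
    if (!is.null(trials) && mods[u] != 0) {
      for (on in trials$cue_onset_s) {
        if (mods[u] > 0) {
          extra <- runif(rpois(1, mods[u] * 0.1), on, on + 0.1)
          ss <- c(ss, extra)
        } else {
          inwin <- ss >= on & ss < on + 0.1
          drop <- inwin & runif(length(ss)) < min(1, -mods[u] / base)
          ss <- ss[!drop]
        }
      }
      ss <- sort(ss)
    }
    if (config$pause_s > 0 && length(cs) > 0 && length(ss) > 0) {
      idx <- findInterval(ss, cs)
      paused <- idx >= 1 & (ss - cs[pmax(idx, 1)]) <= config$pause_s
      ss <- ss[!paused]
    }
    trains[[length(trains) + 1]] <-
      spike_train(sprintf("ss%02d", u), ss, duration_s = dur,
                  truth = "SS", paired_unit = sprintf("cs%02d", u))
    trains[[length(trains) + 1]] <-
      spike_train(sprintf("cs%02d", u), cs, duration_s = dur,
                  truth = "CS", paired_unit = sprintf("ss%02d", u))
  }
  trains
}

#' Generate a complete synthetic session with ground truth
#'
#' Runs all generator stages under a single seed: ROI table with
#' mediolateral coordinates forming contiguous parasagittal zones, trial
#' table with licks and outcomes, binary complex-spike event raster
#' (mother-process background coherence plus sensory-evoked zone events),
#' raw fluorescence traces, and paired simple/complex spike trains. Ground
#' truth (zone labels, planted evoked events, latency parameters) is
#' returned alongside for recovery tests.
#'
#' @param config a [session_config()].
#' @return an object of class `session_bundle`: list with `config`,
#'   `roi_table`, `trials`, `raster`, `fluorescence`, `spike_trains`,
#'   `truth`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  n_rois <- config$n_zones * config$rois_per_zone
  zone_of <- rep(seq_len(config$n_zones), each = config$rois_per_zone)
  # zone 1 is the most lateral; coordinates in um lateral from the midline
  lateral_edge <- 4150
  x <- lateral_edge - (zone_of - 1) * config$zone_width_um -
    runif(n_rois) * config$zone_width_um
  ord <- order(-x)
  roi_table <- data.frame(
    roi_id = seq_len(n_rois),
    ml_um = x[ord],
    ap_um = runif(n_rois, 0, 660),
    n_pixels = rpois(n_rois, 80) + 20L,
    zone = zone_of[ord]
  )

  set.seed(stage_seed(config, "behavior"))
  frame <- draw_trial_frame(config)
  set.seed(stage_seed(config, "raster"))
  planted <- draw_evoked(config, frame)
  set.seed(stage_seed(config, "behavior") + 1L)
  planted_z1 <- frame$trial_id %in% planted$trial_id[planted$zone == 1]
  trials <- draw_licks(config, frame, planted_z1)
  set.seed(stage_seed(config, "raster") + 1L)
  raster <- draw_raster(config, trials, planted)
  fluorescence <- synthesize_fluorescence(raster, config)
  spike_trains <- generate_ephys(config, trials)

  structure(list(
    config = config,
    roi_table = roi_table,
    trials = trials,
    raster = raster,
    fluorescence = fluorescence,
    spike_trains = spike_trains,
    truth = list(
      zone = roi_table$zone,
      planted = planted,
      latency_model = config$latency_model,
      participation = config$participation
    )
  ), class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>\n")
  cat(sprintf("  %d ROIs in %d zones, %d frames at %g fps\n",
              nrow(x$roi_table), x$config$n_zones, nrow(x$raster),
              x$config$frame_rate_hz))
  cat(sprintf("  %d trials, %d spike trains\n", nrow(x$trials),
              length(x$spike_trains)))
  invisible(x)
}
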