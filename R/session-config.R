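#' Configuration for a synthetic imaging/behaviour/ephys session
#'
#' Builds a validated configuration list describing one synthetic session of
#' the multisensory go/no-go licking task. Defaults reflect the recorded
#' data structure this generator emulates: ~300 dendritic ROIs per field of
#' view grouped into ~333-um parasagittal zones, dendritic complex-spike
#' (CS) calcium events at 1.24 events/s imaged at 30.03 frames/s, a
#' fast-rise/exponential-decay fluorescence kernel (tau = 0.15 s, unitary
#' amplitude 0.65 dF/F), Hit first-lick latencies near 210 ms (360 ms under
#' optogenetic stimulation), and paired simple-spike (84.1 spikes/s) /
#' complex-spike (1.5 spikes/s) electrode trains with a 10-ms post-CS pause.
#'
#' Within-zone coherence is generated by a mother-process thinning model:
#' each zone carries a Bernoulli "mother" event train at `cs_rate_hz`
#' (converted to a per-frame probability) in which each member ROI
#' participates with probability `within_zone_coherence`; an optional
#' session-wide mother with participation `across_zone_coherence` adds
#' across-zone correlation; independent per-ROI events top the total rate up
#' to `cs_rate_hz`. Pairwise event correlation is therefore approximately
#' `within_zone_coherence^2 + across_zone_coherence^2` within a zone and
#' `across_zone_coherence^2` across zones.
#'
#' Sensory-evoked CS responses are planted as zone-level events in the first
#' 250 ms after cue onset with per-cue, per-zone probability `evoked_prob`;
#' participation in an evoked event follows a linear design mirroring the
#' downstream regression model:
#' `participation = base + air * (air puff) + tone * (tone) + gain * (lick)`,
#' where the lick gain `coherence_gain_on_lick` is applied at the expert
#' learning stage only (the lick coupling is acquired with learning).
#'
#' @param n_zones number of parasagittal zones in the field of view.
#' @param rois_per_zone dendritic ROIs per zone.
#' @param zone_width_um mediolateral width of each zone (um).
#' @param frame_rate_hz imaging frame rate (frames/s).
#' @param duration_s session duration (s).
#' @param cs_rate_hz per-ROI complex-spike event rate (events/s).
#' @param within_zone_coherence participation probability of a zone ROI in
#'   its zone's mother events, in `[0, 1]`.
#' @param across_zone_coherence participation probability in a session-wide
#'   mother process (adds across-zone correlation), in `[0, 1]`;
#'   `within_zone_coherence + across_zone_coherence` must be at most 1.
#' @param evoked_prob named list (`Go`, `NoGo1`, `NoGo2`) of per-zone
#'   probabilities (scalar or length `n_zones`) that a cue of that type
#'   evokes a zone-level CS event within 0-250 ms of cue onset. The default
#'   alternates responsive (odd) and unresponsive (even) zones, with
#'   air-puff-containing cues more effective than the tone alone.
#' @param participation list with elements `base`, `air`, `tone`: linear
#'   coefficients of the participation probability of evoked events.
#' @param coherence_gain_on_lick additive participation on licking trials
#'   (expert stage).
#' @param lick_coupling_delta additive lick probability on trials with a
#'   planted evoked event in zone 1 (couples CoCS events to lick
#'   initiation; 0 decouples behaviour from imaging).
#' @param residual_shrink_on_cocs multiplier (< 1 shrinks) on the latency CV
#'   of trials with a planted zone-1 event; 1 disables the coupling.
#' @param tau_s indicator decay constant of the fluorescence kernel (s).
#' @param amp unitary event amplitude in dF/F units.
#' @param noise_sd additive Gaussian fluorescence noise, in dF/F units.
#' @param f0 baseline fluorescence above the floor (arbitrary units).
#' @param fb floor fluorescence of the field (arbitrary units).
#' @param trial_mix length-3 ratio of Go : No-go 1 : No-go 2 trials.
#' @param trial_period_s spacing between cue onsets (s); covers the 0.5-s
#'   cue, the inter-trial interval and the randomized withhold period.
#' @param window_s response window after cue onset (s).
#' @param max_consecutive maximum run of identical cues in the
#'   pseudo-randomized sequence.
#' @param lick_prob named list (`Go`, `NoGo1`, `NoGo2`) of per-cue lick
#'   probabilities.
#' @param latency_model list with `air` and `tone` elements, each
#'   `list(mean, cv)` of the first-lick latency (s); air-puff-containing
#'   cues (Go, No-go 1) use `air`, the tone-only cue uses `tone`.
#' @param apprentice_cv_mult multiplier on latency CV at the apprentice
#'   stage (expert training shrinks latency variability).
#' @param stage learning stage, `"apprentice"` or `"expert"`.
#' @param opto_fraction fraction of Go trials receiving photostimulation.
#' @param opto_latency_mean_s mean first-lick latency on photostimulated
#'   licking trials (s).
#' @param opto_abolish_prob probability that photostimulation abolishes the
#'   lick on a would-lick Go trial.
#' @param opto_delay_prob probability that photostimulation pushes the first
#'   lick beyond the response window (drawn uniformly in 0.5-1.0 s).
#' @param lick_rate_hz within-bout lick rate (licks/s).
#' @param bout_duration_s duration of a lick bout after the first lick (s).
#' @param spont_bout_prob probability of a spontaneous lick bout in the
#'   inter-trial period of a non-licking trial.
#' @param tone_level_db tone sound levels (dB); levels below the 80-dB
#'   standard attenuate the tone contribution to lick probability via
#'   `tone_attenuation_slope` (lick-probability-vs-level curve exposed as a
#'   free parameter).
#' @param tone_attenuation_slope drop in tone-driven lick probability per dB
#'   of attenuation below 80 dB.
#' @param n_units number of paired simple/complex spike units.
#' @param ss_rate_hz target simple-spike rate after pause deletion
#'   (spikes/s).
#' @param cs_rate_ephys_hz complex-spike rate of electrode units (spikes/s).
#' @param pause_s pause after each complex spike during which simple spikes
#'   of the paired unit are deleted (s).
#' @param ss_mod_hz per-unit additive simple-spike rate modulation in the
#'   0-100 ms window after cue onset (scalar recycled, or length
#'   `n_units`); sign is per unit.
#' @param seed integer seed; all randomness in the generators flows from it
#'   through fixed per-stage offsets.
#' @return an object of class `session_config` (a named list).
#' @seealso [generate_session()], [generate_behavior()], [generate_ephys()]
#' @export
session_config <- function(n_zones = 6,
                           rois_per_zone = 50,
                           zone_width_um = 333,
                           frame_rate_hz = 30.03,
                           duration_s = 513,
                           cs_rate_hz = 1.24,
                           within_zone_coherence = 0.6,
                           across_zone_coherence = 0,
                           evoked_prob = NULL,
                           participation = list(base = 0.28, air = 0.08,
                                                tone = 0.01),
                           coherence_gain_on_lick = 0.04,
                           lick_coupling_delta = 0,
                           residual_shrink_on_cocs = 1,
                           tau_s = 0.15,
                           amp = 0.65,
                           noise_sd = 0.05,
                           f0 = 100,
                           fb = 20,
                           trial_mix = c(1, 1, 1),
                           trial_period_s = 5,
                           window_s = 0.5,
                           max_consecutive = 3,
                           lick_prob = NULL,
                           latency_model = NULL,
                           apprentice_cv_mult = 4 / 3,
                           stage = c("expert", "apprentice"),
                           opto_fraction = 0,
                           opto_latency_mean_s = 0.36,
                           opto_abolish_prob = 0.30,
                           opto_delay_prob = 0.15,
                           lick_rate_hz = 7,
                           bout_duration_s = 1.5,
                           spont_bout_prob = 0.1,
                           tone_level_db = 80,
                           tone_attenuation_slope = 0.02,
                           n_units = 13,
                           ss_rate_hz = 84.1,
                           cs_rate_ephys_hz = 1.5,
                           pause_s = 0.010,
                           ss_mod_hz = 0,
                           seed = 1L) {
  stage <- match.arg(stage)
  if (n_zones < 1 || rois_per_zone < 1) {
    stop("config must describe at least one zone with at least one ROI",
         call. = FALSE)
  }
  stopifnot(frame_rate_hz > 0, duration_s > 0, cs_rate_hz >= 0, tau_s > 0,
            amp > 0, noise_sd >= 0, zone_width_um > 0, trial_period_s > 0,
            window_s > 0, n_units >= 0, ss_rate_hz >= 0,
            cs_rate_ephys_hz >= 0, pause_s >= 0)
  stop_if_not_scalar_prob(within_zone_coherence, "within_zone_coherence")
  stop_if_not_scalar_prob(across_zone_coherence, "across_zone_coherence")
  if (within_zone_coherence + across_zone_coherence > 1) {
    stop("within_zone_coherence + across_zone_coherence must be <= 1",
         call. = FALSE)
  }
  stop_if_not_scalar_prob(coherence_gain_on_lick, "coherence_gain_on_lick")
  stop_if_not_scalar_prob(lick_coupling_delta, "lick_coupling_delta")
  stop_if_not_scalar_prob(opto_fraction, "opto_fraction")
  stop_if_not_scalar_prob(opto_abolish_prob, "opto_abolish_prob")
  stop_if_not_scalar_prob(opto_delay_prob, "opto_delay_prob")
  stop_if_not_scalar_prob(spont_bout_prob, "spont_bout_prob")
  if (length(trial_mix) != 3 || any(trial_mix < 0) || sum(trial_mix) <= 0) {
    stop("trial_mix must be three non-negative weights with a positive sum",
         call. = FALSE)
  }

  if (is.null(evoked_prob)) {
    odd <- rep_len(c(TRUE, FALSE), n_zones)
    evoked_prob <- list(Go = ifelse(odd, 0.70, 0.10),
                        NoGo1 = ifelse(odd, 0.70, 0.10),
                        NoGo2 = ifelse(odd, 0.25, 0.05))
  }
  evoked_prob <- lapply(evoked_prob, function(p) rep_len(p, n_zones))
  for (nm in c("Go", "NoGo1", "NoGo2")) {
    stop_if_not_scalar_prob(evoked_prob[[nm]], paste0("evoked_prob$", nm))
  }
  if (is.null(lick_prob)) {
    lick_prob <- if (stage == "expert") {
      list(Go = 0.97, NoGo1 = 0.20, NoGo2 = 0.15)
    } else {
      list(Go = 0.80, NoGo1 = 0.45, NoGo2 = 0.35)
    }
  }
  for (nm in c("Go", "NoGo1", "NoGo2")) {
    stop_if_not_scalar_prob(lick_prob[[nm]], paste0("lick_prob$", nm))
  }
  if (is.null(latency_model)) {
    latency_model <- list(air = list(mean = 0.21, cv = 0.20),
                          tone = list(mean = 0.28, cv = 0.30))
  }
  for (nm in c("air", "tone")) {
    lm_ <- latency_model[[nm]]
    if (is.null(lm_) || lm_$mean <= 0 || lm_$cv <= 0) {
      stop("latency_model must give positive mean and cv for 'air' and 'tone'",
           call. = FALSE)
    }
  }
  stopifnot(residual_shrink_on_cocs > 0, apprentice_cv_mult > 0)

  cfg <- list(
    n_zones = as.integer(n_zones), rois_per_zone = as.integer(rois_per_zone),
    zone_width_um = zone_width_um, frame_rate_hz = frame_rate_hz,
    duration_s = duration_s, cs_rate_hz = cs_rate_hz,
    within_zone_coherence = within_zone_coherence,
    across_zone_coherence = across_zone_coherence,
    evoked_prob = evoked_prob, participation = participation,
    coherence_gain_on_lick = coherence_gain_on_lick,
    lick_coupling_delta = lick_coupling_delta,
    residual_shrink_on_cocs = residual_shrink_on_cocs,
    tau_s = tau_s, amp = amp, noise_sd = noise_sd, f0 = f0, fb = fb,
    trial_mix = trial_mix, trial_period_s = trial_period_s,
    window_s = window_s, max_consecutive = as.integer(max_consecutive),
    lick_prob = lick_prob, latency_model = latency_model,
    apprentice_cv_mult = apprentice_cv_mult, stage = stage,
    opto_fraction = opto_fraction,
    opto_latency_mean_s = opto_latency_mean_s,
    opto_abolish_prob = opto_abolish_prob,
    opto_delay_prob = opto_delay_prob,
    lick_rate_hz = lick_rate_hz, bout_duration_s = bout_duration_s,
    spont_bout_prob = spont_bout_prob,
    tone_level_db = tone_level_db,
    tone_attenuation_slope = tone_attenuation_slope,
    n_units = as.integer(n_units), ss_rate_hz = ss_rate_hz,
    cs_rate_ephys_hz = cs_rate_ephys_hz, pause_s = pause_s,
    ss_mod_hz = ss_mod_hz, seed = as.integer(seed)
  )
  class(cfg) <- "session_config"
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  field: %d zones x %d ROIs (%g um wide), %g s at %g fps\n",
              x$n_zones, x$rois_per_zone, x$zone_width_um, x$duration_s,
              x$frame_rate_hz))
  cat(sprintf("  CS events: %g /s, within-zone coherence %g, stage %s\n",
              x$cs_rate_hz, x$within_zone_coherence, x$stage))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# fixed per-stage seed offsets so each generator is reproducible standalone
stage_seed <- function(config, stage) {
  offsets <- c(behavior = 11L, raster = 23L, fluor = 37L, ephys = 53L)
  config$seed + offsets[[stage]]
}
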