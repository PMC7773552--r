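# Small session configurations used across tests. Sizes are chosen so the
# whole suite runs in minutes while keeping enough frames/trials for the
# statistical checks to be stable under their fixed seeds.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_zones = 2, rois_per_zone = 10, duration_s = 60,
                   seed = 42L)
  do.call(session_config, utils::modifyList(defaults, args))
}

# hand-built trial table: cues, onsets and licks fully specified
make_trials <- function(cues, licks = NULL, onset_step = 5, window = 0.5,
                        stage = "expert") {
  n <- length(cues)
  if (is.null(licks)) licks <- rep(list(numeric(0)), n)
  classify_trials(data.frame(
    trial_id = seq_len(n), cue = cues,
    cue_onset_s = 1 + (seq_len(n) - 1) * onset_step,
    window_s = window, opto = FALSE, stage = stage,
    tone_level_db = NA_real_,
    lick_times = I(licks), stringsAsFactors = FALSE))
}

# brute-force truncated-window percentile oracle (sort and type-7 index)
oracle_rolling_percentile <- function(x, p, hw) {
  n <- length(x)
  sapply(seq_len(n), function(t) {
    w <- sort(x[max(1, t - hw):min(n, t + hw)])
    h <- (length(w) - 1) * p / 100 + 1
    lo <- floor(h)
    w[lo] + (h - lo) * (w[min(lo + 1, length(w))] - w[lo])
  })
}

# precision/recall of detected event frames vs truth, +-tol frames
event_pr <- function(detected, truth, tol = 1) {
  det <- which(detected == 1)
  tru <- which(truth == 1)
  if (length(tru) == 0) return(c(recall = NA, precision = NA))
  hit_tru <- vapply(tru, function(t) any(abs(det - t) <= tol), logical(1))
  hit_det <- vapply(det, function(t) any(abs(tru - t) <= tol), logical(1))
  c(recall = mean(hit_tru),
    precision = if (length(det)) mean(hit_det) else NA)
}
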