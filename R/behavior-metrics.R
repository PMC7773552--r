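#' Classify go/no-go trials into Hit/Miss/FA/CR outcomes
#'
#' A trial is a licking trial when at least one lick falls in the half-open
#' response window `[cue_onset, cue_onset + window_s)`. Licking crossed with
#' cue type gives: Go -> Hit/Miss, No-go 1 (air puff only) -> FA1/CR1,
#' No-go 2 (tone only) -> FA2/CR2. The first-lick latency (first lick in
#' window minus cue onset) is recorded for licking trials and absent
#' otherwise.
#'
#' @param trials data.frame with columns `cue` (`Go`, `NoGo1`, `NoGo2`),
#'   `cue_onset_s`, `window_s`, and a `lick_times` list-column of sorted
#'   lick times in seconds.
#' @return the same data.frame with `outcome` and `first_lick_latency_s`
#'   columns (re)computed.
#' @export
classify_trials <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("cue", "cue_onset_s", "window_s", "lick_times") %in%
                  names(trials)))
  bad <- setdiff(unique(trials$cue), c("Go", "NoGo1", "NoGo2"))
  if (length(bad) > 0) {
    stop("unknown cue label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(trials)
  outcome <- character(n)
  latency <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    licks <- trials$lick_times[[i]]
    on <- trials$cue_onset_s[i]
    w <- trials$window_s[i]
    inwin <- licks[licks >= on & licks < on + w]
    licked <- length(inwin) > 0
    outcome[i] <- switch(trials$cue[i],
      Go = if (licked) "Hit" else "Miss",
      NoGo1 = if (licked) "FA1" else "CR1",
      NoGo2 = if (licked) "FA2" else "CR2")
    if (licked) latency[i] <- min(inwin) - on
  }
  trials$outcome <- outcome
  trials$first_lick_latency_s <- latency
  trials
}

#' Per-stimulus outcome rates
#'
#' Rates are computed within each stimulus condition: Hit rate among Go
#' trials, FA1/CR1 rates among No-go 1 trials, FA2/CR2 among No-go 2 (e.g.
#' `CR1 rate = N(CR1) / (N(CR1) + N(FA1))`).
#'
#' @param trials a classified trial table.
#' @return named list of rates (`hit`, `miss`, `fa1`, `cr1`, `fa2`, `cr2`);
#'   a rate is `NA` when its stimulus condition has no trials.
#' @export
outcome_rates <- function(trials) {
  rate <- function(num, den) {
    if (sum(den) == 0) NA_real_ else sum(num) / sum(den)
  }
  oc <- trials$outcome
  list(
    hit = rate(oc == "Hit", trials$cue == "Go"),
    miss = rate(oc == "Miss", trials$cue == "Go"),
    fa1 = rate(oc == "FA1", trials$cue == "NoGo1"),
    cr1 = rate(oc == "CR1", trials$cue == "NoGo1"),
    fa2 = rate(oc == "FA2", trials$cue == "NoGo2"),
    cr2 = rate(oc == "CR2", trials$cue == "NoGo2")
  )
}

#' Signal-detection sensitivity d'
#'
#' `d' = Z(hit rate) - Z(FA rate)` with `Z` the standard-normal quantile
#' function. A hit rate of exactly 1 is replaced by 0.99 before the
#' transform to keep d' finite; rates of exactly 0 (and an FA rate of 1)
#' are capped symmetrically at 0.01/0.99. Capping is flagged in the
#' `"capped"` attribute of the result.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @return d' (unitless) with attribute `capped` (logical).
#' @export
dprime <- function(hit_rate, fa_rate) {
  stop_if_not_scalar_prob(hit_rate, "hit_rate")
  stop_if_not_scalar_prob(fa_rate, "fa_rate")
  cap <- function(p) min(0.99, max(0.01, p))
  capped <- hit_rate %in% c(0, 1) || fa_rate %in% c(0, 1)
  d <- qnorm(cap(hit_rate)) - qnorm(cap(fa_rate))
  attr(d, "capped") <- capped
  d
}

#' Session d' from a classified trial table
#'
#' d' is computed separately against each No-go condition and the session
#' value is the minimum of the two (the harder discrimination).
#'
#' @param trials a classified trial table.
#' @return list with `dprime_nogo1`, `dprime_nogo2`, `dprime` (the min).
#' @export
session_dprime <- function(trials) {
  r <- outcome_rates(trials)
  d1 <- if (is.na(r$fa1)) NA_real_ else dprime(r$hit, r$fa1)
  d2 <- if (is.na(r$fa2)) NA_real_ else dprime(r$hit, r$fa2)
  list(dprime_nogo1 = as.numeric(d1), dprime_nogo2 = as.numeric(d2),
       dprime = suppressWarnings(min(as.numeric(d1), as.numeric(d2),
                                     na.rm = TRUE)))
}

#' First-lick latency statistics and residuals
#'
#' The latency residual of a trial is the absolute difference between its
#' first-lick latency and the median latency of the same trial type within
#' the session, normalized by the mean latency of that trial type and
#' expressed in percent (a temporal-precision measure: smaller is more
#' precise). With an extended analysis window (`window_s` = 1.0 while the
#' task window was 0.5 s) first licks in 0.5-1.0 s are reported as
#' "delayed" and trials with no first lick in 0-1.0 s as "missed",
#' separating slowed from abolished motor initiation.
#'
#' @param trials a classified trial table (classification is re-run at
#'   `window_s` when it differs from the table's window).
#' @param window_s analysis window in seconds (default 0.5).
#' @param types outcomes included as licking trials.
#' @return list with per-type latency mean/median (s), per-trial residuals
#'   (percent), `latency_mean_s`, `latency_residual_pct` (mean residual
#'   over included trials), `delayed_lick_pct` and `missed_lick_pct`
#'   (percent of Go trials; only meaningful with `window_s` > the task
#'   window). Empty selections yield `NA`, never zero.
#' @export
latency_stats <- function(trials, window_s = 0.5,
                          types = c("Hit", "FA1", "FA2")) {
  stopifnot(window_s > 0)
  tr <- trials
  tr$window_s <- window_s
  tr <- classify_trials(tr)

  res <- rep(NA_real_, nrow(tr))
  per_type <- list()
  for (ty in types) {
    sel <- which(tr$outcome == ty & !is.na(tr$first_lick_latency_s))
    if (length(sel) == 0) next
    lat <- tr$first_lick_latency_s[sel]
    med <- median(lat)
    mu <- mean(lat)
    res[sel] <- abs(lat - med) / mu * 100
    per_type[[ty]] <- list(n = length(sel), mean_s = mu, median_s = med,
                           residual_pct = mean(abs(lat - med) / mu * 100))
  }
  incl <- !is.na(res)
  go <- tr$cue == "Go"
  delayed <- go & !is.na(tr$first_lick_latency_s) &
    tr$first_lick_latency_s >= 0.5
  missed <- go & is.na(tr$first_lick_latency_s)

  list(
    per_type = per_type,
    residual_pct = res,
    latency_mean_s = if (any(incl)) mean(tr$first_lick_latency_s[incl])
                     else NA_real_,
    latency_residual_pct = if (any(incl)) mean(res[incl]) else NA_real_,
    delayed_lick_pct = if (any(go)) mean(delayed[go]) * 100 else NA_real_,
    missed_lick_pct = if (any(go)) mean(missed[go]) * 100 else NA_real_
  )
}

#' Spontaneous lick-bout onsets
#'
#' A spontaneous bout onset is the first lick in a trial that falls outside
#' the cue window, restricted to trials following a non-licking outcome
#' (CR1, CR2, or Miss) so the bout is not cue-driven.
#'
#' @param trials a classified trial table.
#' @return numeric vector of bout onset times (s); empty when no qualifying
#'   licks exist.
#' @export
extract_lick_bouts <- function(trials) {
  onsets <- numeric(0)
  for (i in seq_len(nrow(trials))) {
    if (!trials$outcome[i] %in% c("CR1", "CR2", "Miss")) next
    licks <- trials$lick_times[[i]]
    on <- trials$cue_onset_s[i]
    out <- licks[licks >= on + trials$window_s[i] | licks < on]
    if (length(out) > 0) onsets <- c(onsets, min(out))
  }
  onsets
}

#' Fraction of 500-ms epochs containing licking
#'
#' Tiles `[0, duration_s)` with consecutive windows of `epoch_s` and
#' reports the percentage containing at least one lick; a measure of
#' whether licking per se (rather than its initiation) is intact.
#'
#' @param lick_times_s lick times in seconds.
#' @param duration_s total duration tiled by epochs.
#' @param epoch_s epoch length (default 0.5 s).
#' @return percentage in `[0, 100]`.
#' @export
licking_epoch_ratio <- function(lick_times_s, duration_s, epoch_s = 0.5) {
  stopifnot(duration_s > 0, epoch_s > 0)
  n_epochs <- floor(duration_s / epoch_s)
  if (n_epochs < 1) return(NA_real_)
  idx <- floor(lick_times_s / epoch_s)
  idx <- idx[idx >= 0 & idx < n_epochs]
  length(unique(idx)) / n_epochs * 100
}

#' Summarise the behaviour of a session
#'
#' Convenience wrapper bundling outcome rates, session d', latency
#' statistics at the task window and at the extended 1-s window, and the
#' licking-epoch ratio.
#'
#' @param trials a classified trial table.
#' @return list of class `behavior_summary`.
#' @export
behavior_summary <- function(trials) {
  rates <- outcome_rates(trials)
  dp <- session_dprime(trials)
  lat <- latency_stats(trials, window_s = unique(trials$window_s)[1])
  ext <- latency_stats(trials, window_s = 1.0)
  all_licks <- sort(unlist(trials$lick_times))
  dur <- max(trials$cue_onset_s) + unique(trials$window_s)[1]
  structure(list(
    rates = rates, dprime = dp,
    latency = lat, latency_extended = ext,
    licking_epoch_ratio_pct = licking_epoch_ratio(all_licks, dur)
  ), class = "behavior_summary")
}
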