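check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read and write trial tables
#'
#' Trial tables are CSV files with columns trial_id, cue, cue_onset_s,
#' window_s, opto, stage, tone_level_db, lick_times (semicolon-separated
#' seconds), outcome, first_lick_latency_s. Times are seconds; the
#' round-trip is lossless.
#'
#' @param trials classified trial table.
#' @param path file path.
#' @return `read_trials` returns the trial table with a `lick_times`
#'   list-column; `write_trials` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  out$lick_times <- vapply(trials$lick_times, function(x) {
    paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ";")
  }, character(1))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("trial_id", "cue", "cue_onset_s", "window_s",
                      "lick_times"), "trial table")
  df$lick_times <- I(lapply(strsplit(as.character(df$lick_times), ";"),
                            function(x) {
                              x <- suppressWarnings(as.numeric(x))
                              x[is.finite(x)]
                            }))
  df
}

#' Read and write ROI tables
#'
#' CSV with columns roi_id, ml_um, ap_um, n_pixels and optionally zone
#' (coordinates in micrometres, lateral positive).
#'
#' @param roi_table ROI table.
#' @param path file path.
#' @export
write_rois <- function(roi_table, path) {
  write.csv(roi_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("roi_id", "ml_um", "n_pixels"), "ROI table")
  df
}

#' Read and write spike trains
#'
#' Long-format CSV with columns unit_id, time_s, label (and optionally
#' paired_unit); one row per spike.
#'
#' @param trains list of [spike_train()] objects.
#' @param path file path.
#' @param duration_s recording duration used when reading back.
#' @export
write_spikes <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (length(tr$times_s) == 0) return(NULL)
    data.frame(unit_id = tr$unit_id, time_s = tr$times_s,
               label = tr$label, paired_unit = tr$paired_unit)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, duration_s = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("unit_id", "time_s", "label"), "spike table")
  lapply(split(df, df$unit_id), function(d) {
    spike_train(d$unit_id[1], d$time_s, label = d$label[1],
                duration_s = duration_s %||% max(df$time_s),
                paired_unit = if ("paired_unit" %in% names(d))
                  d$paired_unit[1] else NA_character_)
  })
}

#' Read and write numeric matrices as headered TSV
#'
#' Frame-by-ROI matrices (rasters, fluorescence, dF/F) are stored as
#' tab-separated text with `# key=value` attribute lines (always including
#' `frame_rate_hz`) before the data; the round-trip preserves values and
#' attributes.
#'
#' @param mat numeric matrix with an optional `frame_rate_hz` attribute.
#' @param path file path.
#' @param frame_rate_hz frame rate stored in the header (defaults to the
#'   matrix attribute).
#' @export
write_matrix_tsv <- function(mat, path, frame_rate_hz = NULL) {
  fr <- frame_rate_hz %||% attr(mat, "frame_rate_hz") %||% NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz=%.17g", fr), con)
  writeLines(sprintf("# dim=%d,%d", nrow(mat), ncol(mat)), con)
  utils::write.table(mat, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  header <- readLines(path, n = 10)
  meta <- grep("^# ", header, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "="))
  mat <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(mat) <- NULL
  fr <- suppressWarnings(as.numeric(kv[kv[, 1] == "frame_rate_hz", 2]))
  if (length(fr) == 1 && is.finite(fr)) attr(mat, "frame_rate_hz") <- fr
  mat
}

#' Read and write session configurations as YAML
#'
#' @param config a [session_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(session_config, vals[names(vals) %in% names(formals(session_config))])
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes simulate -> dF/F -> event detection -> zone discovery -> CoCS
#' extraction and alignment -> behaviour metrics -> coherence mixed/fixed
#' model, and returns a machine-readable report of the summary statistics
#' together with a provenance block (seed, configuration hash, package
#' version). The same configuration always yields the same report.
#'
#' Event detection is run on the dF/F of the synthesized fluorescence, so
#' the report reflects the full measurement chain rather than the
#' ground-truth raster.
#'
#' @param config a [session_config()].
#' @param out optional path; when given the report is written as JSON.
#' @param use_truth_raster skip fluorescence deconvolution and use the
#'   ground-truth raster (faster; useful for long sessions).
#' @return report list (invisibly when `out` is given).
#' @export
run_pipeline <- function(config, out = NULL, use_truth_raster = FALSE) {
  stopifnot(inherits(config, "session_config"))
  bundle <- generate_session(config)

  raster <- if (use_truth_raster) {
    bundle$raster
  } else {
    d <- dff(bundle$fluorescence, fb = attr(bundle$fluorescence, "fb"))
    detect_events_matrix(d, event_detect_params(
      tau_s = config$tau_s, amp = config$amp,
      dt_s = 1 / config$frame_rate_hz))
  }

  cm <- correlation_matrix(raster, bundle$roi_table)
  part <- sequential_kmeans(cm$corr, cm$roi_table, seed = config$seed)
  geo <- zone_geometry(part, cm$roi_table)

  events <- detect_cocs_all(raster[, cm$order, drop = FALSE],
                            part$assignment,
                            frame_rate_hz = config$frame_rate_hz)
  aligned <- align_to_trials(events, raster[, cm$order, drop = FALSE],
                             bundle$trials,
                             frame_rate_hz = config$frame_rate_hz)

  beh <- behavior_summary(bundle$trials)

  # trial-wise coherence model for the most responsive zone
  model <- NULL
  if (length(aligned$zones) > 0) {
    zi <- which.max(rowMeans(aligned$zone_prob, na.rm = TRUE))
    yz <- aligned$trial_coherence[, zi]
    sel <- which(!is.na(yz))
    if (length(sel) >= 10) {
      Xz <- cbind(air = as.integer(bundle$trials$cue[sel] %in%
                                     c("Go", "NoGo1")),
                  tone = as.integer(bundle$trials$cue[sel] %in%
                                      c("Go", "NoGo2")),
                  lick = as.integer(aligned$lick[sel]))
      model <- tryCatch(fit_glm(yz[sel], Xz), error = function(e) NULL)
    }
  }

  report <- list(
    provenance = list(
      package = "cocs",
      version = as.character(utils::packageVersion("cocs")),
      seed = config$seed,
      config_hash = sum(utils::head(
        utf8ToInt(paste(deparse(unclass(config)), collapse = "")), 1e5))
    ),
    n_rois = nrow(bundle$roi_table),
    n_trials = nrow(bundle$trials),
    zone_count = part$n_zones,
    zone_widths_um = geo$width_um,
    event_rate_hz = mean(colSums(raster)) /
      (nrow(raster) / config$frame_rate_hz),
    cocs_prob_by_type = if (length(aligned$zones))
      as.list(as.data.frame(aligned$zone_prob)) else NULL,
    behavior = list(
      hit_rate = beh$rates$hit,
      dprime = beh$dprime$dprime,
      latency_mean_s = beh$latency$latency_mean_s,
      latency_residual_pct = beh$latency$latency_residual_pct
    ),
    coherence_model = if (!is.null(model)) {
      list(beta = as.list(model$beta), p = as.list(model$p), r2 = model$r2)
    } else {
      NULL
    }
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
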