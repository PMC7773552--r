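`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw gamma variates parameterised by mean and coefficient of variation
#'
#' Right-skewed latency draws use a gamma family with shape `1/cv^2` and
#' scale `mean * cv^2`, so that `E[X] = mean` and `sd(X)/E[X] = cv`.
#'
#' @param n number of draws.
#' @param mean mean of the distribution (same units as the output).
#' @param cv coefficient of variation; must be > 0.
#' @return numeric vector of length `n`.
#' @keywords internal
rgamma_mcv <- function(n, mean, cv) {
  stopifnot(mean > 0, cv > 0)
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# seconds -> 0-based frame index of the first frame triggered at or after t
first_frame_after <- function(t_s, frame_rate_hz) {
  ceiling(t_s * frame_rate_hz - 1e-9)
}

#' Map an event time onto the imaging frame timeline
#'
#' Task events recorded on a fast clock are assigned a time half a frame
#' before the first imaging frame triggered after the event, so that frame-
#' resolution rasters and sub-frame event times share one timeline.
#'
#' @param t_s event time in seconds.
#' @param frame_rate_hz imaging frame rate (frames/s).
#' @return aligned time in seconds on the frame timeline.
#' @export
align_event_time <- function(t_s, frame_rate_hz) {
  first_frame_after(t_s, frame_rate_hz) / frame_rate_hz - 0.5 / frame_rate_hz
}
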