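#' Detect wave-break events in an iRDF series
#'
#' A wave break is any drop of the instantaneous regional dominant
#' frequency more than `drop_hz` below the segment RDF (or below
#' `floor_hz`) lasting longer than `min_dur_s`. Events are maximal runs of
#' consecutive below-threshold frames; runs separated by at least one
#' above-threshold frame are distinct events. The span of a run of
#' `m` frames at hop `h` is `m * h` seconds, so with the default 50-ms hop
#' the ">100 ms" duration gate requires at least 3 below-threshold frames.
#'
#' @param irdf_series a `frequency_series` of kind `"iRDF"` (see [irdf()]).
#' @param rdf_value scalar RDF (Hz) computed from the same series; defaults
#'   to [rdf()] of the series.
#' @param drop_hz relative drop threshold below the RDF (Hz), default 3.
#' @param floor_hz absolute floor (Hz), default 0.5.
#' @param min_dur_s minimum event duration (s, strict), default 0.1.
#' @return data frame of class `wave_break_events` with columns `t_start`,
#'   `t_end` (s), `min_irdf` (Hz) and `trigger` (`"relative_drop"` when the
#'   minimum iRDF crossed the relative threshold, else `"absolute_floor"`).
#' @export
detect_wave_breaks <- function(irdf_series, rdf_value = rdf(irdf_series),
                               drop_hz = 3, floor_hz = 0.5,
                               min_dur_s = 0.1) {
  stopifnot(inherits(irdf_series, "frequency_series"))
  v <- irdf_series$values
  if (length(v) < 1L) stop("iRDF series has no frames")
  hop <- irdf_series$hop_s
  if (!is.finite(hop) || hop <= 0) stop("iRDF series has no frame spacing")
  below <- v < (rdf_value - drop_hz) | v < floor_hz
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    min_irdf = numeric(0), trigger = character(0),
                    stringsAsFactors = FALSE)
  for (i in which(runs$values)) {
    m <- runs$lengths[i]
    if (m * hop > min_dur_s) {
      idx <- starts[i]:ends[i]
      vmin <- min(v[idx])
      out <- rbind(out, data.frame(
        t_start = irdf_series$times[starts[i]],
        t_end = irdf_series$times[ends[i]] + hop,
        min_irdf = vmin,
        trigger = if (vmin < rdf_value - drop_hz) "relative_drop"
                  else "absolute_floor",
        stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("wave_break_events", "data.frame")
  out
}

#' Wave break rate (WBR)
#'
#' Number of detected wave breaks per second of analyzed signal.
#'
#' @param events a `wave_break_events` data frame (or anything with
#'   `nrow()`), or an integer event count.
#' @param duration_s analyzed segment duration in seconds, positive.
#' @return scalar WBR in WB/s.
#' @export
wbr <- function(events, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("duration_s must be a single positive number")
  }
  n <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  n / duration_s
}
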