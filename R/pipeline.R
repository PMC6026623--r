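#' Default analysis configuration
#'
#' All tunable parameters of the pipeline in one nested list, mirroring
#' the YAML layout accepted by [load_config()] and the command-line
#' driver.
#'
#' @return nested list of parameters.
#' @export
default_config <- function() {
  list(
    fs = 2034.5,
    stft = list(window_s = 1.0, overlap = 0.95, grid_hz = 0.05),
    band_hz = c(0.1, 20),
    preprocess = list(band_hz = c(40, 250), sigma_s = 0.02,
                      normalize = TRUE),
    wb = list(drop_hz = 3, floor_hz = 0.5, min_dur_s = 0.1),
    fir = list(length = 180),
    seed = 1L
  )
}

#' Load a YAML configuration, filling unset keys with defaults
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_spectral <- function(config) {
  spectral_config(window_s = config$stft$window_s,
                  overlap = config$stft$overlap,
                  grid_hz = config$stft$grid_hz,
                  band_hz = config$band_hz)
}

#' Run the full RDF/WBR pipeline on one segment
#'
#' Executes condition -> average -> FIR smooth -> mean removal -> STFT ->
#' iRDF -> RDF -> wave-break detection -> WBR, and returns one row of
#' site metrics. Deterministic given the segment and configuration.
#'
#' @param segment an [egm_segment] (>= 2 channels, at least one STFT
#'   window long).
#' @param config configuration list, see [default_config()].
#' @param keep_series also return the iRDF series and event table as
#'   attributes `"irdf"` and `"events"` (default `FALSE`).
#' @return one-row data frame with columns `site_id`, `patient_id`,
#'   `RDF_Hz`, `WBR_per_s`, `n_wavebreaks`, `duration_s`,
#'   `flag_upRDF_downWBR` (`NA` until [classify_sites()]), and `x`, `y`,
#'   `z` when the segment has a position.
#' @export
compute_site_metrics <- function(segment, config = default_config(),
                                 keep_series = FALSE) {
  stopifnot(inherits(segment, "egm_segment"))
  dur <- segment_duration(segment)
  if (dur < config$stft$window_s) {
    stop(sprintf(
      "segment '%s' is %.2f s, shorter than the %g-s analysis window; record at least %g s (>= 25 s recommended for a reliable WBR)",
      segment$site_id, dur, config$stft$window_s, config$stft$window_s))
  }
  if (dur < 25) {
    log_warn("segment '%s' is %.1f s (< 25 s): WBR estimate may be unreliable",
             segment$site_id, dur)
  }
  cfg <- config_spectral(config)
  env <- regional_envelope(segment,
                           band_hz = config$preprocess$band_hz,
                           sigma_s = config$preprocess$sigma_s,
                           normalize = config$preprocess$normalize)
  series <- irdf(env, cfg)
  rdf_value <- rdf(series)
  events <- detect_wave_breaks(series, rdf_value,
                               drop_hz = config$wb$drop_hz,
                               floor_hz = config$wb$floor_hz,
                               min_dur_s = config$wb$min_dur_s)
  log_info("segment %s: RDF %.2f Hz, %d wave breaks in %.1f s",
           segment$site_id, rdf_value, nrow(events), dur)
  out <- data.frame(site_id = segment$site_id,
                    patient_id = segment$patient_id,
                    RDF_Hz = rdf_value,
                    WBR_per_s = wbr(events, dur),
                    n_wavebreaks = nrow(events),
                    duration_s = dur,
                    flag_upRDF_downWBR = NA,
                    stringsAsFactors = FALSE)
  if (!is.null(segment$position)) {
    out$x <- segment$position[1L]
    out$y <- segment$position[2L]
    out$z <- segment$position[3L]
  }
  if (!is.null(segment$anatomical_label)) {
    out$anatomical_label <- segment$anatomical_label
  }
  if (keep_series) {
    attr(out, "irdf") <- series
    attr(out, "events") <- events
  }
  out
}

#' Run the pipeline over a set of segment files
#'
#' Reads each input segment, computes site metrics, classifies
#' high-RDF/low-WBR sites per patient, and optionally writes the metric
#' table and geometry maps.
#'
#' @param inputs character vector of segment CSV paths, or a list of
#'   [egm_segment] objects.
#' @param config configuration list (see [default_config()]).
#' @param metrics_path optional output CSV for [write_metrics()].
#' @param map_dir optional directory for per-patient RDF/WBR geometry maps
#'   (written only for sites with positions).
#' @return classified site-metrics data frame, one row per segment.
#' @export
run_pipeline <- function(inputs, config = default_config(),
                         metrics_path = NULL, map_dir = NULL) {
  segments <- if (is.character(inputs)) lapply(inputs, read_segment) else inputs
  metrics <- do.call(rbind, lapply(segments, compute_site_metrics,
                                   config = config))
  metrics <- do.call(rbind, lapply(split(metrics, metrics$patient_id),
                                   classify_sites))
  rownames(metrics) <- NULL
  if (!is.null(metrics_path)) write_metrics(metrics, metrics_path)
  if (!is.null(map_dir) && all(c("x", "y", "z") %in% names(metrics))) {
    dir.create(map_dir, showWarnings = FALSE, recursive = TRUE)
    for (pid in unique(metrics$patient_id)) {
      m <- metrics[metrics$patient_id == pid, ]
      for (met in c("rdf", "wbr")) {
        gm <- build_map(m, met)
        write_geometry_csv(gm, file.path(map_dir,
                                         sprintf("%s_%s.csv", pid, met)))
        write_geometry_vtk(gm, file.path(map_dir,
                                         sprintf("%s_%s.vtk", pid, met)))
      }
    }
  }
  metrics
}

#' Truncate a segment to its first `duration_s` seconds
#' @param segment an [egm_segment].
#' @param duration_s prefix duration (s), at most the segment duration.
#' @return an [egm_segment] containing the prefix.
#' @export
truncate_segment <- function(segment, duration_s) {
  stopifnot(inherits(segment, "egm_segment"))
  n <- round(duration_s * segment$fs)
  if (n > ncol(segment$samples)) {
    stop("requested prefix exceeds the segment duration")
  }
  egm_segment(segment$samples[, seq_len(n), drop = FALSE], fs = segment$fs,
              channel_ids = segment$channel_ids, site_id = segment$site_id,
              patient_id = segment$patient_id, position = segment$position,
              anatomical_label = segment$anatomical_label)
}
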