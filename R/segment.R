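#' Multichannel bipolar electrogram segment
#'
#' Container for one mapping-catheter recording: a channels-by-samples
#' amplitude matrix (mV) with its sampling frequency and site metadata.
#' Circular mapping catheters record around ten bipolar pairs
#' simultaneously; regional analysis requires at least two channels.
#'
#' @param samples numeric matrix, `n_channels x n_samples`, amplitudes in mV.
#' @param fs sampling frequency in Hz (nominally 2034.5 Hz for the
#'   acquisition system this package targets).
#' @param channel_ids character labels, one per channel; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param site_id recording-site identifier.
#' @param patient_id patient identifier.
#' @param position optional length-3 numeric, site coordinates in mm.
#' @param anatomical_label optional anatomical region label (e.g. "LSPV").
#'
#' @return An object of class `egm_segment`.
#' @export
egm_segment <- function(samples, fs, channel_ids = NULL,
                        site_id = "site", patient_id = "patient",
                        position = NULL, anatomical_label = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric matrix (channels x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (anyNA(samples)) {
    bad <- which(is.na(samples), arr.ind = TRUE)[1L, ]
    stop(sprintf("NaN/NA sample at channel %d, sample index %d",
                 bad[["row"]], bad[["col"]]))
  }
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%02d", seq_len(nrow(samples)))
  }
  if (length(channel_ids) != nrow(samples)) {
    stop("channel_ids length must match the number of channels")
  }
  if (!is.null(position)) {
    position <- as.numeric(position)
    if (length(position) != 3L) stop("position must be a 3-vector (mm)")
  }
  structure(
    list(samples = samples, fs = fs, channel_ids = as.character(channel_ids),
         site_id = as.character(site_id), patient_id = as.character(patient_id),
         position = position, anatomical_label = anatomical_label),
    class = "egm_segment")
}

#' @export
print.egm_segment <- function(x, ...) {
  cat(sprintf("<egm_segment> site %s / patient %s: %d channels x %d samples (%.2f s @ %.1f Hz)\n",
              x$site_id, x$patient_id, nrow(x$samples), ncol(x$samples),
              segment_duration(x), x$fs))
  invisible(x)
}

#' Segment duration in seconds
#' @param segment an [egm_segment].
#' @return duration in seconds.
#' @export
segment_duration <- function(segment) {
  ncol(segment$samples) / segment$fs
}

#' Read an electrogram segment from CSV
#'
#' The format is one column per channel, one row per sample, preceded by
#' metadata header lines prefixed `#` in `key=value` form. The `fs` key is
#' mandatory; `site_id`, `patient_id`, `position` (comma-separated x,y,z in
#' mm) and `anatomical_label` are optional. Column names are the channel
#' ids.
#'
#' @param path path to a CSV file written by [write_segment()] or following
#'   the same convention.
#' @return An [egm_segment].
#' @export
read_segment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1L)) {
    stop("format error: metadata lines must form a contiguous leading block")
  }
  meta <- list()
  for (ln in lines[hdr_idx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
    }
  }
  if (is.null(meta$fs)) {
    stop("format error: header must declare fs (e.g. '# fs=2034.5')")
  }
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs)) stop("format error: fs header is not numeric")
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  ncells <- lengths(strsplit(body[nzchar(body)], ",", fixed = TRUE))
  if (length(unique(ncells)) > 1L) {
    stop("format error: ragged channel columns (rows have ",
         paste(sort(unique(ncells)), collapse = "/"), " cells)")
  }
  tab <- utils::read.csv(textConnection(paste(body, collapse = "\n")),
                         check.names = FALSE)
  mat <- t(as.matrix(tab))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("validation error: missing value in channel '%s' at sample %d",
                 rownames(mat)[bad[["row"]]], bad[["col"]]))
  }
  pos <- if (!is.null(meta$position)) {
    as.numeric(strsplit(meta$position, ",", fixed = TRUE)[[1L]])
  }
  ids <- rownames(mat)
  dimnames(mat) <- NULL
  seg <- egm_segment(mat, fs = fs, channel_ids = ids,
                     site_id = meta$site_id %||% "site",
                     patient_id = meta$patient_id %||% "patient",
                     position = pos,
                     anatomical_label = meta$anatomical_label)
  log_info("read segment %s: %d ch x %d samples", seg$site_id,
           nrow(seg$samples), ncol(seg$samples))
  seg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an electrogram segment to CSV
#'
#' Inverse of [read_segment()]; numeric values are written with full
#' double precision (17 significant digits) so a round trip reproduces the
#' sample matrix bit for bit.
#'
#' @param segment an [egm_segment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path) {
  stopifnot(inherits(segment, "egm_segment"))
  hdr <- c(sprintf("# fs=%.17g", segment$fs),
           sprintf("# site_id=%s", segment$site_id),
           sprintf("# patient_id=%s", segment$patient_id))
  if (!is.null(segment$position)) {
    hdr <- c(hdr, sprintf("# position=%s",
                          paste(sprintf("%.17g", segment$position), collapse = ",")))
  }
  if (!is.null(segment$anatomical_label)) {
    hdr <- c(hdr, sprintf("# anatomical_label=%s", segment$anatomical_label))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(segment$channel_ids, collapse = ","), con)
  body <- apply(segment$samples, 2L, function(col) {
    paste(sprintf("%.17g", col), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' Write per-site metrics to a delimited table
#'
#' @param metrics a `site_metrics` data frame (see [compute_site_metrics()]
#'   and [classify_sites()]); must be non-empty.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("metrics must be a non-empty data frame of site metrics")
  }
  cols <- c("site_id", "patient_id", "RDF_Hz", "WBR_per_s",
            "n_wavebreaks", "duration_s", "flag_upRDF_downWBR")
  missing <- setdiff(cols, names(metrics))
  if (length(missing)) {
    stop("metrics is missing columns: ", paste(missing, collapse = ", "))
  }
  out <- metrics[cols]
  for (nm in c("RDF_Hz", "WBR_per_s", "duration_s")) {
    out[[nm]] <- sprintf("%.6f", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site-metrics table written by [write_metrics()]
#' @param path CSV path.
#' @return data frame with the standard site-metrics columns.
#' @export
read_metrics <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$flag_upRDF_downWBR <- as.logical(tab$flag_upRDF_downWBR)
  tab
}
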