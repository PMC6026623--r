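#' Flag high-RDF / low-WBR sites within one patient
#'
#' A site is flagged when its RDF lies in the patient's upper quartile
#' range (RDF >= per-patient 75th percentile) and its WBR in the lower
#' quartile range (WBR <= per-patient 25th percentile), both with the
#' linear-interpolation percentile convention and ties included. The scale
#' is relative to each patient, not absolute.
#'
#' @param metrics data frame of site metrics for a single patient, with
#'   columns `patient_id`, `RDF_Hz`, `WBR_per_s` (see
#'   [compute_site_metrics()]).
#' @return the input with the logical column `flag_upRDF_downWBR` set.
#'   With fewer than 4 sites no site is flagged and a warning is issued.
#' @export
classify_sites <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  if (length(unique(metrics$patient_id)) > 1L) {
    stop("classify_sites expects sites of a single patient; got: ",
         paste(unique(metrics$patient_id), collapse = ", "))
  }
  if (nrow(metrics) < 4L) {
    log_warn("patient %s has %d sites (< 4): no site classified",
             unique(metrics$patient_id), nrow(metrics))
    metrics$flag_upRDF_downWBR <- rep(FALSE, nrow(metrics))
    return(metrics)
  }
  q3_rdf <- quartile(metrics$RDF_Hz, 0.75)
  q1_wbr <- quartile(metrics$WBR_per_s, 0.25)
  metrics$flag_upRDF_downWBR <-
    metrics$RDF_Hz >= q3_rdf & metrics$WBR_per_s <= q1_wbr
  if (all(metrics$flag_upRDF_downWBR)) {
    log_warn("degenerate metric distribution for patient %s: all sites flagged",
             unique(metrics$patient_id))
  }
  metrics
}

#' Map metric values to 64-level color indices
#'
#' Linear binning of the observed `[min, max]` range into 64 levels:
#' the lowest recorded value maps to index 0 (blue) and the highest to
#' index 63 (red), producing a relative scale per dataset.
#'
#' @param values numeric metric values (Hz or WB/s), at least one.
#' @return integer color indices in `[0, 63]`.
#' @export
colorize <- function(values) {
  if (length(values) == 0L) stop("no values to colorize")
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    log_warn("constant metric values: degenerate color range, all index 0")
    return(rep(0L, length(values)))
  }
  idx <- floor((values - rng[1L]) / (rng[2L] - rng[1L]) * 64)
  pmin(as.integer(idx), 63L)
}

#' 64-entry blue-to-red colormap
#'
#' Fixed linear ramp blue -> cyan -> yellow -> red used for RDF and WBR
#' geometry maps; index 0 is blue (lowest value), 63 red (highest).
#'
#' @return character vector of 64 hex colors.
#' @export
wb_colormap <- function() {
  grDevices::colorRampPalette(
    c("#0000FF", "#00FFFF", "#FFFF00", "#FF0000"))(64)
}

#' Build a colored point-cloud geometry map from site metrics
#'
#' @param metrics data frame of site metrics including a position per site
#'   (columns `x`, `y`, `z` in mm, or a list-column `position`).
#' @param metric which metric to color, `"rdf"` or `"wbr"`.
#' @return data frame of class `geometry_map` with columns `site_id`, `x`,
#'   `y`, `z`, `value`, `color_index`.
#' @export
build_map <- function(metrics, metric = c("rdf", "wbr")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  if (!all(c("x", "y", "z") %in% names(metrics)) &&
      "position" %in% names(metrics)) {
    pos <- do.call(rbind, metrics$position)
    metrics$x <- pos[, 1L]; metrics$y <- pos[, 2L]; metrics$z <- pos[, 3L]
  }
  if (!all(c("x", "y", "z") %in% names(metrics))) {
    stop("no site positions available (need x/y/z columns or position)")
  }
  bad <- metrics$site_id[!stats::complete.cases(metrics[c("x", "y", "z")])]
  if (length(bad)) {
    stop("missing position for site(s): ", paste(bad, collapse = ", "))
  }
  value <- if (metric == "rdf") metrics$RDF_Hz else metrics$WBR_per_s
  out <- data.frame(site_id = metrics$site_id,
                    x = metrics$x, y = metrics$y, z = metrics$z,
                    value = value, color_index = colorize(value),
                    stringsAsFactors = FALSE)
  class(out) <- c("geometry_map", "data.frame")
  out
}

#' Write a geometry map as point-cloud CSV
#' @param map a [build_map()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(map, path) {
  utils::write.csv(map[c("x", "y", "z", "value", "color_index")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a geometry map as legacy-VTK polydata (points + scalars)
#' @param map a [build_map()] result.
#' @param path output path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_geometry_vtk <- function(map, path) {
  n <- nrow(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "rdfwave site map", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%g %g %g", map$x, map$y, map$z), con)
  writeLines(c(sprintf("VERTICES %d %d", n, 2L * n)), con)
  writeLines(sprintf("1 %d", seq_len(n) - 1L), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS value float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", map$value), con)
  writeLines(c("SCALARS color_index int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", map$color_index), con)
  invisible(path)
}

#' Summarize metrics by anatomical region
#'
#' Grouped means/counts keyed by the user-supplied `anatomical_label`,
#' for region-prevalence tables of flagged sites.
#'
#' @param metrics classified site-metrics data frame with an
#'   `anatomical_label` column.
#' @return data frame with one row per label: site count, mean RDF, mean
#'   WBR and number of flagged sites.
#' @export
region_summary <- function(metrics) {
  stopifnot("anatomical_label" %in% names(metrics))
  sp <- split(metrics, metrics$anatomical_label)
  out <- do.call(rbind, lapply(names(sp), function(lbl) {
    m <- sp[[lbl]]
    data.frame(anatomical_label = lbl, n_sites = nrow(m),
               mean_RDF_Hz = mean(m$RDF_Hz),
               mean_WBR_per_s = mean(m$WBR_per_s),
               n_flagged = sum(m$flag_upRDF_downWBR %||% FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
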