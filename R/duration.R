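#' Fisher-z 95% confidence interval for a Pearson correlation
#'
#' @param r sample correlation.
#' @param n number of paired observations (> 3).
#' @param level confidence level, default 0.95.
#' @return length-2 numeric `c(lo, hi)`; degenerate `[r, r]` when
#'   `|r| = 1` (the Fisher transform diverges there).
#' @keywords internal
fisher_ci <- function(r, n, level = 0.95) {
  if (abs(r) >= 1 - 1e-12) return(c(r, r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Metric stability versus analyzed segment duration
#'
#' For each candidate duration D, recomputes the metric (RDF or WBR) from
#' only the first D seconds of every segment and correlates it (Pearson)
#' against the value from the gold-standard duration. This answers the
#' practical mapping question: how short can a recording be before the
#' site metric stops agreeing with a long recording? The working
#' convention is that a duration is acceptable once the correlation with
#' the gold standard exceeds 0.85.
#'
#' @param segments list of [egm_segment] (each at least `gold_duration`
#'   long; shorter segments are excluded with a warning).
#' @param metric `"rdf"` or `"wbr"`.
#' @param durations numeric vector of candidate durations D (s); default
#'   1-30 s step 1 for RDF and 5-50 s step 5 for WBR.
#' @param gold_duration gold-standard duration (s); default 30 for RDF,
#'   50 for WBR.
#' @param config analysis configuration, see [default_config()].
#' @return data frame of class `duration_curve` with columns `D`, `r`,
#'   `ci_lo`, `ci_hi`, plus attributes `metric`, `gold_duration`, `n`.
#' @export
stability_curve <- function(segments, metric = c("rdf", "wbr"),
                            durations = NULL, gold_duration = NULL,
                            config = default_config()) {
  metric <- match.arg(metric)
  if (is.null(gold_duration)) gold_duration <- if (metric == "rdf") 30 else 50
  if (is.null(durations)) {
    durations <- if (metric == "rdf") seq(1, 30) else seq(5, 50, by = 5)
  }
  durations <- durations[durations <= gold_duration]
  long_enough <- vapply(segments, function(s) {
    segment_duration(s) >= gold_duration - 1e-9
  }, logical(1L))
  if (any(!long_enough)) {
    log_warn("%d segment(s) shorter than the %g-s gold duration excluded",
             sum(!long_enough), gold_duration)
  }
  segments <- segments[long_enough]
  if (length(segments) < 3L) {
    stop("need at least 3 segments of gold duration for a correlation")
  }
  metric_at <- function(seg, D) {
    m <- suppressWarnings(
      compute_site_metrics(truncate_segment(seg, D), config))
    if (metric == "rdf") m$RDF_Hz else m$WBR_per_s
  }
  gold <- vapply(segments, metric_at, numeric(1L), D = gold_duration)
  rows <- lapply(durations, function(D) {
    v <- if (abs(D - gold_duration) < 1e-9) gold else {
      vapply(segments, metric_at, numeric(1L), D = D)
    }
    r <- if (stats::sd(v) == 0 || stats::sd(gold) == 0) NA_real_ else
      stats::cor(v, gold)
    ci <- if (is.na(r)) c(NA_real_, NA_real_) else fisher_ci(r, length(gold))
    data.frame(D = D, r = r, ci_lo = ci[1L], ci_hi = ci[2L])
  })
  out <- do.call(rbind, rows)
  attr(out, "metric") <- toupper(metric)
  attr(out, "gold_duration") <- gold_duration
  attr(out, "n") <- length(gold)
  class(out) <- c("duration_curve", "data.frame")
  out
}

#' Cohort statistics report
#'
#' Standard reporting utilities over a table of site metrics: Spearman
#' rank correlation between RDF and WBR, Anderson-Darling normality
#' checks, mean +/- sd summaries, and (when a two-level grouping column is
#' given) Mann-Whitney comparisons of RDF and WBR between the groups.
#'
#' @param metrics site-metrics data frame (>= 5 rows) with columns
#'   `RDF_Hz` and `WBR_per_s`.
#' @param group optional name of a column with exactly two levels (e.g.
#'   paroxysmal vs persistent); each group needs >= 3 members.
#' @return list of class `cohort_report`: `spearman` (rho, p),
#'   `normality` (per-metric Anderson-Darling statistic, p, and a
#'   `normal` flag at alpha = 0.05), `summary` (mean, sd, median, range
#'   per metric), and `group_comparison` when requested (Mann-Whitney W
#'   and p per metric).
#' @export
cohort_stats <- function(metrics, group = NULL) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) < 5L) stop("need at least 5 sites for cohort statistics")
  ct <- suppressWarnings(
    stats::cor.test(metrics$RDF_Hz, metrics$WBR_per_s, method = "spearman"))
  summarize <- function(x) {
    c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
      min = min(x), max = max(x))
  }
  ad <- function(x) {
    # nortest's Anderson-Darling needs non-degenerate data
    if (stats::sd(x) == 0) {
      return(list(statistic = NA_real_, p.value = 0, normal = FALSE))
    }
    t <- nortest::ad.test(x)
    list(statistic = unname(t$statistic), p.value = t$p.value,
         normal = t$p.value >= 0.05)
  }
  report <- list(
    n_sites = nrow(metrics),
    spearman = list(rho = unname(ct$estimate), p.value = ct$p.value),
    normality = list(RDF = ad(metrics$RDF_Hz), WBR = ad(metrics$WBR_per_s)),
    summary = list(RDF_Hz = summarize(metrics$RDF_Hz),
                   WBR_per_s = summarize(metrics$WBR_per_s)))
  if (!is.null(group)) {
    g <- metrics[[group]]
    lv <- unique(g)
    if (length(lv) != 2L) stop("grouping column must have exactly 2 levels")
    if (any(table(g) < 3L)) stop("each group needs at least 3 members")
    mw <- function(x) {
      t <- stats::wilcox.test(x[g == lv[1L]], x[g == lv[2L]], exact = FALSE)
      list(W = unname(t$statistic), p.value = t$p.value)
    }
    report$group_comparison <- list(
      levels = as.character(lv),
      RDF = mw(metrics$RDF_Hz), WBR = mw(metrics$WBR_per_s))
  }
  class(report) <- "cohort_report"
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d sites\n", x$n_sites))
  cat(sprintf("  RDF %.2f +/- %.2f Hz; WBR %.3f +/- %.3f WB/s\n",
              x$summary$RDF_Hz["mean"], x$summary$RDF_Hz["sd"],
              x$summary$WBR_per_s["mean"], x$summary$WBR_per_s["sd"]))
  cat(sprintf("  Spearman rho(RDF, WBR) = %.3f (p = %.3g)\n",
              x$spearman$rho, x$spearman$p.value))
  if (!is.null(x$group_comparison)) {
    cat(sprintf("  Mann-Whitney %s vs %s: RDF p = %.3g, WBR p = %.3g\n",
                x$group_comparison$levels[1L], x$group_comparison$levels[2L],
                x$group_comparison$RDF$p.value, x$group_comparison$WBR$p.value))
  }
  invisible(x)
}

#' Write a cohort report as JSON
#' @param report a [cohort_stats()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
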