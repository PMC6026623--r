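#' @keywords internal
"_PACKAGE"

# Per-stage logging. INFO lines go through message() so they can be
# suppressed or captured; WARN uses warning() to surface degenerate cases.
log_info <- function(...) {
  if (isTRUE(getOption("rdfwave.verbose", FALSE))) {
    message("INFO [rdfwave] ", sprintf(...))
  }
  invisible(NULL)
}

log_warn <- function(...) {
  warning(sprintf(...), call. = FALSE)
  invisible(NULL)
}

#' Same-length centered convolution
#'
#' Linear convolution of `x` with `kernel`, returning a series the same
#' length as `x`, aligned so that the kernel tap at `center` lands on the
#' sample it is applied to (group-delay compensation for a kernel treated
#' as zero-phase).
#'
#' @param x numeric vector.
#' @param kernel numeric filter taps.
#' @param center 1-based index of the kernel tap treated as time zero;
#'   defaults to the position of the kernel maximum.
#' @return numeric vector, `length(x)`.
#' @keywords internal
conv_same <- function(x, kernel, center = which.max(kernel)) {
  nx <- length(x)
  nk <- length(kernel)
  if (nx < nk) {
    stop("series (", nx, " samples) must be at least as long as the kernel (",
         nk, " taps)")
  }
  # full linear convolution via FFT; convolve(type = "open") reverses the
  # second argument, so pass the kernel reversed to get true convolution
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[center:(center + nx - 1L)]
}

# quantile convention used throughout: linear interpolation (type 7)
quartile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}
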