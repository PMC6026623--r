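# Shared fixtures built in code at test time.

# A small clean segment: biphasic spikes at known times on every channel.
# Returns the segment plus the injected spike times.
spike_segment <- function(n_channels = 2, duration_s = 3, fs = 2000,
                          spike_times = seq(0.25, duration_s - 0.25, by = 0.2),
                          delay_s = rep(0, n_channels)) {
  n <- round(duration_s * fs)
  tgrid <- (seq_len(n) - 1) / fs
  mk <- function(d) {
    sig <- numeric(n)
    for (t0 in spike_times + d) {
      sig <- sig - ((tgrid - t0) / 0.002) * exp(-(tgrid - t0)^2 / (2 * 0.002^2))
    }
    sig
  }
  samples <- do.call(rbind, lapply(delay_s, mk))
  egm_segment(samples, fs = fs)
}

# count strict local maxima of a vector above a floor
count_peaks <- function(x, floor = 0.1) {
  n <- length(x)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n] &
        x[2:(n - 1)] > floor)
}

# independent brute-force DFT power by direct summation (double loop kept
# deliberately naive -- this is the oracle, not the implementation)
brute_dft_power <- function(x, fs, freqs) {
  n <- length(x)
  t <- (0:(n - 1)) / fs
  vapply(freqs, function(f) {
    re <- 0; im <- 0
    for (i in seq_len(n)) {
      re <- re + x[i] * cos(2 * pi * f * t[i])
      im <- im - x[i] * sin(2 * pi * f * t[i])
    }
    re^2 + im^2
  }, numeric(1))
}

# reference site-metrics table for classification tests
fake_metrics <- function(rdf, wbr, patient = "p1",
                         site = sprintf("s%02d", seq_along(rdf))) {
  data.frame(site_id = site, patient_id = patient, RDF_Hz = rdf,
             WBR_per_s = wbr, n_wavebreaks = round(wbr * 25),
             duration_s = 25, flag_upRDF_downWBR = NA,
             stringsAsFactors = FALSE)
}
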