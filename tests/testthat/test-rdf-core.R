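make_train <- function(values, fs = 2000) {
  structure(list(values = values, fs = fs, silent = all(values == 0)),
            class = "pulse_train")
}

test_that("averaging is the per-sample mean and validates its inputs", {
  a <- make_train(c(0, 1, 0, 0.5))
  expect_equal(average_pulse_trains(list(a, a)), a$values)
  b <- make_train(c(1, 0, 1, 0.5))
  expect_equal(average_pulse_trains(list(a, b)), c(0.5, 0.5, 0.5, 0.5))
  expect_error(average_pulse_trains(list(a)), "at least 2")
  expect_error(average_pulse_trains(list(a, make_train(c(1, 2)))),
               "mismatched length")
})

test_that("synchronized pulses keep their peak; dispersed pulses lose it", {
  fs <- 2000
  sync <- spike_segment(n_channels = 10, duration_s = 3, fs = fs,
                        delay_s = rep(0, 10))
  tr_sync <- condition_segment(sync)
  avg_sync <- average_pulse_trains(tr_sync)
  expect_gt(max(avg_sync), 0.95 * max(tr_sync[[1]]$values))

  disp <- spike_segment(n_channels = 10, duration_s = 3, fs = fs,
                        delay_s = seq(0, 0.18, length.out = 10))
  tr_disp <- condition_segment(disp)
  avg_disp <- average_pulse_trains(tr_disp)
  expect_lt(max(avg_disp), 0.5 * max(tr_disp[[1]]$values))
})

test_that("the two-sided exponential kernel has its stated shape", {
  h <- exponential_fir()
  expect_length(h, 180L)
  expect_true(all(h > 0 & h <= 1))
  expect_equal(which.max(h), 91L)
  expect_equal(h[[91]], 1)
  expect_equal(h[[1]], exp(-1))
  # two-sided: rises before the center tap, falls after it
  expect_true(all(diff(as.numeric(h)[1:91]) > 0))
  expect_true(all(diff(as.numeric(h)[91:180]) < 0))
})

test_that("smoothing is centered convolution with the expected gain", {
  h <- exponential_fir()
  imp <- c(numeric(300), 1, numeric(300))
  out <- smooth_envelope(imp, h)
  expect_length(out, length(imp))
  expect_equal(which.max(out), 301L)  # no group delay
  expect_equal(out[301 + (-90:89)], as.numeric(h), tolerance = 1e-12)

  dc <- rep(2.5, 1000)
  out_dc <- smooth_envelope(dc, h)
  expect_equal(out_dc[500], 2.5 * sum(h), tolerance = 1e-6)

  alt <- rep(c(1, -1), 500)  # Nyquist-rate alternation
  expect_lt(sqrt(mean(smooth_envelope(alt, h)^2)), 0.5 * sqrt(mean(alt^2)))
  expect_error(smooth_envelope(numeric(10), h), "kernel")
})

test_that("RDF is the linear-interpolation upper quartile", {
  expect_equal(rdf(rep(5, 40)), 5)
  expect_equal(rdf(c(4, 5, 6, 7)), 6.25)
  # independent oracle: manual type-7 percentile
  set.seed(31)
  v <- runif(17, 3, 8)
  s <- sort(v)
  hidx <- (length(v) - 1) * 0.75 + 1
  manual <- s[floor(hidx)] + (hidx - floor(hidx)) * (s[ceiling(hidx)] - s[floor(hidx)])
  expect_equal(rdf(v), manual)
  expect_error(rdf(numeric(0)), "empty")
})

test_that("RDF is monotone under pointwise non-decreasing transforms", {
  set.seed(8)
  for (i in 1:20) {
    v <- runif(30, 1, 9)
    expect_gte(rdf(v + 0.5), rdf(v))
    expect_gte(rdf(pmin(v * 1.3, 20)), rdf(v))
  }
})

test_that("iRDF equals the single-channel iEDF for identical channels", {
  sim <- simulate_segment(simulation_spec(duration_s = 6, n_channels = 1,
                                          fractionation_prob = 0, seed = 4))
  x <- sim$segment$samples[1, ]
  fs <- sim$segment$fs
  seg <- egm_segment(rbind(x, x, x, x), fs = fs)
  s_irdf <- irdf(seg)
  s_iedf <- iedf(x, fs)
  # same envelope up to the FIR smoothing; compare after applying the same
  # chain to the single channel
  pt <- condition_channel(x, fs)
  env1 <- list(values = remove_mean(smooth_envelope(pt$values)), fs = fs)
  s_one <- instantaneous_df(stft_power(env1$values, fs), kind = "iRDF")
  expect_identical(s_irdf$values, s_one$values)
  expect_identical(s_irdf$kind, "iRDF")
  expect_length(s_irdf$values, length(s_iedf$values))
})

test_that("iRDF is invariant to uniform amplitude scaling of all channels", {
  sim <- simulate_segment(simulation_spec(duration_s = 5, seed = 6))
  seg <- sim$segment
  scaled <- egm_segment(7.3 * seg$samples, fs = seg$fs)
  expect_identical(irdf(seg)$values, irdf(scaled)$values)
})

test_that("organized segments hold a tight iRDF span around the base rate", {
  sim <- simulate_segment(simulation_spec(duration_s = 12, base_rate_hz = 5.2,
                                          fractionation_prob = 0, seed = 10))
  s <- irdf(sim$segment)
  expect_true(all(abs(s$values - 5.2) <= 0.05 + 1e-9))
  expect_lte(diff(range(s$values)), 0.6)
})
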