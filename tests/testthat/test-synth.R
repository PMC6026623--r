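test_that("simulation is deterministic given the seed", {
  a <- simulate_segment(simulation_spec(duration_s = 2, seed = 123))
  b <- simulate_segment(simulation_spec(duration_s = 2, seed = 123))
  expect_identical(a$segment$samples, b$segment$samples)
  expect_identical(a$truth$activations, b$truth$activations)
  c <- simulate_segment(simulation_spec(duration_s = 2, seed = 124))
  expect_false(identical(a$segment$samples, c$segment$samples))
})

test_that("activation counts track base_rate x duration per channel", {
  sim <- simulate_segment(simulation_spec(duration_s = 30, base_rate_hz = 5,
                                          seed = 1))
  counts <- lengths(sim$truth$activations)
  expect_true(all(abs(counts - 150) <= 2))
  expect_length(sim$truth$wavefronts, 150L)
})

test_that("episode invariants are validated", {
  expect_error(simulation_spec(episodes = data.frame(t_start = 5, t_end = 40)),
               "within")
  expect_error(simulation_spec(
    episodes = data.frame(t_start = c(5, 5.3), t_end = c(5.6, 5.9))),
    "overlap")
  expect_error(simulation_spec(sigma_wb_ms = 4, sigma_delay_ms = 5))
})

test_that("dispersed activations stay inside their episode", {
  sp <- simulation_spec(duration_s = 10, base_rate_hz = 5,
                        episodes = data.frame(t_start = 4, t_end = 4.5),
                        seed = 9)
  sim <- simulate_segment(sp)
  # one activation per wavefront per channel here (no edge losses), so
  # activation j of every channel belongs to wavefront j
  idx <- which(sim$truth$wavefronts >= 4 & sim$truth$wavefronts < 4.5)
  expect_length(idx, 2L)
  for (at in sim$truth$activations) {
    expect_length(at, length(sim$truth$wavefronts))
    expect_true(all(at[idx] >= 4 & at[idx] < 4.5))
  }
})

test_that("organized segments recover rate and produce no wave breaks", {
  sim <- simulate_segment(simulation_spec(duration_s = 12, base_rate_hz = 6,
                                          fractionation_prob = 0, seed = 2))
  m <- suppressWarnings(compute_site_metrics(sim$segment))
  expect_equal(m$RDF_Hz, 6, tolerance = 0.2)
  expect_identical(m$n_wavebreaks, 0L)

  # under default conditions (baseline fractionation, 10 dB noise) the
  # iRDF wanders a little more but stays near the rate with no breaks
  sim_d <- simulate_segment(simulation_spec(duration_s = 12,
                                            base_rate_hz = 5, seed = 3))
  m_d <- suppressWarnings(compute_site_metrics(sim_d$segment,
                                               keep_series = TRUE))
  expect_true(all(abs(attr(m_d, "irdf")$values - 5) <= 0.2))
  expect_identical(m_d$n_wavebreaks, 0L)
})

test_that("injected episode counts are recovered for K = 0..3", {
  # 0.5-s episodes, >= 1.2 s apart, on a 20-s segment
  starts <- c(4, 8.5, 14)
  for (K in 0:3) {
    eps <- if (K == 0) NULL else
      data.frame(t_start = starts[seq_len(K)],
                 t_end = starts[seq_len(K)] + 0.5)
    sim <- simulate_segment(simulation_spec(duration_s = 20, base_rate_hz = 5,
                                            episodes = eps, seed = 50 + K))
    m <- suppressWarnings(compute_site_metrics(sim$segment))
    expect_identical(m$n_wavebreaks, K, info = paste("K =", K))
  }
})

test_that("cohorts are reproducible and span the requested rate range", {
  coh1 <- simulate_cohort(5, seed = 77, duration_s = 2)
  coh2 <- simulate_cohort(5, seed = 77, duration_s = 2)
  expect_identical(lapply(coh1, function(s) s$segment$samples),
                   lapply(coh2, function(s) s$segment$samples))
  rates <- vapply(coh1, function(s) s$truth$base_rate_hz, numeric(1))
  expect_true(all(rates >= 3.5 & rates <= 7.5))
  expect_length(simulate_cohort(1, seed = 1, duration_s = 2), 1L)
})

test_that("SNR control injects the requested noise power", {
  clean <- simulate_segment(simulation_spec(duration_s = 2, snr_db = Inf,
                                            seed = 31))
  noisy <- simulate_segment(simulation_spec(duration_s = 2, snr_db = 10,
                                            seed = 31))
  noise <- noisy$segment$samples - clean$segment$samples
  snr_emp <- 10 * log10(mean(clean$segment$samples^2) / mean(noise^2))
  expect_equal(snr_emp, 10, tolerance = 0.5)
})
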