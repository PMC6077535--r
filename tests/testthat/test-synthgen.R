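test_that("background noise respects noise_sd, seed, and dimensions", {
  p0 <- quiet_profile(noise_sd = 0)
  expect_equal(generate_background_noise(100, 3, p0),
               matrix(0, 3, 100))

  p <- subject_profile(noise_sd = 1, seed = 99L)
  a <- generate_background_noise(5000, 2, p)
  b <- generate_background_noise(5000, 2, p)
  expect_identical(a, b)
  expect_equal(dim(a), c(2L, 5000L))

  expect_error(generate_background_noise(0, 2, p), "positive")

  # sample SD agrees with an independent re-simulation of the same
  # pink + white mixing policy at the same seed
  n <- 1e5
  set.seed(321)
  got <- generate_background_noise(n, 1, subject_profile(noise_sd = 1,
                                                         seed = 321L))
  set.seed(321)
  k <- 0:(n - 1); fr <- pmin(k, n - k)
  shape <- 1 / sqrt(pmax(fr, 1)); shape[1] <- 0
  w <- rnorm(n)
  pink <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  ref <- 0.8 * pink / sd(pink) + 0.6 * rnorm(n)
  expect_lt(abs(sd(got) - sd(ref)) / sd(ref), 0.2)
})

test_that("ssvep blocks carry the phase-condition and delay timing", {
  cfg <- paradigm_config()
  p <- quiet_profile()

  b0 <- generate_ssvep_block(0, node_timing(0, 0), cfg, p)
  expect_equal(b0$true_peak_ms, 15.625)
  expect_equal(b0$true_lag_deg, 0)

  b90 <- generate_ssvep_block(90, node_timing(0, 0), cfg, p)
  expect_equal(b90$true_lag_deg, 90)
  expect_equal(b90$true_peak_ms, 15.625 + 15.625)

  bd <- generate_ssvep_block(0, node_timing(0, 10), cfg, p)
  expect_equal(bd$true_lag_deg, 10 / 62.5 * 360) # 57.6 degrees

  expect_error(generate_ssvep_block(45, node_timing(0, 0), cfg, p),
               "unsupported")

  # the embedded waveform really peaks where the truth says
  t_res <- estimate_response_peak(bd$segment, 16, 500)
  expect_equal(t_res, bd$true_peak_ms, tolerance = 1e-6)
})

test_that("p300 epochs put the deflection at base + delay (+ jitter)", {
  cfg <- paradigm_config()
  p <- quiet_profile(seed = 5L)

  nt <- generate_p300_epoch(FALSE, node_timing(0, 0, 0), p, cfg)
  expect_true(all(nt$segment == 0))
  expect_true(is.na(nt$true_latency_ms))

  p_flat <- quiet_profile(p300_amplitude = 0, seed = 5L)
  tg <- generate_p300_epoch(TRUE, node_timing(0, 0, 0), p_flat, cfg)
  expect_true(all(tg$segment == 0))

  tg2 <- generate_p300_epoch(TRUE, node_timing(0, 46.875, 0), p, cfg)
  expect_equal(tg2$true_latency_ms, p$p300_base_latency + 46.875)
  # peak sample within one sample period of the recorded latency
  pz <- tg2$segment["Pz", ]
  peak_ms <- (which.max(pz) - 1) / cfg$sampling_rate * 1000
  expect_lt(abs(peak_ms - tg2$true_latency_ms), 1000 / cfg$sampling_rate + 1e-9)
  # parietal amplitude double the occipital amplitude
  expect_equal(max(tg2$segment["O1", ]), max(pz) / 2, tolerance = 1e-9)
})

test_that("registration sessions follow the paradigm arithmetic", {
  cfg <- small_cfg(flashes = 30L)
  p <- subject_profile(noise_sd = 1, seed = 7L)
  nodes <- still_nodes()
  sess <- simulate_registration_session(nodes, cfg, p)

  # per registered node: 30 flashes x 4 stimuli
  blk <- sess$truth$flash[sess$truth$flash$block == 1 &
                            sess$truth$flash$ref_node == 0, ]
  expect_equal(nrow(blk), 120)
  expect_equal(sum(blk$is_target), 30)
  expect_equal(sum(!blk$is_target), 90)

  # one flicker block per condition per node, with zero-delay truth lags 0
  fk <- sess$truth$flicker
  expect_equal(nrow(fk), 4 * 4)
  expect_true(all(fk$true_lag_deg == fk$phase_condition))
  expect_true(all(wrap_deg(fk$true_lag_deg - fk$phase_condition) == 0))

  # event onsets non-decreasing
  expect_true(!is.unsorted(sess$events$onset_s))

  # determinism under the profile seed
  sess2 <- simulate_registration_session(nodes, cfg, p)
  expect_identical(sess$recording$data, sess2$recording$data)
  expect_identical(sess$events, sess2$events)
})

test_that("operation sessions produce the trial-epoch arithmetic", {
  cfg <- small_cfg()
  p <- subject_profile(noise_sd = 1, seed = 11L)
  sess <- simulate_operation_session(still_nodes(), cfg, p, n_trials = 12L)

  expect_equal(nrow(sess$truth$trials), 12)
  fl <- sess$events[sess$events$kind == "flash", ]
  expect_equal(nrow(fl), 12 * 4 * cfg$repetitions)
  # per trial: the cued node is target for exactly `repetitions` flashes
  for (tr in 1:3) {
    rows <- fl[fl$block == tr, ]
    expect_equal(sum(rows$is_target), cfg$repetitions)
    expect_equal(unique(rows$node_id[rows$is_target]),
                 sess$truth$trials$cued_node[tr])
  }
  sess2 <- simulate_operation_session(still_nodes(), cfg, p, n_trials = 12L)
  expect_identical(sess$recording$data, sess2$recording$data)
})

test_that("ssvep lag and p300 latency share the transmission delay", {
  # difference between (P300 latency - base) in ms and lag in delay-ms is
  # constant across nodes when jitter = 0: both equal the node delay
  cfg <- paradigm_config()
  p <- quiet_profile()
  for (d in c(0, 12.5, 31.25)) {
    nd <- node_timing(0, d, 0)
    blk <- generate_ssvep_block(0, nd, cfg, p)
    ep <- generate_p300_epoch(TRUE, nd, p, cfg)
    lag_ms <- blk$true_lag_deg / 360 * 62.5
    expect_equal(lag_ms, d)
    expect_equal(ep$true_latency_ms - p$p300_base_latency, d)
  }
})
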