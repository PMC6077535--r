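make_rec <- function(x, fs = 500) {
  eeg_recording(matrix(x, 1, length(x)), fs, "Pz")
}

test_that("band-pass keeps the SSVEP band and rejects out-of-band energy", {
  fs <- 500; t <- (0:4999) / fs
  rms <- function(x) sqrt(mean(x^2))

  out2 <- bandpass_filter(make_rec(sin(2 * pi * 2 * t)))$data[1, ]
  expect_lt(rms(out2), 0.1 * rms(sin(2 * pi * 2 * t)))

  in16 <- sin(2 * pi * 16 * t)
  out16 <- bandpass_filter(make_rec(in16))$data[1, ]
  # interior samples only: filtfilt edge transients excluded
  core <- 500:4500
  expect_lt(abs(rms(out16[core]) - rms(in16[core])) / rms(in16[core]), 0.05)

  dc <- bandpass_filter(make_rec(rep(3, 5000)))$data[1, ]
  expect_lt(max(abs(dc)), 0.01)

  expect_error(bandpass_filter(make_rec(t), low = 0), "invalid band")
  expect_error(bandpass_filter(make_rec(t), low = 30, high = 20),
               "invalid band")
  expect_error(bandpass_filter(make_rec(t), high = 300), "invalid band")
})

test_that("epoch extraction uses floor-indexed half-open windows", {
  fs <- 500
  rec <- eeg_recording(matrix(seq_len(1000), 1, 1000), fs, "Pz")
  ev <- data.frame(onset_s = c(0.1, 0.5))
  ep <- extract_epochs(rec, ev, 0, 160)
  expect_equal(dim(ep$data), c(1L, 80L, 2L))
  # sample index floor(t * rate): onset 0.1 s -> sample 50 (0-based), value 51
  expect_equal(ep$data[1, 1, 1], 51)
  expect_equal(ep$data[1, 80, 1], 130)

  # start_offset 300 ms places the window at t_s + 300 .. t_s + 460
  ep2 <- extract_epochs(rec, data.frame(onset_s = 0.2), 300, 160)
  expect_equal(ep2$data[1, 1, 1], 251)
  expect_equal(dim(ep2$data)[2], 80L)

  expect_error(extract_epochs(rec, data.frame(onset_s = 1.99), 0, 160),
               "event 1")
  ev120 <- data.frame(onset_s = seq(0.1, 1.29, by = 0.01))
  expect_equal(dim(extract_epochs(rec, ev120, 0, 160)$data)[3], 120L)
})

test_that("decimation preserves geometry, constants, and band amplitudes", {
  fs <- 500
  ev <- data.frame(onset_s = 0)
  rec <- eeg_recording(matrix(rep(2.5, 200), 1), fs, "Pz")
  ep <- extract_epochs(rec, ev, 0, 160)
  dn <- downsample_epochs(ep, 62.5)
  expect_equal(dim(dn$data)[2], 10L)
  expect_true(all(dn$data == 2.5))
  expect_equal(dn$sampling_rate, 62.5)

  expect_error(downsample_epochs(ep, 60), "integer factor")

  # a 16 Hz sine keeps its amplitude through decimation (exact-bin fit
  # over the integer number of cycles in a 1 s epoch)
  t <- (0:499) / fs
  rec16 <- eeg_recording(matrix(sin(2 * pi * 16 * t), 1), fs, "Pz")
  ep16 <- downsample_epochs(extract_epochs(rec16, ev, 0, 1000), 62.5)
  x <- ep16$data[1, , 1]
  td <- (seq_along(x) - 1) / 62.5
  amp <- Mod(sum(x * exp(-2i * pi * 16 * td)) * 2 / length(x))
  expect_lt(abs(amp - 1), 0.05)
})

test_that("averaging is an idempotent, linear group mean", {
  fs <- 500
  base <- matrix(rnorm(5 * 40), 5, 40)
  arr <- array(0, dim = c(5, 40, 4))
  for (i in 1:4) arr[, , i] <- base
  eps <- structure(list(data = arr, t0_ms = 0, sampling_rate = fs,
                        channel_labels = paste0("ch", 1:5),
                        info = data.frame(g = c(1, 1, 2, 2),
                                          onset_s = 1:4)),
                   class = "epoch_set")
  avg <- average_epochs(eps, "g")
  expect_equal(dim(avg$data)[3], 2L)
  expect_equal(avg$data[, , 1], base)
  expect_equal(avg$info$n, c(2L, 2L))

  # cancellation: a and -a average to zero
  arr2 <- arr; arr2[, , 2] <- -base
  eps2 <- eps; eps2$data <- arr2
  expect_equal(max(abs(average_epochs(eps2, NULL)$data[, , 1] -
                         base / 2)), 0)

  # residual noise shrinks like sigma / sqrt(n)
  set.seed(42)
  n <- 30; sigma <- 4
  tmpl <- sin(seq(0, pi, length.out = 50))
  arr3 <- array(rnorm(50 * n, sd = sigma), dim = c(1, 50, n)) +
    rep(tmpl, each = 1)
  eps3 <- structure(list(data = arr3, t0_ms = 0, sampling_rate = fs,
                         channel_labels = "Pz",
                         info = data.frame(onset_s = seq_len(n))),
                    class = "epoch_set")
  resid <- average_epochs(eps3, NULL)$data[1, , 1] - tmpl
  expect_lt(abs(sd(resid) - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.5)

  expect_error(average_epochs(structure(list(
    data = array(0, c(1, 5, 0)), t0_ms = 0, sampling_rate = fs,
    channel_labels = "Pz", info = data.frame()), class = "epoch_set"),
    NULL), "empty")
})

test_that("latency centroid finds symmetric bumps and shifts equivariantly", {
  fs <- 500
  t_ms <- (0:299) / fs * 1000
  mk_ep <- function(center) {
    w <- exp(-(t_ms - center)^2 / (2 * 40^2))
    structure(list(data = matrix(rep(w, 3), 3, byrow = TRUE), t0_ms = 0,
                   sampling_rate = fs,
                   channel_labels = c("P3", "Pz", "P4")),
              class = "epoch_set1")
  }
  c310 <- estimate_p300_centroid(mk_ep(310))
  expect_lt(abs(c310$value - 310), 1000 / fs)
  expect_equal(c310$source, "measured")

  # equivariance: shifting the template shifts the centroid by the shift
  c350 <- estimate_p300_centroid(mk_ep(350))
  expect_lt(abs((c350$value - c310$value) - 40), 1000 / fs)

  flat <- mk_ep(310); flat$data[] <- 0
  expect_error(estimate_p300_centroid(flat), class = "bcicalib_no_p300")

  # recovery of base + delay from a generated average
  cfg <- paradigm_config()
  p <- quiet_profile(seed = 3L)
  eps <- lapply(1:12, function(i)
    generate_p300_epoch(TRUE, node_timing(0, 30, 0), p, cfg)$segment)
  avg <- Reduce(`+`, eps) / length(eps)
  ep <- structure(list(data = avg, t0_ms = 0, sampling_rate = fs,
                       channel_labels = cfg$channel_labels),
                  class = "epoch_set1")
  got <- estimate_p300_centroid(ep)
  expect_lt(abs(got$value - (p$p300_base_latency + 30)), 10)
})
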