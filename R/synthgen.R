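# Synthetic sessions emulating the stimulus-on-device paradigm: a coordinator
# sends triggers to wireless stimulation nodes; each node's flash (and hence
# its evoked response) is shifted by the node's transmission delay, while the
# event markers record the trigger send time. Ground truth for every flash,
# flicker block, and trial is returned alongside the recording.

# 1/f-shaped + white background noise, unit-free internal helper. Uses the
# current RNG stream. Pink component built by FFT amplitude shaping.
make_noise <- function(n_samples, n_channels, noise_sd) {
  if (noise_sd == 0) return(matrix(0, n_channels, n_samples))
  out <- matrix(0, n_channels, n_samples)
  k <- 0:(n_samples - 1)
  fr <- pmin(k, n_samples - k)
  shape <- 1 / sqrt(pmax(fr, 1))
  shape[1] <- 0 # no DC
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(n_samples)
    pink <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n_samples
    pink <- pink / stats::sd(pink)
    white <- stats::rnorm(n_samples)
    out[ch, ] <- noise_sd * (0.8 * pink + 0.6 * white)
  }
  out
}

#' Generate background EEG noise
#'
#' Produces 1/f-shaped ("pink") noise plus a white-noise floor, mixed so the
#' total standard deviation is `profile$noise_sd` microvolts. If the profile
#' carries a seed the call is reproducible.
#'
#' @param n_samples Number of time samples (> 0).
#' @param n_channels Number of channels (> 0).
#' @param profile A [subject_profile()]; `noise_sd` and `seed` are used.
#' @return A `n_channels x n_samples` matrix in microvolts.
#' @export
generate_background_noise <- function(n_samples, n_channels, profile) {
  if (n_samples <= 0 || n_channels <= 0)
    stop("n_samples and n_channels must be positive")
  if (!is.null(profile$seed)) set.seed(profile$seed)
  make_noise(n_samples, n_channels, profile$noise_sd)
}

# Add a Gaussian deflection (amplitude microvolts, center/width ms) to a
# channel x samples matrix, in place semantics via return value.
add_gaussian_bump <- function(data, channels, center_ms, amp, width_ms, fs) {
  n <- ncol(data)
  lo <- max(1L, floor((center_ms - 5 * width_ms) / 1000 * fs) + 1L)
  hi <- min(n, ceiling((center_ms + 5 * width_ms) / 1000 * fs) + 1L)
  if (hi < lo) return(data)
  t_ms <- ((lo:hi) - 1) / fs * 1000
  bump <- amp * exp(-(t_ms - center_ms)^2 / (2 * width_ms^2))
  for (ch in channels) data[ch, lo:hi] <- data[ch, lo:hi] + bump
  data
}

# SSVEP waveform samples for local times t_s (seconds from block onset).
# The response is the flicker sinusoid delayed by the stimulation-phase
# offset plus the node's transmission delay; its first positive peak falls at
# t_ref + phase*T/360 + delay (ms).
ssvep_wave <- function(t_s, condition_phase_deg, delay_ms, cfg, profile) {
  f <- cfg$flicker_freq
  period_ms <- 1000 / f
  shift_s <- (condition_phase_deg / 360 * period_ms + delay_ms +
                profile$ssvep_latency) / 1000
  profile$ssvep_gain * (sin(2 * pi * f * (t_s - shift_s)) +
    profile$ssvep_harmonic_ratio * sin(4 * pi * f * (t_s - shift_s)))
}

#' Generate one SSVEP flicker block
#'
#' A `flicker_duration`-second sinusoidal response at the flicker frequency
#' (plus a weak second harmonic) on the occipital channels, embedded in
#' background noise. The response peak latency equals
#' `t_ref + condition_phase * T/360 + transmission_delay`.
#'
#' @param condition_phase Stimulation phase condition in degrees; must be one
#'   of `cfg$phase_conditions`.
#' @param node A [node_timing()].
#' @param cfg A [paradigm_config()].
#' @param profile A [subject_profile()].
#' @return List with `segment` (channels x samples matrix), `true_lag_deg`
#'   (phase lag in `[0, 360)`), and `true_peak_ms` (first-peak latency within
#'   one period).
#' @export
generate_ssvep_block <- function(condition_phase, node, cfg = paradigm_config(),
                                 profile = subject_profile()) {
  if (!condition_phase %in% cfg$phase_conditions)
    stop("unsupported phase condition: ", condition_phase)
  if (!is.null(profile$seed)) set.seed(profile$seed)
  fs <- cfg$sampling_rate
  n <- round(cfg$flicker_duration * fs)
  seg <- make_noise(n, length(cfg$channel_labels), profile$noise_sd)
  rownames(seg) <- cfg$channel_labels
  t_s <- (0:(n - 1)) / fs
  occ <- which(cfg$channel_labels %in% c("O1", "O2"))
  wave <- ssvep_wave(t_s, condition_phase, node$transmission_delay, cfg, profile)
  for (ch in occ) seg[ch, ] <- seg[ch, ] + wave
  tm <- flicker_timing(cfg)
  total_delay <- node$transmission_delay + profile$ssvep_latency
  lag <- wrap_deg(condition_phase + delay_to_deg(total_delay, tm$period_ms))
  peak <- (tm$t_ref_ms + condition_phase / 360 * tm$period_ms +
             total_delay) %% tm$period_ms
  list(segment = seg, true_lag_deg = lag, true_peak_ms = peak)
}

# Draw the actual flash delay of one flash: Gaussian around the node's
# transmission delay, truncated at zero (a packet never arrives early enough
# to make the total delay negative).
draw_flash_delay <- function(node) {
  max(stats::rnorm(1, node$transmission_delay, node$flash_jitter_sd), 0)
}

#' Generate a single-flash P300 epoch
#'
#' Target flashes add a positive Gaussian deflection at
#' `p300_base_latency + actual flash delay + latency jitter`, full amplitude
#' on the parietal channels (P3, Pz, P4) and half amplitude on O1/O2;
#' nontarget flashes contain background noise only.
#'
#' @param is_target Logical flag.
#' @param node A [node_timing()].
#' @param profile A [subject_profile()].
#' @param cfg A [paradigm_config()].
#' @param epoch_ms Epoch length in ms from the trigger (default 800).
#' @return List with `segment` (channels x samples) and `true_latency_ms`
#'   (NA for nontargets), time measured from the trigger send time.
#' @export
generate_p300_epoch <- function(is_target, node, profile = subject_profile(),
                                cfg = paradigm_config(), epoch_ms = 800) {
  if (!is.null(profile$seed)) set.seed(profile$seed)
  fs <- cfg$sampling_rate
  n <- round(epoch_ms / 1000 * fs)
  seg <- make_noise(n, length(cfg$channel_labels), profile$noise_sd)
  rownames(seg) <- cfg$channel_labels
  lat <- NA_real_
  if (is_target) {
    lat <- max(profile$p300_base_latency + draw_flash_delay(node) +
                 stats::rnorm(1, 0, profile$p300_latency_jitter_sd), 0)
    par_ch <- which(cfg$channel_labels %in% c("P3", "Pz", "P4"))
    occ_ch <- which(cfg$channel_labels %in% c("O1", "O2"))
    seg <- add_gaussian_bump(seg, par_ch, lat, profile$p300_amplitude,
                             profile$p300_width, fs)
    seg <- add_gaussian_bump(seg, occ_ch, lat, profile$p300_amplitude / 2,
                             profile$p300_width, fs)
  }
  list(segment = seg, true_latency_ms = lat)
}

# Accumulator for session assembly ------------------------------------------

new_session <- function(recording, events, truth, cfg, nodes, profile, kind) {
  structure(list(
    recording = recording, events = events, truth = truth,
    cfg = cfg, nodes = nodes, kind = kind
  ), class = "bci_session")
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf("<bci_session: %s> %d events, %.1f s recording\n",
              x$kind, nrow(x$events), ncol(x$recording$data) /
                x$recording$sampling_rate))
  invisible(x)
}

# One P300 oddball flash block: every node flashes `flashes_per_stimulus`
# times in randomized sweeps of all nodes at the flash SOA. Returns events,
# flash truth rows, and the signal additions applied to `data`.
run_flash_block <- function(data, t0, target_node, nodes, cfg, profile,
                            block_id, flashes_each, ref_col) {
  fs <- cfg$sampling_rate
  soa <- 1 / cfg$flash_freq
  n_nodes <- cfg$n_nodes
  par_ch <- which(cfg$channel_labels %in% c("P3", "Pz", "P4"))
  occ_ch <- which(cfg$channel_labels %in% c("O1", "O2"))
  order_mat <- replicate(flashes_each, sample.int(n_nodes) - 1L)
  sent <- t0 + (seq_len(flashes_each * n_nodes) - 1) * soa
  node_seq <- as.integer(order_mat)
  is_tgt <- node_seq == target_node
  actual <- numeric(length(sent))
  latency <- rep(NA_real_, length(sent))
  for (i in seq_along(sent)) {
    nd <- nodes[[node_seq[i] + 1L]]
    actual[i] <- sent[i] + draw_flash_delay(nd) / 1000
    if (is_tgt[i] && profile$p300_amplitude > 0) {
      lat_from_actual <- max(profile$p300_base_latency +
        stats::rnorm(1, 0, profile$p300_latency_jitter_sd), 0)
      center_ms <- actual[i] * 1000 + lat_from_actual
      latency[i] <- center_ms - sent[i] * 1000 # latency relative to trigger
      data <- add_gaussian_bump(data, par_ch, center_ms,
                                profile$p300_amplitude, profile$p300_width, fs)
      data <- add_gaussian_bump(data, occ_ch, center_ms,
                                profile$p300_amplitude / 2, profile$p300_width,
                                fs)
    }
  }
  events <- data.frame(
    onset_s = sent, node_id = node_seq, kind = "flash",
    phase_condition = NA_real_, is_target = is_tgt, block = block_id
  )
  truth <- data.frame(
    block = block_id, ref_node = ref_col, node_id = node_seq,
    is_target = is_tgt, sent_s = sent, actual_onset_s = actual,
    true_latency_ms = latency
  )
  list(data = data, events = events, truth = truth,
       t_end = t0 + flashes_each * n_nodes * soa)
}

#' Simulate a registration session
#'
#' For every node (optionally repeated `n_repeats` times) the session contains
#' one flicker block per phase condition (`flicker_duration` s each, separated
#' by `inter_phase_gap` s) followed by a P300 training block in which each
#' stimulus flashes `flashes_per_stimulus` times (with 4 nodes and 30 flashes:
#' 120 epochs, 30 target / 90 nontarget). Markers record coordinator send
#' times; all wireless delay lives in the signal.
#'
#' @param nodes List of [node_timing()] (see [node_set()]).
#' @param cfg A [paradigm_config()].
#' @param profile A [subject_profile()].
#' @param n_repeats Number of times the per-node protocol is repeated
#'   (default 1; registration workflows use 4 to enlarge the training set).
#' @return A `bci_session` with `recording`, `events`, and `truth`
#'   (`$flicker`, `$flash` tables).
#' @export
simulate_registration_session <- function(nodes, cfg = paradigm_config(),
                                          profile = subject_profile(),
                                          n_repeats = 1L) {
  stopifnot(length(nodes) == cfg$n_nodes)
  if (!is.null(profile$seed)) set.seed(derive_seed(profile$seed, 1L))
  fs <- cfg$sampling_rate
  n_cond <- length(cfg$phase_conditions)
  flick_span <- n_cond * (cfg$flicker_duration + cfg$inter_phase_gap)
  flash_span <- 0.5 + cfg$flashes_per_stimulus * cfg$n_nodes / cfg$flash_freq + 1
  total_s <- n_repeats * cfg$n_nodes * (flick_span + flash_span) + 1
  n_samples <- ceiling(total_s * fs)
  data <- make_noise(n_samples, length(cfg$channel_labels), profile$noise_sd)
  rownames(data) <- cfg$channel_labels
  occ <- which(cfg$channel_labels %in% c("O1", "O2"))

  events <- list(); fl_truth <- list(); flash_truth <- list()
  tcur <- 0
  for (r in seq_len(n_repeats)) {
    for (nd in nodes) {
      for (cond in cfg$phase_conditions) {
        n_blk <- round(cfg$flicker_duration * fs)
        idx <- floor(tcur * fs) + seq_len(n_blk)
        t_local <- (seq_len(n_blk) - 1) / fs
        wave <- ssvep_wave(t_local, cond, nd$transmission_delay, cfg, profile)
        for (ch in occ) data[ch, idx] <- data[ch, idx] + wave
        tm <- flicker_timing(cfg)
        events[[length(events) + 1L]] <- data.frame(
          onset_s = tcur, node_id = nd$node_id, kind = "flicker_onset",
          phase_condition = cond, is_target = NA, block = r
        )
        fl_truth[[length(fl_truth) + 1L]] <- data.frame(
          block = r, node_id = nd$node_id, phase_condition = cond,
          onset_s = tcur,
          true_lag_deg = wrap_deg(cond + delay_to_deg(
            nd$transmission_delay + profile$ssvep_latency, tm$period_ms))
        )
        tcur <- tcur + cfg$flicker_duration + cfg$inter_phase_gap
      }
      blk <- run_flash_block(data, tcur + 0.5, nd$node_id, nodes, cfg, profile,
                             r, cfg$flashes_per_stimulus, nd$node_id)
      data <- blk$data
      events[[length(events) + 1L]] <- blk$events
      flash_truth[[length(flash_truth) + 1L]] <- blk$truth
      tcur <- blk$t_end + 1
    }
  }
  events <- do.call(rbind, events)
  truth <- list(flicker = do.call(rbind, fl_truth),
                flash = do.call(rbind, flash_truth))
  new_session(eeg_recording(data, fs, cfg$channel_labels), events, truth,
              cfg, nodes, profile, "registration")
}

#' Simulate an online operation session
#'
#' Each trial cues one target node; all nodes then flash `repetitions` times
#' in randomized sweep order at the flash SOA. With 4 nodes and 5 repetitions
#' a trial holds 20 flashes; 100 trials yield 100 target and 300 nontarget
#' epoch groups.
#'
#' @param nodes List of [node_timing()].
#' @param cfg A [paradigm_config()].
#' @param profile A [subject_profile()].
#' @param n_trials Number of selection trials (>= 1).
#' @return A `bci_session`; `truth$trials` maps each trial to its cued node.
#' @export
simulate_operation_session <- function(nodes, cfg = paradigm_config(),
                                       profile = subject_profile(),
                                       n_trials = 100L) {
  stopifnot(n_trials >= 1, length(nodes) == cfg$n_nodes)
  if (!is.null(profile$seed)) set.seed(derive_seed(profile$seed, 2L))
  fs <- cfg$sampling_rate
  trial_span <- 0.2 + cfg$repetitions * cfg$n_nodes / cfg$flash_freq + 1
  total_s <- n_trials * trial_span + 1
  n_samples <- ceiling(total_s * fs)
  data <- make_noise(n_samples, length(cfg$channel_labels), profile$noise_sd)
  rownames(data) <- cfg$channel_labels

  events <- list(); flash_truth <- list()
  cued <- sample.int(cfg$n_nodes, n_trials, replace = TRUE) - 1L
  tcur <- 0
  for (tr in seq_len(n_trials)) {
    blk <- run_flash_block(data, tcur + 0.2, cued[tr], nodes, cfg, profile,
                           tr, cfg$repetitions, cued[tr])
    data <- blk$data
    events[[length(events) + 1L]] <- blk$events
    flash_truth[[length(flash_truth) + 1L]] <- blk$truth
    tcur <- blk$t_end + 1
  }
  events <- do.call(rbind, events)
  truth <- list(flash = do.call(rbind, flash_truth),
                trials = data.frame(trial = seq_len(n_trials),
                                    cued_node = cued))
  new_session(eeg_recording(data, fs, cfg$channel_labels), events, truth,
              cfg, nodes, profile, "operation")
}
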