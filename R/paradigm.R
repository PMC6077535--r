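#' Paradigm configuration for the stimulus-on-device hybrid BCI
#'
#' Describes the stimulation protocol: a 16 Hz flickering stimulus probes the
#' SSVEP under four phase conditions (0, pi/2, pi, 3pi/2), and an 8 Hz oddball
#' flashing stimulus elicits the P300. Four appliance-embedded stimulation
#' nodes flash in randomized block order; EEG is recorded at 500 Hz from
#' parietal (P3, Pz, P4) and occipital (O1, O2) electrodes.
#'
#' @param n_nodes Number of stimulation nodes (default 4).
#' @param flicker_freq Flicker frequency in Hz (default 16).
#' @param flash_freq Oddball flash rate in Hz (default 8, i.e. 125 ms SOA).
#' @param flicker_duration Duration of one flicker block in seconds (default 5).
#' @param inter_phase_gap Gap between flicker blocks in seconds (default 2).
#' @param flashes_per_stimulus Flashes of each stimulus in a training block
#'   (default 30, giving 120 epochs: 30 target + 90 nontarget).
#' @param repetitions Flash repetitions per stimulus in one online trial
#'   (default 5).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param channel_labels EEG channel names (default P3, Pz, P4, O1, O2).
#' @param phase_conditions Stimulation phase conditions in degrees
#'   (default 0, 90, 180, 270).
#'
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(n_nodes = 4L,
                            flicker_freq = 16,
                            flash_freq = 8,
                            flicker_duration = 5,
                            inter_phase_gap = 2,
                            flashes_per_stimulus = 30L,
                            repetitions = 5L,
                            sampling_rate = 500,
                            channel_labels = c("P3", "Pz", "P4", "O1", "O2"),
                            phase_conditions = c(0, 90, 180, 270)) {
  stopifnot(n_nodes >= 1, flicker_freq > 0, flash_freq > 0,
            sampling_rate > 2 * flicker_freq,
            flicker_duration > 0, inter_phase_gap >= 0,
            flashes_per_stimulus >= 1, repetitions >= 1)
  if (abs(flicker_freq / flash_freq - round(flicker_freq / flash_freq)) > 1e-9)
    stop("flash_freq must divide flicker_freq evenly in this design")
  structure(list(
    n_nodes = as.integer(n_nodes),
    flicker_freq = flicker_freq,
    flash_freq = flash_freq,
    flicker_duration = flicker_duration,
    inter_phase_gap = inter_phase_gap,
    flashes_per_stimulus = as.integer(flashes_per_stimulus),
    repetitions = as.integer(repetitions),
    sampling_rate = sampling_rate,
    channel_labels = channel_labels,
    phase_conditions = phase_conditions
  ), class = "paradigm_config")
}

#' Flicker period and reference peak latency
#'
#' For a sinusoidal flicker of frequency f starting at phase zero, the
#' luminance peaks a quarter period after onset, so the reference SSVEP
#' signal peaks at T/4 (15.625 ms for 16 Hz, T = 62.5 ms).
#'
#' @param cfg A [paradigm_config()].
#' @return Named list with `period_ms` (T) and `t_ref_ms` (T/4).
#' @export
flicker_timing <- function(cfg = paradigm_config()) {
  period <- 1000 / cfg$flicker_freq
  list(period_ms = period, t_ref_ms = period / 4)
}

#' Subject response profile for the synthetic generator
#'
#' Captures the subject-dependent shape of the elicited responses: the nominal
#' P300 peaks near 300 ms after the (actual) flash with trial-to-trial latency
#' jitter, and the SSVEP follows the flicker with a subject-specific gain.
#'
#' @param p300_base_latency Nominal P300 peak latency in ms (default 300).
#' @param p300_amplitude P300 template peak amplitude in microvolts (default 6.5).
#' @param p300_width Gaussian template SD in ms (default 40).
#' @param p300_latency_jitter_sd Trial-to-trial latency jitter SD in ms
#'   (default 20).
#' @param ssvep_gain SSVEP amplitude in microvolts on O1/O2 (default 3).
#' @param ssvep_harmonic_ratio Second-harmonic amplitude relative to the
#'   fundamental (default 0.25).
#' @param ssvep_latency Subject-specific latency of the evoked SSVEP relative
#'   to the flicker, in ms (default 0). Part of the visual response latency
#'   is shared with the P300, which is what makes the phase lag predictive
#'   of the latency centroid across subjects.
#' @param noise_sd Background EEG noise SD in microvolts (default 15).
#' @param seed Optional integer seed making generator calls reproducible.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(p300_base_latency = 300,
                            p300_amplitude = 6.5,
                            p300_width = 40,
                            p300_latency_jitter_sd = 20,
                            ssvep_gain = 3,
                            ssvep_harmonic_ratio = 0.25,
                            ssvep_latency = 0,
                            noise_sd = 15,
                            seed = NULL) {
  stopifnot(p300_amplitude >= 0, p300_width > 0, p300_latency_jitter_sd >= 0,
            ssvep_gain >= 0, noise_sd >= 0)
  structure(list(
    p300_base_latency = p300_base_latency,
    p300_amplitude = p300_amplitude,
    p300_width = p300_width,
    p300_latency_jitter_sd = p300_latency_jitter_sd,
    ssvep_gain = ssvep_gain,
    ssvep_harmonic_ratio = ssvep_harmonic_ratio,
    ssvep_latency = ssvep_latency,
    noise_sd = noise_sd,
    seed = seed
  ), class = "subject_profile")
}

#' Timing model of one wireless stimulation node
#'
#' Each node receives its trigger over a wireless link: the flash appears
#' `transmission_delay` ms after the coordinator sent the trigger, plus a
#' per-flash random delay (Gaussian, truncated so the total delay is never
#' negative). The same delay shifts the SSVEP phase and the P300 latency,
#' which is the correlation the calibration exploits.
#'
#' @param node_id Integer node index in `0..n_nodes-1`.
#' @param transmission_delay Constant per-node delay in ms (>= 0).
#' @param flash_jitter_sd Per-flash delay jitter SD in ms (default 2).
#' @return An object of class `node_timing`.
#' @export
node_timing <- function(node_id, transmission_delay, flash_jitter_sd = 2) {
  stopifnot(node_id >= 0, transmission_delay >= 0, flash_jitter_sd >= 0)
  structure(list(
    node_id = as.integer(node_id),
    transmission_delay = transmission_delay,
    flash_jitter_sd = flash_jitter_sd
  ), class = "node_timing")
}

#' Build a set of node timing models from a delay vector
#'
#' @param delays_ms Transmission delays in ms, one per node (node ids are
#'   assigned 0, 1, ... in order).
#' @param flash_jitter_sd Shared per-flash jitter SD in ms.
#' @return List of [node_timing()] objects.
#' @export
node_set <- function(delays_ms, flash_jitter_sd = 2) {
  lapply(seq_along(delays_ms), function(i)
    node_timing(i - 1L, delays_ms[i], flash_jitter_sd))
}

#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels),
            sampling_rate > 0)
  rownames(data) <- channel_labels
  structure(list(
    data = data,
    sampling_rate = sampling_rate,
    channel_labels = channel_labels
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}
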