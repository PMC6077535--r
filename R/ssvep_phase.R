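# SSVEP phase-lag estimation. The evoked response to a 16 Hz flicker is a
# near-sinusoid at the flicker frequency; over an integer number of cycles
# the Fourier coefficient at exactly that frequency is an unbiased phase
# estimate, which converts to the latency of the first positive peak and
# then to a phase lag against the zero-delay reference peak (t_ref = T/4).

#' Latency of the evoked SSVEP peak
#'
#' Computes the Fourier component at exactly `flicker_freq` over the whole
#' segment (an exact DFT bin when the segment spans an integer number of
#' cycles) on the mean of the occipital channels, and converts its phase to
#' the latency of the sinusoid's first positive peak within one period.
#'
#' @param segment Channels x samples matrix (or plain numeric vector).
#' @param flicker_freq Flicker frequency in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Channel labels averaged before estimation (default O1, O2);
#'   ignored for vector input or unlabeled matrices.
#' @param min_amplitude Amplitude floor in microvolts below which the segment
#'   is declared to contain no SSVEP (default 0.05).
#' @return `t_res` in ms, in `[0, T)`.
#' @export
estimate_response_peak <- function(segment, flicker_freq = 16,
                                   sampling_rate = 500,
                                   channels = c("O1", "O2"),
                                   min_amplitude = 0.05) {
  if (is.matrix(segment)) {
    ch <- if (!is.null(rownames(segment)) && any(rownames(segment) %in% channels))
      which(rownames(segment) %in% channels) else seq_len(nrow(segment))
    x <- colMeans(segment[ch, , drop = FALSE])
  } else {
    x <- as.numeric(segment)
  }
  n <- length(x)
  cycles <- flicker_freq * n / sampling_rate
  if (cycles < 1) stop("segment shorter than one flicker cycle")
  if (abs(cycles - round(cycles)) > 1e-6)
    stop("segment must span an integer number of flicker cycles")
  t_s <- (seq_len(n) - 1) / sampling_rate
  co <- sum(x * exp(-2i * pi * flicker_freq * t_s)) * 2 / n
  if (Mod(co) < min_amplitude)
    stop_bcicalib(sprintf(
      "no SSVEP: amplitude %.4f below floor %.4f at %g Hz",
      Mod(co), min_amplitude, flicker_freq), "bcicalib_no_ssvep")
  # x ~ A cos(2 pi f t + phi); first positive peak at t = -phi / (2 pi f)
  period_ms <- 1000 / flicker_freq
  ((-Arg(co) / (2 * pi * flicker_freq)) * 1000) %% period_ms
}

#' Phase lag from the response-peak latency
#'
#' `theta = (t_res - t_ref) / T * 360`, wrapped into `[0, 360)`. For a 16 Hz
#' flicker, T = 62.5 ms and the reference signal peaks at t_ref = 15.625 ms,
#' so a flashing delay of 15.625 ms corresponds to a lag of 90 degrees.
#'
#' @param t_res Response peak latency in ms.
#' @param t_ref Reference peak latency in ms (default 15.625).
#' @param period_ms Flicker period T in ms (default 62.5).
#' @return Phase lag in degrees, in `[0, 360)`.
#' @export
compute_phase_lag <- function(t_res, t_ref = 15.625, period_ms = 62.5) {
  stopifnot(period_ms > 0)
  wrap_deg((t_res - t_ref) / period_ms * 360)
}

#' Four-condition phase-lag vector for one node
#'
#' Measures the SSVEP peak latency in the flicker block of each stimulation
#' phase condition and converts it to a lag against the reference. The four
#' lags are the crisp inputs of the fuzzy calibration model.
#'
#' @param recording An [eeg_recording()] (filtered or raw).
#' @param events Event table containing `flicker_onset` rows for the node.
#' @param node_id Node to measure.
#' @param cfg A [paradigm_config()].
#' @param block Optional block/repeat index to select when the session
#'   contains several flicker protocols per node.
#' @return A `phase_lag_vector`: named numeric of 4 lags (degrees) with
#'   attribute `node_id`.
#' @export
build_phase_lag_vector <- function(recording, events, node_id,
                                   cfg = paradigm_config(), block = NULL) {
  ev <- events[events$kind == "flicker_onset" & events$node_id == node_id, ]
  if (!is.null(block)) ev <- ev[ev$block == block, ]
  tm <- flicker_timing(cfg)
  lags <- rep(NA_real_, length(cfg$phase_conditions))
  names(lags) <- as.character(cfg$phase_conditions)
  for (i in seq_along(cfg$phase_conditions)) {
    cond <- cfg$phase_conditions[i]
    row <- ev[!is.na(ev$phase_condition) & ev$phase_condition == cond, ]
    if (nrow(row) == 0)
      stop(sprintf("missing flicker block for condition %g on node %d",
                   cond, node_id))
    fs <- recording$sampling_rate
    start <- floor(row$onset_s[1] * fs)
    n <- round(cfg$flicker_duration * fs)
    seg <- recording$data[, (start + 1):(start + n), drop = FALSE]
    t_res <- estimate_response_peak(seg, cfg$flicker_freq, fs)
    lags[i] <- compute_phase_lag(t_res, tm$t_ref_ms, tm$period_ms)
  }
  phase_lag_vector(lags, node_id)
}

#' Phase-lag vector constructor
#'
#' @param lags Numeric of length 4, degrees in `[0, 360)`, named by the
#'   phase conditions.
#' @param node_id Node the lags belong to.
#' @return A `phase_lag_vector`.
#' @export
phase_lag_vector <- function(lags, node_id = NA_integer_) {
  stopifnot(length(lags) == 4, all(lags >= 0 & lags < 360))
  structure(as.numeric(lags), names = names(lags), node_id = node_id,
            class = "phase_lag_vector")
}

#' @export
print.phase_lag_vector <- function(x, ...) {
  cat(sprintf("<phase_lag_vector> node %s: %s\n", attr(x, "node_id"),
              paste(sprintf("%s->%.1f", names(x), unclass(x)),
                    collapse = ", ")))
  invisible(x)
}
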