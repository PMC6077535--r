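#' @keywords internal
"_PACKAGE"

#' Wrap an angle in degrees into `[0, 360)`
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into `[0, 360)`.
#' @export
wrap_deg <- function(x) x %% 360

# Convert a time delay (ms) into a phase angle (degrees) for a period T (ms).
delay_to_deg <- function(delay_ms, period_ms) delay_ms / period_ms * 360

# Derive a child seed from a base seed and an integer salt, kept within the
# 32-bit range R requires for set.seed().
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1103 + salt * 12289) %% 2147483587L)
}

# Round half away from zero to `digits` decimals (base round() is half-even).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_bcicalib <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "bcicalib_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}
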