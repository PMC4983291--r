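#' Duration of an on-resonance rectangular pulse
#'
#' For a rectangular pulse applied exactly on resonance, the flip angle is
#' `360 * nu1 * tau` degrees, where `nu1` is the radio-frequency (RF) nutation
#' frequency. Inverting for the duration gives `tau = flip / (360 * nu1)`.
#'
#' @param flip_deg Flip angle in degrees (> 0).
#' @param rf_khz RF nutation frequency \eqn{\nu_1} in kHz (> 0).
#'
#' @return Pulse duration in microseconds.
#' @examples
#' pulse_duration(180, 4.68) # ~106.8 us, the MOCCA-XY16 CO 180 at 600 MHz
#' pulse_duration(360, 1)    # one full nutation period at 1 kHz = 1000 us
#' @export
pulse_duration <- function(flip_deg, rf_khz) {
  stopifnot_scalar_num(flip_deg, "flip_deg", positive = TRUE)
  stopifnot_scalar_num(rf_khz, "rf_khz", positive = TRUE)
  (flip_deg / 360) / rf_khz * 1000
}

#' Effective rotation of an off-resonance spin during a rectangular pulse
#'
#' A spin offset by \eqn{\Delta\nu} from the carrier precesses about a tilted
#' effective field of magnitude \eqn{\sqrt{\nu_1^2 + \Delta\nu^2}} during a
#' rectangular pulse. A pulse that nutates an on-resonance spin by
#' `flip_deg` therefore rotates the off-resonance spin by
#' `flip_deg * sqrt(1 + offset_ratio^2)` about that tilted axis. The
#' carbonyl-selective MOCCA pulses exploit this: choosing the CA offset equal
#' to `sqrt(15)` times the RF field makes each CO 180-degree pulse an
#' effective 720-degree rotation for CA (and `sqrt(3)` gives 360 degrees),
#' so CA magnetization is returned to its initial state.
#'
#' @param offset_ratio Dimensionless ratio \eqn{\Delta\nu/\nu_1}.
#' @param flip_deg On-resonance flip angle in degrees (> 0).
#'
#' @return Effective rotation angle in degrees.
#' @examples
#' effective_rotation(sqrt(15), 180) # 720
#' effective_rotation(sqrt(3), 180)  # 360
#' @export
effective_rotation <- function(offset_ratio, flip_deg) {
  stopifnot_scalar_num(offset_ratio, "offset_ratio")
  stopifnot_scalar_num(flip_deg, "flip_deg", positive = TRUE)
  flip_deg * sqrt(1 + offset_ratio^2)
}

#' RF field of a band-selective rectangular CA/CO pulse
#'
#' Rectangular pulses selective for CO (or CA) are calibrated so that the
#' other band, offset by \eqn{|\Delta\Omega|}, experiences a full multiple of
#' 360 degrees and is left untouched: the RF field is set to
#' \eqn{|\Delta\Omega|/\sqrt{15}} for 90-degree pulses and
#' \eqn{|\Delta\Omega|/\sqrt{3}} for 180-degree pulses.
#'
#' @param delta_omega_khz CA-CO offset \eqn{|\Delta\Omega|} in kHz (> 0).
#' @param flip_deg Either 90 or 180.
#'
#' @return RF nutation frequency in kHz.
#' @examples
#' selective_rf(sqrt(15) * 4.68, 90) # 4.68 kHz
#' @export
selective_rf <- function(delta_omega_khz, flip_deg) {
  stopifnot_scalar_num(delta_omega_khz, "delta_omega_khz", positive = TRUE)
  if (!flip_deg %in% c(90, 180)) {
    abort("`flip_deg` must be 90 or 180 for selective CA/CO pulses.")
  }
  delta_omega_khz / if (flip_deg == 90) sqrt(15) else sqrt(3)
}

#' Semi-constant-time and constant-time evolution delays
#'
#' Chemical-shift evolution over a nominal time `t` is implemented with three
#' delays `a`, `b`, `c` satisfying `a + b - c = t`, so that the shift evolves
#' for `t` while scalar-coupling transfer runs for a fixed period `delta`.
#' Semi-constant-time mode: `a = (t + delta)/2`, `b = t (1 - delta/t_max)/2`,
#' `c = delta (1 - t/t_max)/2`. Constant-time mode: `a = (t + delta)/2`,
#' `b = 0`, `c = (delta - t)/2`, with total duration `a + b + c = delta`
#' independent of `t` (requires `t <= delta`).
#'
#' @param t Requested evolution time (s), `0 <= t <= t_max`.
#' @param t_max Maximum evolution time (s).
#' @param delta Fixed transfer delay (s, > 0).
#' @param mode `"semi_constant"` or `"constant"`.
#'
#' @return A tibble with columns `a`, `b`, `c` (seconds) and `total`.
#' @examples
#' sct_delays(0, 0.03, 0.0054)                    # (delta/2, 0, delta/2)
#' sct_delays(0.01, 0.03, 0.028, mode = "constant")
#' @export
sct_delays <- function(t, t_max, delta, mode = c("semi_constant", "constant")) {
  mode <- match.arg(mode)
  stopifnot_scalar_num(t, "t", nonneg = TRUE)
  stopifnot_scalar_num(t_max, "t_max", positive = TRUE)
  stopifnot_scalar_num(delta, "delta", positive = TRUE)
  if (t > t_max) abort("`t` must not exceed `t_max`.")
  if (mode == "constant" && t > delta) {
    abort("constant-time mode requires `t` <= `delta` (delay `c` would be negative).")
  }
  a <- (t + delta) / 2
  if (mode == "semi_constant") {
    b <- t * (1 - delta / t_max) / 2
    c <- delta * (1 - t / t_max) / 2
  } else {
    b <- 0
    c <- (delta - t) / 2
  }
  tibble(a = a, b = b, c = c, total = a + b + c)
}

# fixed scheme delays (ms) and shaped-pulse durations (us); the sinc durations
# are calibration constants of the published schemes, not derivable from the
# rectangular-pulse algebra (time-bandwidth factor of the sinc shape unknown)
pulse_constants <- function() {
  list(
    delta_nh_ms = 5.4,
    delta_nco_ms = 28,
    delta_coca_ms = 9.1,
    mocca_delta_us = c(alpha_synuclein = 500, tau3x = 250),
    sinc_90_us = c(`600` = 87.8, `800` = 65.8),
    sinc_180_us = c(`600` = 78.4, `800` = 58.8),
    mocca_rf_khz = c(`600` = 4.68, `800` = 6.23)
  )
}

#' Pulse-level quantities for a CON-CON experiment at a given field
#'
#' Tabulates the MOCCA-XY16 carbonyl 180-degree pulse and the rectangular
#' band-selective CA/CO pulses at the 600 or 800 MHz setting. The CA-CO
#' offset is derived from the MOCCA calibration condition
#' \eqn{|\Delta\Omega| = \sqrt{15}\,\nu_1(\mathrm{MOCCA})}, which makes each
#' CO 180-degree pulse an effective 720-degree rotation for CA.
#'
#' @param field_mhz Proton frequency, 600 or 800.
#'
#' @return A tibble with columns `quantity`, `flip_deg`, `rf_khz`,
#'   `duration_us`.
#' @examples
#' pulse_table(600)
#' @export
pulse_table <- function(field_mhz = 600) {
  if (!field_mhz %in% c(600, 800)) abort("`field_mhz` must be 600 or 800.")
  pc <- pulse_constants()
  nu_mocca <- pc$mocca_rf_khz[[as.character(field_mhz)]]
  d_omega <- sqrt(15) * nu_mocca
  rf90 <- selective_rf(d_omega, 90)
  rf180 <- selective_rf(d_omega, 180)
  tibble(
    quantity = c("MOCCA CO 180 (rect)", "selective CA/CO 90 (rect)",
                 "selective CA/CO 180 (rect)", "selective CA/CO 90 (sinc)",
                 "selective CA/CO 180 (sinc)"),
    flip_deg = c(180, 90, 180, 90, 180),
    rf_khz = c(nu_mocca, rf90, rf180, NA, NA),
    duration_us = c(pulse_duration(180, nu_mocca),
                    pulse_duration(90, rf90),
                    pulse_duration(180, rf180),
                    pc$sinc_90_us[[as.character(field_mhz)]],
                    pc$sinc_180_us[[as.character(field_mhz)]])
  )
}
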