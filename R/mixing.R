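#' CO-CO isotropic mixing model
#'
#' Parameters of the MOCCA-XY16 carbonyl mixing step: the effective CO-CO
#' isotropic-mixing coupling `J_hz`, the mixing time `t_mix_ms`, and an
#' effective transverse relaxation rate during mixing, quoted at the 600 MHz
#' reference field. Carbonyl relaxation is dominated by chemical shift
#' anisotropy, whose rate grows with the square of the static field, so the
#' rate actually applied is `R600_per_s * (field_mhz / 600)^2`.
#'
#' @param J_hz Effective CO-CO coupling in Hz (>= 0). Default 1 Hz, a value
#'   small enough that a 250 ms mixing time transfers more than 150 ms does.
#' @param t_mix_ms Mixing time in milliseconds (>= 0). Default 250 ms.
#' @param R600_per_s Effective relaxation rate during mixing at 600 MHz
#'   (1/s). Default 1.43/s, i.e. about 30 % amplitude loss over 250 ms.
#' @param field_mhz Proton frequency in MHz (> 0).
#'
#' @return An object of class `mixing_model`.
#' @examples
#' m <- mixing_model()
#' relaxation_rate(mixing_model(field_mhz = 800))
#' @export
mixing_model <- function(J_hz = 1.0, t_mix_ms = 250, R600_per_s = 1.43,
                         field_mhz = 600) {
  stopifnot_scalar_num(J_hz, "J_hz", nonneg = TRUE)
  stopifnot_scalar_num(t_mix_ms, "t_mix_ms", nonneg = TRUE)
  stopifnot_scalar_num(R600_per_s, "R600_per_s", nonneg = TRUE)
  stopifnot_scalar_num(field_mhz, "field_mhz", positive = TRUE)
  structure(list(J_hz = J_hz, t_mix_ms = t_mix_ms, R600_per_s = R600_per_s,
                 field_mhz = field_mhz),
            class = "mixing_model")
}

#' @export
print.mixing_model <- function(x, ...) {
  cat(sprintf(
    "<mixing_model> J = %g Hz, t_mix = %g ms, R(600) = %g /s, field = %g MHz (R = %.3f /s)\n",
    x$J_hz, x$t_mix_ms, x$R600_per_s, x$field_mhz, relaxation_rate(x)))
  invisible(x)
}

#' Field-scaled relaxation rate during mixing
#'
#' @param model A [mixing_model()].
#' @return Effective relaxation rate in 1/s at `model$field_mhz`, scaled from
#'   the 600 MHz reference by the square of the field ratio (CSA mechanism).
#' @export
relaxation_rate <- function(model) {
  stopifnot(inherits(model, "mixing_model"))
  model$R600_per_s * (model$field_mhz / 600)^2
}

#' Magnetization transfer along a chain of coupled carbonyls
#'
#' In-phase transfer under ideal isotropic mixing is modelled as a continuous
#' quantum walk on the chain of sequential CO nuclei: the Hamiltonian is the
#' symmetric tridiagonal matrix with nearest-neighbour elements `pi * J`, the
#' propagator is its matrix exponential over the mixing time, and the
#' fraction of polarization reaching each site is the squared modulus of the
#' propagator element, damped by a single exponential relaxation envelope
#' `exp(-R * t_mix)`. The chain is windowed to the source's +/- 2 neighbours
#' (mixing times here are tuned for i +/- 1 transfer, so more distant sites
#' receive negligible and deliberately unused amplitude). For two spins this
#' reduces to the classic TOCSY closed form
#' `(cos^2(pi J t), sin^2(pi J t)) * exp(-R t)`.
#'
#' @param model A [mixing_model()].
#' @param chain_length Number of CO sites in the chain (>= 1).
#' @param source_index 1-based position of the source CO.
#'
#' @return A tibble with columns `offset` (site - source, -2..2), `position`
#'   (1-based site index) and `fraction` (in `[0, 1]`).
#' @examples
#' chain_transfer(mixing_model(J_hz = 2, R600_per_s = 0), 2, 1)
#' @export
chain_transfer <- function(model, chain_length, source_index) {
  stopifnot(inherits(model, "mixing_model"))
  if (chain_length < 1) abort("`chain_length` must be >= 1.")
  if (source_index < 1 || source_index > chain_length) {
    abort("`source_index` must lie within the chain.")
  }
  lo <- max(1L, as.integer(source_index) - 2L)
  hi <- min(as.integer(chain_length), as.integer(source_index) + 2L)
  n <- hi - lo + 1L
  t <- model$t_mix_ms / 1000
  env <- exp(-relaxation_rate(model) * t)
  if (n == 1L) {
    frac <- 1
    pos <- lo
  } else {
    h <- matrix(0, n, n)
    off <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
    h[off] <- pi * model$J_hz
    h[off[, 2:1, drop = FALSE]] <- pi * model$J_hz
    eg <- eigen(h, symmetric = TRUE)
    src <- as.integer(source_index) - lo + 1L
    # U = V exp(-i lambda t) V'; row of the propagator from the source site
    amp <- eg$vectors %*% (exp(-1i * eg$values * t) * eg$vectors[src, ])
    frac <- Mod(amp)^2
    pos <- lo:hi
  }
  tibble(offset = pos - as.integer(source_index),
         position = pos,
         fraction = as.numeric(frac) * env)
}

#' Compare i +/- 1 cross-peak transfer at two mixing times
#'
#' Evaluates the nearest-neighbour (i +/- 1) transfer fraction of
#' [chain_transfer()] on a three-site chain at two candidate mixing times and
#' reports which transfers more. Longer mixing (up to the sin^2 maximum at
#' `1/(2J)`) is preferred when relaxation permits.
#'
#' @param model A [mixing_model()]; its `t_mix_ms` is ignored.
#' @param t_a_ms,t_b_ms Candidate mixing times in ms.
#'
#' @return A tibble with one row per candidate: `t_mix_ms`, `cross_fraction`,
#'   and logical `preferred` (largest cross fraction).
#' @examples
#' compare_mixing_times(mixing_model(J_hz = 1, R600_per_s = 0), 150, 250)
#' @export
compare_mixing_times <- function(model, t_a_ms, t_b_ms) {
  stopifnot(inherits(model, "mixing_model"))
  cross <- function(tm) {
    m <- mixing_model(model$J_hz, tm, model$R600_per_s, model$field_mhz)
    prof <- chain_transfer(m, chain_length = 3, source_index = 2)
    sum(prof$fraction[prof$offset %in% c(-1L, 1L)]) / 2
  }
  out <- tibble(t_mix_ms = c(t_a_ms, t_b_ms),
                cross_fraction = c(cross(t_a_ms), cross(t_b_ms)))
  out$preferred <- out$cross_fraction == max(out$cross_fraction)
  out
}

#' Plot a transfer profile
#'
#' @param object A tibble returned by [chain_transfer()].
#' @param ... Unused.
#' @return A ggplot of transfer fraction against chain offset.
#' @export
plot_transfer <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = "site offset from source CO", y = "transfer fraction") +
    ggplot2::theme_minimal()
}
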