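# shared fixtures built in code

# independent matrix exponential by scaling-and-squaring Taylor series,
# used as an oracle against the eigendecomposition propagator
expm_series <- function(m) {
  k <- max(0L, ceiling(log2(max(1, Mod(m)))) + 4L)
  a <- m / 2^k
  out <- diag(1 + 0i, nrow(m))
  term <- out
  for (j in 1:25) {
    term <- term %*% a / j
    out <- out + term
  }
  for (j in seq_len(k)) out <- out %*% out
  out
}

# tiny two-NUS-axis system with p random in-window peaks
tiny_axes <- function(n1 = 16, n2 = 16, field = 600) {
  dplyr::bind_rows(
    nmr_axis("COres", "C", 176.25, 11, n1, field, nus = TRUE),
    nmr_axis("Nres", "N", 121, 44, n2, field, nus = TRUE)
  )
}

tiny_peaks <- function(p, seed = 1, amp = NULL) {
  set.seed(seed)
  tibble::tibble(
    COres = 176.25 + runif(p, -4.5, 4.5),
    Nres = 121 + runif(p, -18, 18),
    amplitude = amp %||% runif(p, 0.2, 1)
  )
}

# on-grid ppm position for grid index i (0-based) of an axis row
grid_ppm <- function(ax, i) {
  ax$carrier_ppm + (-ax$sw_hz / 2 + i * ax$sw_hz / ax$n) / ax$obs_mhz
}

# dense FFT magnitude oracle for a fully sampled two-NUS-axis fid,
# arranged on the same frequency grid as cross_section (carrier-centred)
dense_fft_2d <- function(fid) {
  ax <- fid$axes
  n1 <- ax$n[1]; n2 <- ax$n[2]
  full <- matrix(0 + 0i, n1, n2)
  full[cbind(fid$schedule[[ax$label[1]]] + 1, fid$schedule[[ax$label[2]]] + 1)] <-
    as.vector(fid$values)
  ft <- Mod(stats::fft(full)) / (n1 * n2)
  shift <- function(n) c((n / 2 + 1):n, 1:(n / 2))
  ft[shift(n1), shift(n2)]
}

`%||%` <- rlang::`%||%`

# perfect strips/anchors built straight from an enumerated peak list,
# bypassing reconstruction (noiseless picking oracle)
perfect_inputs <- function(shifts, experiment = "HACACONCOCONH_5D",
                           model = mixing_model()) {
  pk <- enumerate_peaks(shifts, experiment, model)
  k <- which(shifts$aa != "P" & shifts$index >= 2)
  anchors <- tibble::tibble(
    id = sprintf("%s%d", shifts$aa[k], k), residue = k,
    CO = shifts$CO[k - 1], N = shifts$N[k]
  )
  strips <- tibble::tibble(
    anchor_id = sprintf("%s%d", shifts$aa[pk$anchor], pk$anchor),
    CO = pk$COres, N = pk$Nres, height = pk$amplitude
  )
  list(anchors = anchors, strips = strips, peaks = pk)
}
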