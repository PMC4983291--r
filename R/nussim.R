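# gyromagnetic ratios relative to 1H, used for ppm <-> Hz conversion
nucleus_gamma <- c(H = 1.0, N = 0.10136767, C = 0.25145020)

#' Define an indirect evolution axis
#'
#' An axis is a Nyquist grid: `n = round(sw_hz * t_max)` points at dwell
#' `1/sw_hz`. Axes flagged `nus = TRUE` are the non-uniformly sampled,
#' newly resolved dimensions; grid axes (`nus = FALSE`) model dimensions whose
#' coordinates are already resolved by the conventionally analysed HNCO base
#' and are synthesized on their full grid.
#'
#' @param label Dimension label (must match a peak-list column, e.g. `"COres"`).
#' @param nucleus `"H"`, `"N"` or `"C"` (sets the observe frequency).
#' @param carrier_ppm Carrier position (ppm).
#' @param sw_ppm Spectral width (ppm).
#' @param n Grid size (points).
#' @param field_mhz Proton frequency (MHz).
#' @param r2 Decay rate (1/s) of the synthetic signal along this axis;
#'   default `2 / t_max`, i.e. a linewidth of about two grid cells.
#' @param nus Whether the axis is non-uniformly sampled.
#'
#' @return One-row tibble describing the axis.
#' @examples
#' nmr_axis("COres", "C", 174.5, 16, 64, 600, nus = TRUE)
#' @export
nmr_axis <- function(label, nucleus = c("C", "N", "H"), carrier_ppm, sw_ppm,
                     n, field_mhz = 600, r2 = NULL, nus = FALSE) {
  nucleus <- match.arg(nucleus)
  obs_mhz <- nucleus_gamma[[nucleus]] * field_mhz
  sw_hz <- sw_ppm * obs_mhz
  t_max <- n / sw_hz
  tibble(label = label, nucleus = nucleus, carrier_ppm = carrier_ppm,
         sw_ppm = sw_ppm, sw_hz = sw_hz, n = as.integer(n),
         obs_mhz = obs_mhz, t_max_s = t_max,
         r2 = r2 %||% (2 / t_max), nus = nus)
}

#' Default axis set for an experiment
#'
#' Builds the indirect axes of the chosen experiment: the anchor nitrogen and
#' carbonyl dimensions as full grids (they are read off the HNCO base
#' spectrum) and the resolved dimensions as NUS axes. The windows cover the
#' whole plausible IDP range, including proline nitrogens near 137 ppm. The
#' detected amide-proton dimension carries no assignment information in this
#' model and is not simulated.
#'
#' @param experiment An [experiment_spec()] or its name.
#' @param field_mhz Proton frequency (MHz).
#' @param n_anchor,n_resolved Grid sizes for anchor and resolved axes.
#' @return An axes tibble (one row per [nmr_axis()]).
#' @export
default_axes <- function(experiment, field_mhz = 600, n_anchor = 64, n_resolved = 64) {
  if (is.character(experiment)) experiment <- experiment_spec(experiment)
  # anchor windows cover only what an HNCO shows (amide N of non-proline
  # residues, any CO); the resolved N window additionally covers proline N
  win <- list(N = c(carrier = 116.5, sw = 30), CO = c(carrier = 176.25, sw = 11),
              Nres = c(carrier = 121, sw = 44), COres = c(carrier = 176.25, sw = 11))
  rows <- list(
    nmr_axis("N", "N", win$N[["carrier"]], win$N[["sw"]], n_anchor, field_mhz),
    nmr_axis("CO", "C", win$CO[["carrier"]], win$CO[["sw"]], n_anchor, field_mhz)
  )
  for (lab in experiment$resolved) {
    nuc <- if (lab == "COres") "C" else "N"
    rows <- c(rows, list(nmr_axis(lab, nuc, win[[lab]][["carrier"]],
                                  win[[lab]][["sw"]], n_resolved, field_mhz,
                                  nus = TRUE)))
  }
  dplyr::bind_rows(rows)
}

#' Generate a NUS sampling schedule
#'
#' Draws `n_points` distinct points uniformly at random from the Nyquist grid
#' spanned by the NUS axes, always including the zero-time coordinate, and
#' deterministically for a given seed.
#'
#' @param axes An axes tibble; only rows with `nus = TRUE` are sampled.
#' @param n_points Number of sampled grid points (<= grid size).
#' @param seed Integer seed.
#' @return A tibble of 0-based integer indices, one column per NUS axis, with
#'   attributes `seed` and `mode`.
#' @examples
#' ax <- default_axes("HACACONCOCONH_5D")
#' sched <- make_schedule(ax, 1100, seed = 7)
#' @export
make_schedule <- function(axes, n_points, seed = 1) {
  nus <- axes[axes$nus, ]
  if (nrow(nus) == 0) abort("no NUS axes to schedule.")
  total <- prod(nus$n)
  if (n_points > total) {
    abort(sprintf("n_points (%d) exceeds the %d-point sampling grid.",
                  as.integer(n_points), as.integer(total)))
  }
  flat <- with_seed(child_seed(seed, 303), sample.int(total, n_points)) - 1L
  if (!0L %in% flat) flat[1L] <- 0L
  flat <- sort(flat)
  coords <- flat
  out <- list()
  for (d in seq_len(nrow(nus))) {
    out[[nus$label[d]]] <- as.integer(coords %% nus$n[d])
    coords <- coords %/% nus$n[d]
  }
  out <- as_tibble(out)
  attr(out, "seed") <- seed
  attr(out, "mode") <- "uniform"
  out
}

#' Write / read a sampling schedule
#'
#' The common NUS schedule text dialect: one line per sampled point,
#' space-separated integer grid indices.
#'
#' @param schedule Schedule tibble from [make_schedule()].
#' @param path File path.
#' @param labels Column labels to assign on reading.
#' @return The path (write) or the schedule tibble (read).
#' @export
write_schedule <- function(schedule, path) {
  writeLines(apply(as.matrix(schedule), 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, labels = NULL) {
  m <- as.matrix(readr::read_table(path, col_names = FALSE,
                                   col_types = readr::cols(.default = "i")))
  colnames(m) <- labels %||% sprintf("dim%d", seq_len(ncol(m)))
  as_tibble(m)
}

# per-peak complex evolution factors along one axis at given time points
axis_factor <- function(peak_ppm, axis, t) {
  nu <- (peak_ppm - axis$carrier_ppm) * axis$obs_mhz # Hz
  outer(2i * pi * nu - axis$r2, t)                   # P x length(t), exponent
}

check_in_window <- function(peaks, axis) {
  nu <- (peaks[[axis$label]] - axis$carrier_ppm) * axis$obs_mhz
  bad <- abs(nu) > axis$sw_hz / 2
  if (any(bad)) {
    abort(sprintf(
      "peak %d (%s = %.3f ppm) falls outside the %s spectral window (%.2f +/- %.2f ppm); folding is not modelled.",
      which(bad)[1], axis$label, peaks[[axis$label]][which(bad)[1]],
      axis$label, axis$carrier_ppm, axis$sw_ppm / 2))
  }
}

#' Synthesize time-domain data for a peak list
#'
#' Each peak contributes a separable complex exponential
#' `amplitude * prod_d exp(2i pi nu_d t_d - r2_d t_d)` (ideal complex
#' quadrature in every dimension; no conjugate symmetry is assumed).
#' Grid axes are evaluated on their full Nyquist grid and NUS axes at the
#' scheduled points; complex Gaussian noise of per-component standard
#' deviation `noise_sigma` is added to every stored value.
#'
#' @param peaks Peak tibble; must carry one ppm column per axis label plus
#'   `amplitude`. Peaks outside any spectral window are an error.
#' @param axes Axes tibble ([nmr_axis()] rows).
#' @param schedule Schedule tibble over the NUS axes ([make_schedule()]).
#' @param noise_sigma Noise standard deviation per real/imaginary component.
#' @param seed Seed for the noise draw.
#'
#' @return An object of class `conconnmr_fid`: list with `axes`, `schedule`,
#'   and `values`, a complex matrix of dimension (full-grid cells) x
#'   (scheduled points). With no grid axes the matrix has one row.
#' @export
synthesize_fid <- function(peaks, axes, schedule, noise_sigma = 0, seed = 1) {
  grid_axes <- axes[!axes$nus, , drop = FALSE]
  nus_axes <- axes[axes$nus, , drop = FALSE]
  if (!setequal(names(schedule), nus_axes$label)) {
    abort("schedule columns must match the NUS axis labels.")
  }
  if (nrow(schedule) == 0) abort("empty sampling schedule.")
  miss <- setdiff(axes$label, names(peaks))
  if (length(miss)) abort(paste("peak list lacks dimension columns:",
                                paste(miss, collapse = ", ")))
  for (d in seq_len(nrow(axes))) check_in_window(peaks, axes[d, ])
  p <- nrow(peaks)

  # anchor (grid) part: kronecker accumulation, first grid axis fastest
  a <- matrix(peaks$amplitude + 0i, nrow = 1, ncol = p)
  for (d in seq_len(nrow(grid_axes))) {
    ax <- grid_axes[d, ]
    t <- (seq_len(ax$n) - 1) / ax$sw_hz
    f <- exp(t(axis_factor(peaks[[ax$label]], ax, t))) # n x P
    r <- nrow(a)
    a <- a[rep(seq_len(r), times = ax$n), , drop = FALSE] *
      f[rep(seq_len(ax$n), each = r), , drop = FALSE]
  }

  # NUS part: per scheduled point
  b <- matrix(1 + 0i, nrow = p, ncol = nrow(schedule))
  for (d in seq_len(nrow(nus_axes))) {
    ax <- nus_axes[d, ]
    t <- schedule[[ax$label]] / ax$sw_hz
    b <- b * exp(axis_factor(peaks[[ax$label]], ax, t))
  }

  values <- a %*% b
  if (noise_sigma > 0) {
    values <- values + with_seed(child_seed(seed, 404), {
      matrix(complex(real = rnorm(length(values), 0, noise_sigma),
                     imaginary = rnorm(length(values), 0, noise_sigma)),
             nrow(values), ncol(values))
    })
  }
  structure(list(axes = axes, schedule = schedule, values = values,
                 noise_sigma = noise_sigma, seed = seed),
            class = "conconnmr_fid")
}

#' Write / read a time-domain set as TSV
#'
#' One row per stored value: the grid-cell indices, the scheduled NUS
#' indices, and the real and imaginary parts.
#'
#' @param fid A `conconnmr_fid` from [synthesize_fid()].
#' @param path File path.
#' @return The path, invisibly; `read_fid_tsv()` returns a plain tibble of
#'   indices and complex parts (metadata is carried by the axes file of the
#'   run, not the TSV).
#' @export
write_fid_tsv <- function(fid, path) {
  grid_axes <- fid$axes[!fid$axes$nus, , drop = FALSE]
  cells <- if (nrow(grid_axes)) {
    do.call(expand.grid, lapply(grid_axes$n, function(n) 0:(n - 1)))
  } else {
    data.frame(row.names = 1)
  }
  n_cells <- nrow(fid$values)
  n_sched <- ncol(fid$values)
  out <- tibble(
    cell = rep(seq_len(n_cells), times = n_sched),
    point = rep(seq_len(n_sched), each = n_cells),
    re = as.vector(Re(fid$values)),
    im = as.vector(Im(fid$values))
  )
  if (nrow(grid_axes)) {
    for (d in seq_len(nrow(grid_axes))) {
      out[[grid_axes$label[d]]] <- cells[[d]][out$cell]
    }
  }
  for (lab in names(fid$schedule)) {
    out[[lab]] <- fid$schedule[[lab]][out$point]
  }
  readr::write_tsv(out[, c(setdiff(names(out), c("re", "im")), "re", "im")], path)
  invisible(path)
}

#' @rdname write_fid_tsv
#' @export
read_fid_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
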