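# frequency evaluation grid (Hz) of an axis, optionally oversampled
axis_freq_grid <- function(axis, oversample = 1) {
  g <- axis$n * oversample
  -axis$sw_hz / 2 + (0:(g - 1)) * axis$sw_hz / g
}

#' Sparse multidimensional Fourier transform cross-section
#'
#' Evaluates the discrete Fourier transform of a (non-uniformly) sampled
#' time-domain set on a dense frequency grid over one or two resolved axes,
#' with every other axis fixed at the anchor's exact frequency:
#' `S(omega) = (1/M) * sum_t d(t) * exp(-2i pi (nu_anchor . t_anchor + omega . t_res))`,
#' where `M` is the number of sampled points. Anchor frequencies are taken
#' from the HNCO-derived anchor peak and are evaluated exactly, not snapped
#' to a grid. The returned section is the magnitude (no phase correction is
#' needed for the ideally phased synthetic model, and magnitude display
#' avoids zero-order phase bookkeeping).
#'
#' @param fid A `conconnmr_fid` from [synthesize_fid()].
#' @param anchor Named numeric vector of ppm positions for every axis not in
#'   `resolved` (e.g. `c(N = 119.2, CO = 176.1)`).
#' @param resolved Labels of 1 or 2 NUS axes to grid.
#' @param oversample Frequency-grid oversampling factor relative to the
#'   Nyquist grid (default 2).
#' @param apodize `"none"` (the plain sparse FT above) or `"cosine"`: weight
#'   every sampled point by `prod_d cos(pi t_d / (2 t_max_d))`, the usual
#'   half-cosine window, suppressing truncation sidelobes at the cost of some
#'   line broadening.
#' @param label Optional anchor label carried through to the result.
#'
#' @return An object of class `conconnmr_section`: list with `values`
#'   (magnitude vector or matrix), `axes` (resolved axis tibble), `ppm`
#'   (list of ppm coordinate vectors), `anchor`, `anchor_label` and `m`
#'   (number of sampled points).
#' @export
cross_section <- function(fid, anchor, resolved, oversample = 2,
                          apodize = c("none", "cosine"), label = NULL) {
  apodize <- match.arg(apodize)
  stopifnot(inherits(fid, "conconnmr_fid"))
  axes <- fid$axes
  if (!all(resolved %in% axes$label[axes$nus])) {
    abort("`resolved` must name NUS axes of the data.")
  }
  if (length(resolved) < 1 || length(resolved) > 2) {
    abort("sections are 1D or 2D: give 1 or 2 resolved axes.")
  }
  other <- setdiff(axes$label, resolved)
  if (!all(other %in% names(anchor))) {
    abort(paste("anchor must fix axes:", paste(setdiff(other, names(anchor)), collapse = ", ")))
  }
  if (ncol(fid$values) == 0 || nrow(fid$schedule) == 0) abort("empty sampling schedule.")

  grid_axes <- axes[!axes$nus, , drop = FALSE]
  # collapse fully gridded axes at the anchor frequencies (conjugate phases)
  w <- matrix(1 + 0i, nrow = 1, ncol = 1)
  for (d in seq_len(nrow(grid_axes))) {
    ax <- grid_axes[d, ]
    nu <- (anchor[[ax$label]] - ax$carrier_ppm) * ax$obs_mhz
    t <- (seq_len(ax$n) - 1) / ax$sw_hz
    f <- exp(-2i * pi * nu * t)
    if (apodize == "cosine") f <- f * cos(pi * t / (2 * ax$t_max_s))
    w <- as.matrix(kronecker(f, w))
  }
  v <- as.vector(crossprod(w[, 1], fid$values)) # 1 x n_sched

  # anchor-fixed NUS axes (if any) add a per-point phase
  for (lab in setdiff(axes$label[axes$nus], resolved)) {
    ax <- axes[axes$label == lab, ]
    nu <- (anchor[[lab]] - ax$carrier_ppm) * ax$obs_mhz
    tl <- fid$schedule[[lab]] / ax$sw_hz
    v <- v * exp(-2i * pi * nu * tl)
    if (apodize == "cosine") v <- v * cos(pi * tl / (2 * ax$t_max_s))
  }

  m_total <- length(fid$values)
  res_axes <- axes[match(resolved, axes$label), , drop = FALSE]
  emat <- function(ax) {
    nu <- axis_freq_grid(ax, oversample)
    t <- fid$schedule[[ax$label]] / ax$sw_hz
    e <- exp(-2i * pi * outer(nu, t)) # grid x n_sched
    if (apodize == "cosine") {
      e <- e * matrix(cos(pi * t / (2 * ax$t_max_s)), nrow(e), length(t), byrow = TRUE)
    }
    e
  }
  if (length(resolved) == 1L) {
    e1 <- emat(res_axes[1, ])
    s <- as.vector(e1 %*% v) / m_total
    values <- Mod(s)
  } else {
    e1 <- emat(res_axes[1, ])
    e2 <- emat(res_axes[2, ])
    s <- (e1 * matrix(v, nrow(e1), length(v), byrow = TRUE)) %*% t(e2) / m_total
    values <- Mod(s)
  }
  ppm <- lapply(seq_len(nrow(res_axes)), function(d) {
    ax <- res_axes[d, ]
    ax$carrier_ppm + axis_freq_grid(ax, oversample) / ax$obs_mhz
  })
  names(ppm) <- resolved
  structure(list(values = values, axes = res_axes, ppm = ppm,
                 anchor = anchor, anchor_label = label %||% "",
                 oversample = oversample, m = m_total),
            class = "conconnmr_section")
}

#' Sampling-artefact noise level of a cross-section
#'
#' Median magnitude of the cross-section at randomly chosen grid positions
#' far (more than three linewidths per axis) from every supplied true peak;
#' incomplete sampling leaks signal energy across the whole section and this
#' median is the natural threshold reference for peak picking.
#'
#' @inheritParams cross_section
#' @param peaks Optional peak tibble with the resolved ppm columns; positions
#'   near these peaks are excluded from the estimate.
#' @param n_off Number of off-peak probe positions (>= 10).
#' @param seed Seed for the probe-position draw.
#' @return The median off-peak magnitude (a scalar).
#' @export
sampling_noise_level <- function(fid, anchor, resolved, peaks = NULL,
                                 n_off = 50, seed = 1,
                                 apodize = c("none", "cosine")) {
  if (n_off < 10) abort("`n_off` must be at least 10.")
  section <- cross_section(fid, anchor, resolved, oversample = 1, apodize = apodize)
  vals <- section$values
  dims <- if (is.matrix(vals)) dim(vals) else length(vals)
  ok <- array(TRUE, dim = dims)
  if (!is.null(peaks)) {
    for (d in seq_along(resolved)) {
      ax <- section$axes[d, ]
      lw_cells <- max(1, (ax$r2 / pi) / (ax$sw_hz / ax$n))
      cell_ppm <- ax$sw_ppm / ax$n
      centers <- section$ppm[[d]]
      for (pk in peaks[[resolved[d]]]) {
        near_d <- abs(centers - pk) <= 3 * lw_cells * cell_ppm
        if (length(dims) == 2L) {
          if (d == 1L) ok[near_d, ] <- FALSE else ok[, near_d] <- FALSE
        } else {
          ok[near_d] <- FALSE
        }
      }
    }
  }
  idx <- which(ok)
  if (length(idx) == 0) abort("no off-peak positions available for the noise estimate.")
  probe <- with_seed(child_seed(seed, 505),
                     sample(idx, min(n_off, length(idx))))
  median(vals[probe])
}

#' Pick peaks on a cross-section
#'
#' Local maxima above `threshold * noise_level`, accepted greedily in height
#' order with a per-axis exclusion radius of `min_separation` grid steps;
#' positions are refined by three-point parabolic interpolation along each
#' axis.
#'
#' @param section A `conconnmr_section`.
#' @param noise_level Reference level, typically [sampling_noise_level()].
#' @param threshold Multiplier on `noise_level` (> 1).
#' @param min_separation Exclusion radius in grid steps.
#' @param rel_floor Additional relative floor: picks below `rel_floor` times
#'   the section maximum are discarded regardless of the noise level (guards
#'   the noiseless limit, where the off-peak median vanishes).
#' @return A tibble with one ppm column per resolved axis plus `height`;
#'   zero rows if nothing exceeds the threshold.
#' @export
pick_peaks <- function(section, noise_level, threshold = 5, min_separation = 2,
                       rel_floor = 0) {
  stopifnot(inherits(section, "conconnmr_section"))
  if (threshold <= 1) abort("`threshold` must exceed 1.")
  vals <- section$values
  cut <- max(threshold * noise_level, rel_floor * max(vals))
  para <- function(hm, h0, hp) {
    den <- hm - 2 * h0 + hp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (hm - hp) / den))
  }
  cand <- list()
  if (is.matrix(vals)) {
    n1 <- nrow(vals); n2 <- ncol(vals)
    for (i in 2:(n1 - 1)) {
      for (j in 2:(n2 - 1)) {
        h <- vals[i, j]
        if (h <= cut) next
        nb <- vals[(i - 1):(i + 1), (j - 1):(j + 1)]
        if (h < max(nb)) next
        if (sum(nb == h) > 1 && (vals[i - 1, j] == h || vals[i, j - 1] == h)) next
        cand[[length(cand) + 1]] <- c(i, j, h)
      }
    }
    if (length(cand) == 0) {
      out <- tibble(height = numeric(0))
      for (lab in rev(names(section$ppm))) out <- dplyr::bind_cols(tibble(!!lab := numeric(0)), out)
      return(out)
    }
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3]), , drop = FALSE]
    kept <- matrix(numeric(0), ncol = 3)
    for (r in seq_len(nrow(cand))) {
      if (nrow(kept) == 0 ||
          all(pmax(abs(kept[, 1] - cand[r, 1]), abs(kept[, 2] - cand[r, 2])) >= min_separation)) {
        kept <- rbind(kept, cand[r, ])
      }
    }
    pos <- lapply(seq_len(nrow(kept)), function(r) {
      i <- kept[r, 1]; j <- kept[r, 2]
      di <- para(vals[i - 1, j], vals[i, j], vals[i + 1, j])
      dj <- para(vals[i, j - 1], vals[i, j], vals[i, j + 1])
      c(interp_ppm(section, 1, i + di), interp_ppm(section, 2, j + dj), vals[i, j])
    })
    pos <- do.call(rbind, pos)
    out <- tibble(!!names(section$ppm)[1] := pos[, 1],
                  !!names(section$ppm)[2] := pos[, 2],
                  height = pos[, 3])
  } else {
    n1 <- length(vals)
    for (i in 2:(n1 - 1)) {
      h <- vals[i]
      if (h > cut && h >= vals[i - 1] && h >= vals[i + 1] && vals[i - 1] != h) {
        cand[[length(cand) + 1]] <- c(i, h)
      }
    }
    if (length(cand) == 0) {
      return(tibble(!!names(section$ppm)[1] := numeric(0), height = numeric(0)))
    }
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 2]), , drop = FALSE]
    kept <- matrix(numeric(0), ncol = 2)
    for (r in seq_len(nrow(cand))) {
      if (nrow(kept) == 0 || all(abs(kept[, 1] - cand[r, 1]) >= min_separation)) {
        kept <- rbind(kept, cand[r, ])
      }
    }
    pos <- vapply(seq_len(nrow(kept)), function(r) {
      i <- kept[r, 1]
      interp_ppm(section, 1, i + para(vals[i - 1], vals[i], vals[i + 1]))
    }, numeric(1))
    out <- tibble(!!names(section$ppm)[1] := pos, height = kept[, 2])
  }
  out[order(-out$height), ]
}

# fractional grid index -> ppm along resolved axis d
interp_ppm <- function(section, d, idx) {
  ppm <- section$ppm[[d]]
  step <- ppm[2] - ppm[1]
  ppm[1] + (idx - 1) * step
}

#' Write a cross-section as a matrix TSV
#'
#' Plain matrix with the resolved ppm coordinates as the first column and
#' header row.
#'
#' @param section A `conconnmr_section`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_section_tsv <- function(section, path) {
  vals <- section$values
  if (is.matrix(vals)) {
    out <- as_tibble(vals, .name_repair = ~ sprintf("%.4f", section$ppm[[2]]))
    out <- dplyr::bind_cols(tibble(ppm = section$ppm[[1]]), out)
  } else {
    out <- tibble(ppm = section$ppm[[1]], value = vals)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot a 2D cross-section
#'
#' @param object A `conconnmr_section` with two resolved axes.
#' @param ... Unused.
#' @return A ggplot raster of the section magnitude, axes reversed in the
#'   usual NMR convention.
#' @method autoplot conconnmr_section
#' @export
autoplot.conconnmr_section <- function(object, ...) {
  if (!is.matrix(object$values)) abort("autoplot needs a 2D section.")
  labs <- names(object$ppm)
  df <- expand.grid(x = object$ppm[[1]], y = object$ppm[[2]])
  df$z <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_reverse() + ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = paste(labs[1], "(ppm)"), y = paste(labs[2], "(ppm)"),
                  fill = "|S|",
                  title = paste("strip", object$anchor_label)) +
    ggplot2::theme_minimal()
}
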