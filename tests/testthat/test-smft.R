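test_that("fully sampled cross-sections equal the dense FFT to machine precision", {
  ax <- tiny_axes(32, 32)
  pk <- tiny_peaks(5, seed = 3)
  fid <- synthesize_fid(pk, ax, make_schedule(ax, 1024, seed = 1))
  sec <- cross_section(fid, c(), c("COres", "Nres"), oversample = 1)
  ft <- dense_fft_2d(fid)
  expect_lt(max(abs(sec$values - ft)) / max(ft), 1e-9)
})

test_that("anchored sections equal the matching dense-FFT plane", {
  axes <- dplyr::bind_rows(
    nmr_axis("N", "N", 116.5, 30, 8, 600),
    tiny_axes(16, 16)
  )
  pk <- tiny_peaks(4, seed = 4)
  pk$N <- grid_ppm(axes[1, ], c(2, 5, 5, 7)) # on-grid anchor frequencies
  fid <- synthesize_fid(pk, axes, make_schedule(axes, 256, seed = 2))
  # dense 3D FFT oracle
  arr <- array(0 + 0i, c(8, 16, 16))
  for (s in seq_len(256)) {
    arr[, fid$schedule$COres[s] + 1, fid$schedule$Nres[s] + 1] <- fid$values[, s]
  }
  ft1 <- apply(arr, c(2, 3), stats::fft)
  ft2 <- aperm(apply(ft1, c(1, 3), stats::fft), c(2, 1, 3))
  ft3 <- aperm(apply(ft2, c(1, 2), stats::fft), c(2, 3, 1))
  shift <- function(n) c((n / 2 + 1):n, 1:(n / 2))
  ftm <- Mod(ft3)[shift(8), shift(16), shift(16)] / (8 * 256)
  for (plane in c(2, 5)) {
    sec <- cross_section(fid, c(N = grid_ppm(axes[1, ], plane)),
                         c("COres", "Nres"), oversample = 1)
    expect_lt(max(abs(sec$values - ftm[plane + 1, , ])) / max(ftm), 1e-9)
  }
  expect_error(cross_section(fid, c(), c("COres", "Nres")), "anchor must fix")
  expect_error(cross_section(fid, c(N = 116), c("N")), "NUS axes")
})

test_that("sampling noise level behaves like a leakage/thermal floor", {
  ax <- tiny_axes(32, 32)
  ax$r2 <- 0
  pk <- tibble::tibble(COres = grid_ppm(ax[1, ], 8), Nres = grid_ppm(ax[2, ], 20),
                       amplitude = 1)
  full <- synthesize_fid(pk, ax, make_schedule(ax, 1024, seed = 1))
  nl_full <- sampling_noise_level(full, c(), c("COres", "Nres"), peaks = pk)
  sec <- cross_section(full, c(), c("COres", "Nres"), oversample = 1)
  expect_lt(nl_full, 1e-6 * max(sec$values))
  # 25 % sampling leaks
  sub <- synthesize_fid(pk, ax, make_schedule(ax, 256, seed = 1))
  nl_sub <- sampling_noise_level(sub, c(), c("COres", "Nres"), peaks = pk)
  expect_gt(nl_sub, nl_full)
  # pure noise: median magnitude ~ 1.18 * sigma / sqrt(M), within a factor 3 of 1/sqrt(M)
  lv <- vapply(1:50, function(s) {
    sched <- make_schedule(ax, 128, seed = s)
    nf <- synthesize_fid(tibble::tibble(COres = 176.25, Nres = 121, amplitude = 0),
                         ax, sched, noise_sigma = 1, seed = s)
    sampling_noise_level(nf, c(), c("COres", "Nres"), seed = s)
  }, numeric(1))
  m <- median(lv)
  expect_gt(m, (1 / sqrt(128)) / 3)
  expect_lt(m, (1 / sqrt(128)) * 3)
})

test_that("picking finds isolated peaks at their cells, ordered by height", {
  ax <- tiny_axes(64, 64)
  ax$r2 <- 0 # pure tones: no truncation ridges
  pk <- tibble::tibble(COres = grid_ppm(ax[1, ], c(10, 40)),
                       Nres = grid_ppm(ax[2, ], c(50, 14)),
                       amplitude = c(1, 0.6))
  fid <- synthesize_fid(pk, ax, make_schedule(ax, 4096, seed = 1))
  sec <- cross_section(fid, c(), c("COres", "Nres"), oversample = 1)
  nl <- sampling_noise_level(fid, c(), c("COres", "Nres"), peaks = pk)
  # the noise level of a fully sampled on-grid pair is numerically zero, so a
  # tiny relative floor guards against machine-precision ripples
  picks <- pick_peaks(sec, nl, threshold = 5, rel_floor = 1e-6)
  expect_equal(nrow(picks), 2)
  expect_true(all(diff(picks$height) <= 0))
  expect_lt(abs(picks$COres[1] - pk$COres[1]), ax$sw_ppm[1] / ax$n[1])
  expect_lt(abs(picks$Nres[2] - pk$Nres[2]), ax$sw_ppm[2] / ax$n[2])
})

test_that("three peaks are recovered within a grid step from 30 % sampling", {
  ax <- tiny_axes(64, 64)
  pk <- tibble::tibble(COres = 176.25 + c(-3.1, 0.4, 3.7),
                       Nres = 121 + c(10.2, -14.6, 2.9),
                       amplitude = c(1, 0.7, 0.5))
  fid <- synthesize_fid(pk, ax, make_schedule(ax, round(0.3 * 4096), seed = 9))
  sec <- cross_section(fid, c(), c("COres", "Nres"), oversample = 1)
  nl <- sampling_noise_level(fid, c(), c("COres", "Nres"), peaks = pk, seed = 9)
  picks <- pick_peaks(sec, nl, threshold = 5)
  expect_gte(nrow(picks), 3)
  cell <- c(ax$sw_ppm[1] / ax$n[1], ax$sw_ppm[2] / ax$n[2])
  for (r in 1:3) {
    d <- sqrt(((picks$COres - pk$COres[r]) / cell[1])^2 +
                ((picks$Nres - pk$Nres[r]) / cell[2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("section energy obeys the zero-augmented Parseval identity", {
  ax <- tiny_axes(16, 16)
  ax$r2 <- 0 # undamped tones so no single time point dominates the energy
  pk <- tiny_peaks(3, seed = 12)
  ratios <- vapply(1:20, function(s) {
    sched <- make_schedule(ax, 96, seed = s)
    fid <- synthesize_fid(pk, ax, sched)
    sec <- cross_section(fid, c(), c("COres", "Nres"), oversample = 1)
    m <- length(fid$values)
    # sum |S|^2 * m^2 / n_grid should equal sum |d|^2 exactly
    sum(sec$values^2) * m^2 / 256 / sum(Mod(fid$values)^2)
  }, numeric(1))
  expect_equal(ratios, rep(1, 20), tolerance = 1e-9)
  # energy grows linearly with the number of sampled points for a fixed
  # signal (in expectation over uniform schedules)
  e <- vapply(c(64, 128, 192), function(np) {
    mean(vapply(1:20, function(s) {
      fid <- synthesize_fid(pk, ax, make_schedule(ax, np, seed = s))
      sum(Mod(fid$values)^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(e[2] / e[1], 2, tolerance = 0.1)
  expect_equal(e[3] / e[1], 3, tolerance = 0.1)
})

test_that("translating every peak translates the picks (shift theorem)", {
  ax <- tiny_axes(32, 32)
  pk <- tiny_peaks(2, seed = 14)
  pk$COres <- pk$COres / 2 + 176.25 / 2 # keep away from window edges
  pk$Nres <- pk$Nres / 2 + 121 / 2
  delta <- c(0.9, -3.2)
  sched <- make_schedule(ax, 512, seed = 3)
  run_picks <- function(p) {
    fid <- synthesize_fid(p, ax, sched)
    sec <- cross_section(fid, c(), c("COres", "Nres"), oversample = 1)
    nl <- sampling_noise_level(fid, c(), c("COres", "Nres"), peaks = p)
    pick_peaks(sec, nl, threshold = 5)
  }
  a <- run_picks(pk)
  b <- run_picks(dplyr::mutate(pk, COres = COres + delta[1], Nres = Nres + delta[2]))
  a <- a[order(a$COres), ]; b <- b[order(b$COres), ]
  cell <- c(ax$sw_ppm[1] / ax$n[1], ax$sw_ppm[2] / ax$n[2])
  expect_equal(nrow(a), nrow(b))
  expect_true(all(abs(b$COres - a$COres - delta[1]) < cell[1]))
  expect_true(all(abs(b$Nres - a$Nres - delta[2]) < cell[2]))
})
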