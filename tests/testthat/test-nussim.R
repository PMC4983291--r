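test_that("axes satisfy the Nyquist-grid relation", {
  ax <- nmr_axis("COres", "C", 176.25, 11, 64, 600, nus = TRUE)
  expect_equal(ax$n, round(ax$sw_hz * ax$t_max_s))
  expect_equal(ax$r2, 2 / ax$t_max_s)
  ax800 <- nmr_axis("Nres", "N", 121, 44, 64, 800)
  expect_gt(ax800$sw_hz, nmr_axis("Nres", "N", 121, 44, 64, 600)$sw_hz)
})

test_that("schedules are uniform, unique, seeded, and bounded", {
  ax <- tiny_axes(8, 8)
  full <- make_schedule(ax, 64, seed = 1)
  expect_equal(nrow(full), 64)
  expect_equal(nrow(dplyr::distinct(full)), 64)

  ax64 <- tiny_axes(64, 64)
  s1 <- make_schedule(ax64, 1100, seed = 5)
  s2 <- make_schedule(ax64, 1100, seed = 5)
  s3 <- make_schedule(ax64, 1100, seed = 6)
  expect_equal(nrow(dplyr::distinct(s1)), 1100)
  expect_identical(s1$COres, s2$COres)
  key <- function(s) paste(s$COres, s$Nres)
  expect_lt(length(intersect(key(s1), key(s3))) / 1100, 1)
  expect_true(any(s1$COres == 0 & s1$Nres == 0))
  expect_true(all(s1$COres >= 0 & s1$COres < 64))
  expect_error(make_schedule(ax, 100, seed = 1), "exceeds")
})

test_that("schedules round-trip through the text dialect", {
  ax <- tiny_axes(16, 16)
  s <- make_schedule(ax, 40, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_schedule(s, path)
  back <- read_schedule(path, labels = names(s))
  expect_equal(unname(as.matrix(back)), unname(as.matrix(s)))
})

test_that("synthesis is linear with unit value at zero time", {
  ax <- tiny_axes(16, 16)
  sched <- make_schedule(ax, 80, seed = 3)
  zero_idx <- which(sched$COres == 0 & sched$Nres == 0)
  one <- tiny_peaks(1, seed = 1, amp = 1)
  fid1 <- synthesize_fid(one, ax, sched)
  expect_equal(fid1$values[1, zero_idx], 1 + 0i, tolerance = 1e-12)
  p2 <- tiny_peaks(2, seed = 2)
  fid_a <- synthesize_fid(p2[1, ], ax, sched)
  fid_b <- synthesize_fid(p2[2, ], ax, sched)
  fid_ab <- synthesize_fid(p2, ax, sched)
  expect_equal(fid_ab$values, fid_a$values + fid_b$values, tolerance = 1e-12)
  expect_equal(fid_ab$values[1, zero_idx], sum(p2$amplitude) + 0i, tolerance = 1e-12)
})

test_that("noise is seeded and out-of-window peaks are refused", {
  ax <- tiny_axes(16, 16)
  sched <- make_schedule(ax, 50, seed = 4)
  pk <- tiny_peaks(2, seed = 5)
  n1 <- synthesize_fid(pk, ax, sched, noise_sigma = 0.3, seed = 11)
  n2 <- synthesize_fid(pk, ax, sched, noise_sigma = 0.3, seed = 11)
  n3 <- synthesize_fid(pk, ax, sched, noise_sigma = 0.3, seed = 12)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  bad <- tiny_peaks(1, seed = 1)
  bad$COres <- 176.25 + 7 # outside the 11 ppm window
  expect_error(synthesize_fid(bad, ax, sched), "outside")
  expect_error(synthesize_fid(pk, ax, sched[0, ]), "empty")
})

test_that("a fully sampled on-grid tone peaks at its own grid cell", {
  ax <- tiny_axes(16, 16)
  ax$r2 <- 0
  pk <- tibble::tibble(COres = grid_ppm(ax[1, ], 5), Nres = grid_ppm(ax[2, ], 11),
                       amplitude = 1)
  fid <- synthesize_fid(pk, ax, make_schedule(ax, 256, seed = 1))
  ft <- dense_fft_2d(fid)
  expect_equal(which(ft == max(ft), arr.ind = TRUE)[1, ], c(row = 6, col = 12))
  sec <- cross_section(fid, c(), c("COres", "Nres"), oversample = 1)
  expect_equal(which(sec$values == max(sec$values), arr.ind = TRUE)[1, ],
               c(row = 6, col = 12))
})

test_that("time-domain sets round-trip through the transparency TSV", {
  ax <- dplyr::bind_rows(
    nmr_axis("N", "N", 116.5, 30, 4, 600),
    tiny_axes(8, 8)
  )
  pk <- tiny_peaks(2, seed = 6)
  pk$N <- c(118, 115)
  sched <- make_schedule(ax, 20, seed = 7)
  fid <- synthesize_fid(pk, ax, sched)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fid_tsv(fid, path)
  back <- read_fid_tsv(path)
  expect_equal(nrow(back), length(fid$values))
  expect_equal(complex(real = back$re, imaginary = back$im)[order(back$point, back$cell)],
               as.vector(fid$values), tolerance = 1e-12)
})
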