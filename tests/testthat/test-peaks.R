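test_that("anchor enumeration skips prolines and the N terminus", {
  sh <- generate_shifts("AAPAA", seed = 1)
  pk <- enumerate_peaks(sh, "HNCO_3D")
  expect_equal(nrow(pk), 3)
  expect_equal(pk$anchor, c(2L, 4L, 5L))
  expect_equal(pk$CO, sh$CO[c(1, 3, 4)])
  expect_equal(pk$amplitude, rep(1, 3))
})

test_that("the two 5D start schemes treat proline pairs differently", {
  sh <- generate_shifts("AAPAA", seed = 1)
  hn <- enumerate_peaks(sh, "HNCOCONH_5D")
  haca <- enumerate_peaks(sh, "HACACONCOCONH_5D")
  # the proline pair is (CO_2, N_3): absent with an amide start ...
  expect_false(any(abs(hn$Nres - sh$N[3]) < 1e-9))
  # ... but present from the HA/CA start, as forward on strip 2 and backward on strip 4
  p_fwd <- haca[haca$anchor == 2 & haca$pair == 3, ]
  p_bwd <- haca[haca$anchor == 4 & haca$pair == 3, ]
  expect_equal(p_fwd$kind, "forward")
  expect_equal(p_bwd$kind, "backward")
  expect_equal(p_fwd$COres, sh$CO[2])
  expect_equal(p_fwd$Nres, sh$N[3])
})

test_that("proline contrast holds for random proline-bearing sequences", {
  for (seed in 1:5) {
    s <- random_idp_sequence(40, 4, seed = seed)
    sh <- generate_shifts(s, seed = seed)
    pro <- which(sh$is_proline)
    hn <- enumerate_peaks(sh, "HNCOCONH_5D")
    haca <- enumerate_peaks(sh, "HACACONCOCONH_5D")
    for (p in pro) {
      expect_false(any(abs(hn$Nres - sh$N[p]) < 1e-9))
      expect_true(any(abs(haca$Nres - sh$N[p]) < 1e-9))
    }
  }
})

test_that("zero mixing time leaves only unit-amplitude diagonal peaks", {
  sh <- generate_shifts(random_idp_sequence(25, 2, seed = 2), seed = 2)
  pk <- enumerate_peaks(sh, "HACACONCOCONH_5D",
                        model = mixing_model(t_mix_ms = 0, R600_per_s = 0))
  expect_true(all(pk$kind == "diagonal"))
  expect_equal(pk$amplitude, rep(1, nrow(pk)), tolerance = 1e-9)
  # diagonal resolved coordinates coincide with the anchor's own pair
  expect_equal(pk$COres, pk$CO)
  expect_equal(pk$Nres, pk$N)
})

test_that("amide-exchange attenuation scales amide-start amplitudes only", {
  sh <- generate_shifts("AAAAA", seed = 3)
  ex <- c(1, 1, 0.25, 1, 1)
  hn <- enumerate_peaks(sh, "HNCOCONH_5D", exchange_attenuation = ex,
                        amplitude_floor = 0)
  hn0 <- enumerate_peaks(sh, "HNCOCONH_5D", amplitude_floor = 0)
  sel <- hn$pair == 3
  expect_equal(hn$amplitude[sel], 0.25 * hn0$amplitude[sel])
  expect_equal(hn$amplitude[!sel], hn0$amplitude[!sel])
  haca <- enumerate_peaks(sh, "HACACONCOCONH_5D", exchange_attenuation = ex,
                          amplitude_floor = 0)
  haca0 <- enumerate_peaks(sh, "HACACONCOCONH_5D", amplitude_floor = 0)
  expect_equal(haca$amplitude, haca0$amplitude)
})

test_that("eligible pair counts follow the start-scheme rules", {
  expect_equal(nrow(eligible_pairs("AAPAA", "HNCOCONH_5D")), 3)
  expect_equal(nrow(eligible_pairs("AAPAA", "HACACONCOCONH_5D")), 4)
  expect_equal(nrow(eligible_pairs("AAAAA", "HNCOCONH_5D")), 4)
  expect_equal(nrow(eligible_pairs("AAAAA", "HACACONCOCONH_5D")), 4)
  s140 <- paste(rep("A", 140), collapse = "")
  expect_equal(nrow(eligible_pairs(s140, "HNCOCONH_5D")), 139)
  expect_equal(nrow(eligible_pairs(s140, "HACACONCOCONH_5D")), 139)
  # HA/CA start dominates on any proline-containing sequence
  for (seed in 1:4) {
    s <- random_idp_sequence(60, 6, seed = seed)
    expect_gt(nrow(eligible_pairs(s, "HACACONCOCONH_5D")),
              nrow(eligible_pairs(s, "HNCOCONH_5D")))
  }
})

test_that("the 5D peak list projects exactly onto the two complementary 4Ds", {
  sh <- generate_shifts(random_idp_sequence(30, 3, seed = 4), seed = 4)
  p5 <- enumerate_peaks(sh, "HACACONCOCONH_5D")
  p4co <- enumerate_peaks(sh, "HACACO_NCO_CONH_4D_CO")
  p4n <- enumerate_peaks(sh, "HACACO_N_CO_CONH_4D_N")
  expect_equal(as.data.frame(project_peaks(p5, "CO")), as.data.frame(p4co))
  expect_equal(as.data.frame(project_peaks(p5, "N")), as.data.frame(p4n))
})

test_that("peak lists round-trip through TSV and render as Sparky lists", {
  sh <- generate_shifts("AAPAA", seed = 1)
  pk <- enumerate_peaks(sh, "HACACONCOCONH_5D")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaks_tsv(pk, path)
  back <- read_peaks_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(pk), tolerance = 1e-12)
  expect_equal(attr(back, "experiment"), "HACACONCOCONH_5D")
  lst <- withr::local_tempfile(fileext = ".list")
  write_sparky(pk, lst, shifts = sh)
  lines <- readLines(lst)
  expect_match(lines[1], "Assignment\\s+w1\\s+w2")
  expect_equal(length(lines), nrow(pk) + 1)
  expect_match(lines[2], "A2CO-P3N-anchorA2|A1CO-A2N-anchorA2")
})
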