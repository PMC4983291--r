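test_that("perfect peak lists give complete links and one chain", {
  sh <- generate_shifts(random_idp_sequence(20, 0, seed = 8), seed = 8)
  inp <- perfect_inputs(sh)
  links <- build_links(inp$strips, inp$anchors)
  stats <- score_links(links, sh, "HACACONCOCONH_5D")
  expect_equal(stats$matched, stats$eligible)
  expect_equal(stats$percentage, c(100, 100))
  expect_match(stats$label[1], "^100 % \\(\\d+/\\d+\\)$")
  chains <- assemble_chains(links)
  expect_equal(max(chains$chain), 1)
  expect_equal(chains$residue, 2:20)
})

test_that("a proline is bridged by its flanking strips", {
  sh <- generate_shifts("AAPAA", seed = 1)
  inp <- perfect_inputs(sh)
  links <- build_links(inp$strips, inp$anchors)
  expect_equal(nrow(links$bridges), 1)
  eb <- links$edges[links$edges$to_type == "bridge", ]
  expect_setequal(eb$from, c("A2", "A4"))
  expect_setequal(eb$direction, c("forward", "backward"))
  chains <- assemble_chains(links)
  main <- chains[chains$chain == 1, ]
  expect_equal(main$node, c("A2", links$bridges$id, "A4", "A5"))
  stats <- score_links(links, sh, "HACACONCOCONH_5D")
  expect_equal(stats$percentage, c(100, 100))
})

test_that("near-degenerate anchors with one incoming cross-peak are rejected as ambiguous", {
  anchors <- tibble::tibble(
    id = c("A2", "B3", "C9", "C10"),
    residue = c(2, 3, 9, 10),
    CO = c(175, 176, 177.00, 177.01),
    N = c(110, 115, 120.00, 120.04)
  )
  strips <- tibble::tibble(
    anchor_id = c("A2", "B3"),
    CO = c(175, 177.005), N = c(110, 120.02),
    height = 1
  )
  links <- build_links(strips, anchors, tol_co = 0.05, tol_n = 0.2)
  expect_equal(nrow(links$edges), 0)
  expect_equal(nrow(links$ambiguities), 1)
  expect_setequal(unlist(links$ambiguities[, c("candidate_1", "candidate_2")]),
                  c("C9", "C10"))
})

test_that("deleting one interior strip splits the chain in two", {
  sh <- generate_shifts(random_idp_sequence(50, 0, seed = 15), seed = 15)
  inp <- perfect_inputs(sh)
  links_full <- build_links(inp$strips, inp$anchors)
  chains_full <- assemble_chains(links_full)
  expect_equal(max(chains_full$chain), 1)
  expect_equal(nrow(chains_full), 49)
  # the strip vanishes but its HNCO anchor entry remains
  drop <- inp$anchors$id[inp$anchors$residue == 25]
  links_cut <- build_links(inp$strips[inp$strips$anchor_id != drop, ],
                           inp$anchors)
  chains_cut <- assemble_chains(links_cut)
  expect_equal(max(chains_cut$chain), 2)
  expect_setequal(chains_cut$residue, setdiff(2:50, 25))
})

test_that("swapping two anchors' pairs is caught by the consistency check", {
  sh <- generate_shifts(random_idp_sequence(30, 0, seed = 16), seed = 16)
  inp <- perfect_inputs(sh)
  # swap the claimed pairs of residues 14 and 15 (mimicking a mixed-up
  # assignment of consecutive residues)
  anchors <- inp$anchors
  i14 <- which(anchors$residue == 14)
  i15 <- which(anchors$residue == 15)
  tmp <- anchors[i14, c("CO", "N")]
  anchors[i14, c("CO", "N")] <- anchors[i15, c("CO", "N")]
  anchors[i15, c("CO", "N")] <- tmp
  links <- build_links(inp$strips, anchors)
  chains <- assemble_chains(links)
  conflicts <- attr(chains, "conflicts")
  broken <- max(chains$chain) > 1
  expect_true(broken || nrow(conflicts) > 0)
  stats <- score_links(links, sh, "HACACONCOCONH_5D")
  expect_lt(stats$matched[1], stats$eligible[1])
})

test_that("random cross-peak deletion matches a brute-force recount", {
  sh <- generate_shifts(random_idp_sequence(40, 0, seed = 17), seed = 17)
  inp <- perfect_inputs(sh)
  cross <- inp$peaks$kind != "diagonal"
  set.seed(99)
  drop <- which(cross)[runif(sum(cross)) < 0.2]
  keep <- setdiff(seq_len(nrow(inp$strips)), drop)
  links <- build_links(inp$strips[keep, ], inp$anchors)
  stats <- score_links(links, sh, "HACACONCOCONH_5D")
  # brute-force oracle: a forward link for pair i survives iff the forward
  # cross-peak on strip i-1 was kept (all anchors are unique here)
  kept_peaks <- inp$peaks[keep, ]
  fwd <- sum(vapply(3:40, function(i) {
    any(kept_peaks$anchor == i - 1 & kept_peaks$pair == i)
  }, logical(1)))
  bwd <- sum(vapply(2:39, function(i) {
    any(kept_peaks$anchor == i + 1 & kept_peaks$pair == i)
  }, logical(1)))
  expect_equal(stats$matched[stats$direction == "forward"], fwd)
  expect_equal(stats$matched[stats$direction == "backward"], bwd)
})

test_that("linking from the complementary 4Ds equals linking from the 5D", {
  sh <- generate_shifts(random_idp_sequence(30, 3, seed = 18), seed = 18)
  inp <- perfect_inputs(sh)
  links5 <- build_links(inp$strips, inp$anchors)
  p5 <- inp$peaks
  strip_id <- sprintf("%s%d", sh$aa[p5$anchor], p5$anchor)
  picks_co <- tibble::tibble(anchor_id = strip_id, CO = p5$COres, height = p5$amplitude)
  picks_n <- tibble::tibble(anchor_id = strip_id, N = p5$Nres, height = p5$amplitude)
  links4 <- build_links(combine_4d_picks(picks_co, picks_n), inp$anchors)
  s5 <- score_links(links5, sh, "HACACONCOCONH_5D")
  s4 <- score_links(links4, sh, "HACACONCOCONH_5D")
  expect_equal(as.data.frame(s4), as.data.frame(s5))
  e5 <- dplyr::arrange(links5$edges[links5$edges$to_type == "anchor",
                                    c("from", "to", "direction")], from, to)
  e4 <- dplyr::arrange(links4$edges[links4$edges$to_type == "anchor",
                                    c("from", "to", "direction")], from, to)
  expect_equal(as.data.frame(e4), as.data.frame(e5))
})

test_that("tidy and glance summarise the link graph", {
  sh <- generate_shifts(random_idp_sequence(15, 1, seed = 19), seed = 19)
  inp <- perfect_inputs(sh)
  links <- build_links(inp$strips, inp$anchors)
  td <- tidy(links)
  expect_true(all(c("from", "to", "direction", "from_residue", "to_residue")
                  %in% names(td)))
  g <- glance(links)
  expect_equal(g$n_anchors, nrow(inp$anchors))
  expect_equal(g$n_edges, nrow(links$edges))
  map <- assignment_map(links, sh, "HACACONCOCONH_5D")
  expect_equal(nrow(map), nrow(sh) - 1)
  expect_true(all(map$status %in% c("pair", "only_CO", "only_N", "none")))
})
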