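#' Build the sequential link graph from picked strips
#'
#' Every anchor strip carries picked cross-peaks in the resolved
#' `(CO(i-1), N(i))` plane. The anchor's own pair (known from the HNCO base)
#' identifies the diagonal pick; every remaining pick is matched against the
#' other anchors' pairs using the normalized distance
#' `sqrt((dCO/tol_co)^2 + (dN/tol_n)^2)`, accepted when it is at most 1.
#' The closest anchor wins; if the second-closest candidate is within a
#' distance ratio of 1.2 the match is ambiguous and rejected (no guessing).
#' Picks matching no anchor are then cross-matched between strips: a forward
#' pick of strip k agreeing with a backward pick of a later strip creates a
#' *bridge node* — a CO-N pair with no strip of its own, which is how proline
#' pairs enter the graph and how chains pass through prolines.
#'
#' @param strips Tibble of picks with columns `anchor_id`, `CO`, `N`,
#'   `height` (one row per picked cross-peak; see [combine_4d_picks()] for
#'   the complementary-4D route).
#' @param anchors Tibble with columns `id`, `residue` (sequence index of the
#'   anchor amide), `CO`, `N` (the anchor's own pair from the HNCO).
#' @param tol_co,tol_n Match tolerances in ppm.
#'
#' @return An object of class `conconnmr_links`: list with `anchors` (plus
#'   `has_diagonal`), `edges`, `bridges`, `ambiguities`, `unmatched` and the
#'   tolerances.
#' @export
build_links <- function(strips, anchors, tol_co = 0.05, tol_n = 0.2) {
  stopifnot(all(c("anchor_id", "CO", "N") %in% names(strips)),
            all(c("id", "residue", "CO", "N") %in% names(anchors)))
  if (!"height" %in% names(strips)) strips$height <- 1
  ndist <- function(co, n, co0, n0) sqrt(((co - co0) / tol_co)^2 + ((n - n0) / tol_n)^2)

  anchors <- as_tibble(anchors)
  anchors$has_strip <- anchors$id %in% strips$anchor_id
  anchors$has_diagonal <- FALSE
  strips <- as_tibble(strips)
  strips$.row <- seq_len(nrow(strips))
  strips$role <- "cross"

  # identify each strip's diagonal: nearest pick to the anchor's own pair
  for (r in seq_len(nrow(anchors))) {
    on_strip <- strips$anchor_id == anchors$id[r]
    if (!any(on_strip)) next
    d <- ndist(strips$CO[on_strip], strips$N[on_strip], anchors$CO[r], anchors$N[r])
    if (min(d) <= 1) {
      anchors$has_diagonal[r] <- TRUE
      strips$role[strips$.row[on_strip][which.min(d)]] <- "diagonal"
    }
  }

  edges <- list()
  ambiguities <- list()
  unmatched <- list()
  cross <- strips[strips$role == "cross", , drop = FALSE]
  for (r in seq_len(nrow(cross))) {
    from <- cross$anchor_id[r]
    from_res <- anchors$residue[match(from, anchors$id)]
    cand <- anchors[anchors$id != from, ]
    d <- ndist(cross$CO[r], cross$N[r], cand$CO, cand$N)
    in_tol <- which(d <= 1)
    if (length(in_tol) == 0) {
      unmatched[[length(unmatched) + 1]] <- cross[r, ]
      next
    }
    o <- in_tol[order(d[in_tol])]
    if (length(o) > 1 && d[o[2]] / max(d[o[1]], 1e-12) < 1.2) {
      ambiguities[[length(ambiguities) + 1]] <-
        dplyr::mutate(cross[r, ], candidate_1 = cand$id[o[1]],
                      candidate_2 = cand$id[o[2]])
      next
    }
    to <- cand$id[o[1]]
    to_res <- cand$residue[o[1]]
    edges[[length(edges) + 1]] <- tibble(
      from = from, to = to, to_type = "anchor",
      direction = if (to_res > from_res) "forward" else "backward",
      distance = d[o[1]], CO = cross$CO[r], N = cross$N[r],
      height = cross$height[r]
    )
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else empty_edges()
  # at most one accepted edge per strip and direction; prefer candidates whose
  # reverse cross-peak exists on the target strip (mutual support beats raw
  # distance: leaked copies of other strips' peaks are never reciprocated)
  if (nrow(edges)) {
    rev_key <- paste(edges$to, edges$from)
    edges$supported <- paste(edges$from, edges$to) %in% rev_key
    edges <- edges |>
      dplyr::group_by(.data$from, .data$direction) |>
      dplyr::arrange(dplyr::desc(.data$supported), .data$distance,
                     .by_group = TRUE) |>
      dplyr::slice_head(n = 1) |>
      dplyr::ungroup()
  } else {
    edges$supported <- logical(0)
  }

  # bridge unmatched picks between different strips (proline pairs)
  un <- if (length(unmatched)) dplyr::bind_rows(unmatched) else strips[0, ]
  bridges <- tibble(id = character(0), CO = numeric(0), N = numeric(0))
  if (nrow(un) >= 2) {
    un$residue <- anchors$residue[match(un$anchor_id, anchors$id)]
    pairs <- list()
    for (a in seq_len(nrow(un) - 1)) {
      for (b in (a + 1):nrow(un)) {
        if (un$anchor_id[a] == un$anchor_id[b]) next
        dd <- ndist(un$CO[a], un$N[a], un$CO[b], un$N[b])
        if (dd <= 1) {
          pairs[[length(pairs) + 1]] <-
            c(a, b, dd, abs(un$residue[a] - un$residue[b]))
        }
      }
    }
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      # a bridge spans exactly one missing strip, so partners two residues
      # apart are the expected geometry; prefer them, then closeness
      pm <- pm[order(pm[, 4] != 2, pm[, 3]), , drop = FALSE]
      used <- logical(nrow(un))
      for (r in seq_len(nrow(pm))) {
        a <- pm[r, 1]; b <- pm[r, 2]
        if (used[a] || used[b]) next
        used[a] <- used[b] <- TRUE
        lo <- if (un$residue[a] < un$residue[b]) a else b
        hi <- if (lo == a) b else a
        bid <- sprintf("pair_%s_%s", un$anchor_id[lo], un$anchor_id[hi])
        bridges <- dplyr::bind_rows(bridges, tibble(
          id = bid, CO = mean(un$CO[c(a, b)]), N = mean(un$N[c(a, b)])))
        edges <- dplyr::bind_rows(
          edges,
          tibble(from = un$anchor_id[lo], to = bid, to_type = "bridge",
                 direction = "forward", distance = pm[r, 3],
                 CO = un$CO[lo], N = un$N[lo], height = un$height[lo],
                 supported = TRUE),
          tibble(from = un$anchor_id[hi], to = bid, to_type = "bridge",
                 direction = "backward", distance = pm[r, 3],
                 CO = un$CO[hi], N = un$N[hi], height = un$height[hi],
                 supported = TRUE))
      }
      un <- un[!used, , drop = FALSE]
    }
  }
  structure(list(
    anchors = anchors,
    edges = edges,
    bridges = bridges,
    ambiguities = if (length(ambiguities)) dplyr::bind_rows(ambiguities) else NULL,
    unmatched = un,
    tol_co = tol_co, tol_n = tol_n
  ), class = "conconnmr_links")
}

empty_edges <- function() {
  tibble(from = character(0), to = character(0), to_type = character(0),
         direction = character(0), distance = numeric(0),
         CO = numeric(0), N = numeric(0), height = numeric(0))
}

#' @export
print.conconnmr_links <- function(x, ...) {
  cat("<conconnmr link graph>\n")
  cat("  anchors:", nrow(x$anchors),
      "| with diagonal:", sum(x$anchors$has_diagonal), "\n")
  cat("  edges:", nrow(x$edges),
      "| bridges:", nrow(x$bridges),
      "| ambiguous:", if (is.null(x$ambiguities)) 0 else nrow(x$ambiguities),
      "| unmatched:", nrow(x$unmatched), "\n")
  invisible(x)
}

#' Combine picks from the two complementary 4D experiments
#'
#' The CO-resolved and N-resolved 4Ds each contribute one dimension of the
#' sequential pair. Per strip, every CO pick is co-thresholded with every N
#' pick into a candidate `(CO, N)` combination (height = the weaker of the
#' two); a link then requires both dimensions to match the same target
#' anchor, exactly as [build_links()] enforces.
#'
#' @param picks_co Tibble with `anchor_id`, `CO`, `height`.
#' @param picks_n Tibble with `anchor_id`, `N`, `height`.
#' @return A strips tibble suitable for [build_links()].
#' @export
combine_4d_picks <- function(picks_co, picks_n) {
  stopifnot(all(c("anchor_id", "CO") %in% names(picks_co)),
            all(c("anchor_id", "N") %in% names(picks_n)))
  if (!"height" %in% names(picks_co)) picks_co$height <- 1
  if (!"height" %in% names(picks_n)) picks_n$height <- 1
  dplyr::inner_join(
    dplyr::select(picks_co, "anchor_id", "CO", h_co = "height"),
    dplyr::select(picks_n, "anchor_id", "N", h_n = "height"),
    by = "anchor_id", relationship = "many-to-many"
  ) |>
    dplyr::mutate(height = pmin(.data$h_co, .data$h_n)) |>
    dplyr::select("anchor_id", "CO", "N", "height")
}

#' Assemble sequential chains from the link graph
#'
#' Edges assert successions: a forward edge from strip k to node j asserts
#' that j follows k; a backward edge from strip j to node k asserts the same.
#' An assertion is kept when its reverse agrees or is absent; nodes claimed
#' as successor (or predecessor) by several partners with equal support are
#' conflicts — all competing assertions are dropped and flagged. Chains are
#' the maximal paths of the surviving succession map, ordered by length and
#' then by first node.
#'
#' @param links A `conconnmr_links` from [build_links()].
#' @return A tibble with columns `chain`, `position`, `node`, `residue`
#'   (NA for bridge nodes), `type`; conflicts are attached as the
#'   `"conflicts"` attribute.
#' @export
assemble_chains <- function(links) {
  stopifnot(inherits(links, "conconnmr_links"))
  e <- links$edges
  res_of <- setNames(links$anchors$residue, links$anchors$id)
  succession <- function(sub) {
    if (!nrow(sub)) return(sub[0, c("from", "to")])
    tibble(
      pred = ifelse(sub$direction == "forward", sub$from, sub$to),
      succ = ifelse(sub$direction == "forward", sub$to, sub$from)
    )
  }
  conflicts <- tibble(node = character(0), role = character(0))
  resolve <- function(asr, conflicts) {
    if (!nrow(asr)) return(list(map = tibble(pred = character(0), succ = character(0)),
                                conflicts = conflicts))
    asr <- dplyr::count(asr, .data$pred, .data$succ, name = "support")
    asr <- asr |>
      dplyr::group_by(.data$pred) |>
      dplyr::filter(.data$support == max(.data$support)) |>
      dplyr::ungroup()
    dup_p <- asr$pred[duplicated(asr$pred)]
    if (length(dup_p)) {
      conflicts <- dplyr::bind_rows(conflicts,
                                    tibble(node = unique(dup_p), role = "successor"))
      asr <- asr[!asr$pred %in% dup_p, ]
    }
    asr <- asr |>
      dplyr::group_by(.data$succ) |>
      dplyr::filter(.data$support == max(.data$support)) |>
      dplyr::ungroup()
    dup_s <- asr$succ[duplicated(asr$succ)]
    if (length(dup_s)) {
      conflicts <- dplyr::bind_rows(conflicts,
                                    tibble(node = unique(dup_s), role = "predecessor"))
      asr <- asr[!asr$succ %in% dup_s, ]
    }
    list(map = asr, conflicts = conflicts)
  }
  # anchors whose strip is entirely absent cannot be walked through: their own
  # cross-peaks were never observed, so successions touching them are dropped
  # (their HNCO pair still serves as a match target for scoring)
  walkable <- links$anchors$id[links$anchors$has_strip]
  node_ok <- function(x) x %in% walkable | x %in% links$bridges$id
  # direct strip-to-strip links are primary evidence; bridge successions only
  # fill slots no anchor edge claims
  prim <- succession(e[e$to_type == "anchor", , drop = FALSE])
  if (nrow(prim)) prim <- prim[node_ok(prim$pred) & node_ok(prim$succ), , drop = FALSE]
  prim <- resolve(prim, conflicts)
  conflicts <- prim$conflicts
  brg <- succession(e[e$to_type == "bridge", , drop = FALSE])
  if (nrow(brg)) {
    brg <- brg[!(brg$pred %in% prim$map$pred) & !(brg$succ %in% prim$map$succ), ,
               drop = FALSE]
    sec <- resolve(brg, conflicts)
    conflicts <- sec$conflicts
    map_tbl <- dplyr::bind_rows(prim$map, sec$map)
  } else {
    map_tbl <- prim$map
  }
  succ_map <- setNames(map_tbl$succ, map_tbl$pred)
  nodes <- c(links$anchors$id[links$anchors$has_strip], links$bridges$id)
  starts <- setdiff(nodes, unname(succ_map))
  # deterministic start order: by residue where known, then label
  start_res <- res_of[starts]
  starts <- starts[order(is.na(start_res), start_res, starts)]
  chains <- list()
  seen <- character(0)
  for (s in starts) {
    path <- s
    while (tail(path, 1) %in% names(succ_map)) {
      nxt <- succ_map[[tail(path, 1)]]
      if (nxt %in% path) break # cycle guard
      path <- c(path, nxt)
    }
    seen <- c(seen, path)
    chains[[length(chains) + 1]] <- path
  }
  # an isolated bridge is not a chain: it is an orphan pair with no strip
  chains <- purrr::keep(chains, function(p) {
    length(p) > 1 || !(p[1] %in% links$bridges$id)
  })
  ord <- order(-vapply(chains, length, integer(1)),
               vapply(chains, `[`, character(1), 1))
  chains <- chains[ord]
  out <- purrr::imap_dfr(chains, function(p, ci) {
    tibble(chain = ci, position = seq_along(p), node = p,
           residue = unname(res_of[p]),
           type = ifelse(p %in% links$bridges$id, "bridge", "anchor"))
  })
  attr(out, "conflicts") <- conflicts
  out
}

#' Score forward and backward link recovery against ground truth
#'
#' Mirrors the published bookkeeping: for each direction, the number of
#' sequential pairs correctly linked over the number of pairs linkable in
#' principle (see [linkable_pairs()]), formatted `"NN % (m/e)"`. A
#' non-proline pair `(i-1, i)` is forward-matched when the accepted forward
#' edge from strip `i-1` points at anchor `i` (backward: strip `i+1` at
#' anchor `i`); a proline pair is matched when a bridge node carries the
#' forward edge from strip `i-1` and the backward edge from strip `i+1`.
#'
#' @param links A `conconnmr_links`.
#' @param truth The ground-truth shift table.
#' @param experiment The experiment ([experiment_spec()] or name).
#' @return A tibble of class `conconnmr_linkstats` with columns `direction`,
#'   `matched`, `eligible`, `percentage`, `label`.
#' @export
score_links <- function(links, truth, experiment) {
  if (is.character(experiment)) experiment <- experiment_spec(experiment)
  aa <- truth$aa
  res_of <- setNames(links$anchors$residue, links$anchors$id)
  e <- links$edges
  edge_res <- function(direction) {
    sub <- e[e$direction == direction & e$to_type == "anchor", , drop = FALSE]
    cbind(from = unname(res_of[sub$from]), to = unname(res_of[sub$to]))
  }
  fwd <- edge_res("forward")
  bwd <- edge_res("backward")
  bridge_ok <- function(i) {
    # bridge carrying forward from i-1 and backward from i+1
    eb <- e[e$to_type == "bridge", , drop = FALSE]
    if (!nrow(eb)) return(FALSE)
    f <- eb$to[eb$direction == "forward" & res_of[eb$from] == i - 1L]
    b <- eb$to[eb$direction == "backward" & res_of[eb$from] == i + 1L]
    length(intersect(f, b)) > 0
  }
  one <- function(direction) {
    elig <- linkable_pairs(truth, experiment, direction)
    matched <- vapply(elig$i, function(i) {
      if (aa[i] == "P") return(bridge_ok(i))
      if (direction == "forward") {
        any(fwd[, "from"] == i - 1L & fwd[, "to"] == i)
      } else {
        any(bwd[, "from"] == i + 1L & bwd[, "to"] == i)
      }
    }, logical(1))
    tibble(direction = direction, matched = sum(matched), eligible = nrow(elig))
  }
  out <- dplyr::bind_rows(one("forward"), one("backward"))
  out$percentage <- round(100 * out$matched / pmax(out$eligible, 1))
  out$label <- sprintf("%d %% (%d/%d)", out$percentage, out$matched, out$eligible)
  class(out) <- c("conconnmr_linkstats", class(out))
  out
}

#' @export
print.conconnmr_linkstats <- function(x, ...) {
  cat(sprintf("%-15s %s\n", "Forward links", x$label[x$direction == "forward"]))
  cat(sprintf("%-15s %s\n", "Backwards links", x$label[x$direction == "backward"]))
  invisible(x)
}

#' Tidy the edges of a link graph
#'
#' @param x A `conconnmr_links`.
#' @param ... Unused.
#' @return The edge tibble with residue annotations.
#' @method tidy conconnmr_links
#' @export
tidy.conconnmr_links <- function(x, ...) {
  res_of <- setNames(x$anchors$residue, x$anchors$id)
  dplyr::mutate(x$edges,
                from_residue = unname(res_of[.data$from]),
                to_residue = unname(res_of[.data$to]))
}

#' One-row summary of a link graph
#'
#' @param x A `conconnmr_links`.
#' @param ... Unused.
#' @return A one-row tibble with node/edge/bridge/ambiguity counts.
#' @method glance conconnmr_links
#' @export
glance.conconnmr_links <- function(x, ...) {
  tibble(
    n_anchors = nrow(x$anchors),
    n_with_diagonal = sum(x$anchors$has_diagonal),
    n_edges = nrow(x$edges),
    n_forward = sum(x$edges$direction == "forward"),
    n_backward = sum(x$edges$direction == "backward"),
    n_bridges = nrow(x$bridges),
    n_ambiguous = if (is.null(x$ambiguities)) 0L else nrow(x$ambiguities),
    n_unmatched = nrow(x$unmatched)
  )
}

#' Export the assignment map
#'
#' Per-residue bookkeeping of what the run assigned: the sequential pair
#' `(CO(i-1), N(i))` fully assigned, only its CO, only its N, or nothing.
#'
#' @param links A `conconnmr_links`.
#' @param truth Ground-truth shift table.
#' @param experiment The experiment.
#' @return A tibble `residue`, `aa`, `CO_prev`, `N`, `status`.
#' @export
assignment_map <- function(links, truth, experiment) {
  if (is.character(experiment)) experiment <- experiment_spec(experiment)
  aa <- truth$aa
  n <- length(aa)
  res_of <- setNames(links$anchors$residue, links$anchors$id)
  linked_f <- linked_set(links, truth, experiment, "forward")
  linked_b <- linked_set(links, truth, experiment, "backward")
  diag_ok <- links$anchors$residue[links$anchors$has_diagonal]
  purrr::map_dfr(2:n, function(i) {
    pair_seen <- (i %in% diag_ok) || (i %in% linked_f) || (i %in% linked_b)
    status <- if (pair_seen) "pair" else "none"
    tibble(residue = i, aa = aa[i],
           CO_prev = truth$CO[i - 1L], N = truth$N[i],
           status = status)
  })
}

linked_set <- function(links, truth, experiment, direction) {
  elig <- linkable_pairs(truth, experiment, direction)
  # recompute per-pair match (same rule as score_links)
  aa <- truth$aa
  res_of <- setNames(links$anchors$residue, links$anchors$id)
  e <- links$edges
  keep <- vapply(elig$i, function(i) {
    if (aa[i] == "P") {
      eb <- e[e$to_type == "bridge", , drop = FALSE]
      if (!nrow(eb)) return(FALSE)
      f <- eb$to[eb$direction == "forward" & res_of[eb$from] == i - 1L]
      b <- eb$to[eb$direction == "backward" & res_of[eb$from] == i + 1L]
      return(length(intersect(f, b)) > 0)
    }
    sub <- e[e$direction == direction & e$to_type == "anchor", , drop = FALSE]
    if (direction == "forward") {
      any(res_of[sub$from] == i - 1L & res_of[sub$to] == i)
    } else {
      any(res_of[sub$from] == i + 1L & res_of[sub$to] == i)
    }
  }, logical(1))
  elig$i[keep]
}
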