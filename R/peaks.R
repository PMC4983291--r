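#' Supported experiment definitions
#'
#' The five experiments share the HNCO anchor triple (detected amide proton
#' `HN`, its nitrogen `N`, and the preceding carbonyl `CO`) and differ in the
#' newly resolved dimensions and in where the magnetization starts:
#'
#' * `HNCO_3D` — anchor triple only; the base spectrum.
#' * `HNCOCONH_5D` — amide-proton start; resolved `COres` = CO(i-1) and
#'   `Nres` = N(i). Pairs whose residue i is a proline are never observed
#'   (the start requires an amide proton on residue i).
#' * `HACACONCOCONH_5D` — HA/CA start on residue i-1; proline pairs are
#'   observed and no amide-exchange attenuation applies.
#' * `HACACO_NCO_CONH_4D_CO` / `HACACO_N_CO_CONH_4D_N` — the complementary
#'   "1 + 3" reductions of the HA/CA-start 5D, resolving only CO(i-1) or only
#'   N(i) against the anchor triple.
#'
#' @param name Experiment name (see above).
#' @return An object of class `conconnmr_experiment`: a list with `name`,
#'   `dims` (anchor + resolved dimension labels with nucleus types),
#'   `resolved`, `start` and `hn_start` fields.
#' @examples
#' experiment_spec("HACACONCOCONH_5D")
#' @export
experiment_spec <- function(name = c("HNCO_3D", "HNCOCONH_5D", "HACACONCOCONH_5D",
                                     "HACACO_NCO_CONH_4D_CO", "HACACO_N_CO_CONH_4D_N")) {
  name <- match.arg(name)
  resolved <- switch(name,
    HNCO_3D = character(0),
    HNCOCONH_5D = c("COres", "Nres"),
    HACACONCOCONH_5D = c("COres", "Nres"),
    HACACO_NCO_CONH_4D_CO = "COres",
    HACACO_N_CO_CONH_4D_N = "Nres")
  dims <- tibble(
    label = c("HN", "N", "CO", resolved),
    nucleus = c("H", "N", "C",
                c(COres = "C", Nres = "N")[resolved]),
    role = c(rep("anchor", 3), rep("resolved", length(resolved)))
  )
  structure(list(name = name, dims = dims, resolved = resolved,
                 start = if (name == "HNCOCONH_5D") "HN" else "HACA",
                 hn_start = name == "HNCOCONH_5D"),
            class = "conconnmr_experiment")
}

#' @export
print.conconnmr_experiment <- function(x, ...) {
  cat("<conconnmr experiment>", x$name, "\n")
  cat("  dimensions:", paste0(x$dims$label, " (", x$dims$role, ")", collapse = ", "), "\n")
  cat("  start:", x$start, "\n")
  invisible(x)
}

# residues able to serve as anchor strips: have an amide proton and a
# preceding residue (k >= 2, not proline, not N-terminal)
anchor_residues <- function(aa) {
  which(aa != "P" & seq_along(aa) >= 2L)
}

#' Enumerate the expected peak content of an experiment
#'
#' Walks the coherence pathway of the chosen experiment over a ground-truth
#' shift table. Every anchor residue k (k >= 2, non-proline) contributes an
#' HNCO anchor triple at `(HN_k, N_k, CO_{k-1})`. The 5D/4D experiments add,
#' for each pair residue `i` in `{k-1, k, k+1}` (within the chain), a peak
#' whose resolved coordinates are the sequential pair `(CO_{i-1}, N_i)`, with
#' amplitude given by the CO-CO mixing transfer from source `CO_{i-1}` to the
#' anchor's `CO_{k-1}` (see [chain_transfer()]). For the amide-start 5D the
#' source residue `i` must itself carry an amide proton, so proline pairs are
#' never emitted and the amplitude is multiplied by `exchange_attenuation[i]`;
#' the HA/CA-start experiments emit proline pairs and take no exchange factor.
#' Peaks weaker than `amplitude_floor` times the strongest peak are dropped.
#'
#' @param shifts A shift table from [generate_shifts()] or [read_shift_table()].
#' @param experiment An [experiment_spec()] or its name.
#' @param model A [mixing_model()] supplying transfer amplitudes.
#' @param exchange_attenuation Optional numeric vector (one value per residue,
#'   in `(0, 1]`) modelling amide-proton exchange losses at the start of the
#'   amide-start experiment. Default 1 for every residue.
#' @param amplitude_floor Relative floor below which peaks are dropped.
#'
#' @return A tibble of class `conconnmr_peaks`: one row per peak with the
#'   experiment's dimension columns (ppm), `amplitude`, and provenance columns
#'   `anchor` (residue k), `pair` (residue i), `kind`
#'   (`diagonal`/`forward`/`backward`).
#' @examples
#' sh <- generate_shifts("AAPAA", seed = 1)
#' enumerate_peaks(sh, "HNCO_3D")
#' @export
enumerate_peaks <- function(shifts, experiment, model = mixing_model(),
                            exchange_attenuation = NULL,
                            amplitude_floor = 0.01) {
  validate_shifts(shifts)
  if (is.character(experiment)) experiment <- experiment_spec(experiment)
  stopifnot(inherits(experiment, "conconnmr_experiment"))
  aa <- shifts$aa
  n <- length(aa)
  anchors <- anchor_residues(aa)
  ex <- exchange_attenuation %||% rep(1, n)
  if (length(ex) != n || any(ex <= 0 | ex > 1)) {
    abort("`exchange_attenuation` must give one value in (0, 1] per residue.")
  }

  base <- tibble(
    anchor = anchors, pair = anchors, kind = "diagonal",
    HN = shifts$HN[anchors], N = shifts$N[anchors], CO = shifts$CO[anchors - 1L],
    amplitude = 1
  )
  if (experiment$name == "HNCO_3D") {
    out <- base[, c("HN", "N", "CO", "amplitude", "anchor", "pair", "kind")]
    return(new_peaks(out, experiment))
  }

  rows <- purrr::map_dfr(anchors, function(k) {
    purrr::map_dfr(intersect((k - 1L):(k + 1L), 2:n), function(i) {
      if (experiment$hn_start && (aa[i] == "P")) return(NULL)
      # mixing source is CO_{i-1}; fraction reaching CO_{k-1}
      prof <- chain_transfer(model, chain_length = n, source_index = i - 1L)
      f <- prof$fraction[match(k - i, prof$offset)]
      if (is.na(f)) return(NULL)
      amp <- f * if (experiment$hn_start) ex[i] else 1
      tibble(anchor = k, pair = i,
             kind = c("backward", "diagonal", "forward")[(i - k) + 2L],
             HN = shifts$HN[k], N = shifts$N[k], CO = shifts$CO[k - 1L],
             COres = shifts$CO[i - 1L], Nres = shifts$N[i],
             amplitude = amp)
    })
  })
  keep_cols <- c(experiment$dims$label, "amplitude", "anchor", "pair", "kind")
  rows <- rows[, keep_cols]
  if (nrow(rows) > 0 && amplitude_floor > 0) {
    rows <- rows[rows$amplitude >= amplitude_floor * max(rows$amplitude), ]
  }
  new_peaks(rows, experiment)
}

new_peaks <- function(tbl, experiment) {
  tbl <- as_tibble(tbl)
  attr(tbl, "experiment") <- experiment$name
  class(tbl) <- c("conconnmr_peaks", class(tbl))
  tbl
}

#' Project a 5D peak list onto a complementary 4D experiment
#'
#' The two "1 + 3" 4D experiments are projections of the HA/CA-start 5D:
#' dropping the resolved N(i) dimension gives the CO-resolved 4D and dropping
#' the resolved CO(i-1) dimension gives the N-resolved 4D, with identical
#' provenance and amplitudes.
#'
#' @param peaks A `HACACONCOCONH_5D` peak list.
#' @param which `"CO"` or `"N"`: which resolved dimension the 4D keeps.
#' @return A 4D peak tibble.
#' @export
project_peaks <- function(peaks, which = c("CO", "N")) {
  which <- match.arg(which)
  if (!identical(attr(peaks, "experiment"), "HACACONCOCONH_5D")) {
    abort("`peaks` must come from the HACACONCOCONH_5D experiment.")
  }
  target <- experiment_spec(if (which == "CO") "HACACO_NCO_CONH_4D_CO" else "HACACO_N_CO_CONH_4D_N")
  keep <- c(target$dims$label, "amplitude", "anchor", "pair", "kind")
  new_peaks(as_tibble(peaks)[, keep], target)
}

#' Sequential pairs observable by an experiment
#'
#' Counts the sequential pairs `(i-1, i)` (`i` from 2 to the chain length)
#' that the experiment can show at all: the pair appears on some existing
#' anchor strip in `{i-1, i, i+1}`, and for the amide-start 5D the pair
#' residue `i` must not be a proline. This is the denominator of the link
#' statistics.
#'
#' @param sequence One-letter sequence string (or a shift table).
#' @param experiment An [experiment_spec()] or its name.
#' @return A tibble with columns `i_prev`, `i` (one row per observable pair);
#'   the count is `nrow()` of the result.
#' @examples
#' nrow(eligible_pairs("AAPAA", "HNCOCONH_5D"))      # 3
#' nrow(eligible_pairs("AAPAA", "HACACONCOCONH_5D")) # 4
#' @export
eligible_pairs <- function(sequence, experiment) {
  if (is.character(experiment)) experiment <- experiment_spec(experiment)
  aa <- if (is.data.frame(sequence)) sequence$aa else parse_sequence(sequence)
  n <- length(aa)
  anchors <- anchor_residues(aa)
  ok <- vapply(2:n, function(i) {
    if (experiment$hn_start && aa[i] == "P") return(FALSE)
    length(intersect((i - 1L):(i + 1L), anchors)) > 0
  }, logical(1))
  tibble(i_prev = (2:n)[ok] - 1L, i = (2:n)[ok])
}

#' Direction-specific linkable pairs
#'
#' A pair `(i-1, i)` is *forward-linkable* when the strip of residue `i-1`
#' exists to show it as a forward cross-peak and a match target exists: the
#' strip of residue `i` itself or, for a proline pair under the HA/CA-start
#' experiments, the strip of residue `i+1` (proline bridging needs both
#' flanking strips). Backward-linkable is the mirror image via strip `i+1`.
#' These are the denominators of the per-direction link scores.
#'
#' @inheritParams eligible_pairs
#' @param direction `"forward"` or `"backward"`.
#' @return A tibble with columns `i_prev`, `i`.
#' @export
linkable_pairs <- function(sequence, experiment, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (is.character(experiment)) experiment <- experiment_spec(experiment)
  aa <- if (is.data.frame(sequence)) sequence$aa else parse_sequence(sequence)
  n <- length(aa)
  anchors <- anchor_residues(aa)
  strip <- if (direction == "forward") function(i) i - 1L else function(i) i + 1L
  ok <- vapply(2:n, function(i) {
    if (experiment$hn_start && aa[i] == "P") return(FALSE)
    s <- strip(i)
    if (!(s %in% anchors)) return(FALSE)
    if (aa[i] != "P") return(i %in% anchors)
    # proline pair: bridge requires both flanking strips
    (i - 1L) %in% anchors && (i + 1L) %in% anchors
  }, logical(1))
  tibble(i_prev = (2:n)[ok] - 1L, i = (2:n)[ok])
}

#' Write / read peak lists
#'
#' `write_sparky()` emits the common Sparky list dialect: a header
#' `Assignment w1 w2 ...` and one line per peak, the assignment string
#' encoding the provenance (pair and anchor residues). `write_peaks_tsv()` /
#' `read_peaks_tsv()` are the lossless tabular round-trip carrying every
#' column including amplitudes.
#'
#' @param peaks A peak tibble from [enumerate_peaks()] or [pick_peaks()].
#' @param path Output file.
#' @param shifts Optional shift table used to name residues in assignments.
#' @return The path, invisibly; `read_peaks_tsv()` returns the peak tibble.
#' @export
write_sparky <- function(peaks, path, shifts = NULL) {
  dims <- setdiff(names(peaks), c("amplitude", "anchor", "pair", "kind"))
  aa_of <- function(i) {
    if (is.null(shifts)) "X" else shifts$aa[i]
  }
  assig <- if (all(c("anchor", "pair") %in% names(peaks))) {
    mapply(function(k, i, kind) {
      if (kind == "diagonal" && !("COres" %in% dims) && !("Nres" %in% dims)) {
        sprintf("anchor%s%d", aa_of(k), k)
      } else {
        sprintf("%s%dCO-%s%dN-anchor%s%d", aa_of(i - 1L), i - 1L, aa_of(i), i, aa_of(k), k)
      }
    }, peaks$anchor, peaks$pair, peaks$kind)
  } else {
    sprintf("peak%d", seq_len(nrow(peaks)))
  }
  w <- as.matrix(peaks[, dims, drop = FALSE])
  lines <- c(paste(c(" Assignment", sprintf("w%d", seq_along(dims))), collapse = "  "),
             sprintf("%s  %s", format(assig, width = 28),
                     apply(format(round(w, 4), nsmall = 4), 1, paste, collapse = "  ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sparky
#' @export
write_peaks_tsv <- function(peaks, path) {
  out <- as_tibble(peaks)
  out$experiment <- attr(peaks, "experiment") %||% NA_character_
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sparky
#' @export
read_peaks_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expn <- unique(tab$experiment)
  tab$experiment <- NULL
  tab <- as_tibble(tab)
  if (length(expn) == 1 && !is.na(expn)) attr(tab, "experiment") <- expn
  class(tab) <- c("conconnmr_peaks", class(tab))
  tab
}
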