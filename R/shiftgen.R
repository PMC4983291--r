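#' Random-coil backbone chemical shifts
#'
#' Literature-style random-coil means (ppm) for the backbone nuclei of the 20
#' standard residues, together with the per-nucleus standard deviations used
#' by [generate_shifts()] to emulate the narrow, residue-type-dominated
#' dispersion of intrinsically disordered proteins. These are configuration
#' data for the synthetic generator, not measured values.
#'
#' @return A list with elements `means` (tibble: `aa`, `HN`, `N`, `CO`, `CA`,
#'   `HA`) and `sds` (named numeric per nucleus, ppm).
#' @export
random_coil_shifts <- function() {
  means <- tibble::tribble(
    ~aa,  ~HN,  ~N,    ~CO,   ~CA,  ~HA,
    "A", 8.24, 123.8, 177.8, 52.5, 4.32,
    "R", 8.23, 120.5, 176.3, 56.0, 4.34,
    "N", 8.40, 118.7, 175.2, 53.1, 4.74,
    "D", 8.34, 120.4, 176.3, 54.2, 4.64,
    "C", 8.32, 118.8, 174.6, 58.2, 4.55,
    "Q", 8.32, 119.8, 176.0, 55.7, 4.34,
    "E", 8.42, 120.2, 176.6, 56.6, 4.35,
    "G", 8.33, 108.8, 174.9, 45.1, 3.96,
    "H", 8.42, 118.2, 174.3, 55.0, 4.73,
    "I", 8.00, 119.9, 176.4, 61.1, 4.17,
    "L", 8.16, 121.8, 177.6, 55.1, 4.34,
    "K", 8.29, 120.4, 176.6, 56.2, 4.32,
    "M", 8.28, 119.6, 176.3, 55.4, 4.48,
    "F", 8.30, 120.3, 175.8, 57.7, 4.62,
    "P",   NA, 136.6, 177.3, 63.3, 4.42,
    "S", 8.31, 115.7, 174.6, 58.3, 4.47,
    "T", 8.15, 113.6, 174.7, 61.8, 4.35,
    "W", 8.25, 121.3, 176.1, 57.5, 4.66,
    "Y", 8.12, 120.3, 175.9, 57.9, 4.55,
    "V", 8.03, 119.2, 176.3, 62.2, 4.12
  )
  list(means = means,
       sds = c(HN = 0.25, N = 2.0, CO = 0.8, CA = 0.6, HA = 0.15))
}

# plausibility windows (ppm) enforced on every shift table
shift_windows <- function() {
  list(HN = c(6, 11), N = c(100, 140), CO = c(165, 185),
       CA = c(40, 70), HA = c(3, 6))
}

#' Generate a synthetic ground-truth chemical-shift table
#'
#' Draws each backbone shift from a Gaussian centred on the residue type's
#' random-coil mean with a per-nucleus standard deviation scaled by
#' `dispersion_scale`, emulating the residue-type-dominated dispersion of an
#' IDP. Draws are truncated at three standard deviations and clamped to the
#' plausibility window of each nucleus.
#' Prolines and the N-terminal residue carry no amide proton. Near-degenerate
#' (CO, N) pairs between different residues are allowed and expected; they
#' are the realistic overlap challenge for the assignment stage.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param seed Integer seed; the table is deterministic given
#'   `(sequence, seed, dispersion_scale)`.
#' @param dispersion_scale Multiplier on the per-nucleus standard deviations;
#'   0 returns the random-coil means exactly.
#'
#' @return A tibble of class `conconnmr_shifts` with columns `index`, `aa`,
#'   `HN`, `N`, `CO`, `CA`, `HA`, `is_proline`, `is_n_terminal`,
#'   `is_c_terminal`.
#' @examples
#' generate_shifts("MDVFMKGLSKAKEGVVAAAE", seed = 1)
#' @export
generate_shifts <- function(sequence, seed = 1, dispersion_scale = 1.0) {
  aa <- parse_sequence(sequence)
  n <- length(aa)
  rc <- random_coil_shifts()
  win <- shift_windows()
  rows <- match(aa, rc$means$aa)
  tab <- with_seed(child_seed(seed, 101), {
    draws <- lapply(c("HN", "N", "CO", "CA", "HA"), function(nuc) {
      mu <- rc$means[[nuc]][rows]
      s <- rc$sds[[nuc]] * dispersion_scale
      x <- mu + rnorm(n, 0, s)
      # truncate at 3 sigma and at the plausibility window
      x <- pmin(pmax(x, mu - 3 * s), mu + 3 * s)
      pmin(pmax(x, win[[nuc]][1]), win[[nuc]][2])
    })
    names(draws) <- c("HN", "N", "CO", "CA", "HA")
    as_tibble(draws)
  })
  out <- dplyr::bind_cols(tibble(index = seq_len(n), aa = aa), tab)
  out$is_proline <- aa == "P"
  out$is_n_terminal <- seq_len(n) == 1L
  out$is_c_terminal <- seq_len(n) == n
  out$HN[out$is_proline | out$is_n_terminal] <- NA_real_
  out <- validate_shifts(out)
  class(out) <- c("conconnmr_shifts", class(out))
  out
}

parse_sequence <- function(sequence) {
  if (length(sequence) == 1L && is.character(sequence)) {
    aa <- strsplit(toupper(sequence), "")[[1]]
  } else {
    aa <- toupper(as.character(sequence))
  }
  if (length(aa) == 0) abort("`sequence` must be non-empty.")
  ok <- aa %in% random_coil_shifts()$means$aa
  if (!all(ok)) {
    bad <- which(!ok)[1]
    abort(sprintf("unknown residue '%s' at position %d.", aa[bad], bad))
  }
  aa
}

#' Validate a chemical-shift table
#'
#' Checks the structural invariants of a shift table: prolines and the
#' N-terminal residue carry no HN; every other residue does; all shifts lie
#' within their nucleus's plausibility window (HN 6-11, N 100-140, CO
#' 165-185, CA 40-70, HA 3-6 ppm).
#'
#' @param shifts A shift table (tibble with the [generate_shifts()] columns).
#' @return The table, invisibly classed, or an error describing the violation.
#' @export
validate_shifts <- function(shifts) {
  need <- c("index", "aa", "HN", "N", "CO", "CA", "HA")
  miss <- setdiff(need, names(shifts))
  if (length(miss)) abort(paste("shift table lacks columns:", paste(miss, collapse = ", ")))
  if (!"is_proline" %in% names(shifts)) shifts$is_proline <- shifts$aa == "P"
  if (!"is_n_terminal" %in% names(shifts)) shifts$is_n_terminal <- shifts$index == min(shifts$index)
  if (!"is_c_terminal" %in% names(shifts)) shifts$is_c_terminal <- shifts$index == max(shifts$index)
  no_hn <- shifts$is_proline | shifts$is_n_terminal
  if (any(!is.na(shifts$HN[no_hn]))) {
    abort(sprintf("residue %d is proline or N-terminal but carries an HN shift.",
                  shifts$index[no_hn & !is.na(shifts$HN)][1]))
  }
  if (any(is.na(shifts$HN[!no_hn]))) {
    abort(sprintf("residue %d should carry an HN shift but does not.",
                  shifts$index[!no_hn & is.na(shifts$HN)][1]))
  }
  win <- shift_windows()
  for (nuc in names(win)) {
    v <- shifts[[nuc]]
    bad <- !is.na(v) & (v < win[[nuc]][1] | v > win[[nuc]][2])
    if (any(bad)) {
      abort(sprintf("%s shift of residue %d outside the plausible window [%g, %g] ppm.",
                    nuc, shifts$index[bad][1], win[[nuc]][1], win[[nuc]][2]))
    }
  }
  invisible(shifts)
}

#' Read / write shift tables as TSV
#'
#' Tab-separated with header `index aa HN N CO CA HA`; empty cells denote
#' absent shifts. [read_shift_table()] validates the invariants on load and
#' reports the offending line for malformed rows.
#'
#' @param shifts A shift table.
#' @param path File path.
#' @return `read_shift_table()` returns a validated shift-table tibble;
#'   `write_shift_table()` returns `path` invisibly.
#' @export
write_shift_table <- function(shifts, path) {
  readr::write_tsv(shifts[, c("index", "aa", "HN", "N", "CO", "CA", "HA")], path)
  invisible(path)
}

#' @rdname write_shift_table
#' @export
read_shift_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    index = readr::col_integer(), aa = readr::col_character(),
    HN = readr::col_double(), N = readr::col_double(),
    CO = readr::col_double(), CA = readr::col_double(),
    HA = readr::col_double()
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed shift table %s: parse failure at line %d (%s).",
                  path, probs$row[1] + 1L, probs$expected[1]))
  }
  tab <- validate_shifts(as_tibble(tab))
  class(tab) <- c("conconnmr_shifts", class(tab))
  tab
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return One-letter sequence string.
#' @export
read_fasta_sequence <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(seqs) == 0) abort(sprintf("no sequences in %s.", path))
  toupper(as.character(seqs[[1]]))
}

#' Generate a random IDP-like test sequence
#'
#' Uniform over the 19 non-proline residues with a fixed proline fraction
#' (IDPs are proline rich; the disordered test systems here run near 7-10 %),
#' prolines never at the first two or last positions and never consecutive.
#'
#' @param n Sequence length.
#' @param n_proline Number of prolines to place.
#' @param seed Integer seed.
#' @return One-letter sequence string.
#' @export
random_idp_sequence <- function(n, n_proline = round(0.1 * n), seed = 1) {
  if (n < 4) abort("`n` must be at least 4.")
  with_seed(child_seed(seed, 202), {
    non_p <- setdiff(random_coil_shifts()$means$aa, "P")
    aa <- sample(non_p, n, replace = TRUE)
    slots <- 3:(n - 1)
    pos <- integer(0)
    for (p in sample(slots)) {
      if (length(pos) >= n_proline) break
      if (!any(abs(pos - p) <= 1)) pos <- c(pos, p)
    }
    aa[pos] <- "P"
    paste(aa, collapse = "")
  })
}
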