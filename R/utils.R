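# internal helpers shared across modules

# deterministic scoped RNG: run `code` under a local seed without disturbing
# the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream-specific child seed; kept well below .Machine$integer.max
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

#' @export
print.conconnmr_fid <- function(x, ...) {
  cat("<conconnmr time-domain set>\n")
  cat("  axes: ", paste0(x$axes$label, "[", x$axes$n, ifelse(x$axes$nus, ",NUS", ""), "]",
                         collapse = " x "), "\n", sep = "")
  cat("  stored values: ", length(x$values), " (",
      nrow(x$values), " grid cells x ", ncol(x$values), " scheduled points)\n", sep = "")
  invisible(x)
}

#' @export
print.conconnmr_section <- function(x, ...) {
  cat("<conconnmr cross-section> anchor:", x$anchor_label, "\n")
  d <- dim(x$values)
  cat("  grid:", paste(d, collapse = " x "),
      "| max:", format(max(x$values), digits = 4), "\n")
  invisible(x)
}
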