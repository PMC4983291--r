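#' Plot the CON plane of a shift table
#'
#' Scatter of the sequential pairs `(CO(i-1), N(i))` — the plane in which the
#' assignment walk happens; proline pairs highlighted.
#'
#' @param object A shift table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conconnmr_shifts
#' @export
autoplot.conconnmr_shifts <- function(object, ...) {
  n <- nrow(object)
  df <- tibble(
    CO_prev = object$CO[1:(n - 1)],
    N = object$N[2:n],
    proline = object$is_proline[2:n]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$CO_prev, y = .data$N,
                                   colour = .data$proline)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_reverse() + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "CO(i-1) (ppm)", y = "N(i) (ppm)", colour = "proline pair") +
    ggplot2::theme_minimal()
}

#' Plot recovered chains along the sequence
#'
#' One tile per node, coloured by chain membership; bridge nodes (proline
#' pairs) are marked.
#'
#' @param object A `conconnmr_run` with chains.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conconnmr_run
#' @export
autoplot.conconnmr_run <- function(object, ...) {
  if (is.null(object$chains)) abort("run has no assembled chains to plot.")
  df <- object$chains
  df$x <- ifelse(is.na(df$residue),
                 stats::ave(seq_len(nrow(df)), df$chain, FUN = seq_along), df$residue)
  # place bridges between their neighbours
  for (r in which(is.na(df$residue))) {
    nb <- df$residue[df$chain == df$chain[r] &
                       abs(df$position - df$position[r]) == 1]
    if (any(!is.na(nb))) df$x[r] <- mean(nb, na.rm = TRUE)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = factor(.data$chain),
                                   fill = factor(.data$chain))) +
    ggplot2::geom_tile(height = 0.8, width = 1,
                       colour = "white", linewidth = 0.2) +
    ggplot2::geom_point(data = df[df$type == "bridge", , drop = FALSE],
                        ggplot2::aes(x = .data$x, y = factor(.data$chain)),
                        inherit.aes = FALSE, shape = 21, fill = "white") +
    ggplot2::labs(x = "residue", y = "chain") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
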