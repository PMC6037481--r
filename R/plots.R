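#' Plot a cleavage-kinetics fit
#'
#' Observed cleaved fractions with the fitted one-phase (or linear)
#' curve overlaid.
#'
#' @param object A `kobs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kobs_fit
#' @export
autoplot.kobs_fit <- function(object, ...) {
  grid <- tibble(time_s = seq(min(object$data$time_s), max(object$data$time_s),
                              length.out = 200))
  grid$fraction_cleaved <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_s, .data$fraction_cleaved)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (s)", y = "fraction cleaved",
      title = sprintf("k_obs = %.3g +/- %.2g s^-1 (%s fit)",
                      object$k_obs, object$stderr, object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a DMS reactivity profile
#'
#' Per-base normalised DMS signal as bars, A/C bases filled, with the
#' constraint threshold drawn as a dashed line.
#'
#' @param records Normalised reactivity records.
#' @param threshold Constraint threshold to mark (default 0.2).
#' @return A ggplot object.
#' @export
plot_reactivity <- function(records, threshold = 0.2) {
  if (!"normalized_signal" %in% names(records)) records <- normalize_window(records)
  records$reports <- ifelse(records$base %in% c("A", "C"), "A/C", "G/U")
  ggplot2::ggplot(records,
                  ggplot2::aes(.data$position, .data$normalized_signal,
                               fill = .data$reports)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`A/C` = "#2e8b57", `G/U` = "grey70")) +
    ggplot2::labs(x = "position", y = "normalised DMS signal", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Arc diagram of a secondary structure
#'
#' Base pairs drawn as arcs over the sequence line; hairpin loops are
#' visible as arc-free spans under a closing arc.
#'
#' @param seq RNA sequence.
#' @param structure Its `rna_structure`.
#' @return A ggplot object.
#' @export
plot_structure_arcs <- function(seq, structure) {
  seq <- as_rna(seq)
  pt <- structure$pair_table
  ii <- which(pt > seq_along(pt))
  arcs <- if (length(ii)) {
    purrr::map_dfr(ii, function(i) {
      j <- pt[i]
      th <- seq(0, pi, length.out = 40)
      tibble(x = (i + j) / 2 + (j - i) / 2 * cos(th),
             y = (j - i) / 2 * sin(th), pair = paste0(i, "-", j))
    })
  } else {
    tibble(x = numeric(), y = numeric(), pair = character())
  }
  bases <- tibble(x = seq_len(structure$length), y = 0, base = seq_chars(seq))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = arcs, ggplot2::aes(.data$x, .data$y, group = .data$pair),
                       colour = "steelblue") +
    ggplot2::geom_text(data = bases, ggplot2::aes(.data$x, .data$y, label = .data$base),
                       size = 2.6, vjust = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = seq_id(seq))
}
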