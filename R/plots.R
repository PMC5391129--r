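# Plotting and broom-style methods for the result objects.

jet_colours <- c("#000080", "#0000FF", "#00FFFF", "#80FF80", "#FFFF00",
                 "#FF0000", "#800000")

kymo_df <- function(m) {
  Tn <- nrow(m); Xn <- ncol(m)
  tidyr::expand_grid(cycle = seq(0, 1, length.out = Tn),
                     position = seq(0, 1, length.out = Xn)) |>
    dplyr::mutate(intensity = as.vector(t(unclass(m))))
}

#' @describeIn cycle_kymograph Heat-map of a kymograph (cycle time vs
#'   relative position, jet colour code; old pole at 0).
#' @param object A `kymograph`.
#' @param ... Unused.
#' @export
autoplot.kymograph <- function(object, ...) {
  ggplot2::ggplot(kymo_df(object),
                  ggplot2::aes(.data$cycle, .data$position,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = jet_colours) +
    ggplot2::labs(x = "cell cycle (0 = birth, 1 = division)",
                  y = "relative position (0 = old pole)",
                  fill = attr(object, "channel") %||% "intensity") +
    ggplot2::theme_minimal()
}

#' @describeIn consensus_image Heat-map of a consensus image.
#' @param object A `consensus_image`.
#' @param ... Unused.
#' @export
autoplot.consensus_image <- function(object, ...) {
  autoplot.kymograph(object, ...) +
    ggplot2::ggtitle(sprintf("consensus of %d cells",
                             attr(object, "n_cells")))
}

#' @describeIn align_to_septation Focus-count frequency curves around
#'   septation detection.
#' @param object An `aligned_series`.
#' @param min_cells Hide offsets supported by fewer cells (default 5).
#' @param ... Unused.
#' @export
autoplot.aligned_series <- function(object, min_cells = 5, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$n_cells >= min_cells) |>
    dplyr::select("offset", "freq1", "freq2", "freq3p") |>
    tidyr::pivot_longer(-"offset", names_to = "class",
                        values_to = "frequency") |>
    dplyr::mutate(class = dplyr::recode(.data$class, freq1 = "1 focus",
                                        freq2 = "2 foci",
                                        freq3p = "3+ foci"))
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$frequency,
                                   colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c("1 focus" = "#2166AC",
                                            "2 foci" = "#B2182B",
                                            "3+ foci" = "black")) +
    ggplot2::labs(x = "time from septation detection (min)",
                  y = "fraction of cells", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn snapshot_stats Focus position against cell length, split
#'   by constriction state and focus class.
#' @param object A `snapshot_summary`.
#' @param ... Unused.
#' @export
autoplot.snapshot_summary <- function(object, ...) {
  ggplot2::ggplot(object$positions,
                  ggplot2::aes(.data$length_um, .data$x)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$focus_class),
      cols = ggplot2::vars(.data$constricting),
      labeller = ggplot2::labeller(
        constricting = c(`FALSE` = "no indentation",
                         `TRUE` = "constricting"))) +
    ggplot2::labs(x = "cell length (um)",
                  y = "relative long-axis position") +
    ggplot2::theme_minimal()
}

#' @rdname align_to_septation
#' @param x An `aligned_series`.
#' @param ... Unused.
#' @export
tidy.aligned_series <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname snapshot_stats
#' @param x A `snapshot_summary`.
#' @param ... Unused.
#' @export
tidy.snapshot_summary <- function(x, ...) x$classes

#' @rdname snapshot_stats
#' @export
glance.snapshot_summary <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_constricting = sum(x$classes$n_cells[x$classes$constricting]),
    midcell_fraction = if (nrow(x$positions))
      midcell_fraction(x$positions) else NA_real_)
}
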