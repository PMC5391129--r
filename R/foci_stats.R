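#' Fraction of foci in the immediate vicinity of mid-cell
#'
#' A focus counts as mid-cell-proximal when its distance from the cell
#' centre is strictly less than `threshold` cell lengths (default 5% — the
#' neighbourhood of the assembling division apparatus). A focus at exactly
#' the threshold distance is excluded.
#'
#' @param foci A numeric vector of centre distances `d`, or a data frame
#'   with a `d` column (as returned by [detect_foci()]).
#' @param threshold Distance threshold in cell-length fractions.
#' @return The fraction of foci with `d < threshold`.
#' @export
midcell_fraction <- function(foci, threshold = 0.05) {
  d <- if (is.data.frame(foci)) foci$d else foci
  if (!length(d)) stop("no foci supplied.", call. = FALSE)
  mean(d < threshold)
}

focus_class <- function(n) {
  dplyr::case_when(n <= 0 ~ "0", n == 1 ~ "1", n == 2 ~ "2",
                   TRUE ~ "3+")
}

#' Snapshot summary of focus counts and positions
#'
#' Classifies snapshot cell observations by constriction state and focus
#' count (1, 2, 3+ as in snapshot figures) and aggregates counts, the
#' mid-cell fraction per class, and a tidy position-vs-length table.
#'
#' @param cells A tibble with one row per cell and columns `cell_id`,
#'   `length_um`, `constricting` (logical), `n_foci`, and a list-column
#'   `foci_x` of relative focus positions (as from [snapshot_sample()], or
#'   assembled from the imaging pipeline).
#' @param midcell_threshold Threshold for [midcell_fraction()].
#' @return An object of class `snapshot_summary`: list with `classes`
#'   (tibble: `constricting`, `focus_class`, `n_cells`, `n_foci`,
#'   `midcell_fraction`), `positions` (tibble: one row per focus with
#'   `cell_id`, `length_um`, `constricting`, `focus_class`, `x`, `d`), and
#'   `n_cells`.
#' @export
snapshot_stats <- function(cells, midcell_threshold = 0.05) {
  cells <- tibble::as_tibble(cells)
  if (!nrow(cells)) {
    return(structure(list(
      classes = tibble::tibble(constricting = logical(),
                               focus_class = character(),
                               n_cells = integer(), n_foci = integer(),
                               midcell_fraction = numeric()),
      positions = tibble::tibble(cell_id = character(),
                                 length_um = numeric(),
                                 constricting = logical(),
                                 focus_class = character(),
                                 x = numeric(), d = numeric()),
      n_cells = 0L), class = "snapshot_summary"))
  }
  cells <- dplyr::mutate(cells, focus_class = focus_class(.data$n_foci))
  positions <- cells |>
    dplyr::select("cell_id", "length_um", "constricting", "focus_class",
                  "foci_x") |>
    tidyr::unnest_longer("foci_x", values_to = "x") |>
    dplyr::mutate(d = abs(.data$x - 0.5))
  classes <- cells |>
    dplyr::group_by(.data$constricting, .data$focus_class) |>
    dplyr::summarise(n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      positions |>
        dplyr::group_by(.data$constricting, .data$focus_class) |>
        dplyr::summarise(
          n_foci = dplyr::n(),
          midcell_fraction = mean(.data$d < midcell_threshold),
          .groups = "drop"),
      by = c("constricting", "focus_class")) |>
    dplyr::mutate(n_foci = dplyr::coalesce(.data$n_foci, 0L)) |>
    dplyr::arrange(.data$constricting, .data$focus_class)
  structure(list(classes = classes, positions = positions,
                 n_cells = nrow(cells)),
            class = "snapshot_summary")
}

#' @export
print.snapshot_summary <- function(x, ...) {
  cat("<snapshot_summary>", x$n_cells, "cells\n")
  print(x$classes)
  invisible(x)
}

#' Align single-cell focus-count series on septation detection
#'
#' Re-indexes each cell's time so that the frame at which septation was
#' first detected becomes offset 0, then computes, per offset, the
#' frequencies of 1-, 2- and 3-plus-focus cells, the median focus position
#' per class, and the number of at-risk (single-focus) cells, over the
#' cells contributing at that offset.
#'
#' @param obs Tibble of per-cell per-frame observations: `cell_id`,
#'   `frame`, `n_foci`.
#' @param sept Tibble of septation calls: `cell_id`, `sept_frame`. Cells
#'   without a call are dropped; an error is raised if none remains.
#' @param frame_interval Minutes between frames.
#' @param foci Optional tibble (`cell_id`, `frame`, `x`) of focus positions
#'   (old pole = 0) for the per-class median positions.
#' @return An object of class `aligned_series`: a tibble with one row per
#'   time offset (`offset` in minutes, on the frame-interval lattice):
#'   `n_cells`, `n1`, `n2`, `n3p`, `freq1`, `freq2`, `freq3p`,
#'   `n_at_risk`, and `median_x1`, `median_x2`, `median_x3p`. The
#'   attribute `"percell"` retains the per-cell offset table used by
#'   [duplication_rate()]; `"frame_interval"` the lattice spacing.
#' @export
align_to_septation <- function(obs, sept, frame_interval, foci = NULL) {
  sept <- dplyr::filter(sept, !is.na(.data$sept_frame))
  if (!nrow(sept)) {
    stop("no cell has a septation call; nothing to align.", call. = FALSE)
  }
  percell <- obs |>
    dplyr::inner_join(dplyr::select(sept, "cell_id", "sept_frame"),
                      by = "cell_id") |>
    dplyr::mutate(
      offset = (.data$frame - .data$sept_frame) * frame_interval,
      focus_class = focus_class(.data$n_foci))
  if (!is.null(foci)) {
    foci <- foci |>
      dplyr::inner_join(dplyr::select(sept, "cell_id", "sept_frame"),
                        by = "cell_id") |>
      dplyr::mutate(
        offset = (.data$frame - .data$sept_frame) * frame_interval) |>
      dplyr::inner_join(
        dplyr::select(percell, "cell_id", "frame", "focus_class"),
        by = c("cell_id", "frame"))
  }
  out <- percell |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n1 = sum(.data$n_foci == 1),
      n2 = sum(.data$n_foci == 2),
      n3p = sum(.data$n_foci >= 3),
      .groups = "drop") |>
    dplyr::mutate(
      freq1 = .data$n1 / .data$n_cells,
      freq2 = .data$n2 / .data$n_cells,
      freq3p = .data$n3p / .data$n_cells,
      n_at_risk = .data$n1) |>
    dplyr::arrange(.data$offset)
  if (!is.null(foci)) {
    med <- foci |>
      dplyr::group_by(.data$offset, .data$focus_class) |>
      dplyr::summarise(median_x = median(.data$x), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "focus_class",
                         values_from = "median_x",
                         names_prefix = "median_x") |>
      dplyr::rename_with(~ sub("median_x3\\+", "median_x3p", .x))
    out <- dplyr::left_join(out, med, by = "offset")
  }
  for (col in c("median_x1", "median_x2", "median_x3p")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  structure(out, class = c("aligned_series", class(out)),
            percell = percell, frame_interval = frame_interval)
}

#' Rate of new sister-locus duplication events
#'
#' The percentage of at-risk (single-focus) cells per minute that gain a
#' second focus between a given offset and the next frame. To guard
#' against detection blinking, a 1-to-2 transition only counts when the
#' cell still shows two or more foci one further frame later (or is no
#' longer observed then).
#'
#' @param aligned An `aligned_series` from [align_to_septation()].
#' @param at_offset Offset (minutes from septation detection) at which to
#'   evaluate the rate.
#' @return Duplication rate in percent per minute.
#' @export
duplication_rate <- function(aligned, at_offset) {
  percell <- attr(aligned, "percell")
  dt <- attr(aligned, "frame_interval")
  now <- dplyr::filter(percell, .data$offset == at_offset)
  at_risk <- dplyr::filter(now, .data$n_foci == 1)
  if (!nrow(at_risk)) {
    stop("no at-risk (single-focus) cells at this offset.", call. = FALSE)
  }
  nxt <- dplyr::filter(percell, .data$offset == at_offset + dt) |>
    dplyr::select("cell_id", n_next = "n_foci")
  nxt2 <- dplyr::filter(percell, .data$offset == at_offset + 2 * dt) |>
    dplyr::select("cell_id", n_next2 = "n_foci")
  tr <- at_risk |>
    dplyr::inner_join(nxt, by = "cell_id") |>
    dplyr::left_join(nxt2, by = "cell_id") |>
    dplyr::mutate(dup = .data$n_next >= 2 &
                    (is.na(.data$n_next2) | .data$n_next2 >= 2))
  if (!nrow(tr)) {
    stop("no at-risk cell is observed at the next offset.", call. = FALSE)
  }
  100 * sum(tr$dup) / nrow(tr) / dt
}
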